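#' Average contact-probability maps into an ensemble prediction
#'
#' The ensembling rule: the per-pair arithmetic mean of the members'
#' contact probabilities. Under the default `zero_fill` policy a pair a
#' member never reported contributes 0 to the mean (RR submissions list
#' only confident pairs, so absent means "not predicted in contact"). Under
#' `average_available` each pair is averaged only over the members that
#' report it with nonzero probability — appropriate for distogram-derived
#' maps, where every pair is defined.
#'
#' @param members List of [contact_map()] objects for the same target.
#' @param policy `"zero_fill"` (default) or `"average_available"`.
#' @param name Target/ensemble identifier for the output map; defaults to
#'   the members' common target id.
#' @return A [contact_map()].
#' @examples
#' a <- contact_map("t", matrix(c(0, .2, .2, 0), 2))
#' b <- contact_map("t", matrix(c(0, .8, .8, 0), 2))
#' ensemble_mean(list(a, b))$p[1, 2]  # 0.5
#' @export
ensemble_mean <- function(members, policy = c("zero_fill",
                                              "average_available"),
                          name = NULL) {
  policy <- match.arg(policy)
  if (!length(members)) stop("empty member list", call. = FALSE)
  stopifnot(all(vapply(members, inherits, logical(1), "contact_map")))
  Ls <- vapply(members, function(m) m$L, numeric(1))
  if (length(unique(Ls)) != 1) {
    stop("members disagree on L: ", paste(unique(Ls), collapse = ", "),
         call. = FALSE)
  }
  ids <- unique(vapply(members, function(m) m$target_id, character(1)))
  if (length(ids) != 1) {
    stop("members belong to different targets: ",
         paste(ids, collapse = ", "), call. = FALSE)
  }
  total <- Reduce(`+`, lapply(members, function(m) m$p))
  if (policy == "zero_fill") {
    p <- total / length(members)
  } else {
    count <- Reduce(`+`, lapply(members, function(m) (m$p > 0) * 1L))
    p <- total / pmax(count, 1L)
  }
  seqs <- Filter(Negate(is.null), lapply(members, function(m) m$sequence))
  contact_map(name %||% ids, p,
              sequence = if (length(seqs)) seqs[[1]] else NULL)
}

#' Rank prediction methods by overall accuracy
#'
#' @param accuracy Named numeric vector: overall (across-class mean)
#'   accuracy per method.
#' @return Character vector of method ids, best first; ties broken by
#'   method id ascending.
#' @export
rank_methods <- function(accuracy) {
  if (!length(accuracy) || is.null(names(accuracy))) {
    stop("accuracy must be a non-empty named vector", call. = FALSE)
  }
  if (any(!is.finite(accuracy))) {
    stop("every method needs a finite overall accuracy", call. = FALSE)
  }
  names(accuracy)[order(-accuracy, names(accuracy))]
}

#' Select the top fraction of a ranked method list
#'
#' Takes the first `ceiling(fraction * n)` methods — the rounding that maps
#' a top-20% cut of 33 methods to 7 members.
#'
#' @param ranked Character vector of method ids, best first.
#' @param fraction Fraction in `(0, 1]`.
#' @return The leading methods.
#' @examples
#' select_top_fraction(paste0("m", 1:33), 0.2)  # 7 methods
#' @export
select_top_fraction <- function(ranked, fraction) {
  if (!length(ranked)) stop("empty method list", call. = FALSE)
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction <= 0 || fraction > 1) {
    stop("fraction must lie in (0, 1]", call. = FALSE)
  }
  utils::head(ranked, ceiling(fraction * length(ranked)))
}
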