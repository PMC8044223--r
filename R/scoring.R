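#' Raw top-L precision of a predicted contact set
#'
#' Since contact predictors make no negative predictions, accuracy reduces
#' to precision, `TP / (TP + FP)`. Predicted pairs that cannot be verified
#' (either residue unresolved in the structure, i.e. `NA` in the label
#' distance matrix) are removed before counting, so an unverifiable
#' prediction is neither rewarded nor punished.
#'
#' @param predicted A `contact_set` (e.g. from [top_l()]), all pairs of
#'   class `cls`.
#' @param labels A [build_labels()] result for the same target.
#' @param cls The separation class being scored.
#' @return A list with `tp`, `fp`, `n_scored` (pairs remaining after
#'   dropping unverifiable ones) and `precision` (0 when nothing is
#'   scoreable).
#' @export
raw_precision <- function(predicted, labels, cls) {
  stopifnot(inherits(labels, "label_set"))
  cls <- match.arg(cls, contact_classes())
  if (nrow(predicted) && any(predicted$class != cls)) {
    stop("predicted set contains pairs outside class '", cls, "'",
         call. = FALSE)
  }
  if (nrow(predicted)) {
    verifiable <- !is.na(labels$distances[cbind(predicted$i, predicted$j)])
    predicted <- predicted[verifiable, , drop = FALSE]
  }
  truth <- labels$contacts[labels$contacts$class == cls, , drop = FALSE]
  tp <- sum(pair_key(predicted$i, predicted$j) %in%
              pair_key(truth$i, truth$j))
  n <- nrow(predicted)
  list(tp = tp, fp = n - tp, n_scored = n,
       precision = if (n > 0) tp / n else 0)
}

#' Ceiling-normalized top-L accuracy
#'
#' A target-class with fewer than `L` true contacts cannot reach precision
#' 1 under top-L selection; its best achievable precision (the ceiling) is
#' `min(1, n_true / L)`. The normalized score divides raw precision by this
#' ceiling, which is equivalent to `TP / min(L, n_true)`, so every
#' target-class is scored on a 0-to-1 scale. A class with no true contacts
#' is undefined (`NA`) and skipped in averages.
#'
#' @param tp True-positive count.
#' @param n_selected Number of predictions scored (`min(L,` eligible
#'   pairs`)`).
#' @param n_true Number of true contacts of the class.
#' @param L The top-L selection size (target sequence length).
#' @return Normalized score in `[0, 1]`, or `NA` when `n_true` is 0.
#' @examples
#' normalized_accuracy(tp = 40, n_selected = 50, n_true = 80, L = 50)  # 0.8
#' @export
normalized_accuracy <- function(tp, n_selected, n_true, L) {
  stopifnot(tp >= 0, n_true >= 0, L >= 1)
  if (n_true == 0) return(NA_real_)
  tp / min(L, n_true)
}

#' Evaluate one contact map against a target's labels
#'
#' Runs the standard evaluation for one method on one target: top-L
#' selection per separation class, raw precision with unverifiable pairs
#' dropped, the per-class ceiling, and the normalized accuracy; the overall
#' score is the mean of the defined per-class normalized accuracies.
#'
#' @param map A [contact_map()].
#' @param labels A [build_labels()] result for the same target.
#' @param L Top-L selection size; defaults to the label set's sequence
#'   length.
#' @return An object of class `evaluation_result`: a data frame with one
#'   row per class (`class`, `tp`, `fp`, `n_selected`, `n_true`,
#'   `raw_precision`, `ceiling`, `normalized_accuracy`) and attributes
#'   `target_id` and `overall`.
#' @export
evaluate_map <- function(map, labels, L = labels$L) {
  stopifnot(inherits(map, "contact_map"), inherits(labels, "label_set"))
  if (map$L != labels$L) {
    stop("map L = ", map$L, " does not match labels L = ", labels$L,
         call. = FALSE)
  }
  rows <- lapply(contact_classes(), function(cls) {
    sel <- top_l(map, L, cls)
    pr <- raw_precision(sel, labels, cls)
    n_true <- unname(labels$n_true[cls])
    data.frame(class = cls, tp = pr$tp, fp = pr$fp,
               n_selected = pr$n_scored, n_true = n_true,
               raw_precision = pr$precision,
               ceiling = min(1, n_true / L),
               normalized_accuracy =
                 normalized_accuracy(pr$tp, pr$n_scored, n_true, L),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "target_id") <- labels$target_id
  attr(out, "L") <- L
  attr(out, "overall") <- mean(out$normalized_accuracy, na.rm = TRUE)
  class(out) <- c("evaluation_result", "data.frame")
  out
}

#' Aggregate per-target evaluations into a method summary
#'
#' The two-stage (macro) average: for each separation class, the mean of
#' that class's normalized accuracy over the targets where it is defined
#' (targets with no true contacts of a class are skipped for that class);
#' the overall score is the mean of the three per-class means. A pooled
#' micro average (summed TP over summed `min(L, n_true)` per class) is
#' available for comparison.
#'
#' @param results List of [evaluate_map()] results (one per target).
#' @param micro If `TRUE`, pool counts across targets instead of averaging
#'   per-target scores.
#' @return A list with `per_class` (named mean normalized accuracy),
#'   `overall`, and `n_targets`.
#' @export
aggregate_evaluations <- function(results, micro = FALSE) {
  if (!length(results)) stop("no evaluation results", call. = FALSE)
  Ls <- vapply(results, function(r) attr(r, "L") %||% NA_real_, numeric(1))
  per_class <- vapply(contact_classes(), function(cls) {
    rows <- do.call(rbind, lapply(results, function(r) {
      r[r$class == cls, , drop = FALSE]
    }))
    defined <- rows$n_true > 0
    if (!any(defined)) return(NA_real_)
    if (micro) {
      sum(rows$tp[defined]) / sum(pmin(Ls[defined], rows$n_true[defined]))
    } else {
      mean(rows$normalized_accuracy[defined])
    }
  }, numeric(1))
  if (all(is.na(per_class))) {
    stop("no target-class had any true contacts; nothing to aggregate",
         call. = FALSE)
  }
  list(per_class = per_class,
       overall = mean(per_class, na.rm = TRUE),
       n_targets = length(results))
}

#' Jaccard distance between two contact sets
#'
#' `d_j = (|A union B| - |A intersect B|) / |A union B|`: 0 for identical
#' sets, 1 for disjoint nonempty sets. Two empty sets are at distance 0.
#' Both sets must belong to the same target and should carry the same class
#' restriction (e.g. both long-range top-L sets, or both the union over
#' classes).
#'
#' @param A,B `contact_set` data frames.
#' @return Jaccard distance in `[0, 1]`.
#' @export
jaccard_distance <- function(A, B) {
  ta <- attr(A, "target_id"); tb <- attr(B, "target_id")
  if (!is.null(ta) && !is.null(tb) && !identical(ta, tb)) {
    stop("contact sets belong to different targets: ", ta, " vs ", tb,
         call. = FALSE)
  }
  a <- unique(pair_key(A$i, A$j))
  b <- unique(pair_key(B$i, B$j))
  u <- length(union(a, b))
  if (u == 0) return(0)
  (u - length(intersect(a, b))) / u
}

#' Pairwise per-class Jaccard distances between methods
#'
#' For every pair of methods, computes the Jaccard distance between their
#' top-L contact sets in each separation class plus the unweighted mean of
#' the three class distances — the shape of the standard method-similarity
#' table.
#'
#' @param method_sets Named list; each element is itself a list of
#'   `contact_set`s keyed by class name (as produced by [top_l()] per
#'   class).
#' @return Data frame with columns `method_a`, `method_b`, one column per
#'   class, and `average`.
#' @export
jaccard_table <- function(method_sets) {
  stopifnot(length(method_sets) >= 2, !is.null(names(method_sets)))
  ids <- names(method_sets)
  combs <- utils::combn(ids, 2)
  rows <- lapply(seq_len(ncol(combs)), function(k) {
    a <- combs[1, k]; b <- combs[2, k]
    d <- vapply(contact_classes(), function(cls) {
      jaccard_distance(method_sets[[a]][[cls]], method_sets[[b]][[cls]])
    }, numeric(1))
    cbind(data.frame(method_a = a, method_b = b,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(d)), average = mean(d))
  })
  do.call(rbind, rows)
}
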