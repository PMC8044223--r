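#' Contact-probability maps
#'
#' The common currency of contact prediction: a symmetric `L x L` matrix of
#' per-pair contact probabilities with zero diagonal. Pairs a method never
#' reported hold probability 0 (CASP groups submit only confident pairs, and
#' ensemble averaging needs a defined value for every pair).
#'
#' @param target_id Target identifier.
#' @param p Numeric `L x L` matrix, entries in `[0, 1]`, symmetric.
#' @param sequence Optional amino-acid sequence of length L.
#' @return An object of class `contact_map` with fields `target_id`, `L`,
#'   `p`, `sequence`.
#' @export
contact_map <- function(target_id, p, sequence = NULL) {
  if (!is.matrix(p) || nrow(p) != ncol(p)) {
    stop("p must be a square matrix", call. = FALSE)
  }
  if (any(p < 0) || any(p > 1)) {
    stop("contact probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (max(abs(p - t(p))) > 1e-9) {
    stop("contact map must be symmetric", call. = FALSE)
  }
  diag(p) <- 0
  L <- nrow(p)
  if (!is.null(sequence)) {
    sequence <- toupper(as.character(sequence)[1])
    if (nchar(sequence) != L) {
      stop("sequence length ", nchar(sequence), " does not match L = ", L,
           call. = FALSE)
    }
  }
  structure(list(target_id = as.character(target_id)[1], L = L, p = p,
                 sequence = sequence),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("contact_map for target '%s': L = %d, %d nonzero pairs\n",
              x$target_id, x$L, sum(x$p[upper.tri(x$p)] > 0)))
  invisible(x)
}

#' Sequence-separation class of a residue pair
#'
#' Contacts are grouped by the sequence separation `s = |i - j|` of the two
#' residues: pairs separated by 6 to 11 residues are short-range, 12 to 23
#' mid-range, and 24 or more long-range. Pairs closer than 6 residues along
#' the chain are excluded from evaluation.
#'
#' @param i,j 1-based residue indices (vectorized).
#' @return Character vector over `"short"`, `"mid"`, `"long"`, `"excluded"`.
#' @examples
#' separation_class(10, 16)  # "short" (separation 6)
#' separation_class(1, 25)   # "long" (separation 24)
#' @export
separation_class <- function(i, j) {
  if (any(i == j)) stop("invalid pair: i equals j", call. = FALSE)
  s <- abs(i - j)
  out <- rep("excluded", length(s))
  out[s >= 6 & s <= 11] <- "short"
  out[s >= 12 & s <= 23] <- "mid"
  out[s >= 24] <- "long"
  out
}

#' The three contact classes, in canonical order
#' @export
contact_classes <- function() c("short", "mid", "long")

# Build a contact-set data.frame (the canonical representation of a finite
# set of declared contacts): columns i, j (i < j), class, prob.
contact_set <- function(target_id, i, j, prob = rep(NA_real_, length(i)),
                        class = separation_class(i, j)) {
  stopifnot(length(i) == length(j))
  df <- data.frame(i = as.integer(pmin(i, j)), j = as.integer(pmax(i, j)),
                   class = class, prob = as.numeric(prob),
                   stringsAsFactors = FALSE)
  attr(df, "target_id") <- as.character(target_id)[1]
  class(df) <- c("contact_set", "data.frame")
  df
}

#' Select the top-L most probable contacts of a separation class
#'
#' Declares in contact the `L` highest-probability residue pairs whose
#' sequence separation falls in the requested class, where `L` is
#' conventionally the target sequence length. If fewer than `L` eligible
#' pairs exist all of them are returned. Ties are broken deterministically:
#' higher probability first, then smaller `i`, then smaller `j`.
#'
#' @param map A [contact_map()].
#' @param L Number of contacts to select (>= 1); defaults to the map's
#'   residue count, the standard top-L rule.
#' @param cls One of `"short"`, `"mid"`, `"long"`.
#' @return A `contact_set` data frame with columns `i`, `j`, `class`,
#'   `prob`, at most `L` rows, sorted by the tie-break order.
#' @export
top_l <- function(map, L = map$L, cls) {
  stopifnot(inherits(map, "contact_map"))
  if (!is.numeric(L) || length(L) != 1 || L < 1) {
    stop("L must be a single count >= 1", call. = FALSE)
  }
  if (identical(cls, "excluded")) {
    stop("cls 'excluded' is not a scoreable contact class", call. = FALSE)
  }
  cls <- match.arg(cls, contact_classes())
  pr <- upper_pairs(map$L)
  keep <- separation_class(pr[, 1], pr[, 2]) == cls
  pr <- pr[keep, , drop = FALSE]
  p <- map$p[pr]
  ord <- order(-p, pr[, 1], pr[, 2])
  take <- utils::head(ord, L)
  contact_set(map$target_id, pr[take, 1], pr[take, 2], prob = p[take],
              class = rep(cls, length(take)))
}

# ---- CASP RR format ---------------------------------------------------------

#' Read a CASP RR contact-prediction file
#'
#' Parses the CASP residue-residue contact submission format: optional
#' header lines (`PFRMAT`, `TARGET`, `AUTHOR`, `METHOD`, `REMARK`, `MODEL`,
#' `END`), optional sequence lines (concatenated), and contact records
#' `i j d_low d_high probability`. Every listed pair is set symmetrically at
#' its probability; unlisted pairs hold probability 0.
#'
#' @param path Path to an RR file.
#' @param L Residue count; required only when the file carries no sequence
#'   (otherwise inferred from the sequence, or as a fallback from the
#'   largest residue index seen).
#' @return A [contact_map()]; the sequence, when present, is attached.
#' @export
read_rr <- function(path, L = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  target_id <- "unknown"
  seq_parts <- character()
  rec_i <- integer()
  rec_j <- integer()
  rec_p <- numeric()
  header_re <- "^(PFRMAT|AUTHOR|METHOD|REMARK|MODEL|END|TARGET)\\b"
  for (k in seq_along(lines)) {
    ln <- trimws(lines[k])
    if (ln == "") next
    if (grepl("^TARGET", ln)) {
      target_id <- trimws(sub("^TARGET", "", ln))
      next
    }
    if (grepl(header_re, ln)) next
    if (grepl("^[A-Za-z]+$", ln)) {
      seq_parts <- c(seq_parts, ln)
      next
    }
    f <- strsplit(ln, "\\s+")[[1]]
    if (length(f) != 5 || anyNA(suppressWarnings(as.numeric(f)))) {
      stop("RR parse error at line ", k, " of ", path, ": '", ln, "'",
           call. = FALSE)
    }
    i <- as.integer(f[1]); j <- as.integer(f[2]); p <- as.numeric(f[5])
    if (i == j) {
      stop("RR parse error at line ", k, ": self-pair ", i, call. = FALSE)
    }
    if (p < 0 || p > 1) {
      stop("RR parse error at line ", k, ": probability ", p,
           " outside [0, 1]", call. = FALSE)
    }
    rec_i <- c(rec_i, i); rec_j <- c(rec_j, j); rec_p <- c(rec_p, p)
  }
  sequence <- if (length(seq_parts)) toupper(paste(seq_parts, collapse = ""))
              else NULL
  if (is.null(L)) {
    L <- if (!is.null(sequence)) nchar(sequence)
         else if (length(rec_i)) max(rec_i, rec_j)
         else stop("cannot determine L: no sequence, no records and no L ",
                   "argument", call. = FALSE)
  }
  if (length(rec_i) && (min(rec_i, rec_j) < 1 || max(rec_i, rec_j) > L)) {
    stop("RR parse error: residue index outside 1..", L, call. = FALSE)
  }
  p <- matrix(0, L, L)
  if (length(rec_i)) {
    key <- pair_key(rec_i, rec_j)
    for (g in unique(key[duplicated(key)])) {
      pg <- rec_p[key == g]
      if (length(unique(pg)) > 1) {
        stop("RR parse error: duplicate pair ", g,
             " with conflicting probabilities", call. = FALSE)
      }
    }
    p[cbind(rec_i, rec_j)] <- rec_p
    p[cbind(rec_j, rec_i)] <- rec_p
  }
  contact_map(target_id, p, sequence = sequence)
}

#' Write a contact map as a CASP RR file
#'
#' Emits the standard header (`PFRMAT RR`, `TARGET`, `MODEL 1`), the
#' sequence in 50-character lines when the map carries one, then one record
#' per pair with probability at least `min_prob`, as
#' `i j 0 8 probability` with `i < j`, probabilities printed with 6
#' decimals, sorted by descending probability (ties: smaller `i`, then
#' smaller `j`), terminated by `END`.
#'
#' @param map A [contact_map()].
#' @param path Output file path.
#' @param min_prob Minimum probability for a pair to be written (default
#'   keeps every nonzero pair).
#' @return `path`, invisibly.
#' @export
write_rr <- function(map, path, min_prob = 1e-9) {
  stopifnot(inherits(map, "contact_map"))
  pr <- upper_pairs(map$L)
  p <- map$p[pr]
  keep <- p >= min_prob
  pr <- pr[keep, , drop = FALSE]
  p <- p[keep]
  ord <- order(-p, pr[, 1], pr[, 2])
  lines <- c("PFRMAT RR", paste("TARGET", map$target_id), "MODEL 1")
  if (!is.null(map$sequence)) {
    starts <- seq(1, nchar(map$sequence), by = 50)
    lines <- c(lines, substring(map$sequence, starts,
                                pmin(starts + 49, nchar(map$sequence))))
  }
  lines <- c(lines,
             sprintf("%d %d 0 8 %.6f", pr[ord, 1], pr[ord, 2], p[ord]),
             "END")
  writeLines(lines, path)
  invisible(path)
}

#' Export a contact set as CSV
#'
#' Writes the canonical tabular form of a contact set: one row per pair
#' with `target_id`, `i`, `j`, `class` and `probability`.
#'
#' @param set A `contact_set` (e.g. from [top_l()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_contact_csv <- function(set, path) {
  df <- data.frame(target_id = attr(set, "target_id") %||% NA_character_,
                   i = set$i, j = set$j, class = set$class,
                   probability = set$prob)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
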