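#' Distogram: per-pair probability distributions over binned distances
#'
#' A distogram holds, for every residue pair of a target, a probability
#' distribution over the distance bins of a [bin_scheme()]. Constructing one
#' validates that per-pair distributions are non-negative and sum to 1
#' (tolerance 1e-6) and that the tensor is symmetric in the pair indices;
#' nearly-symmetric tensors (as emitted by most networks) are symmetrized by
#' averaging the (i,j) and (j,i) distributions, with a warning.
#'
#' @param target_id Target identifier.
#' @param probs Numeric array of dimension `L x L x n_bins(scheme)`.
#' @param scheme The [bin_scheme()] describing the third dimension.
#' @param sequence Optional amino-acid sequence of length L.
#' @return An object of class `distogram` with fields `target_id`, `L`,
#'   `probs`, `scheme`, `sequence`.
#' @export
distogram <- function(target_id, probs, scheme, sequence = NULL) {
  stopifnot(inherits(scheme, "bin_scheme"))
  if (!is.array(probs) || length(dim(probs)) != 3 ||
      dim(probs)[1] != dim(probs)[2]) {
    stop("probs must be an L x L x n_bins array", call. = FALSE)
  }
  if (dim(probs)[3] != n_bins(scheme)) {
    stop("probs has ", dim(probs)[3], " bins but scheme '", scheme$name,
         "' declares ", n_bins(scheme), call. = FALSE)
  }
  L <- dim(probs)[1]
  if (!is.null(sequence)) {
    sequence <- toupper(as.character(sequence)[1])
    if (nchar(sequence) != L) {
      stop("sequence length ", nchar(sequence), " does not match L = ", L,
           call. = FALSE)
    }
  }
  if (any(probs < -1e-9)) {
    stop("distogram probabilities must be non-negative", call. = FALSE)
  }
  sums <- apply(probs, c(1, 2), sum)
  if (any(abs(sums - 1) > 1e-6)) {
    stop("distogram per-pair probabilities must sum to 1 (max deviation ",
         format(max(abs(sums - 1))), ")", call. = FALSE)
  }
  tprobs <- aperm(probs, c(2, 1, 3))
  asym <- max(abs(probs - tprobs))
  if (asym > 1e-6) {
    warning("distogram tensor asymmetric (max |p_ij - p_ji| = ",
            format(asym), "); symmetrizing by averaging", call. = FALSE)
  }
  probs <- (probs + tprobs) / 2
  structure(
    list(target_id = as.character(target_id)[1], L = L, probs = probs,
         scheme = scheme, sequence = sequence),
    class = "distogram"
  )
}

#' @export
print.distogram <- function(x, ...) {
  cat(sprintf("distogram for target '%s': L = %d, scheme '%s' (%d bins)\n",
              x$target_id, x$L, x$scheme$name, n_bins(x$scheme)))
  invisible(x)
}

#' Integrate a distogram into a contact-probability map
#'
#' Converts per-pair distance distributions into a single contact
#' probability per pair by summing the probability mass of all bins up to
#' the contact threshold, taking the appropriate fraction of the bin that
#' straddles it (see [contact_weights()]). The output is a symmetric
#' [contact_map()] with entries in `[0, 1]` and zero diagonal.
#'
#' @param dgm A [distogram()].
#' @param threshold Contact distance threshold in Angstrom (default 8).
#' @return A [contact_map()].
#' @examples
#' sc <- scheme_trrosetta()
#' pr <- array(1 / n_bins(sc), c(3, 3, n_bins(sc)))
#' dg <- distogram("toy", pr, sc)
#' integrate_contacts(dg)$p[1, 2]  # 12/36 for the uniform distribution
#' @export
integrate_contacts <- function(dgm, threshold = 8) {
  stopifnot(inherits(dgm, "distogram"))
  w <- contact_weights(dgm$scheme, threshold)
  L <- dgm$L
  p <- matrix(matrix(dgm$probs, L * L, length(w)) %*% w, L, L)
  p <- (p + t(p)) / 2
  p <- pmin(pmax(p, 0), 1)
  diag(p) <- 0
  contact_map(dgm$target_id, p, sequence = dgm$sequence)
}

#' Read and write the distogram container format
#'
#' Distograms are stored in a plain-text JSON container holding the target
#' id, the optional sequence, the bin scheme (edges, no-contact-bin flag,
#' name), the tensor dimensions and the probability tensor flattened in
#' column-major (R-native) order. `read_distogram()` re-validates all
#' distogram invariants on load.
#'
#' @param dgm A [distogram()].
#' @param path File path of the `.json` container.
#' @return `read_distogram()` returns a [distogram()];
#'   `write_distogram()` returns `path` invisibly.
#' @export
write_distogram <- function(dgm, path) {
  stopifnot(inherits(dgm, "distogram"))
  obj <- list(
    format = "contactens-distogram-v1",
    target_id = dgm$target_id,
    sequence = dgm$sequence,
    scheme = list(edges = dgm$scheme$edges,
                  has_no_contact_bin = dgm$scheme$has_no_contact_bin,
                  name = dgm$scheme$name),
    dim = dim(dgm$probs),
    probs = as.vector(dgm$probs)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_distogram
#' @export
read_distogram <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "contactens-distogram-v1")) {
    stop("not a distogram container: ", path, call. = FALSE)
  }
  scheme <- bin_scheme(obj$scheme$edges, obj$scheme$has_no_contact_bin,
                       obj$scheme$name)
  probs <- array(as.numeric(obj$probs), dim = as.integer(obj$dim))
  distogram(obj$target_id, probs, scheme, sequence = obj$sequence)
}
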