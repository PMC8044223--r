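# Shared fixture builders for the test suite. Everything is generated in
# code; no stored data files.

# A symmetric contact map with given nonzero pairs (list of c(i, j, p)).
toy_map <- function(L, pairs = list(), target_id = "TOY") {
  p <- matrix(0, L, L)
  for (pp in pairs) {
    p[pp[1], pp[2]] <- pp[3]
    p[pp[2], pp[1]] <- pp[3]
  }
  contact_map(target_id, p)
}

# A random symmetric contact map with all eligible pairs nonzero.
random_map <- function(L, seed, target_id = "RND") {
  set.seed(seed)
  p <- matrix(0, L, L)
  up <- upper.tri(p)
  p[up] <- runif(sum(up))
  p[lower.tri(p)] <- t(p)[lower.tri(p)]
  contact_map(target_id, p)
}

# A random valid bin scheme: random positive strictly increasing edges,
# random no-contact flag.
random_scheme <- function(seed) {
  set.seed(seed)
  n_edges <- sample(3:40, 1)
  edges <- cumsum(c(runif(1, 0, 4), runif(n_edges - 1, 0.05, 2)))
  bin_scheme(edges, has_no_contact_bin = runif(1) < 0.5,
             name = paste0("rand", seed))
}

# Independent brute-force oracle for contact_weights: spread each bin's
# mass uniformly over n_sub equal sub-bins and accumulate each sub-bin's
# exact overlap with [0, threshold).
riemann_weights <- function(scheme, threshold, n_sub = 1e4) {
  e <- scheme$edges
  w <- numeric(length(e) - 1)
  for (k in seq_along(w)) {
    sub <- seq(e[k], e[k + 1], length.out = n_sub + 1)
    lo <- sub[-length(sub)]
    hi <- sub[-1]
    overlap <- pmin(hi, threshold) - pmin(lo, threshold)
    w[k] <- sum(overlap / (hi - lo)) / n_sub
  }
  if (scheme$has_no_contact_bin) w <- c(0, w)
  w
}

# A distogram with specified per-pair distributions; default uniform.
uniform_distogram <- function(L, scheme, target_id = "UNI") {
  distogram(target_id, array(1 / n_bins(scheme), c(L, L, n_bins(scheme))),
            scheme)
}

# A random contact set of n pairs on an L-residue target (class-eligible).
random_contact_set <- function(L, n, seed, target_id = "RND") {
  set.seed(seed)
  pr <- contactens:::upper_pairs(L)
  pr <- pr[abs(pr[, 1] - pr[, 2]) >= 6, , drop = FALSE]
  take <- sample(nrow(pr), min(n, nrow(pr)))
  contactens:::contact_set(target_id, pr[take, 1], pr[take, 2])
}

# A structure chain with explicit coordinates (pos 1..nrow).
chain_from_coords <- function(coords, aa = NULL, target_id = "TOY") {
  n <- nrow(coords)
  if (is.null(aa)) aa <- rep("A", n)
  structure_chain(target_id, seq_len(n), aa, coords)
}

# Write a minimal (possibly multi-MODEL) PDB file: one representative atom
# per residue (CB, CA for glycine). Fixture emitter only; reading goes
# through the package's bio3d-based reader.
write_toy_pdb <- function(path, models, aa) {
  aa3 <- vapply(aa, bio3d::aa123, character(1))
  lines <- character()
  multi <- length(models) > 1
  for (m in seq_along(models)) {
    if (multi) lines <- c(lines, sprintf("MODEL     %4d", m))
    xyz <- models[[m]]
    for (r in seq_along(aa)) {
      if (anyNA(xyz[r, ])) next
      elety <- if (aa[r] == "G") "CA" else "CB"
      lines <- c(lines, sprintf(
        "ATOM  %5d  %-3s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
        r, elety, aa3[r], r, xyz[r, 1], xyz[r, 2], xyz[r, 3]))
    }
    if (multi) lines <- c(lines, "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  path
}
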