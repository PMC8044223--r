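# Synthetic benchmark: toy folded chains and families of noisy distance
# predictors, so ensembling claims are testable without external data.

# Approximate natural amino-acid frequencies (Swiss-Prot order-of-magnitude
# values); glycine sits near its ~7% natural abundance so the
# representative-atom rule (CA for glycine) is exercised.
aa_frequencies <- function() {
  c(A = 8.3, R = 5.5, N = 4.1, D = 5.5, C = 1.4, Q = 3.9, E = 6.7,
    G = 7.1, H = 2.3, I = 5.9, L = 9.7, K = 5.8, M = 2.4, F = 3.9,
    P = 4.7, S = 6.6, T = 5.4, W = 1.1, Y = 2.9, V = 6.9)
}

#' Generate a synthetic folded chain with ground-truth labels
#'
#' Builds a coarse-grained chain (one representative point per residue) as
#' a self-avoiding random walk with fixed 3.8 Angstrom steps and a
#' compaction bias pulling each step toward the centroid of the chain so
#' far, which collapses the walk into a globule with realistic contact
#' densities in all three separation classes. No non-adjacent pair comes
#' closer than 3.5 Angstrom (excluded volume). Ground-truth labels are
#' derived through the standard label pipeline
#' ([distance_matrix()] + [contacts_from_distances()]).
#'
#' @param L Chain length (>= 15).
#' @param seed Integer seed; the same seed always yields the same chain.
#' @param target_id Identifier for the target.
#' @param compaction Strength of the centroid pull in `[0, 1)`; 0 gives an
#'   open random walk, larger values a denser globule. The default 0.4
#'   yields globules whose long-range contact counts resemble small folded
#'   domains.
#' @param threshold Contact threshold in Angstrom for the labels.
#' @return An object of class `synthetic_target` with fields `target_id`,
#'   `sequence`, `coords` (`L x 3`), `chain` (a [structure_chain()]) and
#'   `labels` (a `label_set`).
#' @export
gen_chain <- function(L, seed, target_id = sprintf("SYN%05d", seed %% 100000L),
                      compaction = 0.4, threshold = 8) {
  if (L < 15) stop("L must be at least 15", call. = FALSE)
  step <- 3.8
  min_clash <- 3.5
  freqs <- aa_frequencies()
  with_seed(seed, {
    sequence <- paste(sample(names(freqs), L, replace = TRUE,
                             prob = freqs), collapse = "")
    coords <- NULL
    for (attempt in 1:25) {
      coords <- try_walk(L, step, min_clash, compaction)
      if (!is.null(coords)) break
    }
  })
  if (is.null(coords)) {
    stop("chain placement failed after maximum restarts (L = ", L, ")",
         call. = FALSE)
  }
  chain <- structure_chain(target_id, seq_len(L),
                           strsplit(sequence, "")[[1]], coords)
  target <- target_record(target_id, sequence)
  labels <- build_labels(chain, target, threshold = threshold)
  structure(list(target_id = target_id, sequence = sequence,
                 coords = coords, chain = chain, labels = labels),
            class = "synthetic_target")
}

# One attempt at a self-avoiding compacted walk; NULL on placement failure.
try_walk <- function(L, step, min_clash, compaction) {
  coords <- matrix(NA_real_, L, 3)
  coords[1, ] <- 0
  d0 <- stats::rnorm(3)
  coords[2, ] <- step * d0 / sqrt(sum(d0^2))
  clash2 <- min_clash^2
  for (t in 3:L) {
    centroid <- colMeans(coords[1:(t - 1), , drop = FALSE])
    pull <- centroid - coords[t - 1, ]
    npull <- sqrt(sum(pull^2))
    placed <- FALSE
    for (try in 1:120) {
      u <- stats::rnorm(3)
      u <- u / sqrt(sum(u^2))
      # bias the first tries toward the centroid; fall back to pure
      # random directions when the biased ones keep clashing
      dir <- if (try <= 60 && npull > 1e-9) {
        v <- u + compaction * 2 * pull / npull
        v / sqrt(sum(v^2))
      } else u
      cand <- coords[t - 1, ] + step * dir
      prev <- coords[1:(t - 2), , drop = FALSE]
      d2 <- (prev[, 1] - cand[1])^2 + (prev[, 2] - cand[2])^2 +
        (prev[, 3] - cand[3])^2
      if (all(d2 >= clash2)) {
        coords[t, ] <- cand
        placed <- TRUE
        break
      }
    }
    if (!placed) return(NULL)
  }
  coords
}

#' @export
print.synthetic_target <- function(x, ...) {
  cat(sprintf(
    "synthetic_target '%s': L = %d, true contacts short/mid/long = %d/%d/%d\n",
    x$target_id, nchar(x$sequence), x$labels$n_true["short"],
    x$labels$n_true["mid"], x$labels$n_true["long"]))
  invisible(x)
}

#' Specification of a simulated distance predictor
#'
#' A simulated predictor perceives each true inter-residue distance with
#' additive Gaussian error and emits a distogram. The error of predictor
#' `k` on a pair decomposes into a component shared by the whole predictor
#' family and a private component:
#' `d' = d + rho * shared + sqrt(1 - rho^2) * own`, with
#' `own ~ Normal(0, noise_sd)` and the shared field drawn once per target
#' at the same scale, so the marginal error scale is `noise_sd` for every
#' `rho`. `rho = 0` gives independent predictors (maximal diversity),
#' `rho = 1` makes all family members identical — the knob that reproduces
#' the argument that diverse-but-equally-good predictors gain most from
#' ensembling.
#'
#' @param noise_sd Error scale sigma in Angstrom (>= 0).
#' @param rho Shared-error weight in `[0, 1]`.
#' @param scheme [bin_scheme()] for the emitted distogram.
#' @param seed Integer seed for the predictor's private noise.
#' @param dist_sd Width (sd, Angstrom) of the Gaussian the predictor spreads
#'   around its perceived distance when binning; defaults to
#'   `max(noise_sd, 0.5)` so the emitted distribution stays well-defined in
#'   the noiseless limit.
#' @return An object of class `predictor_spec`.
#' @export
predictor_spec <- function(noise_sd, rho = 0, scheme = scheme_trrosetta(),
                           seed = 1, dist_sd = max(noise_sd, 0.5)) {
  stopifnot(noise_sd >= 0, rho >= 0, rho <= 1, dist_sd > 0,
            inherits(scheme, "bin_scheme"))
  structure(list(noise_sd = noise_sd, rho = rho, scheme = scheme,
                 seed = as.integer(seed), dist_sd = dist_sd),
            class = "predictor_spec")
}

#' Draw the per-target shared error field of a predictor family
#'
#' @param target A [gen_chain()] result.
#' @param noise_sd Error scale in Angstrom.
#' @param seed Integer seed.
#' @return Symmetric `L x L` matrix of Gaussian errors (zero diagonal).
#' @export
shared_noise_field <- function(target, noise_sd, seed) {
  L <- target$labels$L
  with_seed(seed, {
    S <- matrix(0, L, L)
    up <- upper.tri(S)
    S[up] <- stats::rnorm(sum(up), 0, noise_sd)
    S[lower.tri(S)] <- t(S)[lower.tri(S)]
    S
  })
}

#' Simulate a distance predictor on a synthetic target
#'
#' Perceives each true pair distance with the spec's correlated Gaussian
#' error, then emits a [distogram()] by discretizing
#' `Normal(d', dist_sd)` over the spec's bin scheme: interior bins take the
#' Gaussian mass between their edges, mass below the first edge joins the
#' first distance bin (impossibly short distances still mean contact), and
#' mass beyond the last edge goes to the no-contact bin when the scheme has
#' one, otherwise to the last distance bin. Rows therefore sum to exactly 1.
#'
#' @param target A [gen_chain()] result.
#' @param spec A [predictor_spec()].
#' @param shared Optional shared error field from [shared_noise_field()];
#'   required when `spec$rho > 0`.
#' @return A [distogram()].
#' @export
simulate_predictor <- function(target, spec, shared = NULL) {
  stopifnot(inherits(target, "synthetic_target"),
            inherits(spec, "predictor_spec"))
  L <- target$labels$L
  d <- target$labels$distances
  if (spec$rho > 0 && is.null(shared)) {
    stop("rho > 0 requires a shared error field", call. = FALSE)
  }
  if (is.null(shared)) shared <- matrix(0, L, L)
  own <- with_seed(spec$seed, {
    M <- matrix(0, L, L)
    up <- upper.tri(M)
    M[up] <- stats::rnorm(sum(up), 0, spec$noise_sd)
    M[lower.tri(M)] <- t(M)[lower.tri(M)]
    M
  })
  dprime <- d + spec$rho * shared + sqrt(1 - spec$rho^2) * own
  e <- spec$scheme$edges
  s <- spec$dist_sd
  dp <- as.vector(dprime)
  cum <- vapply(e, function(edge) stats::pnorm((edge - dp) / s),
                numeric(length(dp)))
  nb_dist <- length(e) - 1
  P <- cum[, -1, drop = FALSE] - cum[, -ncol(cum), drop = FALSE]
  P[, 1] <- cum[, 2]               # mass below the first edge -> first bin
  tail_mass <- 1 - cum[, ncol(cum)]
  if (spec$scheme$has_no_contact_bin) {
    P <- cbind(tail_mass, P)
  } else {
    P[, nb_dist] <- P[, nb_dist] + tail_mass
  }
  probs <- array(P, dim = c(L, L, ncol(P)))
  distogram(target$target_id, probs, spec$scheme,
            sequence = target$sequence)
}

#' Run the synthetic ensembling experiment
#'
#' The package's in-silico version of the headline comparison: `k`
#' simulated predictors of equal error scale `noise_sd` and inter-predictor
#' error correlation `rho` are run on `n_targets` synthetic chains; each
#' predictor's distograms are integrated to contact maps, the maps are
#' averaged into a mean ensemble, and every method (the `k` predictors plus
#' the ensemble) is scored with ceiling-normalized top-L precision,
#' aggregated over targets. Pairwise Jaccard distances between the
#' predictors' top-L sets are reported per class.
#'
#' @param n_targets Number of synthetic targets.
#' @param L Chain length of every target.
#' @param k Number of predictors in the family (>= 2).
#' @param noise_sd Predictor error scale in Angstrom.
#' @param rho Inter-predictor error correlation in `[0, 1]`.
#' @param seed Master seed; all target, shared-field and predictor seeds
#'   derive from it deterministically.
#' @param scheme Bin scheme the simulated predictors emit.
#' @param threshold Contact threshold in Angstrom.
#' @return A list with `summary` (data frame: method, per-class mean
#'   normalized accuracy, overall), `jaccard` (per-class mean pairwise
#'   Jaccard distances across targets), and the call parameters.
#' @export
ensemble_experiment <- function(n_targets, L, k = 3, noise_sd = 2, rho = 0,
                                seed = 1, scheme = scheme_trrosetta(),
                                threshold = 8) {
  stopifnot(k >= 2, n_targets >= 1)
  method_ids <- c(sprintf("predictor_%d", seq_len(k)), "ensemble")
  evals <- stats::setNames(
    replicate(k + 1, vector("list", n_targets), simplify = FALSE),
    method_ids)
  jac_sum <- NULL
  for (t in seq_len(n_targets)) {
    tgt <- gen_chain(L, derive_seed(seed, t), compaction = 0.4,
                     threshold = threshold)
    shared <- shared_noise_field(tgt, noise_sd,
                                 derive_seed(seed, 100000 + t))
    maps <- lapply(seq_len(k), function(m) {
      spec <- predictor_spec(noise_sd, rho, scheme,
                             seed = derive_seed(seed, 200000 + t * 100 + m))
      integrate_contacts(simulate_predictor(tgt, spec, shared), threshold)
    })
    maps$ensemble <- ensemble_mean(maps, policy = "average_available")
    names(maps) <- method_ids
    sets <- lapply(maps[seq_len(k)], function(mp) {
      stats::setNames(lapply(contact_classes(), function(cls) {
        top_l(mp, L, cls)
      }), contact_classes())
    })
    jt <- jaccard_table(sets)
    jac_sum <- if (is.null(jac_sum)) jt else {
      cbind(jt[, 1:2],
            jt[, -(1:2)] + jac_sum[, -(1:2)])
    }
    for (m in method_ids) {
      evals[[m]][[t]] <- evaluate_map(maps[[m]], tgt$labels, L)
    }
  }
  summary <- do.call(rbind, lapply(method_ids, function(m) {
    agg <- aggregate_evaluations(evals[[m]])
    data.frame(method = m, short = agg$per_class["short"],
               mid = agg$per_class["mid"], long = agg$per_class["long"],
               overall = agg$overall, row.names = NULL,
               stringsAsFactors = FALSE)
  }))
  jaccard <- cbind(jac_sum[, 1:2], jac_sum[, -(1:2)] / n_targets)
  list(summary = summary, jaccard = jaccard,
       params = list(n_targets = n_targets, L = L, k = k,
                     noise_sd = noise_sd, rho = rho, seed = seed,
                     threshold = threshold))
}

#' Write a synthetic target as on-disk fixtures
#'
#' Emits the target as a FASTA sequence file and a PDB-format coordinate
#' file (one representative atom per residue: CB, or CA for glycine), so
#' the package's structure- and sequence-reading paths can be exercised on
#' generated data.
#'
#' @param target A [gen_chain()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector with the `fasta` and `pdb` paths,
#'   invisibly.
#' @export
write_synthetic_fixture <- function(target, dir) {
  stopifnot(inherits(target, "synthetic_target"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, paste0(target$target_id, ".fasta"))
  pdb <- file.path(dir, paste0(target$target_id, ".pdb"))
  write_target_fasta(target_record(target$target_id, target$sequence),
                     fasta)
  aa <- strsplit(target$sequence, "")[[1]]
  aa3 <- vapply(aa, bio3d::aa123, character(1))
  elety <- ifelse(aa == "G", "CA", "CB")
  bio3d::write.pdb(file = pdb, xyz = as.vector(t(target$coords)),
                   resno = seq_along(aa), resid = aa3, elety = elety,
                   chain = "A")
  invisible(c(fasta = fasta, pdb = pdb))
}
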