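test_that("representative atom is CB, CA for glycine, with CA fallback", {
  expect_equal(contactens:::pick_representative(c("N", "CA", "CB"), "A"), 3)
  expect_equal(contactens:::pick_representative(c("N", "CA"), "G"), 2)
  expect_warning(
    r <- contactens:::pick_representative(c("N", "CA"), "A"), "CB")
  expect_equal(r, 2)
  expect_true(is.na(contactens:::pick_representative(c("N", "O"), "A")))
})

test_that("PDB reading extracts representative coordinates per model", {
  aa <- c("A", "G", "K", "L", "R")
  m1 <- matrix(seq_len(15), 5, 3)
  m2 <- m1 + 100
  path <- tempfile(fileext = ".pdb")
  write_toy_pdb(path, list(m1, m2), aa)
  models <- read_structure_models(path, "tgt")
  expect_length(models, 2)
  expect_equal(unname(as.matrix(models[[1]]$residues[, c("x", "y", "z")])),
               m1)
  expect_equal(unname(as.matrix(models[[2]]$residues[, c("x", "y", "z")])),
               m2)
  expect_equal(models[[1]]$residues$aa, aa)
})

test_that("reconciliation drops mismatching positions without renumbering", {
  target <- target_record("t", "AGKLRAGKLRAGKLR")
  coords <- matrix(rnorm(18), 6, 3)
  # positions 3 and 5 disagree with the target sequence
  chain <- structure_chain("t", c(1, 2, 3, 4, 5, 6),
                           c("A", "G", "W", "L", "W", "A"), coords)
  rec <- reconcile(chain, target)
  expect_equal(rec$residues$pos, c(1, 2, 4, 6))
  expect_equal(attr(rec, "dropped"), c(3, 5))
  # perfect agreement is the identity
  chain2 <- structure_chain("t", 1:6, strsplit("AGKLRA", "")[[1]], coords)
  rec2 <- reconcile(chain2, target)
  expect_equal(rec2$residues[, c("pos", "aa")],
               chain2$residues[, c("pos", "aa")], ignore_attr = TRUE)
  # a per-position comparison oracle on a half-shuffled decoy
  set.seed(11)
  L <- 40
  seq_letters <- sample(c("A", "G", "K", "L"), L, replace = TRUE)
  tgt <- target_record("t", paste(seq_letters, collapse = ""))
  decoy <- seq_letters
  flip <- sample(L, L / 2)
  decoy[flip] <- ifelse(decoy[flip] == "A", "V", "A")
  ch <- structure_chain("t", 1:L, decoy, matrix(rnorm(3 * L), L, 3))
  rec3 <- reconcile(ch, tgt)
  expect_equal(rec3$residues$pos, which(decoy == seq_letters))
  expect_error(
    reconcile(structure_chain("t", 1:3, c("W", "W", "W"),
                              matrix(0, 3, 3)), target),
    "fewer than 2")
})

test_that("distance matrices are Euclidean with NA for unresolved pairs", {
  coords <- rbind(c(0, 0, 0), c(3, 4, 0), c(NA, NA, NA))
  chain <- chain_from_coords(coords)
  D <- distance_matrix(chain, 4)
  expect_equal(D[1, 2], 5)          # 3-4-5 triangle
  expect_equal(D[1, 1], 0)
  expect_true(all(is.na(D[3, ])))   # unresolved residue
  expect_true(all(is.na(D[4, ])))   # residue absent from the chain
  # brute-force double-loop oracle on random coordinates
  set.seed(7)
  xyz <- matrix(rnorm(30), 10, 3)
  D2 <- distance_matrix(chain_from_coords(xyz), 10)
  for (i in 1:10) for (j in 1:10) {
    expect_equal(D2[i, j], sqrt(sum((xyz[i, ] - xyz[j, ])^2)),
                 tolerance = 1e-12)
  }
})

test_that("mean distance matrix averages over resolving models", {
  c1 <- rbind(c(0, 0, 0), c(7, 0, 0))
  c2 <- rbind(c(0, 0, 0), c(9, 0, 0))
  m <- mean_distance_matrix(list(chain_from_coords(c1),
                                 chain_from_coords(c2)), 2)
  expect_equal(m[1, 2], 8)  # boundary reached via the mean
  # single model is the identity
  expect_equal(mean_distance_matrix(list(chain_from_coords(c1)), 2),
               distance_matrix(chain_from_coords(c1), 2))
  # a pair unresolved in one model averages over the others only
  c3 <- rbind(c(0, 0, 0), c(NA, NA, NA))
  m2 <- mean_distance_matrix(list(chain_from_coords(c1),
                                  chain_from_coords(c3)), 2)
  expect_equal(m2[1, 2], 7)
  expect_error(mean_distance_matrix(list(), 2), "at least one")
  # brute-force per-pair averaging oracle on 5 random models
  set.seed(21)
  models <- lapply(1:5, function(k) chain_from_coords(matrix(rnorm(24), 8, 3)))
  mm <- mean_distance_matrix(models, 8)
  ds <- lapply(models, distance_matrix, L = 8)
  for (i in 1:8) for (j in 1:8) {
    expect_equal(mm[i, j], mean(sapply(ds, `[`, i, j)), tolerance = 1e-12)
  }
  # k copies of one model equal the single-model matrix
  expect_equal(mean_distance_matrix(rep(list(models[[1]]), 4), 8), ds[[1]])
})

test_that("contacts are resolved pairs at separation >= 6 within 8 A", {
  D <- matrix(20, 30, 30)
  D[1, 9] <- D[9, 1] <- 8.000     # exactly 8 A counts
  D[1, 5] <- D[5, 1] <- 3         # separation 4: excluded
  D[2, 28] <- D[28, 2] <- 7.5
  D[3, 16] <- D[16, 3] <- NA      # unresolved
  diag(D) <- 0
  lab <- contacts_from_distances(D, 8, "t")
  keys <- paste(lab$contacts$i, lab$contacts$j)
  expect_setequal(keys, c("1 9", "2 28"))
  expect_equal(lab$contacts$class[keys == "1 9"], "short")
  expect_equal(unname(lab$n_true), c(1L, 0L, 1L))
  expect_equal(sum(lab$n_true), nrow(lab$contacts))
})

test_that("a toy coiled chain matches an exhaustive enumeration oracle", {
  # a tight coil (large radius, slow rise) guarantees recurrent approaches
  # at separations >= 6; the oracle enumerates every pair by explicit loops
  t <- (0:29) * 40 * pi / 180
  coords <- cbind(6 * cos(t), 6 * sin(t), (0:29) * 0.7)
  lab <- contacts_from_distances(distance_matrix(chain_from_coords(coords),
                                                 30), 8, "coil")
  expected <- character()
  for (i in 1:29) for (j in (i + 1):30) {
    d <- sqrt(sum((coords[i, ] - coords[j, ])^2))
    if (j - i >= 6 && d <= 8) expected <- c(expected, paste(i, j))
  }
  expect_gt(length(expected), 0)
  expect_setequal(paste(lab$contacts$i, lab$contacts$j), expected)
  expect_equal(sum(lab$n_true), nrow(lab$contacts))
})

test_that("labels are invariant under rigid-body motion", {
  set.seed(13)
  tg <- gen_chain(40, seed = 3)
  base <- contacts_from_distances(
    distance_matrix(chain_from_coords(tg$coords), 40), 8, "t")
  for (rep in 1:5) {
    q <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    shift <- rnorm(3, sd = 50)
    moved <- sweep(tg$coords %*% q, 2, shift, `+`)
    lab <- contacts_from_distances(
      distance_matrix(chain_from_coords(moved), 40), 8, "t")
    expect_equal(lab$contacts[c("i", "j", "class")],
                 base$contacts[c("i", "j", "class")])
    expect_equal(lab$n_true, base$n_true)
  }
})

test_that("build_labels runs the full pipeline from multi-model PDB files", {
  tg <- gen_chain(30, seed = 8)
  aa <- strsplit(tg$sequence, "")[[1]]
  path <- tempfile(fileext = ".pdb")
  # two models: the chain itself and a rigidly shifted copy
  write_toy_pdb(path, list(tg$coords, tg$coords + 5), aa)
  models <- read_structure_models(path, tg$target_id)
  labels <- build_labels(models, target_record(tg$target_id, tg$sequence))
  expect_s3_class(labels, "label_set")
  # both models have identical internal geometry, so labels match the
  # single-chain derivation
  expect_equal(labels$n_true, tg$labels$n_true)
  expect_equal(labels$contacts[c("i", "j")],
               tg$labels$contacts[c("i", "j")])
})
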