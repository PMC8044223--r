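# A label set built directly from a distance matrix, for scoring tests.
labels_from_D <- function(D, target_id = "t") {
  lab <- contacts_from_distances(D, 8, target_id)
  structure(list(target_id = target_id, L = nrow(D), distances = D,
                 contacts = lab$contacts, n_true = lab$n_true,
                 dropped = integer()),
            class = "label_set")
}

# A distance matrix whose long-range contacts are an explicit pair list.
D_with_contacts <- function(L, pairs) {
  D <- matrix(30, L, L)
  diag(D) <- 0
  for (pp in pairs) {
    D[pp[1], pp[2]] <- D[pp[2], pp[1]] <- 5
  }
  D
}

test_that("raw precision counts set intersections, dropping unverifiable pairs", {
  L <- 60
  truth <- list(c(1, 30), c(2, 40), c(3, 50))
  D <- D_with_contacts(L, truth)
  D[4, 55] <- D[55, 4] <- NA    # unresolved pair
  labels <- labels_from_D(D)
  pred <- contactens:::contact_set("t", c(1, 2, 5, 4), c(30, 40, 45, 55))
  res <- raw_precision(pred, labels, "long")
  expect_equal(res$tp, 2)
  expect_equal(res$fp, 1)       # (5,45) wrong; (4,55) unverifiable, dropped
  expect_equal(res$n_scored, 3)
  expect_equal(res$precision, 2 / 3)
  # perfect and empty-overlap cases
  perfect <- contactens:::contact_set("t", c(1, 2, 3), c(30, 40, 50))
  expect_equal(raw_precision(perfect, labels, "long")$precision, 1)
  miss <- contactens:::contact_set("t", c(6, 7), c(47, 48))
  expect_equal(raw_precision(miss, labels, "long")$precision, 0)
  empty <- contactens:::contact_set("t", integer(), integer())
  expect_equal(raw_precision(empty, labels, "long")$precision, 0)
  short_pair <- contactens:::contact_set("t", 1, 8)
  expect_error(raw_precision(short_pair, labels, "long"), "outside class")
  # randomized set-operation oracle
  set.seed(17)
  for (rep in 1:5) {
    pr <- contactens:::upper_pairs(L)
    pr <- pr[abs(pr[, 1] - pr[, 2]) >= 24, , drop = FALSE]
    tr <- pr[sample(nrow(pr), 40), , drop = FALSE]
    Dr <- D_with_contacts(L, asplit(tr, 1))
    labr <- labels_from_D(Dr)
    pd <- pr[sample(nrow(pr), 50), , drop = FALSE]
    resr <- raw_precision(contactens:::contact_set("t", pd[, 1], pd[, 2]),
                          labr, "long")
    expected_tp <- length(intersect(paste(pd[, 1], pd[, 2]),
                                    paste(tr[, 1], tr[, 2])))
    expect_equal(resr$tp, expected_tp)
    expect_equal(resr$fp, 50 - expected_tp)
  }
})

test_that("ceiling normalization maps top-L precision to a 0-1 scale", {
  # all 30 true contacts found among L = 50 picks: ceiling saturates
  expect_equal(normalized_accuracy(tp = 30, n_selected = 50, n_true = 30,
                                   L = 50), 1)
  expect_equal(normalized_accuracy(40, 50, 80, 50), 0.8)
  expect_equal(normalized_accuracy(0, 50, 30, 50), 0)
  expect_true(is.na(normalized_accuracy(0, 50, 0, 50)))
})

test_that("evaluate_map combines top-L selection, precision and ceilings", {
  L <- 60
  truth <- list(c(1, 30), c(2, 40), c(3, 50))
  labels <- labels_from_D(D_with_contacts(L, truth))
  map <- toy_map(L, list(c(1, 30, 0.9), c(2, 40, 0.8), c(5, 45, 0.7)),
                 target_id = "t")
  ev <- evaluate_map(map, labels, L = 60)
  long <- ev[ev$class == "long", ]
  expect_equal(long$tp, 2)
  expect_equal(long$n_true, 3)
  expect_equal(long$ceiling, 3 / 60)
  expect_equal(long$normalized_accuracy, 2 / 3)  # tp / min(L, n_true)
  expect_true(is.na(ev$normalized_accuracy[ev$class == "short"]))
  # a map whose nonzero pairs are exactly the truth scores 1 where defined
  perfect <- toy_map(L, lapply(truth, function(x) c(x, 0.9)),
                     target_id = "t")
  evp <- evaluate_map(perfect, labels)
  expect_equal(evp$normalized_accuracy[evp$class == "long"], 1)
})

test_that("aggregation macro-averages classes over defined targets only", {
  L <- 60
  lab1 <- labels_from_D(D_with_contacts(L, list(c(1, 30), c(2, 14))))
  lab2 <- labels_from_D(D_with_contacts(L, list(c(3, 50))))  # long only
  map1 <- toy_map(L, list(c(1, 30, 0.9), c(2, 14, 0.8)), "t")
  map2 <- toy_map(L, list(c(5, 45, 0.9)), "t")
  r1 <- evaluate_map(map1, lab1)
  r2 <- evaluate_map(map2, lab2)
  agg <- aggregate_evaluations(list(r1, r2))
  # long defined on both targets: mean of 1 and 0; mid only on target 1
  expect_equal(unname(agg$per_class["long"]), 0.5)
  expect_equal(unname(agg$per_class["mid"]), 1)
  expect_true(is.na(agg$per_class["short"]))
  expect_equal(agg$overall, mean(c(1, 0.5)))
  # order invariance and single-target macro mean
  agg_rev <- aggregate_evaluations(list(r2, r1))
  expect_equal(agg_rev$per_class, agg$per_class)
  # brute-force two-stage averaging oracle on random results
  set.seed(23)
  res <- lapply(1:20, function(k) {
    lab <- labels_from_D(D_with_contacts(
      L, asplit(cbind(sample(1:10, 5), sample(40:60, 5)), 1)))
    evaluate_map(random_map(L, k, "t"), lab)
  })
  agg2 <- aggregate_evaluations(res)
  for (cls in contact_classes()) {
    vals <- sapply(res, function(r) r$normalized_accuracy[r$class == cls])
    expect_equal(unname(agg2$per_class[cls]), mean(vals, na.rm = TRUE),
                 tolerance = 1e-12)
  }
  expect_equal(agg2$overall, mean(agg2$per_class, na.rm = TRUE),
               tolerance = 1e-12)
})

test_that("micro aggregation pools counts across targets", {
  L <- 60
  # the second true pair of target 1 sits beyond the reach of the zero-fill
  # tie-break, so the predictor genuinely misses it
  lab1 <- labels_from_D(D_with_contacts(L, list(c(1, 30), c(3, 50))))
  lab2 <- labels_from_D(D_with_contacts(L, list(c(3, 50))))
  map1 <- toy_map(L, list(c(1, 30, 0.9)), "t")   # 1 of 2 found
  map2 <- toy_map(L, list(c(3, 50, 0.9)), "t")   # 1 of 1 found
  agg <- aggregate_evaluations(list(evaluate_map(map1, lab1),
                                    evaluate_map(map2, lab2)),
                               micro = TRUE)
  expect_equal(unname(agg$per_class["long"]), 2 / 3)
})

test_that("jaccard distance follows the set formula", {
  A <- contactens:::contact_set("t", c(1, 2, 3), c(30, 40, 50))
  B <- contactens:::contact_set("t", c(2, 3, 4), c(40, 50, 60))
  expect_equal(jaccard_distance(A, B), 0.5)       # (4 - 2) / 4
  expect_equal(jaccard_distance(A, A), 0)         # identical sets
  C <- contactens:::contact_set("t", c(5, 6), c(45, 46))
  expect_equal(jaccard_distance(A, C), 1)         # disjoint sets
  empty <- contactens:::contact_set("t", integer(), integer())
  expect_equal(jaccard_distance(empty, empty), 0)
  other <- contactens:::contact_set("u", 1, 30)
  expect_error(jaccard_distance(A, other), "different targets")
})

test_that("jaccard distance is a bounded metric on contact sets", {
  set.seed(41)
  for (rep in 1:200) {
    A <- random_contact_set(40, sample(0:12, 1), seed = rep * 3 + 1)
    B <- random_contact_set(40, sample(0:12, 1), seed = rep * 3 + 2)
    C <- random_contact_set(40, sample(0:12, 1), seed = rep * 3 + 3)
    dab <- jaccard_distance(A, B)
    dba <- jaccard_distance(B, A)
    dac <- jaccard_distance(A, C)
    dcb <- jaccard_distance(C, B)
    expect_identical(dab, dba)
    expect_true(dab >= 0 && dab <= 1)
    expect_true(dab <= dac + dcb + 1e-12)  # triangle inequality
    same <- setequal(paste(A$i, A$j), paste(B$i, B$j))
    expect_equal(dab == 0, same)
  }
})

test_that("jaccard_table reports per-class and average distances", {
  mk <- function(pairs) {
    s <- lapply(contact_classes(), function(cls) {
      keep <- separation_class(pairs[, 1], pairs[, 2]) == cls
      contactens:::contact_set("t", pairs[keep, 1], pairs[keep, 2])
    })
    names(s) <- contact_classes()
    s
  }
  a <- mk(cbind(c(1, 1, 1), c(8, 15, 30)))
  b <- mk(cbind(c(1, 1, 1), c(8, 16, 40)))
  tab <- jaccard_table(list(A = a, B = b))
  expect_equal(nrow(tab), 1)
  expect_equal(tab$short, 0)
  expect_equal(tab$mid, 1)
  expect_equal(tab$long, 1)
  expect_equal(tab$average, mean(c(0, 1, 1)))
})
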