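test_that("hypergeometric p-value matches enumeration and handles edge cases", {
  expect_equal(hypergeom_pvalue(10, 5, 4, 3), 55 / 210, tolerance = 1e-14)
  expect_identical(hypergeom_pvalue(10, 5, 4, 0), 1)    # empty sum
  expect_identical(hypergeom_pvalue(5, 5, 5, 5), 1)     # forced overlap
  expect_error(hypergeom_pvalue(10, 11, 4, 0), "exceed N")
  expect_error(hypergeom_pvalue(10, 5, 4, 5), "min")
  expect_error(hypergeom_pvalue(10, 9, 9, 2), "feasible")
})

test_that("log-space tail sum agrees with oracles over the full small grid", {
  worst <- 0
  for (N in c(1:12, 20)) {
    for (K in 0:N) for (O in 0:N) {
      for (x in max(0, K + O - N):min(K, O)) {
        p <- hypergeom_pvalue(N, K, O, x)
        worst <- max(worst,
                     abs(p - hyper_tail_oracle(N, K, O, x)),
                     abs(p - phyper(x - 1, K, N - K, O,
                                    lower.tail = FALSE)))
      }
    }
  }
  expect_lt(worst, 1e-12)
})

test_that("p-value is monotone in overlap, symmetric in K and O, and stable
          at catalog scale", {
  p <- vapply(0:4, function(x) hypergeom_pvalue(10, 5, 4, x), numeric(1))
  expect_true(all(diff(p) <= 0))
  expect_equal(hypergeom_pvalue(40, 12, 7, 5),
               hypergeom_pvalue(40, 7, 12, 5), tolerance = 1e-14)
  # no overflow at realistic catalog size
  p_big <- hypergeom_pvalue(2500, 900, 700, 300)
  expect_true(is.finite(p_big) && p_big >= 0 && p_big <= 1)
  expect_equal(p_big, phyper(299, 900, 1600, 700, lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("shared miRNA sets equal a brute-force edge-scan oracle", {
  cat <- random_catalog(12, 6, 0.3, seed = 5)
  edges <- cat$edges
  targets <- unique(edges$target_id)
  for (a in targets) for (b in setdiff(targets, a)) {
    brute <- character()
    for (i in seq_len(nrow(edges))) for (j in seq_len(nrow(edges))) {
      if (edges$target_id[i] == a && edges$target_id[j] == b &&
            edges$mirna_id[i] == edges$mirna_id[j]) {
        brute <- c(brute, edges$mirna_id[i])
      }
    }
    expect_setequal(shared_mirnas(cat, a, b), unique(brute))
  }
  expect_error(shared_mirnas(cat, "t01", "nope"), "nope")
})

test_that("shared set is empty for targets with disjoint regulators", {
  cat <- make_catalog(c("m1", "m2", "m3"), c("A", "A", "B"))
  expect_equal(shared_mirnas(cat, "A", "B"), character(0))
  expect_equal(shared_mirnas(cat, "A", "B"),
               sort(intersect(c("m1", "m2"), "m3")))
})

test_that("candidate enumeration matches an exhaustive all-pairs oracle", {
  # toy catalog: 6 targets x 8 miRNAs, mixed biotypes
  set.seed(21)
  cat <- random_catalog(8, 6, 0.45, seed = 21)
  bt <- rep(c("protein_coding", "lncRNA", "pseudogene"), 2)
  cat$edges$target_biotype <- bt[match(cat$edges$target_id,
                                       sprintf("t%02d", 1:6))]
  cat <- interaction_catalog(cat$edges)
  g <- make_expr(sprintf("t%02d", 1:6), sprintf("s%d", 1:10),
                 bt, seed = 22)
  m <- make_expr(sprintf("m%02d", 1:8), sprintf("s%d", 1:10), "miRNA",
                 seed = 23)
  ds <- tissue_dataset(g, m, cat)
  got <- enumerate_candidates(ds, min_shared = 1L, alpha = 1,
                              adjust = "none")

  # oracle: loop every unordered pair, apply the tail formula directly
  map <- split(cat$edges$mirna_id, cat$edges$target_id)
  N <- length(unique(cat$edges$mirna_id))
  expected <- list()
  tg <- names(map)
  for (i in seq_along(tg)) for (j in seq_along(tg)) {
    a <- tg[i]; b <- tg[j]
    bta <- cat$target_biotype[[a]]; btb <- cat$target_biotype[[b]]
    if (bta != "protein_coding") next
    if (btb == "protein_coding" && a >= b) next
    if (a == b) next
    x <- length(intersect(map[[a]], map[[b]]))
    if (x < 1) next
    expected[[paste(a, b)]] <-
      hyper_tail_oracle(N, length(map[[a]]), length(map[[b]]), x)
  }
  expect_gt(length(expected), 0)
  expect_setequal(paste(got$cerna_a, got$cerna_b), names(expected))
  expect_equal(got$p_hyper,
               unname(unlist(expected)[paste(got$cerna_a, got$cerna_b)]),
               tolerance = 1e-12)
  # alpha cutoffs on the oracle p-values match the function's retention
  for (al in c(0.05, 0.5)) {
    sub <- enumerate_candidates(ds, min_shared = 1L, alpha = al,
                                adjust = "none")
    expect_setequal(paste(sub$cerna_a, sub$cerna_b),
                    names(expected)[unlist(expected) <= al])
  }
  # deterministic ordering by adjusted p then ids
  expect_false(is.unsorted(got$p_hyper_adj))

  # no-filter limit: alpha = 1 retains every pair with x >= 1
  all_pairs <- enumerate_candidates(ds, min_shared = 1L, alpha = 1,
                                    adjust = "none")
  n_x1 <- 0L
  for (i in seq_along(tg)) for (j in seq_along(tg)) {
    a <- tg[i]; b <- tg[j]
    if (cat$target_biotype[[a]] != "protein_coding" || a == b) next
    if (cat$target_biotype[[b]] == "protein_coding" && a >= b) next
    if (length(intersect(map[[a]], map[[b]])) >= 1) n_x1 <- n_x1 + 1L
  }
  expect_equal(nrow(all_pairs), n_x1)

  # pairs sharing nothing never appear
  expect_true(all(all_pairs$n_shared >= 1))
})

test_that("tested-pair p-values are roughly uniform under a random catalog", {
  # independent random edges: the overlap of two targets is genuinely
  # hypergeometric, so upper-tail p-values are (discretely) superuniform
  set.seed(77)
  cat <- random_catalog(60, 40, 0.25, seed = 77)
  g <- make_expr(sprintf("t%02d", 1:40), sprintf("s%d", 1:10),
                 "protein_coding", seed = 78)
  m <- make_expr(sprintf("m%02d", 1:60), sprintf("s%d", 1:10), "miRNA",
                 seed = 79)
  ds <- tissue_dataset(g, m, cat)
  all_tested <- enumerate_candidates(ds, min_shared = 1L, alpha = 1,
                                     adjust = "none")
  expect_gte(nrow(all_tested), 500)
  ks <- suppressWarnings(ks.test(all_tested$p_hyper, "punif"))
  # coarse tolerance: the discreteness of the tail probabilities alone
  # shifts the statistic upward
  expect_lt(unname(ks$statistic), 0.2)
  # and superuniformity across thresholds
  for (al in c(0.05, 0.1, 0.25, 0.5)) {
    expect_lte(mean(all_tested$p_hyper <= al), al + 0.08)
  }
})
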