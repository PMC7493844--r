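test_that("partial correlation reduces to Pearson and matches closed forms", {
  set.seed(6)
  a <- rnorm(30); b <- rnorm(30); m <- rnorm(30)
  expect_identical(partial_correlation(a, b), cor(a, b))
  expect_identical(partial_correlation(a, b, matrix(nrow = 30, ncol = 0)),
                   cor(a, b))
  # single conditioning vector: textbook formula
  r_ab <- cor(a, b); r_am <- cor(a, m); r_bm <- cor(b, m)
  closed <- (r_ab - r_am * r_bm) / sqrt((1 - r_am^2) * (1 - r_bm^2))
  expect_equal(partial_correlation(a, b, m), closed, tolerance = 1e-10)
  expect_equal(partial_correlation(a, b, m, method = "residual"), closed,
               tolerance = 1e-10)
})

test_that("matrix-inverse and residual-regression routes agree to 1e-10", {
  set.seed(7)
  worst <- 0
  for (rep in 1:200) {
    n <- 100
    k <- sample(1:5, 1)
    # latent factors induce realistic dependence between a, b and M
    f <- rnorm(n)
    M <- matrix(rnorm(n * k) + 0.5 * f, ncol = k)
    a <- rnorm(n) + 0.7 * f
    b <- rnorm(n) + 0.4 * f + 0.3 * M[, 1]
    d <- abs(partial_correlation(a, b, M) -
               partial_correlation(a, b, M, method = "residual"))
    worst <- max(worst, d)
  }
  expect_lt(worst, 1e-10)
})

test_that("conditional independence given M drives pcor to zero", {
  set.seed(8)
  n <- 10000
  m <- rnorm(n)
  a <- 0.8 * m + rnorm(n)
  b <- -0.6 * m + rnorm(n)
  expect_lt(abs(partial_correlation(a, b, m)), 0.05)
  expect_gt(abs(cor(a, b)), 0.2)  # marginally correlated through m
})

test_that("rank-deficient conditioning errors in strict mode, warns otherwise", {
  set.seed(9)
  n <- 50
  m <- rnorm(n)
  M <- cbind(m, m)   # exactly collinear
  a <- rnorm(n); b <- rnorm(n)
  expect_error(partial_correlation(a, b, M, strict = TRUE), "rank-deficient")
  expect_warning(p <- partial_correlation(a, b, M), "pseudo-inverse")
  expect_true(is.finite(p))
})

test_that("mscor matches its bivariate-normal closed form and null limits", {
  # a = -m + e, b = -m + e': cor = 1/2, pcor | m = 0, mscor = 1/2
  set.seed(10)
  n <- 10000
  m <- rnorm(n); a <- -m + rnorm(n); b <- -m + rnorm(n)
  expect_equal(mscor(a, b, matrix(m)), 0.5, tolerance = 0.03)
  # conditioning on nothing gives exactly zero
  expect_identical(mscor(a, b), 0)
  # irrelevant conditioning set: mscor -> 0
  Z <- matrix(rnorm(n * 3), ncol = 3)
  expect_lt(abs(mscor(a, b, Z)), 0.05)
})

test_that("mscor is symmetric and invariant to positive affine rescaling", {
  set.seed(13)
  n <- 60
  a <- rnorm(n); b <- rnorm(n); M <- matrix(rnorm(n * 2), ncol = 2)
  expect_equal(mscor(a, b, M), mscor(b, a, M), tolerance = 1e-13)
  expect_equal(mscor(3 * a + 7, 0.5 * b - 2, M), mscor(a, b, M),
               tolerance = 1e-12)
  expect_equal(mscor(a, b, 10 * M + 1), mscor(a, b, M), tolerance = 1e-12)
})

test_that("null model strata are centred at zero and tighten with sample size", {
  nm50 <- build_null_model(n_samples = 50, m_levels = 2L,
                           cor_bin_edges = c(0.4, 0.6), n_draws = 400,
                           seed = 3)
  draws <- nm50$draws[[1]]
  expect_equal(length(draws), 400)
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws)), 3 * se)

  nm1000 <- build_null_model(n_samples = 1000, m_levels = 2L,
                             cor_bin_edges = c(0.4, 0.6), n_draws = 400,
                             seed = 3)
  expect_lt(sd(nm1000$draws[[1]]), sd(draws))
})

test_that("null model is reproducible and serializes losslessly", {
  nm1 <- build_null_model(60, m_levels = 1:2, cor_bin_edges = c(0, 0.5, 1),
                          n_draws = 100, seed = 17)
  nm2 <- build_null_model(60, m_levels = 1:2, cor_bin_edges = c(0, 0.5, 1),
                          n_draws = 100, seed = 17)
  expect_identical(nm1, nm2)
  path <- tempfile(fileext = ".json")
  write_null_model(nm1, path)
  nm3 <- read_null_model(path)
  expect_equal(nm3$draws, nm1$draws)
  expect_equal(nm3$seed, nm1$seed)
  expect_error(build_null_model(60, m_levels = integer(0)), "empty stratum")
})

test_that("empirical p-values follow the add-one tail convention", {
  nm <- build_null_model(50, m_levels = 1L, cor_bin_edges = c(0, 1),
                         n_draws = 100, seed = 1)
  nm$draws[[1]] <- c(0.1, 0.2, 0.3)   # hand-set tail for exact counting
  expect_equal(empirical_pvalue(nm, 0.15, 1, 0.5), (1 + 2) / 4)
  expect_equal(empirical_pvalue(nm, 0.99, 1, 0.5), 1 / 4)
  expect_equal(empirical_pvalue(nm, -1, 1, 0.5), 1)
  nm$draws[[1]] <- rep(0, 999)
  expect_equal(empirical_pvalue(nm, 0.5, 1, 0.5), 1 / 1000)
  expect_error(empirical_pvalue(nm, 0.5, 1, 1.5), "no null stratum")
  expect_error(empirical_pvalue(nm, 0.5, 0, 0.5), "no null stratum")
})

test_that("observed m above the largest stratum maps into the top bin", {
  nm <- build_null_model(40, m_levels = 1:3, cor_bin_edges = c(0, 1),
                         n_draws = 100, seed = 2)
  expect_equal(empirical_pvalue(nm, 99, 12, 0.5),
               empirical_pvalue(nm, 99, 3, 0.5))
})

test_that("candidate scoring intersects with step-B survivors and enforces
          positive correlation", {
  gen <- generate_dataset(generator_spec(n_samples = 150L, seed = 61))
  ds <- gen$dataset
  cands <- enumerate_candidates(ds, adjust = "none")
  et <- filter_negative_edges(ds, alpha = 0.05, n_perm = 199, seed = 4)
  nm <- build_null_model(150, m_levels = 1:4,
                         cor_bin_edges = seq(0, 1, 0.1), n_draws = 300,
                         seed = 6)
  got <- score_candidates(ds, cands, et, nm)
  # planted pairs present with positive mscor; mscor identity holds
  ev <- evaluate_recovery(got, gen$truth)
  expect_gte(ev$recall, 0.8)
  expect_true(all(got$mscor > 0))
  expect_equal(got$mscor, got$cor - got$pcor, tolerance = 1e-12)
  expect_true(all(got$cor > 0))
  expect_true(all(abs(got$mscor) <= 2))

  # decoys absent
  dk <- with(gen$truth$decoy_pairs, paste(cerna_a, cerna_b))
  expect_false(any(paste(got$cerna_a, got$cerna_b) %in% dk))

  # empty candidate list gives an empty, well-formed table
  none <- score_candidates(ds, cands[0, ], et, nm)
  expect_equal(nrow(none), 0L)
  expect_named(none, c("cerna_a", "cerna_b", "n_shared_mirnas",
                       "shared_mirnas", "cor", "pcor", "mscor", "p_value"))

  # no retained edges: every candidate drops at the intersection
  et_none <- et; et_none$retained <- FALSE
  expect_equal(nrow(score_candidates(ds, cands, et_none, nm)), 0L)
})
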