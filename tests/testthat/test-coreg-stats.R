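test_that("count_coregulation matches hand counts", {
  # A = 1101, B = 1001 over 4 contrasts -> n = 2; signs make 1 discordant
  binary <- rbind(A = c(1L, 1L, 0L, 1L),
                  B = c(1L, 0L, 0L, 1L),
                  Z = c(0L, 0L, 0L, 0L))
  colnames(binary) <- paste0("k", 1:4)
  signed <- rbind(A = c(1L, 1L, 0L, 1L),
                  B = c(-1L, 0L, 0L, 1L),
                  Z = c(0L, 0L, 0L, 0L))
  colnames(signed) <- colnames(binary)
  res <- count_coregulation(binary, signed, min_obs = 1)
  expect_equal(nrow(res), 1L)  # pairs with all-zero Z excluded at min_obs 1
  expect_equal(res$gene_i, "A")
  expect_equal(res$gene_j, "B")
  expect_equal(res$n, 2L)
  expect_equal(res$n_discordant, 1L)
  expect_equal(res$K, 4L)
})

test_that("count_coregulation agrees with a brute-force pair loop", {
  set.seed(21)
  G <- 12; K <- 15
  binary <- matrix(rbinom(G * K, 1L, 0.3), G, K,
                   dimnames = list(sprintf("g%02d", 1:G), paste0("k", 1:K)))
  signed <- binary * matrix(sample(c(-1L, 1L), G * K, TRUE), G, K)
  dimnames(signed) <- dimnames(binary)
  res <- count_coregulation(binary, signed, min_obs = 0)
  for (r in sample(nrow(res), 10)) {
    i <- res$gene_i[r]; j <- res$gene_j[r]
    co <- binary[i, ] == 1L & binary[j, ] == 1L
    expect_equal(res$n[r], sum(co))
    expect_equal(res$n_discordant[r], sum(co & signed[i, ] != signed[j, ]))
  }
  # canonical ordering
  expect_true(all(res$gene_i < res$gene_j))
})

test_that("misaligned or inconsistent matrices are rejected", {
  mats <- make_hand_matrices()
  expect_error(count_coregulation(mats$binary, mats$signed[, 1:3]),
               "aligned")
  bad <- mats$signed; bad[1, 1] <- 0L
  expect_error(count_coregulation(mats$binary, bad), "nonzero exactly")
})

test_that("betabinom_pmf matches closed forms and sums to one", {
  # Beta(1,1) prior makes the count uniform on 0..K
  par <- betabinom_params(1, 1, 5)
  expect_equal(betabinom_pmf(0:5, par), rep(1 / 6, 6), tolerance = 1e-12)
  # K = 1: mass at 1 is the prior mean
  expect_equal(betabinom_pmf(1L, betabinom_params(2, 3, 1)), 2 / 5,
               tolerance = 1e-12)
  # normalisation and agreement with the direct Beta-function formula
  set.seed(4)
  for (i in 1:25) {
    K <- sample(2:60, 1); a <- runif(1, 0.1, 20); b <- runif(1, 0.1, 20)
    par <- betabinom_params(a, b, K)
    p <- betabinom_pmf(0:K, par)
    expect_equal(sum(p), 1, tolerance = 1e-9)
    expect_equal(p, bb_pmf_direct(0:K, K, a, b), tolerance = 1e-9)
  }
  expect_error(betabinom_params(-1, 2, 5), "positive")
  expect_error(betabinom_pmf(7L, betabinom_params(1, 1, 5)), "0..K")
})

test_that("betabinom_pmf matches a two-stage Monte-Carlo oracle", {
  set.seed(11)
  draws <- rbetabinom(1e6, 10, 2.5, 7.1)
  mc <- mean(draws == 4L)
  se <- sqrt(mc * (1 - mc) / 1e6)
  p <- betabinom_pmf(4L, betabinom_params(2.5, 7.1, 10))
  expect_true(abs(p - mc) <= 3 * se)
})

test_that("moment fit recovers beta-binomial parameters from draws", {
  set.seed(8)
  x <- rbetabinom(1e5, 20, 2, 5)
  fit <- fit_betabinom(x, 20)
  expect_false(fit$degenerate)
  expect_true(fit$alpha >= 1.8 && fit$alpha <= 2.2)
  expect_true(fit$beta >= 4.5 && fit$beta <= 5.5)
})

test_that("binomial draws trigger the binomial-matching fallback", {
  set.seed(12)
  x <- rbinom(20000, 20, 0.3)
  fit <- fit_betabinom(x, 20)
  expect_false(fit$degenerate)
  # fitted variance within 5% of the binomial variance
  p <- betabinom_pmf(0:20, fit)
  mu <- sum(0:20 * p)
  v <- sum((0:20)^2 * p) - mu^2
  vb <- 20 * 0.3 * 0.7
  expect_true(abs(v - vb) / vb < 0.05)
})

test_that("degenerate all-zero null vectors are flagged and handled", {
  fit <- fit_betabinom(rep(0L, 100), 10)
  expect_true(fit$degenerate)
  expect_equal(pair_pvalue(0L, fit), 1)
  expect_equal(pair_pvalue(3L, fit), .Machine$double.xmin)
})

test_that("pair_pvalue is the inclusive upper tail and monotone", {
  par <- betabinom_params(1, 1, 5)
  expect_equal(pair_pvalue(0L, par), 1)
  expect_equal(pair_pvalue(5L, par), 1 / 6, tolerance = 1e-12)
  # brute-force summation oracle, K = 10, alpha = beta = 2, n = 7
  par2 <- betabinom_params(2, 2, 10)
  expect_equal(pair_pvalue(7L, par2), sum(bb_pmf_direct(7:10, 10, 2, 2)),
               tolerance = 1e-12)
  # brute force on random cases
  set.seed(6)
  for (i in 1:25) {
    K <- sample(2:40, 1); a <- runif(1, 0.2, 10); b <- runif(1, 0.2, 10)
    n <- sample(0:K, 1)
    expect_equal(pair_pvalue(n, betabinom_params(a, b, K)),
                 sum(bb_pmf_direct(n:K, K, a, b)), tolerance = 1e-9)
  }
  # non-increasing in the observed count
  ps <- pair_pvalue(0:10, par2)
  expect_true(all(diff(ps) <= 1e-12))
})

test_that("compute_fdr reproduces hand BH values and stays monotone", {
  df <- data.frame(p_value = c(0.01, 0.02, 0.03))
  expect_equal(compute_fdr(df)$fdr, c(0.03, 0.03, 0.03))
  expect_equal(compute_fdr(data.frame(p_value = 0.2))$fdr, 0.2)
  # rank order of fdr equals rank order of p
  set.seed(13)
  p <- runif(50)
  out <- compute_fdr(data.frame(p_value = p))
  expect_equal(order(out$fdr, p), order(p))
  # enlarged family scales the adjustment
  expect_equal(compute_fdr(data.frame(p_value = 0.001), m = 100)$fdr, 0.1)
  expect_equal(nrow(compute_fdr(data.frame(p_value = numeric(0)))), 0L)
})

test_that("coreg_pair_stats flags planted signal against the margin null", {
  cfg <- simulation_config(seed = 31,
                           planted_pairs = data.frame(type = "concordant",
                                                      co_deg_rate = 0.4))
  sim <- simulate_contrast_set(cfg)
  mats <- build_deg_matrices(sim$contrasts)
  st <- coreg_pair_stats(mats$binary, mats$signed, n_samplings = 300,
                         seed = 31)
  planted <- st$gene_i == "G0001" & st$gene_j == "G0002"
  expect_true(any(planted))
  expect_lt(st$fdr[planted], 0.05)
  expect_true(all(st$p_value >= 0 & st$p_value <= 1))
  expect_true(all(st$fdr >= st$p_value - 1e-12))
})
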