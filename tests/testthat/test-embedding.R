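test_that("stratified split is exact in the divisible case and deterministic", {
  site <- factor(rep(sprintf("s%02d", 1:10), each = 10))
  sp <- stratified_split(100, site_labels = site, seed = 3)
  expect_equal(as.vector(table(sp)), c(80, 10, 10))
  per_site <- table(site, sp)
  expect_true(all(per_site[, "train"] == 8))
  expect_true(all(per_site[, "val"] == 1))
  expect_true(all(per_site[, "test"] == 1))
  sp2 <- stratified_split(100, site_labels = site, seed = 3)
  expect_identical(as.integer(sp), as.integer(sp2))
  expect_false(identical(as.integer(sp),
                         as.integer(stratified_split(100, site_labels = site,
                                                     seed = 4))))
})

test_that("unequal sites keep per-site proportions within one participant", {
  withr::with_seed(1, {
    sizes <- sample(20:150, 12)
  })
  site <- factor(rep(sprintf("s%02d", seq_along(sizes)), times = sizes))
  sp <- stratified_split(length(site), site_labels = site, seed = 7)
  counts <- table(site, sp)
  for (s in rownames(counts)) {
    ns <- sum(counts[s, ])
    expect_lte(abs(counts[s, "train"] / ns - 0.8), 1 / ns)
    expect_lte(abs(counts[s, "val"] / ns - 0.1), 1 / ns)
  }
  # exhaustive and disjoint by construction of a factor: every participant
  # has exactly one assignment
  expect_equal(sum(counts), length(site))
})

test_that("sites smaller than the number of splits are rejected by name", {
  site <- factor(c(rep("big", 50), "tiny", "tiny"))
  expect_error(stratified_split(52, site_labels = site), "tiny")
})

test_that("KL term is zero at the prior and matches quadrature off it", {
  # hand-built model: mu = first input coordinate, log-variance = 0
  d <- 2
  cfg <- cvae_config(latent_dim = 1, hidden_dim = d, frontend_dim = NULL,
                     conditioned = FALSE, activation = "linear")
  params <- list(
    W1 = diag(d), b1 = rep(0, d),
    Wmu = matrix(c(1, 0), d, 1), bmu = 0,
    Wlv = matrix(0, d, 1), blv = 0,
    W4 = diag(1), b4 = rep(0, 1),
    W5 = matrix(0, 1, d), b5 = rep(0, d)
  )
  model <- cvae_model(params, cfg)
  # mu = 0, sigma = 1: posterior equals prior, KL = 0
  out0 <- elbo_loss(matrix(c(0, 5), 1, 2), model = model)
  expect_equal(out0$kl, 0)
  # mu = 1, sigma = 1: closed form 0.5; cross-check by numerical quadrature
  out1 <- elbo_loss(matrix(c(1, 0), 1, 2), model = model)
  q <- function(z) stats::dnorm(z, 1, 1)
  integrand <- function(z) q(z) * (stats::dnorm(z, 1, 1, log = TRUE) -
                                     stats::dnorm(z, 0, 1, log = TRUE))
  kl_quad <- stats::integrate(integrand, -10, 12)$value
  expect_equal(out1$kl, 0.5, tolerance = 1e-10)
  expect_equal(out1$kl, kl_quad, tolerance = 1e-6)
})

test_that("perfect reconstruction gives a zero reconstruction term", {
  # identity autoencoder in one latent dimension
  cfg <- cvae_config(latent_dim = 1, hidden_dim = 1, frontend_dim = NULL,
                     conditioned = FALSE, activation = "linear")
  params <- list(
    W1 = matrix(1), b1 = 0,
    Wmu = matrix(1), bmu = 0,
    Wlv = matrix(0), blv = 0,
    W4 = matrix(1), b4 = 0,
    W5 = matrix(1), b5 = 0
  )
  model <- cvae_model(params, cfg)
  x <- matrix(rnorm(20), 20, 1)
  out <- elbo_loss(x, model = model)
  expect_equal(out$reconstruction, 0)
  expect_equal(out$total, out$reconstruction + out$kl)
})

test_that("KL term is never negative", {
  withr::with_seed(5, {
    for (i in 1:50) {
      mu <- matrix(rnorm(40, sd = 3), 8)
      lv <- matrix(rnorm(40, sd = 2), 8)
      expect_gte(min(phenostrat:::kl_diag_gaussian(mu, lv)), 0)
    }
  })
})

test_that("training reduces the validation objective and is seed-deterministic", {
  fx <- small_trained_fixture()
  h <- fx$model$history
  expect_lt(min(h$val_loss), h$val_loss[1])
  cfg <- fx$model$config
  again <- train_cvae(fx$curated, fx$split, cfg)
  expect_identical(again$params, fx$model$params)
  expect_identical(again$history, fx$model$history)
})

test_that("reconstruction is deterministic at the posterior mean and seed-replayable when sampling", {
  fx <- small_trained_fixture()
  X <- fx$curated$values[1:10, , drop = FALSE]
  cc <- fx$curated$site[1:10]
  a <- reconstruct(fx$model, X, cc)
  b <- reconstruct(fx$model, X, cc)
  expect_identical(a, b)
  s1 <- reconstruct(fx$model, X, cc, mode = "sample", seed = 9)
  s2 <- reconstruct(fx$model, X, cc, mode = "sample", seed = 9)
  s3 <- reconstruct(fx$model, X, cc, mode = "sample", seed = 10)
  expect_identical(s1, s2)
  expect_false(identical(s1, s3))
  expect_error(reconstruct(fx$model, X, rep("nowhere", 10)), "unseen")
})

test_that("PCA train MSE equals the discarded eigenvalue mass", {
  withr::with_seed(31, {
    for (i in 1:3) {
      n <- 150; p <- 25; K <- 6
      X <- matrix(rnorm(n * p), n) %*% matrix(rnorm(p * p, sd = 0.5), p)
      tab <- toy_table(X)
      split <- factor(rep("train", n), levels = c("train", "val", "test"))
      fit <- fit_pca_baseline(tab, split, n_components = K)
      got <- mse_test(fit, tab, split, subset = "train")
      # eigendecomposition oracle (population-scaled covariance)
      Xc <- sweep(X, 2, colMeans(X))
      lam <- eigen(crossprod(Xc) / n, symmetric = TRUE, only.values = TRUE)$values
      expect_equal(got, sum(lam[(K + 1):p]), tolerance = 1e-6)
    }
  })
})

test_that("full-rank PCA reconstructs exactly and the basis is orthonormal", {
  withr::with_seed(8, {
    X <- matrix(rnorm(60 * 10), 60)
  })
  tab <- toy_table(X)
  split <- factor(rep(c("train", "val", "test"), each = 20),
                  levels = c("train", "val", "test"))
  fit <- fit_pca_baseline(tab, split, n_components = 10)
  expect_lt(mse_test(fit, tab, split), 1e-16)
  expect_lt(max(abs(crossprod(fit$rotation) - diag(10))), 1e-8)
  expect_error(fit_pca_baseline(tab, split, n_components = 21), "exceeds")
})

test_that("zero-predictor MSE on standardized data approximates the variable count", {
  fx <- small_trained_fixture()
  te <- which(fx$split == "test")
  X <- fx$curated$values[te, ]
  # summed-per-participant convention: predicting the test mean leaves
  # roughly the summed unit variances of the continuous block plus the
  # indicator variances
  mse0 <- mean(rowSums(sweep(X, 2, colMeans(X))^2))
  expected <- sum(apply(X, 2, stats::var)) * (length(te) - 1) / length(te)
  expect_equal(mse0, expected, tolerance = 1e-10)
  cont <- sum(fx$curated$meta$dtype == "continuous")
  expect_gt(mse0, 0.5 * cont)
  expect_lt(mse0, 1.5 * ncol(X))
})

test_that("site conditioning absorbs batch structure", {
  # large site offsets: the conditioned model reconstructs unseen
  # participants better than the unconditioned one for most seeds
  wins <- 0L
  for (s in 1:3) {
    cfg <- clean_config(n_participants = 500, n_variables = 40,
                        site_effect_sd = 3, n_sites = 4, seed = 100L + s)
    sim <- generate_phenome(cfg)
    cur <- curate(sim$table)
    split <- stratified_split(cur$table, seed = s)
    base <- list(latent_dim = 4, hidden_dim = 24, frontend_dim = 20,
                 max_epochs = 80, patience = 15, seed = s)
    m_c <- train_cvae(cur$table, split, do.call(cvae_config, c(base, conditioned = TRUE)))
    m_u <- train_cvae(cur$table, split, do.call(cvae_config, c(base, conditioned = FALSE)))
    if (mse_test(m_c, cur$table, split) < mse_test(m_u, cur$table, split)) {
      wins <- wins + 1L
    }
  }
  expect_gte(wins, 2L)
})

test_that("architecture selection reports replicate statistics and flags the winner", {
  fx <- small_trained_fixture()
  cands <- list(
    cvae_config(latent_dim = 4, hidden_dim = 8, frontend_dim = 15,
                max_epochs = 25, patience = 8),
    cvae_config(latent_dim = 4, hidden_dim = 48, frontend_dim = 15,
                max_epochs = 25, patience = 8)
  )
  tab <- select_architecture(cands, fx$curated, fx$split, n_replicates = 3,
                             base_seed = 2)
  expect_equal(nrow(tab), 2)
  expect_true(all(tab$n_replicates == 3))
  expect_equal(sum(tab$winner), 1)
  expect_equal(which(tab$winner), which.min(tab$mean_mse))
  expect_s3_class(attr(tab, "winner_model"), "cvae_model")
  # single candidate: trivially selected
  tab1 <- select_architecture(cands[1], fx$curated, fx$split, n_replicates = 2,
                              base_seed = 2)
  expect_true(tab1$winner[1])
})
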