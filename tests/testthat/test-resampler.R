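test_that("lognormal moment matching reproduces the stated closed forms", {
  rho <- diag(2)
  lp <- lognormal_params(c(a = 1, b = 1), c(a = 0, b = 0), rho)
  expect_equal(unname(lp$mu), c(0, 0))
  expect_equal(unname(diag(lp$cov)), c(0, 0))
  lp2 <- lognormal_params(c(a = 2, b = 2), c(a = 1, b = 1), rho)
  expect_equal(unname(lp2$mu[1]), log(4 / sqrt(5)), tolerance = 1e-12)
  expect_equal(unname(lp2$cov[1, 1]), log(1.25), tolerance = 1e-12)
  expect_equal(lp2$cov[1, 2], 0)
  expect_error(lognormal_params(c(0, 1), c(0, 0), rho),
               class = "qaop_domain_error")
})

test_that("exponentiated Gaussian draws recover the primary moments", {
  fbar <- c(x = 1.8, y = 2.6, z = 1.1)
  s <- c(x = 0.3, y = 0.5, z = 0.1)
  rho <- matrix(c(1, .5, .2, .5, 1, .4, .2, .4, 1), 3)
  lp <- lognormal_params(fbar, s, rho)
  set.seed(99)
  draws <- exp(MASS::mvrnorm(1e5, lp$mu, lp$cov))
  expect_equal(unname(colMeans(draws)), unname(fbar), tolerance = 0.02)
  expect_equal(unname(apply(draws, 2, sd)), unname(s), tolerance = 0.02)
  # cross-node correlation on the log scale matches the plug-in rho
  expect_equal(cor(log(draws))[1, 2], 0.5, tolerance = 0.02)
})

test_that("correlation estimates behave at the boundaries", {
  fx <- tiny_fixture()
  p <- fx$primary
  # make two responses exactly affine: correlation must be 1
  p$mean_fc[, , , "KE1"] <- 2 * p$mean_fc[, , , "MIE1"] - 0.5
  rho <- estimate_rho(p, 1)
  expect_equal(rho["KE1", "MIE1"], 1, tolerance = 1e-12)
  expect_true(all(diag(rho) == 1))
  expect_true(all(abs(rho) <= 1 + 1e-12))
})

test_that("acute and pre-onset chronic responses are nearly uncorrelated", {
  vals <- vapply(1:10, function(seed) {
    p <- generate_primary(study_design(seed = seed))
    estimate_rho(p, 1)["KE1", "KE4"]   # exposure 1: KE4 unelicited everywhere
  }, numeric(1))
  expect_lt(abs(mean(vals)), 0.2)
})

test_that("the conjugate update matches hand linear algebra", {
  # one predictor, three points on the diagonal, prior N(0, 1), sigma2 = 1:
  # XtX = 14, Xty = 14, posterior precision 15, posterior mean 14/15
  up <- bayes_update(list(beta = 0, cov = matrix(1)),
                     matrix(c(1, 2, 3)), c(1, 2, 3), 1)
  expect_equal(unname(up$beta), 14 / 15, tolerance = 1e-10)
  expect_equal(up$cov[1, 1], 1 / 15, tolerance = 1e-10)
})

test_that("flat-prior and uninformative-data limits are honored", {
  set.seed(1)
  X <- cbind(1, rnorm(50))
  y <- 2 + 3 * X[, 2] + rnorm(50, 0, .1)
  ols <- qr.coef(qr(X), y)
  flat <- bayes_update(list(beta = c(0, 0), cov = diag(1e6, 2)), X, y, 1)
  expect_equal(unname(flat$beta), unname(ols), tolerance = 1e-4)
  tight <- bayes_update(list(beta = c(5, -1), cov = diag(1e-8, 2)), X, y, 1e6)
  expect_equal(unname(tight$beta), c(5, -1), tolerance = 1e-4)
})

test_that("sequential updates equal one pooled update under fixed sigma2", {
  set.seed(2)
  XA <- cbind(1, rnorm(20)); yA <- rnorm(20)
  XB <- cbind(1, rnorm(25)); yB <- rnorm(25)
  prior <- list(beta = c(0, 0), cov = diag(2))
  seq2 <- bayes_update(bayes_update(prior, XA, yA, 1.3), XB, yB, 1.3)
  pool <- bayes_update(prior, rbind(XA, XB), c(yA, yB), 1.3)
  expect_equal(seq2$beta, pool$beta, tolerance = 1e-10)
  expect_equal(seq2$cov, pool$cov, tolerance = 1e-10)
})

test_that("more within-cell draws tighten the posterior", {
  set.seed(3)
  X1 <- matrix(rnorm(30), 30)
  X2 <- rbind(X1, matrix(rnorm(60), 60))
  prior <- list(beta = 0, cov = matrix(2))
  t1 <- sum(diag(bayes_update(prior, X1, rnorm(30), 1)$cov))
  t2 <- sum(diag(bayes_update(prior, X2, rnorm(90), 1)$cov))
  expect_lt(t2, t1)
})

test_that("resampling is deterministic and anchored at the control", {
  fx <- tiny_fixture()
  r1 <- resample_replicates(fx$primary, seed = 5L)
  r2 <- resample_replicates(fx$primary, seed = 5L)
  expect_identical(r1$replicates, r2$replicates)
  expect_true(all(r1$replicates[, , 1, , ] == 1))
  expect_true(all(r1$replicates > 0))
  expect_equal(r1$mean, apply(r1$replicates, c(1, 2, 3, 5), mean))
})

test_that("replicate averages converge to the primary fold changes", {
  fx <- tiny_fixture()
  big <- resample_replicates(fx$primary, R = 4000, seed = 21L)
  # marginal node (dose-rooted): lognormal mean is exactly the primary mean
  m <- big$replicates[1, 2, 2, , "MIE1"]
  se <- sd(m) / sqrt(length(m))
  expect_lt(abs(mean(m) - fx$primary$mean_fc[1, 2, 2, "MIE1"]), 3 * se)
})

test_that("kappa too small for the largest parent set is rejected", {
  fx <- full_fixture()
  expect_error(resample_replicates(fx$primary, kappa = 5L),
               class = "qaop_design_error")
})

test_that("indefinite plug-in covariances are repaired without touching the diagonal", {
  o <- c(0.3, 0.2, 0.1)
  rho <- matrix(c(1, .95, -.9, .95, 1, .9, -.9, .9, 1), 3)  # infeasible triple
  O <- rho * sqrt(outer(o, o)); diag(O) <- o
  expect_lt(min(eigen(O, symmetric = TRUE)$values), 0)
  R <- qaopr:::repair_psd(O)
  expect_gte(min(eigen(R, symmetric = TRUE)$values), 0)
  expect_equal(diag(R), o, tolerance = 1e-8)
})
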