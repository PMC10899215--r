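test_that("ridge at lambda 0 is ordinary least squares", {
  set.seed(10)
  X <- matrix(rnorm(120), 40)
  colnames(X) <- c("a", "b", "c")
  y <- 1 + X %*% c(0.5, -1, 2) + rnorm(40, 0, 0.3)
  fit <- ridge_loocv(X, y, lambda = 0)
  ols <- coef(lm(y ~ X))
  expect_equal(unname(fit$beta), unname(ols), tolerance = 1e-8)
})

test_that("infinite shrinkage drives slopes to zero, intercept to the mean", {
  set.seed(11)
  X <- matrix(rnorm(60), 30); colnames(X) <- c("a", "b")
  y <- 2 + X %*% c(1, -1) + rnorm(30, 0, .1)
  fit <- ridge_loocv(X, y, lambda = 1e12)
  expect_equal(unname(fit$beta[-1]), c(0, 0), tolerance = 1e-6)
  expect_equal(unname(fit$beta[1]), mean(y), tolerance = 1e-4)
})

test_that("the leverage shortcut equals brute-force leave-one-out", {
  set.seed(12)
  n <- 18
  X <- matrix(rnorm(n * 2), n); colnames(X) <- c("a", "b")
  y <- 0.5 + X %*% c(1, 2) + rnorm(n, 0, 0.5)
  for (lam in c(0.01, 1, 10)) {
    fit <- ridge_loocv(X, y, lambda = lam)
    manual <- mean(vapply(seq_len(n), function(i) {
      Xi <- X[-i, , drop = FALSE]; yi <- y[-i]
      xm <- colMeans(Xi); ym <- mean(yi)
      Xc <- sweep(Xi, 2, xm); yc <- yi - ym
      b <- solve(crossprod(Xc) + diag(lam, 2), crossprod(Xc, yc))
      pred <- ym + sum((X[i, ] - xm) * b)
      (y[i] - pred)^2
    }, numeric(1)))
    expect_equal(fit$cv$mse[fit$cv$lambda == lam], manual, tolerance = 1e-8)
  }
})

test_that("lagged coefficients are recovered within 3 SEs at n = 200", {
  set.seed(13)
  n <- 200
  X <- cbind(p1 = rnorm(n, 0.3, 0.2), p2 = rnorm(n, 0.1, 0.2))
  y <- 0.05 + X %*% c(0.8, -0.3) + rnorm(n, 0, 0.05)
  fit <- ridge_loocv(X, y)
  se <- sqrt(0.05^2 * diag(solve(crossprod(sweep(X, 2, colMeans(X))))))
  expect_lt(fit$lambda, 1)   # near-unpenalized on clean, well-posed data
  expect_true(all(abs(fit$beta[-1] - c(0.8, -0.3)) < 3 * se))
})

test_that("slice models cover all target exposures and parentless nodes", {
  fx <- tiny_fixture()
  dbn <- fit_dbn(fx$replicates)
  expect_identical(dbn$exposures, 2:3)
  expect_null(dbn$slices[[1]])
  sl <- dbn$slices[[2]]
  expect_identical(sl$MIE1$parents, character(0))   # dose root excluded
  expect_identical(sl$KE8$parents, "KE1")
  expect_identical(sl$AO$parents, "KE8")
  expect_true(all(vapply(sl, function(p) p$sigma2 >= 0, logical(1))))
})

test_that("infeasible or mismatched transition queries are rejected", {
  fx <- tiny_fixture()
  dbn <- fit_dbn(fx$replicates)
  # KE8 sits one slice upstream of the AO; tau = 2 contradicts the graph
  expect_error(transition_probability(dbn, fx$replicates, "KE8", 2, 3),
               class = "qaop_design_error")
  # e - tau must leave at least one fitted slice before the evidence
  expect_error(transition_probability(dbn, fx$replicates, "KE8", 1, 2),
               class = "qaop_design_error")
  expect_error(transition_probability(dbn, fx$replicates, "XX", 1, 3),
               class = "qaop_unknown_node_error")
})

test_that("transition estimates are seed-reproducible", {
  fx <- tiny_fixture()
  dbn <- fit_dbn(fx$replicates)
  a <- transition_probability(dbn, fx$replicates, "KE8", 1, 3,
                              delta = 0.1, n_sims = 2000, seed = 14)
  b <- transition_probability(dbn, fx$replicates, "KE8", 1, 3,
                              delta = 0.1, n_sims = 2000, seed = 14)
  expect_identical(a, b)
  expect_true(a$prob >= 0 && a$prob <= 1)
  expect_equal(a$se, sqrt(a$prob * (1 - a$prob) / a$n_conditioning))
})

test_that("deterministic sub-threshold chains give zero probability", {
  g <- tiny_fixture()$graph
  d <- study_design(doses = c(0, 100), n_donors = 4L, n_exposures = 3L,
                    seed = 1L)
  m <- blank_mean(d, g)
  m[, , 2, "KE8"] <- 10     # conditioning event certain at treated dose
  rd <- fake_rep(m, d, g)
  slices <- rep(list(NULL), 3)
  mk <- function(pa, beta, s2) list(parents = pa, beta = beta, sigma2 = s2)
  for (e in 2:3) {
    slices[[e]] <- list(
      MIE1 = mk(character(0), c(`(Intercept)` = 0), 0),
      KE1 = mk("MIE1", c(`(Intercept)` = 0, MIE1 = 0), 0),
      KE8 = mk("KE1", c(`(Intercept)` = 0.1, KE1 = 0), 0),
      AO = mk("KE8", c(`(Intercept)` = 0.1, KE8 = 0), 0))
  }
  dbn <- structure(list(slices = slices, graph = g, dose_mode = "pooled",
                        exposures = 2:3, design = d),
                   class = "dbn_model")
  out <- transition_probability(dbn, rd, "KE8", 1, 3, n_sims = 500, seed = 15)
  expect_equal(out$prob, 0)
})

test_that("simulation matches the closed-form conditional for a 2-slice chain", {
  g <- tiny_fixture()$graph
  d <- study_design(doses = c(0, 100), n_donors = 8L, n_exposures = 3L,
                    seed = 1L)
  m <- blank_mean(d, g)
  ke8_vals <- seq(0.1, 0.6, length.out = 8)     # log10 fold changes
  m[, 2, 2, "KE8"] <- 10^ke8_vals
  rd <- fake_rep(m, d, g)
  b <- 1.2; s <- 0.15; a <- -0.05
  slices <- rep(list(NULL), 3)
  mk <- function(pa, beta, s2) list(parents = pa, beta = beta, sigma2 = s2)
  slices[[3]] <- list(
    MIE1 = mk(character(0), c(`(Intercept)` = 0), 0),
    KE1 = mk("MIE1", c(`(Intercept)` = 0, MIE1 = 0), 0),
    KE8 = mk("KE1", c(`(Intercept)` = 0, KE1 = 0), 0),
    AO = mk("KE8", c(`(Intercept)` = a, KE8 = b), s^2))
  dbn <- structure(list(slices = slices, graph = g, dose_mode = "pooled",
                        exposures = 2:3, design = d),
                   class = "dbn_model")
  delta <- log10(2)
  out <- transition_probability(dbn, rd, "KE8", 1, 3, delta = delta,
                                n_sims = 4e4, seed = 16)
  # bootstrap init is uniform over rows; condition selects ke8 > delta, and
  # AO | ke8 is Gaussian, so the target is the average tail probability
  exceed <- ke8_vals[ke8_vals > delta]
  p_exact <- mean(pnorm(delta, a + b * exceed, s, lower.tail = FALSE))
  expect_lt(abs(out$prob - p_exact),
            3 * sqrt(p_exact * (1 - p_exact) / out$n_conditioning))
})

test_that("per-dose fits flag small samples and produce a full dose table", {
  fx <- tiny_fixture()
  expect_warning(fit_dbn(fx$replicates, dose = 100), "error prone")
  tab <- suppressWarnings(
    dose_specific_transitions(fx$replicates, n_sims = 1000, seed = 17))
  expect_true(all(tab$dose == "100"))
  expect_true(all(tab$ke == "KE8"))
  expect_true(all(is.na(tab$prob) | (tab$prob >= 0 & tab$prob <= 1)))
})
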