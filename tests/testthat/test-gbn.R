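# Build a gbn_model by hand on the tiny 5-node pathway.
toy_gbn <- function(coefs, sigmas, dose_range = c(0, 100)) {
  g <- tiny_fixture()$graph
  params <- lapply(g$bio_nodes, function(v) {
    pv <- ifelse(parents(g, v) == "DOSE", "DOSE", parents(g, v))
    list(parents = pv,
         coef = stats::setNames(coefs[[v]], c("(Intercept)", pv)),
         sigma2 = sigmas[[v]], r2 = NA_real_, n = NA_integer_)
  })
  names(params) <- g$bio_nodes
  structure(list(node_params = params, graph = g, exposure = 1L,
                 dose_range = dose_range, doses = c(0, 100)),
            class = "gbn_model")
}

test_that("noiseless networks propagate deterministically", {
  m <- toy_gbn(list(MIE1 = c(0.1, 0.002), KE1 = c(0, 2),
                    KE8 = c(0.05, 1), AO = c(-0.1, 1.5)),
               list(MIE1 = 0, KE1 = 0, KE8 = 0, AO = 0))
  s <- logic_sample(m, 50, seed = 1, dose = 50)
  mie <- 0.1 + 0.002 * 50
  expect_true(all(s[, "MIE1"] == mie))
  expect_true(all(s[, "KE1"] == 2 * mie))
  expect_true(all(s[, "AO"] == -0.1 + 1.5 * (0.05 + 2 * mie)))
  s2 <- logic_sample(m, 50, seed = 1, dose = 50)
  expect_identical(s, s2)
})

test_that("sampled node means match the fitted conditional means", {
  m <- toy_gbn(list(MIE1 = c(0.1, 0.004), KE1 = c(0.05, 1.2),
                    KE8 = c(0, 0.8), AO = c(0, 1)),
               list(MIE1 = 0.01, KE1 = 0.01, KE8 = 0.01, AO = 0.01))
  s <- logic_sample(m, 4e4, seed = 2)
  # MIE mean at uniformly sampled doses: intercept + slope * E[dose]
  expect_equal(mean(s[, "MIE1"]), 0.1 + 0.004 * 50, tolerance = 0.01)
  expect_equal(mean(s[, "KE1"]), 0.05 + 1.2 * mean(s[, "MIE1"]),
               tolerance = 0.01)
})

test_that("per-node OLS recovers known coefficients within 3 SEs", {
  m <- toy_gbn(list(MIE1 = c(0.1, 0.003), KE1 = c(0.05, 1.4),
                    KE8 = c(0.02, 0.7), AO = c(-0.05, 1.1)),
               list(MIE1 = 0.004, KE1 = 0.004, KE8 = 0.004, AO = 0.004))
  s <- logic_sample(m, 200, seed = 3)
  fit <- qaopr:::fit_gbn_matrix(s, tiny_fixture()$graph)
  for (v in c("MIE1", "KE1", "KE8", "AO")) {
    est <- fit$node_params[[v]]
    se <- sqrt(diag(est$cov))
    truth <- m$node_params[[v]]$coef
    expect_true(all(abs(est$coef - truth) < 3 * se),
                info = paste("recovery", v))
  }
})

test_that("degenerate designs raise rank errors", {
  s <- logic_sample(toy_gbn(list(MIE1 = c(0.1, 0.003), KE1 = c(0, 1),
                                 KE8 = c(0, 1), AO = c(0, 1)),
                            list(MIE1 = 0.01, KE1 = 0.01, KE8 = 0.01,
                                 AO = 0.01)),
                    100, seed = 4)
  s[, "KE1"] <- 0.2   # constant parent of KE8
  expect_error(qaopr:::fit_gbn_matrix(s, tiny_fixture()$graph),
               class = "qaop_rank_error")
})

test_that("activation probability is an exceedance fraction with sane limits", {
  fx <- full_fixture()
  gbn <- fit_gbn(fx$replicates, 5)
  s <- logic_sample(gbn, 2e4, seed = 5)
  expect_equal(activation_probability(s, "KE1", 200, delta = -100)$prob, 1)
  p1 <- activation_probability(s, "KE8", 100)
  expect_true(p1$prob >= 0 && p1$prob <= 1)
  expect_equal(p1$se, sqrt(p1$prob * (1 - p1$prob) / p1$n))
  expect_error(activation_probability(s, "KE8", 1e6, eps = 1),
               class = "qaop_empty_window_error")
  # monotone non-increasing in the threshold, by construction
  surf <- probability_surface(s, "KE8", delta_grid = seq(0, 1, 0.05))
  expect_true(all(apply(surf$prob, 2, diff) <= 0))
  expect_true(all(surf$prob >= 0 & surf$prob <= 1))
})

test_that("logic sampling converges to the closed-form Gaussian exceedance", {
  # dose-independent 2-node chain: KE8 ~ N(mu, s1), AO = a + b KE8 + N(0, s2)
  m <- toy_gbn(list(MIE1 = c(0.2, 0), KE1 = c(0.1, 1),
                    KE8 = c(0, 1), AO = c(0.05, 1.3)),
               list(MIE1 = 0.02^2, KE1 = 0.05^2, KE8 = 0.08^2, AO = 0.06^2))
  s <- logic_sample(m, 1e5, seed = 6)
  mu_ke8 <- 0.3
  var_ke8 <- 0.02^2 + 0.05^2 + 0.08^2
  mu_ao <- 0.05 + 1.3 * mu_ke8
  sd_ao <- sqrt(1.3^2 * var_ke8 + 0.06^2)
  delta <- log10(2)
  p_exact <- pnorm(delta, mu_ao, sd_ao, lower.tail = FALSE)
  p_mc <- mean(s[, "AO"] > delta)
  expect_lt(abs(p_mc - p_exact),
            3 * sqrt(p_exact * (1 - p_exact) / 1e5))
})

test_that("volume under the surface integrates exactly on analytic inputs", {
  unit_surface <- function(prob) {
    structure(list(delta_grid = seq(0, 1, length.out = nrow(prob)),
                   dose_grid = seq(0, 1, length.out = ncol(prob)),
                   prob = prob, node = "x", eps = 0.05),
              class = "probability_surface")
  }
  expect_equal(vus(unit_surface(matrix(1, 11, 11))), 1, tolerance = 1e-12)
  expect_equal(vus(unit_surface(matrix(0, 11, 11))), 0)
  # threshold-independent plane rising linearly with dose
  plane <- matrix(rep(seq(0, 1, length.out = 101), each = 101), 101)
  expect_equal(vus(unit_surface(plane)), 0.5, tolerance = 1e-3)
  bad <- unit_surface(matrix(1, 1, 1))
  expect_error(vus(bad), class = "qaop_grid_error")
})
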