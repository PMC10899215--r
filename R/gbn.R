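#' Fit the static Gaussian Bayesian network for one exposure repetition
#'
#' Each biology node is modeled as linear-Gaussian in its pathway parents,
#' with the dose root entering as a continuous covariate; the joint density
#' factorizes over the DAG. Fitting is per-node ordinary least squares on
#' the replicate-averaged log10 fold changes of all donors and doses at the
#' given exposure repetition. The per-node training R2 is recorded: chronic
#' nodes regressed on chronic parents fit well once the chronic phase is
#' elicited, while nodes bridging poorly correlated acute and chronic
#' branches do not.
#'
#' @param rep_data a [resample_replicates()] result.
#' @param exposure exposure repetition index.
#' @return Object of class `gbn_model`: per-node coefficients, residual
#'   variance and R2, plus the graph and dose range.
#' @export
fit_gbn <- function(rep_data, exposure) {
  stopifnot(inherits(rep_data, "replicate_dataset"))
  X <- slice_matrix(rep_data, exposure)
  info <- attr(X, "info")
  dat <- cbind(X, DOSE = info$dose)
  model <- fit_gbn_matrix(dat, rep_data$graph)
  model$exposure <- exposure
  model$dose_range <- range(rep_data$design$doses)
  model$doses <- rep_data$design$doses
  model
}

# Core per-node OLS on a data matrix whose columns include the biology
# nodes and a DOSE column. Exposed separately so parameter-recovery tests
# can fit data simulated from known coefficients.
fit_gbn_matrix <- function(dat, graph) {
  nodes <- graph$bio_nodes
  params <- vector("list", length(nodes)); names(params) <- nodes
  for (v in nodes) {
    pv <- graph$parents[[v]]
    pv <- ifelse(pv == graph$dose_node, "DOSE", pv)
    Xd <- cbind(`(Intercept)` = 1, dat[, pv, drop = FALSE])
    y <- dat[, v]
    qr_ <- qr(Xd)
    if (qr_$rank < ncol(Xd)) {
      qaop_stop("qaop_rank_error",
                "rank-deficient design for node '%s' (collinear or constant parent)", v)
    }
    beta <- qr.coef(qr_, y)
    resid <- y - Xd %*% beta
    rss <- sum(resid^2)
    tss <- sum((y - mean(y))^2)
    if (tss == 0) {
      qaop_stop("qaop_rank_error", "node '%s' has zero variance", v)
    }
    params[[v]] <- list(
      parents = pv,
      coef = stats::setNames(beta, c("(Intercept)", pv)),
      sigma2 = rss / max(length(y) - ncol(Xd), 1),
      cov = chol2inv(qr.R(qr_)) * rss / max(length(y) - ncol(Xd), 1),
      r2 = 1 - rss / tss,
      n = length(y)
    )
  }
  structure(list(node_params = params, graph = graph,
                 exposure = NA_integer_, dose_range = NULL),
            class = "gbn_model")
}

#' @export
print.gbn_model <- function(x, ...) {
  r2 <- vapply(x$node_params, `[[`, numeric(1), "r2")
  cat(sprintf("Static Gaussian Bayesian network (exposure %s)\n",
              x$exposure))
  print(round(r2, 3))
  invisible(x)
}

#' Per-node training R2 of a fitted GBN
#'
#' @param model a [fit_gbn()] result.
#' @return named numeric vector.
#' @export
gbn_r2 <- function(model) {
  vapply(model$node_params, `[[`, numeric(1), "r2")
}

#' Logic sampling from a fitted GBN
#'
#' Ancestral (forward) sampling in topological order: doses are drawn from
#' `dose_dist` (uniform over the dose range by default), then each node is
#' drawn from its linear-Gaussian conditional given the sampled parents.
#'
#' @param model a [fit_gbn()] result.
#' @param n_samples number of joint draws.
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @param dose fixed dose value(s) to condition the root on, or `NULL` to
#'   draw from `dose_dist`.
#' @param dose_dist function of `n` returning dose draws.
#' @return `n_samples` x (1 + nodes) matrix of log10 fold changes with the
#'   sampled `DOSE` in the first column.
#' @export
logic_sample <- function(model, n_samples = 1e5, seed = NULL, dose = NULL,
                         dose_dist = NULL) {
  stopifnot(inherits(model, "gbn_model"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(dose)) {
    if (is.null(dose_dist)) {
      rng <- model$dose_range
      if (is.null(rng)) rng <- c(0, 1)
      dose_dist <- function(n) stats::runif(n, rng[1], rng[2])
    }
    dose <- dose_dist(n_samples)
  } else {
    dose <- rep_len(dose, n_samples)
  }
  graph <- model$graph
  nodes <- graph$bio_nodes
  out <- matrix(NA_real_, n_samples, length(nodes) + 1L,
                dimnames = list(NULL, c("DOSE", nodes)))
  out[, "DOSE"] <- dose
  for (v in topo_order(graph, include_dose = FALSE)) {
    p <- model$node_params[[v]]
    mu <- p$coef[["(Intercept)"]] +
      drop(out[, p$parents, drop = FALSE] %*% p$coef[p$parents])
    out[, v] <- mu + stats::rnorm(n_samples, 0, sqrt(p$sigma2))
  }
  out
}

#' Activation probability within a dose window
#'
#' Fraction of logic samples whose dose lies in `[dose - eps, dose + eps]`
#' and whose node value exceeds the activation threshold `delta`
#' (log10 fold-change units; the default corresponds to a doubling).
#'
#' @param samples a [logic_sample()] matrix.
#' @param node node name.
#' @param dose window center.
#' @param delta activation threshold.
#' @param eps window half-width.
#' @return list with `prob`, the window sample count `n`, and the binomial
#'   standard error `se`.
#' @export
activation_probability <- function(samples, node, dose, delta = log10(2),
                                   eps = NULL) {
  if (is.null(eps)) eps <- 0.05 * diff(range(samples[, "DOSE"]))
  idx <- abs(samples[, "DOSE"] - dose) <= eps
  n <- sum(idx)
  if (n == 0L) {
    qaop_stop("qaop_empty_window_error",
              "no samples in dose window [%g, %g]", dose - eps, dose + eps)
  }
  p <- mean(samples[idx, node] > delta)
  list(prob = p, n = n, se = sqrt(p * (1 - p) / n))
}

#' Activation-probability surface over threshold and dose
#'
#' Evaluates `P(node > delta | dose window)` on a grid of thresholds and
#' dose window centers from one set of logic samples.
#'
#' @inheritParams activation_probability
#' @param delta_grid ascending thresholds (log10 fold change).
#' @param dose_grid ascending dose window centers.
#' @return Object of class `probability_surface` with the grids and the
#'   `length(delta_grid)` x `length(dose_grid)` probability matrix.
#' @export
probability_surface <- function(samples, node,
                                delta_grid = seq(0, 1, length.out = 21),
                                dose_grid = NULL, eps = NULL) {
  rng <- range(samples[, "DOSE"])
  if (is.null(dose_grid)) dose_grid <- seq(rng[1], rng[2], length.out = 21)
  if (is.null(eps)) eps <- 0.05 * diff(rng)
  prob <- vapply(dose_grid, function(d) {
    idx <- abs(samples[, "DOSE"] - d) <= eps
    if (!any(idx)) {
      qaop_stop("qaop_empty_window_error", "no samples near dose %g", d)
    }
    vals <- samples[idx, node]
    vapply(delta_grid, function(dl) mean(vals > dl), numeric(1))
  }, numeric(length(delta_grid)))
  structure(list(delta_grid = delta_grid, dose_grid = dose_grid,
                 prob = matrix(prob, nrow = length(delta_grid)),
                 node = node, eps = eps),
            class = "probability_surface")
}

#' Volume under a probability surface
#'
#' Composite two-dimensional trapezoid integral of the activation
#' probability over the (threshold, dose) grid; a scalar index of pathway
#' perturbation that grows as activation spreads to higher thresholds and
#' doses.
#'
#' @param surface a [probability_surface()].
#' @return scalar volume.
#' @export
vus <- function(surface) {
  stopifnot(inherits(surface, "probability_surface"))
  dg <- surface$delta_grid; sg <- surface$dose_grid
  if (length(dg) < 2 || length(sg) < 2 ||
      is.unsorted(dg, strictly = TRUE) || is.unsorted(sg, strictly = TRUE)) {
    qaop_stop("qaop_grid_error", "grids must be ascending with >= 2 points")
  }
  inner <- apply(surface$prob, 2, function(col) pracma::trapz(dg, col))
  pracma::trapz(sg, inner)
}

#' @export
print.probability_surface <- function(x, ...) {
  cat(sprintf("Activation-probability surface for %s: %d thresholds x %d doses\n",
              x$node, length(x$delta_grid), length(x$dose_grid)))
  invisible(x)
}
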