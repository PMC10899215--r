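#' Default ridge/lasso penalty grid
#'
#' Fifty log-spaced values between 1e-4 and 1e2.
#' @return numeric vector.
#' @export
default_lambda_grid <- function() 10^seq(-4, 2, length.out = 50)

#' Ridge regression with exact leave-one-out cross-validation
#'
#' Solves `min ||y - b0 - X b||^2 + lambda ||b||^2` (intercept unpenalized,
#' predictors and response centered, no rescaling since all variables are
#' log10 fold changes on a common scale) for every penalty in `lambda`, and
#' selects the penalty minimizing the exact LOOCV mean squared error via the
#' leverage shortcut `e_loo = e / (1 - h)`. At `lambda = 0` the solution is
#' ordinary least squares.
#'
#' @param X predictor matrix.
#' @param y response vector.
#' @param lambda penalty grid.
#' @return list with `lambda` (selected), `beta` (named, including
#'   `(Intercept)`), `sigma2` (residual variance at the selected penalty),
#'   `cv` (data frame of lambda and LOOCV MSE), `parents` (colnames of X).
#' @export
ridge_loocv <- function(X, y, lambda = default_lambda_grid()) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) {
    qaop_stop("qaop_alignment_error", "X and y have different lengths")
  }
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm); yc <- y - ym
  sv <- svd(Xc, nu = min(n, p), nv = p)
  d <- sv$d
  uty <- crossprod(sv$u, yc)
  tol <- max(d) * 1e-12
  cv_mse <- numeric(length(lambda))
  for (i in seq_along(lambda)) {
    lam <- lambda[i]
    shrink <- ifelse(d > tol, d^2 / (d^2 + lam), 0)
    fitted_c <- sv$u %*% (shrink * uty)
    resid <- yc - fitted_c
    h <- 1 / n + rowSums(sweep(sv$u^2, 2, shrink, `*`))
    loo <- resid / pmax(1 - h, 1e-8)
    cv_mse[i] <- mean(loo^2)
  }
  best <- which.min(cv_mse)
  lam <- lambda[best]
  shrink_coef <- ifelse(d > tol, d / (d^2 + lam), 0)
  beta <- drop(sv$v %*% (shrink_coef * uty))
  b0 <- ym - sum(xm * beta)
  fitted <- b0 + drop(X %*% beta)
  rss <- sum((y - fitted)^2)
  sigma2 <- rss / max(n - p - 1, 1)
  list(lambda = lam,
       beta = stats::setNames(c(b0, beta), c("(Intercept)", colnames(X))),
       sigma2 = sigma2,
       cv = data.frame(lambda = lambda, mse = cv_mse),
       parents = colnames(X))
}

#' Fit a non-stationary dynamic Bayesian network across exposure slices
#'
#' First-order Markov model over exposure repetitions: the value of a node
#' at exposure `e` is linear-Gaussian in its pathway parents evaluated at
#' exposure `e - 1`, with no edges between nodes of the same exposure and no
#' stationarity constraint -- coefficients are learned separately for every
#' slice pair `(e - 1, e)` by ridge regression with exact LOOCV penalty
#' selection (the chronic-phase responses are strongly collinear, which
#' ridge tolerates where subset selection would prune pathway links). The
#' dose root is not part of the model; doses are either pooled (rows are all
#' donor x dose cells) or a single treated dose is analyzed on its own, in
#' which case only the donors' rows are available and a small-sample warning
#' is emitted when a node has fewer than `parents + 2` rows.
#'
#' @param rep_data a [resample_replicates()] result.
#' @param dose `"pooled"` or one treated dose level.
#' @param lambda penalty grid.
#' @return Object of class `dbn_model` with one slice per target exposure
#'   `e = 2..E`; each slice holds per-node coefficients over the lagged
#'   parents, residual variance and the selected penalty. Nodes without
#'   biology parents get an intercept-plus-noise model.
#' @export
fit_dbn <- function(rep_data, dose = "pooled", lambda = default_lambda_grid()) {
  stopifnot(inherits(rep_data, "replicate_dataset"))
  graph <- rep_data$graph
  E <- rep_data$design$n_exposures
  pa <- bio_parents(graph)
  slices <- vector("list", E)
  for (e in 2:E) {
    Xprev <- slice_matrix(rep_data, e - 1, dose)
    Ycur <- slice_matrix(rep_data, e, dose)
    if (!identical(dim(Xprev), dim(Ycur))) {
      qaop_stop("qaop_alignment_error",
                "unmatched rows between exposures %d and %d", e - 1, e)
    }
    slices[[e]] <- fit_dbn_slice(Xprev, Ycur, pa, lambda)
  }
  structure(list(slices = slices, graph = graph, dose_mode = dose,
                 lambda = lambda, exposures = 2:E,
                 design = rep_data$design),
            class = "dbn_model")
}

# One slice: regress each node at e on its lagged parents at e-1.
fit_dbn_slice <- function(Xprev, Ycur, pa, lambda) {
  nodes <- names(pa)
  out <- vector("list", length(nodes)); names(out) <- nodes
  for (v in nodes) {
    pv <- pa[[v]]
    y <- Ycur[, v]
    if (!length(pv)) {
      out[[v]] <- list(parents = character(0),
                       beta = c(`(Intercept)` = mean(y)),
                       sigma2 = stats::var(y), lambda = NA_real_)
      next
    }
    if (nrow(Xprev) < length(pv) + 2L) {
      warning(sprintf("node %s: only %d rows for %d lagged parents; estimates are error prone",
                      v, nrow(Xprev), length(pv)), call. = FALSE)
    }
    fit <- ridge_loocv(Xprev[, pv, drop = FALSE], y, lambda)
    out[[v]] <- list(parents = pv, beta = fit$beta, sigma2 = fit$sigma2,
                     lambda = fit$lambda)
  }
  out
}

#' @export
print.dbn_model <- function(x, ...) {
  cat(sprintf("Non-stationary DBN: slices e = %s, dose mode %s\n",
              paste(range(x$exposures), collapse = ".."),
              if (identical(x$dose_mode, "pooled")) "pooled" else x$dose_mode))
  invisible(x)
}

# Forward-simulate the slice models from exposure `from_e` to `to_e`.
# `state` is an n x nodes matrix of log10 fold changes at from_e.
propagate_slices <- function(slices, state, from_e, to_e) {
  nodes <- colnames(state)
  for (e in seq(from_e + 1L, to_e)) {
    sl <- slices[[e]]
    if (is.null(sl)) {
      qaop_stop("qaop_design_error", "no slice model for exposure %d", e)
    }
    new_state <- state
    for (v in nodes) {
      p <- sl[[v]]
      mu <- p$beta[["(Intercept)"]]
      if (length(p$parents)) {
        mu <- mu + drop(state[, p$parents, drop = FALSE] %*% p$beta[p$parents])
      }
      new_state[, v] <- mu + stats::rnorm(nrow(state), 0, sqrt(max(p$sigma2, 0)))
    }
    state <- new_state
  }
  state
}

check_transition_query <- function(dbn, ke, tau, e) {
  graph <- dbn$graph
  E <- max(dbn$exposures)
  if (!ke %in% graph$bio_nodes) {
    qaop_stop("qaop_unknown_node_error", "unknown node '%s'", ke)
  }
  lag <- ao_lag(graph)[[ke]]
  if (!identical(as.integer(tau), as.integer(lag))) {
    qaop_stop("qaop_design_error",
              "node %s is %d slice(s) upstream of the AO; tau = %d is not a valid lag",
              ke, lag, tau)
  }
  if (e > E || e - tau < 2L) {
    qaop_stop("qaop_design_error",
              "query (tau = %d, e = %d) infeasible: need tau + 2 <= e <= E = %d",
              tau, e, E)
  }
  invisible(lag)
}

#' Transition probability of the adverse outcome
#'
#' Estimates `P(AO at exposure e exceeds delta | KE at exposure e - tau
#' exceeded delta)` by forward simulation: initial states at `e - tau` are
#' drawn with replacement from the empirical replicate-mean rows (which
#' preserves cross-node dependence), trajectories are propagated through the
#' slice models with per-node Gaussian residual noise, and the conditional
#' exceedance fraction is taken over trajectories satisfying the evidence --
#' with inequality evidence, likelihood weighting reduces to 0/1 weights,
#' i.e. rejection.
#'
#' The lag `tau` must equal the node's graph distance to the AO, and
#' `e - tau >= 2` so at least one fitted slice precedes the conditioning
#' exposure.
#'
#' @param dbn a [fit_dbn()] result.
#' @param rep_data the [resample_replicates()] result the DBN was fit to
#'   (source of the empirical initial distribution).
#' @param ke conditioning key event.
#' @param tau lag between the conditioning exposure and the outcome.
#' @param e target exposure of the AO.
#' @param delta activation threshold (log10 fold change).
#' @param n_sims number of simulated trajectories.
#' @param seed integer seed, or `NULL`.
#' @return one-row data frame: ke, tau, e, dose, prob, n_conditioning, se.
#' @export
transition_probability <- function(dbn, rep_data, ke, tau, e,
                                   delta = log10(2), n_sims = 1e4,
                                   seed = NULL) {
  stopifnot(inherits(dbn, "dbn_model"))
  check_transition_query(dbn, ke, tau, e)
  if (!is.null(seed)) set.seed(seed)
  init <- slice_matrix(rep_data, e - tau, dbn$dose_mode)
  idx <- sample.int(nrow(init), n_sims, replace = TRUE)
  state <- init[idx, , drop = FALSE]
  cond <- state[, ke] > delta
  n_c <- sum(cond)
  if (n_c == 0L) {
    qaop_stop("qaop_empty_conditioning_error",
              "no simulated trajectory satisfies %s > %.3g at exposure %d",
              ke, delta, e - tau)
  }
  final <- propagate_slices(dbn$slices, state, e - tau, e)
  p <- mean(final[cond, dbn$graph$ao_node] > delta)
  data.frame(ke = ke, tau = tau, e = e,
             dose = if (identical(dbn$dose_mode, "pooled")) "pooled"
                    else as.character(dbn$dose_mode),
             prob = p, n_conditioning = n_c,
             se = sqrt(p * (1 - p) / n_c),
             stringsAsFactors = FALSE)
}

#' Full table of AO transition probabilities
#'
#' Evaluates [transition_probability()] for every chronic key event with a
#' path to the AO, at its graph lag `tau`, over all feasible target
#' exposures `e = tau + 2 .. E`. Queries whose conditioning event never
#' occurs among the bootstrap states (for instance a chronic key event at a
#' repetition before any donor's onset) are reported with `prob = NA` and
#' `n_conditioning = 0` instead of aborting the table.
#'
#' @inheritParams transition_probability
#' @param kes conditioning nodes; defaults to all key events upstream of
#'   the AO with lag between 1 and 3.
#' @return data frame, one row per (ke, e).
#' @export
transition_table <- function(dbn, rep_data, kes = NULL, delta = log10(2),
                             n_sims = 1e4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  graph <- dbn$graph
  lag <- ao_lag(graph)
  if (is.null(kes)) {
    kes <- names(lag)[!is.na(lag) & lag >= 1 & lag <= 3 &
                        grepl("^KE", names(lag))]
  }
  E <- max(dbn$exposures)
  rows <- list()
  for (ke in kes) {
    tau <- lag[[ke]]
    es <- seq_len(E)[seq_len(E) >= tau + 2]
    for (e in es) {
      rows[[length(rows) + 1L]] <- tryCatch(
        transition_probability(dbn, rep_data, ke, tau, e, delta, n_sims),
        qaop_empty_conditioning_error = function(cnd) {
          data.frame(ke = ke, tau = tau, e = e,
                     dose = if (identical(dbn$dose_mode, "pooled")) "pooled"
                            else as.character(dbn$dose_mode),
                     prob = NA_real_, n_conditioning = 0L, se = NA_real_,
                     stringsAsFactors = FALSE)
        })
    }
  }
  do.call(rbind, rows)
}

#' Dose-specific transition probabilities
#'
#' Refits the DBN separately for each treated dose (slice regressions then
#' see only the donors' rows) and evaluates the transition table per dose.
#'
#' @inheritParams transition_table
#' @param doses treated dose levels; defaults to all non-control design
#'   doses.
#' @return data frame, one row per (ke, e, dose).
#' @export
dose_specific_transitions <- function(rep_data, kes = NULL, doses = NULL,
                                      delta = log10(2), n_sims = 1e4,
                                      seed = NULL,
                                      lambda = default_lambda_grid()) {
  if (is.null(doses)) doses <- setdiff(rep_data$design$doses, 0)
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(doses, function(d) {
    dbn_d <- fit_dbn(rep_data, dose = d, lambda = lambda)
    transition_table(dbn_d, rep_data, kes = kes, delta = delta,
                     n_sims = n_sims)
  })
  do.call(rbind, out)
}
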