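#' Response-response correlation at one exposure repetition
#'
#' Pearson correlation of the primary mean fold changes across the pooled
#' donor-by-dose cells of a single exposure repetition. This is the
#' correlation plugged into the off-diagonal entries of the per-cell
#' log-scale covariance so that resampled responses co-vary the way a
#' common stimulus makes real responses co-vary.
#'
#' @param primary a [generate_primary()] result.
#' @param exposure exposure repetition index.
#' @param level `"pooled"` (default) correlates across all donor x dose
#'   cells; `"donor"` averages per-donor correlation matrices, which with
#'   few doses per donor is considerably noisier.
#' @return node x node correlation matrix; unit diagonal, zero off-diagonals
#'   for any node with no variance at that exposure.
#' @export
estimate_rho <- function(primary, exposure, level = c("pooled", "donor")) {
  stopifnot(inherits(primary, "primary_dataset"))
  level <- match.arg(level)
  f <- primary$mean_fc
  V <- dim(f)[4]
  nodes <- dimnames(f)$node
  cell_matrix <- function(donor_idx) {
    m <- matrix(aperm(f[donor_idx, exposure, , , drop = FALSE], c(1, 3, 4, 2)),
                ncol = V)
    colnames(m) <- nodes
    m
  }
  if (level == "pooled") {
    m <- cell_matrix(seq_len(dim(f)[1]))
    if (nrow(m) < 3L) {
      qaop_stop("qaop_degenerate_error",
                ">= 3 donor x dose cells are required to estimate correlations")
    }
    rho <- suppressWarnings(stats::cor(m))
  } else {
    per <- lapply(seq_len(dim(f)[1]),
                  function(n) suppressWarnings(stats::cor(cell_matrix(n))))
    rho <- Reduce(`+`, lapply(per, function(r) {
      r[!is.finite(r)] <- 0; r
    })) / length(per)
  }
  rho[!is.finite(rho)] <- 0   # zero-variance nodes contribute no correlation
  diag(rho) <- 1
  rho
}

#' Lognormal parameters of one (donor, exposure, dose) cell
#'
#' Moment-matches a multivariate lognormal to the primary mean fold change
#' and standard deviation of each node: on the natural-log scale the mean is
#' `mu = ln(fbar^2 / sqrt(fbar^2 + s^2))` and the variance
#' `o = ln(1 + s^2 / fbar^2)`; off-diagonal covariances are
#' `rho * sqrt(o_v o_v')`. Exponentiating draws from `MVN(mu, O)` therefore
#' reproduces `fbar` and `s` exactly in expectation.
#'
#' Plugging an empirical correlation into a diagonal rebuilt from different
#' variances can leave `O` indefinite; eigenvalues are clipped at 1e-10 and
#' the diagonal rescaled back, the standard nearest-PSD repair.
#'
#' @param fbar named vector of mean fold changes (> 0).
#' @param s named vector of fold-change standard deviations (>= 0).
#' @param rho node x node correlation matrix, as from [estimate_rho()].
#' @return list with `mu` (log-scale means), `cov` (log-scale covariance).
#' @export
lognormal_params <- function(fbar, s, rho) {
  if (any(fbar <= 0)) {
    qaop_stop("qaop_domain_error", "mean fold changes must be positive")
  }
  if (any(s < 0)) {
    qaop_stop("qaop_domain_error", "standard deviations must be non-negative")
  }
  mu <- log(fbar^2 / sqrt(fbar^2 + s^2))
  o <- log(1 + s^2 / fbar^2)
  cov <- rho * sqrt(outer(o, o))
  diag(cov) <- o
  list(mu = mu, cov = repair_psd(cov))
}

# Nearest-PSD repair: clip eigenvalues, then rescale the diagonal back.
repair_psd <- function(O, eps = 1e-10) {
  Osym <- (O + t(O)) / 2
  es <- eigen(Osym, symmetric = TRUE)
  if (min(es$values) >= 0) return(Osym)
  d0 <- diag(Osym)
  O2 <- es$vectors %*% (pmax(es$values, eps) * t(es$vectors))
  sc <- ifelse(d0 > 0, sqrt(d0 / diag(O2)), 0)
  O2 <- O2 * outer(sc, sc)
  dimnames(O2) <- dimnames(O)
  (O2 + t(O2)) / 2
}

#' Conjugate Gaussian update of regression coefficients
#'
#' With known residual variance, a Gaussian prior `N(beta_pr, V_pr)` on the
#' coefficients of a linear-Gaussian node updates to the posterior
#' `V_pos^-1 = V_pr^-1 + X'X / sigma2` and
#' `beta_pos = V_pos (V_pr^-1 beta_pr + X'y / sigma2)`. Across exposure
#' repetitions the posterior of the previous repetition serves as the prior
#' of the next, so information accumulates and the posterior covariance can
#' only tighten.
#'
#' @param prior list with `beta` (coefficient vector) and `cov` (its
#'   covariance).
#' @param X design matrix (include an intercept column if wanted).
#' @param y response vector.
#' @param sigma2 known residual variance.
#' @return list with updated `beta` and `cov`.
#' @export
bayes_update <- function(prior, X, y, sigma2) {
  X <- as.matrix(X)
  Vpr_inv <- tryCatch(solve(prior$cov),
                      error = function(e) qaop_stop("qaop_singular_error",
                                                    "prior covariance is singular"))
  prec <- Vpr_inv + crossprod(X) / sigma2
  Vpos <- tryCatch(solve(prec),
                   error = function(e) qaop_stop("qaop_singular_error",
                                                 "posterior precision is singular"))
  beta <- Vpos %*% (Vpr_inv %*% prior$beta + crossprod(X, y) / sigma2)
  list(beta = drop(beta), cov = (Vpos + t(Vpos)) / 2)
}

# OLS of a node on its parents with the residual-variance convention of the
# updating chain: denominator kappa - |parents|. Works on centered data, so
# beta is the slope vector; the intercept is recovered from the cell means.
ols_node_fit <- function(Xc, yc, n_parents) {
  qr_ <- qr(Xc)
  if (qr_$rank < ncol(Xc)) {
    qaop_stop("qaop_singular_error", "rank-deficient design in node regression")
  }
  beta <- qr.coef(qr_, yc)
  resid <- yc - Xc %*% beta
  sigma2 <- max(sum(yc * resid) / (length(yc) - n_parents), 1e-12)
  XtX_inv <- chol2inv(qr.R(qr_))
  list(beta = drop(beta), sigma2 = sigma2, cov = sigma2 * XtX_inv)
}

#' Resample replicate-level virtual data from the primary dataset
#'
#' For every treated (donor, exposure, dose) cell, `kappa` draws are taken
#' from the moment-matched multivariate lognormal ([lognormal_params()]).
#' Each biology node is then regressed on its pathway parents within the
#' cell. The node likelihood carries a separate intercept, so the conjugate
#' chain runs over the slope vector only: slope posteriors are carried
#' across exposure repetitions by [bayes_update()] (ordinary least squares
#' at the first repetition, the known residual variance set to the OLS
#' estimate of the current cell), while the intercept is re-anchored to the
#' cell means, `b0 = ybar - xbar' beta_pos`. The replicate averages
#' therefore track the ground-truth fold changes -- the primary dataset
#' stays the grand truth -- while information about the parent-child
#' coupling accumulates over repetitions. Finally `R` replicates per cell
#' are drawn ancestrally in topological order from the posterior predictive
#' `N(b0 + x_pa' beta_pos, sigma2 + (x_pa - xbar)' V_pos (x_pa - xbar))`;
#' nodes whose only parent is the dose root are drawn from their lognormal
#' marginal. Control cells are a point mass at fold change 1 and bypass the
#' network.
#'
#' Replicate-averaged fold changes (`$mean`) feed all downstream analyses.
#'
#' @param primary a [generate_primary()] result.
#' @param R replicates per cell; defaults to the design's `n_replicates`.
#' @param kappa training draws per cell; defaults to the design's `kappa`.
#'   Must exceed the largest parent set plus one.
#' @param seed integer seed; defaults to `design$seed + 1`.
#' @param rho_level correlation pooling level passed to [estimate_rho()].
#' @return Object of class `replicate_dataset`: `replicates` (donor x
#'   exposure x dose x replicate x node array of fold changes), `mean`
#'   (replicate average), plus design, donors, graph and the per-exposure
#'   correlation matrices used.
#' @export
resample_replicates <- function(primary, R = NULL, kappa = NULL, seed = NULL,
                                rho_level = "pooled") {
  stopifnot(inherits(primary, "primary_dataset"))
  design <- primary$design
  graph <- primary$graph
  if (is.null(R)) R <- design$n_replicates
  if (is.null(kappa)) kappa <- design$kappa
  if (is.null(seed)) seed <- design$seed + 1L
  nodes <- graph$bio_nodes
  topo <- topo_order(graph, include_dose = FALSE)
  pa <- bio_parents(graph)
  max_pa <- max(lengths(pa))
  if (kappa <= max_pa + 1L) {
    qaop_stop("qaop_design_error",
              "kappa (%d) must exceed the largest parent set + 1 (%d)",
              kappa, max_pa + 1L)
  }
  N <- design$n_donors; E <- design$n_exposures
  doses <- design$doses; D <- length(doses); V <- length(nodes)

  dn <- list(donor = as.character(1:N), exposure = as.character(1:E),
             dose = as.character(doses), replicate = as.character(1:R),
             node = nodes)
  reps <- array(NA_real_, dim = c(N, E, D, R, V), dimnames = dn)

  set.seed(seed)
  rho_e <- lapply(1:E, function(e) estimate_rho(primary, e, level = rho_level))

  for (n in 1:N) {
    for (di in 1:D) {
      if (doses[di] == 0) {
        reps[n, , di, , ] <- 1   # control: degenerate at fold change 1
        next
      }
      post <- vector("list", V); names(post) <- nodes
      for (e in 1:E) {
        fbar <- primary$mean_fc[n, e, di, ]
        sdev <- primary$sd_fc[n, e, di, ]
        lp <- lognormal_params(fbar, sdev, rho_e[[e]])
        Xk <- MASS::mvrnorm(kappa, lp$mu, lp$cov)
        Z <- matrix(NA_real_, R, V, dimnames = list(NULL, nodes))
        for (v in topo) {
          pv <- pa[[v]]
          if (!length(pv)) {
            Z[, v] <- stats::rnorm(R, lp$mu[v], sqrt(lp$cov[v, v]))
            next
          }
          xbar <- colMeans(Xk[, pv, drop = FALSE])
          Xc <- sweep(Xk[, pv, drop = FALSE], 2, xbar)
          yc <- Xk[, v] - mean(Xk[, v])
          fit <- ols_node_fit(Xc, yc, n_parents = length(pv))
          post[[v]] <- if (e == 1L) {
            list(beta = fit$beta, cov = fit$cov)
          } else {
            bayes_update(post[[v]], Xc, yc, fit$sigma2)
          }
          b0 <- mean(Xk[, v]) - sum(xbar * post[[v]]$beta)
          Xt <- sweep(Z[, pv, drop = FALSE], 2, xbar)
          mu_pred <- b0 + drop(Z[, pv, drop = FALSE] %*% post[[v]]$beta)
          var_pred <- fit$sigma2 + rowSums((Xt %*% post[[v]]$cov) * Xt)
          Z[, v] <- stats::rnorm(R, mu_pred, sqrt(pmax(var_pred, 0)))
        }
        reps[n, e, di, , ] <- exp(Z)
      }
    }
  }

  mean_fc <- apply(reps, c(1, 2, 3, 5), mean)
  structure(list(replicates = reps, mean = mean_fc, R = R, kappa = kappa,
                 seed = seed, rho = rho_e, design = design,
                 donors = primary$donors, graph = graph),
            class = "replicate_dataset")
}

#' @export
print.replicate_dataset <- function(x, ...) {
  d <- dim(x$replicates)
  cat(sprintf(
    "Replicate virtual dataset: %d donors x %d exposures x %d doses x %d replicates x %d nodes\n",
    d[1], d[2], d[3], d[4], d[5]))
  invisible(x)
}

#' Tidy view of replicate-level data
#'
#' @param x a `replicate_dataset`.
#' @param ... unused.
#' @return Long data frame with columns donor, exposure, dose, replicate,
#'   node, fold_change.
#' @export
as.data.frame.replicate_dataset <- function(x, ...) {
  dn <- dimnames(x$replicates)
  g <- expand.grid(donor = as.integer(dn$donor),
                   exposure = as.integer(dn$exposure),
                   dose = as.numeric(dn$dose),
                   replicate = as.integer(dn$replicate),
                   node = dn$node,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$fold_change <- as.vector(x$replicates)
  g
}

#' Replicate-mean slice of one exposure repetition
#'
#' Rows are (donor, dose) cells (all doses including control for
#' `dose = "pooled"`, a single treated dose otherwise); columns are the
#' biology nodes. Values are replicate-averaged fold changes, by default on
#' the log10 scale on which the activation threshold is defined.
#'
#' @param rep_data a [resample_replicates()] result.
#' @param exposure exposure repetition index.
#' @param dose `"pooled"` or one dose level.
#' @param scale `"log10"` or `"fold"`.
#' @return matrix with attribute `info`, a data frame of the row donor and
#'   dose labels.
#' @export
slice_matrix <- function(rep_data, exposure, dose = "pooled",
                         scale = c("log10", "fold")) {
  stopifnot(inherits(rep_data, "replicate_dataset"))
  scale <- match.arg(scale)
  m <- rep_data$mean
  doses <- rep_data$design$doses
  nodes <- dimnames(m)[[4]]
  N <- dim(m)[1]
  if (identical(dose, "pooled")) {
    out <- matrix(aperm(m[, exposure, , , drop = FALSE], c(1, 3, 4, 2)),
                  ncol = length(nodes))
    info <- expand.grid(donor = 1:N, dose = doses, KEEP.OUT.ATTRS = FALSE)
  } else {
    di <- match(dose, doses)
    if (is.na(di)) qaop_stop("qaop_design_error", "dose %s not in design", dose)
    out <- matrix(m[, exposure, di, ], ncol = length(nodes))
    info <- data.frame(donor = 1:N, dose = doses[di])
  }
  colnames(out) <- nodes
  if (scale == "log10") out <- log10(out)
  attr(out, "info") <- info
  out
}
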