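#' Dose-response linear mixed model for one node and exposure
#'
#' Fits `log10(fold change) = b0 + b1 * dose + donor intercept + error` by
#' maximum likelihood, with a Gaussian random intercept per donor capturing
#' donor-to-donor offsets (for chronic nodes, largely the onset/severity
#' heterogeneity). The conditional R2 is the Nakagawa-Schielzeth ratio
#' `(var_fixed + var_donor) / (var_fixed + var_donor + var_resid)`, i.e. the
#' variance explained by dose and donor identity together.
#'
#' @param rep_data a [resample_replicates()] result.
#' @param node node name.
#' @param exposure exposure repetition index.
#' @return Object of class `lmm_fit`: `beta` (fixed effects), `sigma_n2`
#'   (donor-intercept variance), `sigma_e2` (residual variance),
#'   `conditional_r2`, and the underlying `lme4` fit.
#' @export
fit_dose_lmm <- function(rep_data, node, exposure) {
  X <- slice_matrix(rep_data, exposure)
  info <- attr(X, "info")
  df <- data.frame(y = X[, node], dose = info$dose,
                   donor = factor(info$donor))
  lmm_fit_impl(y ~ dose + (1 | donor), df)
}

#' Response-response models for a node pair
#'
#' Both models pool every exposure repetition. `fit_rr_lmm()` regresses
#' `node` on `node2` with a donor random intercept (maximum likelihood);
#' `fit_rr_poly()` fits a cubic polynomial in `node2` by ordinary least
#' squares and reports the training R2. Values are log10 fold changes.
#'
#' @inheritParams fit_dose_lmm
#' @param node2 predictor node name.
#' @return `lmm_fit` (for the LMM) or `poly_fit` (cubic, with `r2`).
#' @export
fit_rr_lmm <- function(rep_data, node, node2) {
  df <- pooled_pair(rep_data, node, node2)
  lmm_fit_impl(y ~ x + (1 | donor), df)
}

#' @rdname fit_rr_lmm
#' @export
fit_rr_poly <- function(rep_data, node, node2) {
  df <- pooled_pair(rep_data, node, node2)
  if (stats::var(df$y) == 0) {
    qaop_stop("qaop_singular_error", "response has zero variance")
  }
  fit <- stats::lm(y ~ x + I(x^2) + I(x^3), data = df)
  structure(list(beta = stats::coef(fit),
                 r2 = summary(fit)$r.squared,
                 model = fit),
            class = "poly_fit")
}

pooled_pair <- function(rep_data, node, node2) {
  E <- rep_data$design$n_exposures
  do.call(rbind, lapply(1:E, function(e) {
    X <- slice_matrix(rep_data, e)
    info <- attr(X, "info")
    data.frame(y = X[, node], x = X[, node2],
               donor = factor(info$donor), exposure = e)
  }))
}

lmm_fit_impl <- function(formula, df) {
  if (stats::var(df$y) == 0) {
    qaop_stop("qaop_singular_error", "response has zero variance")
  }
  fit <- tryCatch(
    suppressWarnings(suppressMessages(
      lme4::lmer(formula, data = df, REML = FALSE,
                 control = lme4::lmerControl(check.conv.singular = "ignore"))
    )),
    error = function(e) qaop_stop("qaop_convergence_error",
                                  "mixed model failed: %s", conditionMessage(e))
  )
  fixed <- drop(lme4::getME(fit, "X") %*% lme4::fixef(fit))
  sigma_f2 <- stats::var(fixed)
  vc <- as.data.frame(lme4::VarCorr(fit))
  sigma_n2 <- vc$vcov[vc$grp == "donor"][1]
  sigma_e2 <- stats::sigma(fit)^2
  r2c <- (sigma_f2 + sigma_n2) / (sigma_f2 + sigma_n2 + sigma_e2)
  structure(list(beta = lme4::fixef(fit), sigma_n2 = sigma_n2,
                 sigma_e2 = sigma_e2,
                 conditional_r2 = unname(r2c), model = fit),
            class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("Linear mixed model (ML), donor random intercept\n")
  cat("  fixed effects:", paste(sprintf("%s=%.4g", names(x$beta), x$beta),
                                collapse = ", "), "\n")
  cat(sprintf("  donor variance %.4g, residual variance %.4g, conditional R2 %.3f\n",
              x$sigma_n2, x$sigma_e2, x$conditional_r2))
  invisible(x)
}

#' Dose-response R2 table across nodes and exposures
#'
#' Convenience wrapper applying [fit_dose_lmm()] to every biology node and
#' exposure repetition.
#'
#' @inheritParams fit_dose_lmm
#' @return data frame with node, exposure, conditional_r2, slope.
#' @export
dose_r2_table <- function(rep_data) {
  E <- rep_data$design$n_exposures
  nodes <- rep_data$graph$bio_nodes
  out <- expand.grid(node = nodes, exposure = 1:E,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res <- Map(function(v, e) {
    fit <- fit_dose_lmm(rep_data, v, e)
    c(fit$conditional_r2, fit$beta[["dose"]])
  }, out$node, out$exposure)
  out$conditional_r2 <- vapply(res, `[`, numeric(1), 1)
  out$slope <- vapply(res, `[`, numeric(1), 2)
  out
}
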