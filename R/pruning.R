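#' Data-driven pruning of the DBN slice structure
#'
#' Per slice and node, the lagged pathway edges are screened: nodes with
#' more than one parent are fit by lasso with the penalty chosen by
#' leave-one-out cross-validation -- by default the one-standard-error rule,
#' the standard parsimony choice when the goal is to shrink uninformative
#' regulators to exactly zero (`rule = "min"` selects the CV-minimizing
#' penalty instead) -- and parents whose coordinate-descent coefficient is
#' exactly zero at the selected penalty are dropped; nodes with a single
#' parent keep the edge only when the ordinary-least-squares slope has
#' p < `p_cut`. Surviving edges are then culled for
#' AO-reachability on the unrolled slice graph: an edge into a node
#' instance from which no directed path of kept edges reaches the adverse
#' outcome is uninformative for AO inference and is dropped as well (a node
#' whose only outlet loses its edge is thereby pruned, exactly as the
#' pathway logic requires). Kept edges are refit by ridge ([ridge_loocv()]).
#'
#' @param rep_data a [resample_replicates()] result.
#' @param dose `"pooled"` or one treated dose level.
#' @param p_cut p-value threshold for single-parent nodes.
#' @param rule lasso penalty selection: `"1se"` (default) or `"min"`.
#' @param lambda penalty grid for the ridge refit.
#' @return Object of class `pruned_dbn`: `edges` (data frame slice, parent,
#'   child, status, reason, coefficient), `slices` (refit per-slice models
#'   restricted to kept parents), the graph and dose mode.
#' @export
lasso_prune <- function(rep_data, dose = "pooled", p_cut = 0.05,
                        rule = c("1se", "min"),
                        lambda = default_lambda_grid()) {
  rule <- match.arg(rule)
  stopifnot(inherits(rep_data, "replicate_dataset"))
  graph <- rep_data$graph
  E <- rep_data$design$n_exposures
  pa <- bio_parents(graph)
  edge_rows <- list()
  for (e in 2:E) {
    Xprev <- slice_matrix(rep_data, e - 1, dose)
    Ycur <- slice_matrix(rep_data, e, dose)
    for (v in names(pa)) {
      pv <- pa[[v]]
      if (!length(pv)) next
      y <- Ycur[, v]
      if (length(pv) == 1L) {
        fit <- stats::lm(y ~ x, data = data.frame(y = y, x = Xprev[, pv]))
        sm <- summary(fit)$coefficients
        pval <- if (nrow(sm) >= 2) sm[2, 4] else NA_real_
        keep <- is.finite(pval) && pval < p_cut
        coefv <- unname(stats::coef(fit)[2])
        reason <- if (keep) "" else sprintf("p>=%.2g", p_cut)
        edge_rows[[length(edge_rows) + 1L]] <- data.frame(
          slice = e, parent = pv, child = v,
          status = if (keep) "kept" else "dropped",
          reason = reason, coefficient = coefv, stringsAsFactors = FALSE)
      } else {
        cv <- glmnet::cv.glmnet(Xprev[, pv, drop = FALSE], y, alpha = 1,
                                nfolds = length(y), grouped = FALSE,
                                standardize = TRUE)
        b <- as.vector(stats::coef(
          cv, s = if (rule == "1se") "lambda.1se" else "lambda.min"))[-1]
        edge_rows[[length(edge_rows) + 1L]] <- data.frame(
          slice = e, parent = pv, child = v,
          status = ifelse(b != 0, "kept", "dropped"),
          reason = ifelse(b != 0, "", "lasso-zero"),
          coefficient = b, stringsAsFactors = FALSE)
      }
    }
  }
  edges <- do.call(rbind, edge_rows)
  edges <- cull_unreachable(edges, graph, E)

  # relaxed refit: ridge on the kept parents of each (slice, node)
  slices <- vector("list", E)
  for (e in 2:E) {
    Xprev <- slice_matrix(rep_data, e - 1, dose)
    Ycur <- slice_matrix(rep_data, e, dose)
    kept_here <- edges[edges$slice == e & edges$status == "kept", , drop = FALSE]
    sl <- vector("list", length(names(pa))); names(sl) <- names(pa)
    for (v in names(pa)) {
      pv <- kept_here$parent[kept_here$child == v]
      y <- Ycur[, v]
      sl[[v]] <- if (length(pv)) {
        fit <- ridge_loocv(Xprev[, pv, drop = FALSE], y, lambda)
        list(parents = pv, beta = fit$beta, sigma2 = fit$sigma2,
             lambda = fit$lambda)
      } else {
        list(parents = character(0), beta = c(`(Intercept)` = mean(y)),
             sigma2 = stats::var(y), lambda = NA_real_)
      }
    }
    slices[[e]] <- sl
  }
  structure(list(edges = edges, slices = slices, graph = graph,
                 dose_mode = dose, exposures = 2:E,
                 design = rep_data$design),
            class = "pruned_dbn")
}

# Drop kept edges whose child instance has no directed path of kept edges
# to any AO instance. Backward induction over the unrolled slice graph;
# applying it twice changes nothing.
cull_unreachable <- function(edges, graph, E) {
  ao <- graph$ao_node
  reach <- matrix(FALSE, nrow = length(graph$bio_nodes), ncol = E,
                  dimnames = list(graph$bio_nodes, NULL))
  reach[ao, ] <- TRUE
  for (e in seq(E - 1L, 1L)) {
    kept_next <- edges[edges$slice == e + 1L & edges$status == "kept", ,
                       drop = FALSE]
    for (v in graph$bio_nodes) {
      if (v == ao) next
      ch <- kept_next$child[kept_next$parent == v]
      reach[v, e] <- length(ch) > 0 && any(reach[ch, e + 1L])
    }
  }
  kept <- edges$status == "kept"
  dead <- kept & !reach[cbind(match(edges$child, rownames(reach)), edges$slice)]
  edges$status[dead] <- "dropped"
  edges$reason[dead] <- "unreachable"
  edges
}

#' @export
print.pruned_dbn <- function(x, ...) {
  tab <- table(x$edges$status)
  cat(sprintf("Pruned DBN: %s kept / %s dropped lagged edges over slices e = %s\n",
              tab[["kept"]], sum(x$edges$status == "dropped"),
              paste(range(x$exposures), collapse = "..")))
  invisible(x)
}

# Does a path of kept edges run from ke@e-tau to AO@e?
surviving_query <- function(pruned, ke, tau, e) {
  edges <- pruned$edges[pruned$edges$status == "kept", , drop = FALSE]
  ao <- pruned$graph$ao_node
  frontier <- ke
  for (step in seq_len(tau)) {
    sl <- e - tau + step
    frontier <- unique(edges$child[edges$slice == sl &
                                     edges$parent %in% frontier])
    if (!length(frontier)) return(FALSE)
  }
  ao %in% frontier
}

#' Transition probabilities on the pruned DBN
#'
#' Recomputes the AO transition probabilities of [transition_table()] with
#' the pruned, refit slice models. Queries whose conditioning key event no
#' longer has a path of kept edges to the AO at the target exposure are
#' conditionally independent of the AO under the pruned structure; they are
#' reported with `prob = NA` and status `"conditionally_independent"`
#' rather than a number.
#'
#' @param pruned a [lasso_prune()] result.
#' @param rep_data the underlying [resample_replicates()] result.
#' @inheritParams transition_table
#' @return data frame, one row per (ke, e), with a `status` column.
#' @export
pruned_transitions <- function(pruned, rep_data, kes = NULL,
                               delta = log10(2), n_sims = 1e4, seed = NULL) {
  stopifnot(inherits(pruned, "pruned_dbn"))
  if (!is.null(seed)) set.seed(seed)
  graph <- pruned$graph
  lag <- ao_lag(graph)
  if (is.null(kes)) {
    kes <- names(lag)[!is.na(lag) & lag >= 1 & lag <= 3 &
                        grepl("^KE", names(lag))]
  }
  E <- max(pruned$exposures)
  shim <- structure(list(slices = pruned$slices, graph = graph,
                         dose_mode = pruned$dose_mode,
                         exposures = pruned$exposures),
                    class = "dbn_model")
  rows <- list()
  for (ke in kes) {
    tau <- lag[[ke]]
    es <- seq_len(E)[seq_len(E) >= tau + 2]
    for (e in es) {
      if (surviving_query(pruned, ke, tau, e)) {
        row <- tryCatch({
          r <- transition_probability(shim, rep_data, ke, tau, e, delta, n_sims)
          r$status <- "estimated"
          r
        }, qaop_empty_conditioning_error = function(cnd) {
          data.frame(ke = ke, tau = tau, e = e,
                     dose = if (identical(pruned$dose_mode, "pooled"))
                       "pooled" else as.character(pruned$dose_mode),
                     prob = NA_real_, n_conditioning = 0L, se = NA_real_,
                     status = "no_conditioning_event",
                     stringsAsFactors = FALSE)
        })
      } else {
        row <- data.frame(ke = ke, tau = tau, e = e,
                          dose = if (identical(pruned$dose_mode, "pooled"))
                            "pooled" else as.character(pruned$dose_mode),
                          prob = NA_real_, n_conditioning = NA_integer_,
                          se = NA_real_, status = "conditionally_independent",
                          stringsAsFactors = FALSE)
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}
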