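#' Configuration for an end-to-end run
#'
#' Bundles the study design, donor table, graph, activation threshold,
#' grids and simulation sizes. All randomness flows from per-stage seeds
#' derived deterministically from the master seed.
#'
#' @param out_dir output directory (created if missing).
#' @param design a [study_design()].
#' @param donors donor table.
#' @param graph an [aop_graph()].
#' @param delta activation threshold in log10 fold-change units.
#' @param epsilon dose window half-width; default 5 percent of the dose
#'   range.
#' @param delta_grid,dose_grid surface grids; defaults: 21 thresholds on
#'   [0, 1], the design doses plus interpolated points.
#' @param n_sims Monte-Carlo size for logic sampling and transition
#'   estimates.
#' @param seed master seed.
#' @return list of class `qaop_config`.
#' @export
qaop_config <- function(out_dir = tempfile("qaop_run_"),
                        design = study_design(),
                        donors = default_donor_table(),
                        graph = canonical_aop(),
                        delta = log10(2),
                        epsilon = NULL,
                        delta_grid = seq(0, 1, length.out = 21),
                        dose_grid = NULL,
                        n_sims = 1e4,
                        seed = 1L) {
  rng <- range(design$doses)
  if (is.null(epsilon)) epsilon <- 0.05 * diff(rng)
  if (is.null(dose_grid)) {
    dose_grid <- sort(unique(c(design$doses,
                               seq(rng[1], rng[2], length.out = 17))))
  }
  set.seed(seed)
  stage_seeds <- stats::setNames(
    sample.int(.Machine$integer.max - 1L, 5),
    c("simulate", "resample", "gbn", "dbn", "prune"))
  structure(list(out_dir = out_dir, design = design, donors = donors,
                 graph = graph, delta = delta, epsilon = epsilon,
                 delta_grid = delta_grid, dose_grid = dose_grid,
                 n_sims = n_sims, seed = seed, stage_seeds = stage_seeds),
            class = "qaop_config")
}

write_stage <- function(df, path, stage, seed) {
  utils::write.csv(df, path, row.names = FALSE)
  data.frame(stage = stage, path = path, seed = seed,
             checksum = unname(tools::md5sum(path)),
             stringsAsFactors = FALSE)
}

#' Run the full pipeline
#'
#' Simulate -> resample -> dose-response and response-response regression ->
#' per-exposure GBNs with activation surfaces and volumes -> DBN with pooled
#' and dose-specific transition tables -> lasso pruning with recomputed
#' transitions. Every stage writes a tidy CSV into `config$out_dir`; the
#' returned manifest lists each artifact with its stage, seed and checksum,
#' so two runs under the same configuration produce identical checksums.
#'
#' @param config a [qaop_config()].
#' @return data frame manifest (also written to `manifest.csv`).
#' @export
run_qaop <- function(config) {
  stopifnot(inherits(config, "qaop_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  ss <- config$stage_seeds
  design <- config$design
  design$seed <- ss[["simulate"]]
  E <- design$n_exposures
  manifest <- list()
  p <- function(f) file.path(config$out_dir, f)

  primary <- generate_primary(design, config$donors, config$graph)
  manifest$primary <- write_stage(as.data.frame(primary), p("primary.csv"),
                                  "simulate", ss[["simulate"]])

  rep_data <- resample_replicates(primary, seed = ss[["resample"]])
  manifest$replicates <- write_stage(as.data.frame(rep_data),
                                     p("replicates.csv"),
                                     "resample", ss[["resample"]])

  manifest$dose_r2 <- write_stage(dose_r2_table(rep_data), p("r2_dose.csv"),
                                  "regress", ss[["resample"]])

  gbn_rows <- list(); vus_rows <- list()
  set.seed(ss[["gbn"]])
  for (e in 1:E) {
    gbn <- fit_gbn(rep_data, e)
    r2 <- gbn_r2(gbn)
    gbn_rows[[e]] <- data.frame(exposure = e, node = names(r2), r2 = unname(r2))
    samples <- logic_sample(gbn, config$n_sims)
    kes <- grep("^(KE|AO)", config$graph$bio_nodes, value = TRUE)
    vus_rows[[e]] <- data.frame(
      exposure = e, node = kes,
      vus = vapply(kes, function(v) {
        vus(probability_surface(samples, v, config$delta_grid,
                                config$dose_grid, config$epsilon))
      }, numeric(1)))
  }
  manifest$gbn_r2 <- write_stage(do.call(rbind, gbn_rows), p("gbn_r2.csv"),
                                 "gbn", ss[["gbn"]])
  manifest$vus <- write_stage(do.call(rbind, vus_rows), p("vus.csv"),
                              "gbn", ss[["gbn"]])

  dbn <- fit_dbn(rep_data)
  pooled <- transition_table(dbn, rep_data, delta = config$delta,
                             n_sims = config$n_sims, seed = ss[["dbn"]])
  manifest$transit <- write_stage(pooled, p("transitions_pooled.csv"),
                                  "dbn", ss[["dbn"]])
  per_dose <- suppressWarnings(
    dose_specific_transitions(rep_data, delta = config$delta,
                              n_sims = ceiling(config$n_sims / 10),
                              seed = ss[["dbn"]] %% 1000000L + 1L))
  manifest$transit_dose <- write_stage(per_dose, p("transitions_dose.csv"),
                                       "dbn", ss[["dbn"]])

  pruned <- lasso_prune(rep_data)
  manifest$prune <- write_stage(pruned$edges, p("pruning_report.csv"),
                                "prune", ss[["prune"]])
  ptab <- pruned_transitions(pruned, rep_data, delta = config$delta,
                             n_sims = config$n_sims, seed = ss[["prune"]])
  manifest$ptransit <- write_stage(ptab, p("pruned_transitions.csv"),
                                   "prune", ss[["prune"]])

  manifest <- do.call(rbind, unname(manifest))
  utils::write.csv(manifest, p("manifest.csv"), row.names = FALSE)
  manifest
}

#' Fixture bundles for fast experimentation and testing
#'
#' `"tiny"` is a 2-donor, 2-dose, 3-exposure design on a five-node pathway
#' (dose root, one MIE, one acute KE, one chronic KE, the AO); `"default"`
#' is the full study: canonical 20-node graph, 8 donors, 4 doses,
#' 6 exposures, 3 replicates.
#'
#' @param scale `"tiny"` or `"default"`.
#' @param seed integer seed.
#' @return list with `graph`, `design`, `donors`, `primary`, `replicates`.
#' @export
make_fixtures <- function(scale = c("tiny", "default"), seed = 1L) {
  scale <- match.arg(scale)
  if (scale == "tiny") {
    nodes <- data.frame(
      name = c("DOSE", "MIE1", "KE1", "KE8", "AO"),
      role = c("DOSE", "MIE", "ACUTE_KE", "CHRONIC_KE", "AO"),
      stringsAsFactors = FALSE)
    edges <- rbind(c("DOSE", "MIE1"), c("MIE1", "KE1"),
                   c("KE1", "KE8"), c("KE8", "AO"))
    graph <- aop_graph(nodes, edges)
    design <- study_design(doses = c(0, 100), n_donors = 2L,
                           n_exposures = 3L, n_replicates = 3L,
                           kappa = 30L, seed = seed)
    donors <- data.frame(donor = 1:2, onset = c(2L, NA),
                         severity = c("severe", "none"),
                         stringsAsFactors = FALSE)
  } else {
    graph <- canonical_aop()
    design <- study_design(seed = seed)
    donors <- default_donor_table()
  }
  primary <- generate_primary(design, donors, graph)
  list(graph = graph, design = design, donors = donors, primary = primary,
       replicates = resample_replicates(primary))
}
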