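#' Study design for a repeated-exposure experiment
#'
#' Defaults reproduce the study conditions quantified throughout the
#' package: four doses including the untreated control, eight donors, six
#' exposure repetitions, three replicates, and 100 within-cell draws for the
#' Bayesian updating step.
#'
#' @param doses ascending dose levels; the first must be the control 0.
#'   Dose units are arbitrary exposure-concentration units.
#' @param n_donors number of donors N.
#' @param n_exposures number of exposure repetitions E.
#' @param n_replicates replicates R drawn per (donor, exposure, dose) cell.
#' @param kappa draws per cell used to learn the resampling network.
#' @param seed integer seed for the simulator.
#' @return An object of class `study_design`.
#' @export
study_design <- function(doses = c(0, 50, 100, 200), n_donors = 8L,
                         n_exposures = 6L, n_replicates = 3L,
                         kappa = 100L, seed = 1L) {
  if (length(doses) < 2L || doses[1] != 0 || is.unsorted(doses, strictly = TRUE)) {
    qaop_stop("qaop_design_error",
              "doses must be >= 2 strictly ascending levels starting at 0")
  }
  if (n_donors < 1L || n_exposures < 1L || n_replicates < 1L || kappa < 2L) {
    qaop_stop("qaop_design_error", "design counts must be positive")
  }
  structure(list(doses = doses, n_donors = as.integer(n_donors),
                 n_exposures = as.integer(n_exposures),
                 n_replicates = as.integer(n_replicates),
                 kappa = as.integer(kappa), seed = as.integer(seed)),
            class = "study_design")
}

#' Donor table: onset and severity of chronic toxicity
#'
#' Eight donors with donor-dependent appearance of chronic-phase responses:
#' donors 1, 3 and 5 first elicit chronic key events at exposure repetition
#' 4 and donors 2, 4 and 6 at repetition 3; severities are paired
#' (severe, severe, moderate, moderate, weak, weak); donors 7 and 8 never
#' show chronic toxicity.
#'
#' @return data frame with columns `donor`, `onset` (exposure repetition at
#'   which chronic responses appear; `NA` = never) and `severity`
#'   (`severe`, `moderate`, `weak`, or `none`).
#' @export
default_donor_table <- function() {
  data.frame(
    donor = 1:8,
    onset = c(4L, 3L, 4L, 3L, 4L, 3L, NA, NA),
    severity = c("severe", "severe", "moderate", "moderate",
                 "weak", "weak", "none", "none"),
    stringsAsFactors = FALSE
  )
}

validate_donors <- function(donors, design) {
  if (nrow(donors) != design$n_donors) {
    qaop_stop("qaop_design_error", "donor table has %d rows; design has N = %d",
              nrow(donors), design$n_donors)
  }
  if (any(!is.na(donors$onset) & (donors$onset < 1 | donors$onset > design$n_exposures))) {
    qaop_stop("qaop_design_error", "donor onset outside [1, E]")
  }
  if (any(is.na(donors$onset) != (donors$severity == "none"))) {
    qaop_stop("qaop_design_error",
              "onset NA and severity 'none' must coincide")
  }
  invisible(donors)
}

#' Generate the primary virtual dataset
#'
#' Produces the ground-truth mean fold change and fold-change standard
#' deviation for every (donor, exposure, dose, node) cell.
#'
#' Mean fold changes are anchored at 1 for the untreated control. For
#' acute-phase nodes the mean grows along the dose axis by independent
#' increments `zeta_d ~ U(0, 1)` (drawn once per donor and node and shared
#' across exposures) and along the exposure axis by increments
#' `zeta_e ~ U(0, 0.2)` added to every treated dose, so the response is
#' strictly increasing in dose and non-decreasing in exposure repetition.
#' Chronic-phase nodes follow the same recursions from their donor-specific
#' onset repetition onward (baseline 1 at onset); before onset (or always,
#' for donors that never develop chronic toxicity) treated cells are
#' unelicited noise `0.8 + 0.4 * U(0, 1)`. The donor table's severity grade
#' can optionally scale the chronic increment draws through
#' `severity_scale`; the default leaves magnitudes ungraded, since the
#' generating recursions are fully specified without a severity term and
#' severity then describes the onset pattern rather than a separate
#' amplitude.
#'
#' Standard deviations follow
#' `s(d+1) = (fbar(d) + zeta * (fbar(d+1) - fbar(d))) / (4 + 6 * zeta)`
#' with a fresh `zeta ~ U(0, 1)` per cell, so a larger jump between adjacent
#' dose means yields a larger spread; `s = 0` at the control.
#'
#' @param design a [study_design()].
#' @param donors donor table as from [default_donor_table()].
#' @param graph an [aop_graph()]; the node list and acute/chronic phases
#'   drive the generator.
#' @param severity_scale named multipliers of the chronic increment draws
#'   per severity grade; e.g. `c(severe = 1, moderate = 0.6, weak = 0.3,
#'   none = 0)` grades amplitudes by severity.
#' @return Object of class `primary_dataset`: arrays `mean_fc` and `sd_fc`
#'   with dimensions donor x exposure x dose x node, plus the design, donor
#'   table and graph.
#' @export
generate_primary <- function(design = study_design(),
                             donors = default_donor_table(),
                             graph = canonical_aop(),
                             severity_scale = c(severe = 1, moderate = 1,
                                                weak = 1, none = 0)) {
  stopifnot(inherits(design, "study_design"), inherits(graph, "aop_graph"))
  validate_donors(donors, design)
  N <- design$n_donors; E <- design$n_exposures
  doses <- design$doses; D <- length(doses)
  nodes <- graph$bio_nodes; V <- length(nodes)
  chronic <- chronic_nodes(graph)

  dn <- list(donor = as.character(1:N), exposure = as.character(1:E),
             dose = as.character(doses), node = nodes)
  f <- array(NA_real_, dim = c(N, E, D, V), dimnames = dn)
  s <- array(NA_real_, dim = c(N, E, D, V), dimnames = dn)

  set.seed(design$seed)
  for (n in 1:N) {
    onset <- donors$onset[n]
    for (v in seq_along(nodes)) {
      is_chronic <- nodes[v] %in% chronic
      sev <- if (is_chronic) unname(severity_scale[donors$severity[n]]) else 1
      from <- if (is_chronic) {
        if (is.na(onset)) Inf else onset
      } else 1L
      zd <- stats::runif(D - 1L) * sev          # dose increments
      ze <- stats::runif(E - 1L, 0, 0.2) * sev  # exposure lifts
      cum_d <- cumsum(zd)
      for (e in 1:E) {
        f[n, e, 1L, v] <- 1
        if (e >= from) {
          lift <- if (e > from) sum(ze[from:(e - 1L)]) else 0
          f[n, e, 2:D, v] <- 1 + cum_d + lift
        } else {
          f[n, e, 2:D, v] <- 0.8 + 0.4 * stats::runif(D - 1L)
        }
      }
      for (e in 1:E) {
        s[n, e, 1L, v] <- 0
        for (j in 2:D) {
          z <- stats::runif(1L)
          gap <- f[n, e, j, v] - f[n, e, j - 1L, v]
          s[n, e, j, v] <- (f[n, e, j - 1L, v] + z * gap) / (4 + 6 * z)
        }
      }
    }
  }

  structure(list(mean_fc = f, sd_fc = s, design = design, donors = donors,
                 graph = graph),
            class = "primary_dataset")
}

#' @export
print.primary_dataset <- function(x, ...) {
  d <- dim(x$mean_fc)
  cat(sprintf("Primary virtual dataset: %d donors x %d exposures x %d doses x %d nodes\n",
              d[1], d[2], d[3], d[4]))
  invisible(x)
}

#' Tidy view of a primary dataset
#'
#' @param x a `primary_dataset`.
#' @param ... unused.
#' @return Long data frame with columns donor, exposure, dose, node,
#'   mean_fc, sd_fc.
#' @export
as.data.frame.primary_dataset <- function(x, ...) {
  g <- expand.grid(donor = as.integer(dimnames(x$mean_fc)$donor),
                   exposure = as.integer(dimnames(x$mean_fc)$exposure),
                   dose = as.numeric(dimnames(x$mean_fc)$dose),
                   node = dimnames(x$mean_fc)$node,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$mean_fc <- as.vector(x$mean_fc)
  g$sd_fc <- as.vector(x$sd_fc)
  g
}
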