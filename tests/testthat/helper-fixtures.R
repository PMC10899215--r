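# Fixture bundles built once per test run and shared across files.
.fixture_cache <- new.env(parent = emptyenv())

tiny_fixture <- function() {
  if (is.null(.fixture_cache$tiny)) {
    .fixture_cache$tiny <- make_fixtures("tiny", seed = 11L)
  }
  .fixture_cache$tiny
}

full_fixture <- function() {
  if (is.null(.fixture_cache$full)) {
    .fixture_cache$full <- make_fixtures("default", seed = 7L)
  }
  .fixture_cache$full
}

# Hand-built replicate_dataset with a given mean array; used to feed the
# regression / DBN layers data with exactly known structure.
fake_rep <- function(mean_arr, design, graph) {
  structure(list(replicates = NULL, mean = mean_arr,
                 R = design$n_replicates, kappa = design$kappa,
                 seed = design$seed, rho = NULL, design = design,
                 donors = NULL, graph = graph),
            class = "replicate_dataset")
}

# Empty mean array for a design/graph, filled with fold change 1.
blank_mean <- function(design, graph) {
  N <- design$n_donors; E <- design$n_exposures
  doses <- design$doses; nodes <- graph$bio_nodes
  array(1, dim = c(N, E, length(doses), length(nodes)),
        dimnames = list(donor = as.character(1:N),
                        exposure = as.character(1:E),
                        dose = as.character(doses), node = nodes))
}
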