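# Shared synthetic study, generated once per test run.

.fixture_env <- new.env(parent = emptyenv())

# Full-scale study: 300 reads (240 toxin / 40 motif-free / 20 error) from 15
# planted toxins, plus the matching PSM table.
shared_study <- function() {
  if (is.null(.fixture_env$study)) {
    .fixture_env$study <- synth_venomics(synth_config(
      seed = 20230211L, n_toxins = 15L, n_toxin_reads = 240L,
      n_nontoxin_reads = 40L, n_error_reads = 20L))
  }
  .fixture_env$study
}

shared_pipeline <- function() {
  if (is.null(.fixture_env$pipeline)) {
    .fixture_env$pipeline <- mine_toxins(shared_study()$reads)
  }
  .fixture_env$pipeline
}

# Small study for module-level tests.
small_study <- function() {
  if (is.null(.fixture_env$small)) {
    .fixture_env$small <- synth_venomics(synth_config(
      seed = 7L, n_toxins = 10L, n_toxin_reads = 25L,
      n_nontoxin_reads = 6L, n_error_reads = 3L))
  }
  .fixture_env$small
}

expected_mature <- function(truth) {
  cass <- ifelse(truth$cassette == "GKR", "GKR",
                 ifelse(truth$cassette == "GR", "GR", ""))
  paste0(truth$mature, cass)
}
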