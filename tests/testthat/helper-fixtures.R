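# Shared fixtures, computed once per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

toy <- function() cached("toy", toy_assay_fixture())

toy_clean <- function() {
  cached("toy_clean", {
    t <- toy()
    list(agonist = run_pipeline(t$agonist),
         antagonist = run_pipeline(t$antagonist))
  })
}

# a small library for module tests (fast); the acceptance suite uses the
# default study-scale configuration instead
small_config <- function(seed = 7L) {
  simulation_config(
    seed = seed, n_scaffold_templates = 12L, n_compounds = 60L,
    n_dual_active = 2L, n_planted_strong_cliffs = 1L,
    n_planted_weak_cliffs = 1L
  )
}

small_lib <- function() cached("small_lib", generate_library(small_config()))

study_lib <- function() {
  cached("study_lib", generate_library(simulation_config(seed = 20260101L)))
}

pair_key <- function(l, r) paste(pmin(l, r), pmax(l, r))
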