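# memoized fixtures shared across test files (built once per test run)
.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache, inherits = FALSE))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache, inherits = FALSE)
}

shared_emissions <- function() {
  cached_fixture("emissions", fit_emission_model(n_train = 12, seed = 7))
}

# cohort + features used by the end-to-end and feature-contract checks
cv_cohort <- function() {
  cached_fixture("cv_cohort",
                 generate_cohort(cohort_config(n_participants = 150, seed = 202)))
}

cv_features <- function() {
  cached_fixture("cv_features", prepare_features(cv_cohort(), shared_emissions()))
}
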