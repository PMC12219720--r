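# Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

# Default desk-scale scenario (200 x 200, seed 1), cached across test files.
default_scenario <- function() {
  if (is.null(.fixture_env$scenario))
    .fixture_env$scenario <- generate_scenario(seed = 1L)
  .fixture_env$scenario
}

# A small scenario for fast structural tests.
small_scenario <- function() {
  if (is.null(.fixture_env$small))
    .fixture_env$small <- generate_scenario(shape = c(60L, 60L),
                                            n_counties = 12L, seed = 4L)
  .fixture_env$small
}
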