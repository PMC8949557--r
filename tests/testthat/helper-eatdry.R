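# Shared fixtures. The default configuration is deterministic, so build it
# once per test run.
.cfg_cache <- new.env(parent = emptyenv())

test_cfg <- function(overrides = NULL) {
  if (is.null(overrides)) {
    if (is.null(.cfg_cache$default)) .cfg_cache$default <- eatdry_config()
    return(.cfg_cache$default)
  }
  eatdry_config(overrides)
}

# A short, fully deterministic scenario: pinned lot mean and no slab noise.
quiet_scenario <- function(duration_h = 6, seed = 1, ...) {
  drying_scenario("continuous", duration_h = duration_h, seed = seed,
                  inlet_mean = 25.5, inlet_sd = 0, ...)
}

expect_eatdry_error <- function(expr, class) {
  expect_error(expr, class = class)
}
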