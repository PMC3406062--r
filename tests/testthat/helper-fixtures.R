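# Shared fixtures, built once per test run. The small world keeps unit
# tests fast; the standard world is the acceptance fixture (built only by
# the acceptance tests).

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache, inherits = FALSE)
}

# a scaled-down world with the standard structure (12 sources, 8 samples
# per site, 60 reads each); used by unit tests of downstream stages
small_world <- function() {
  cached_fixture("small_world",
                 standard_fixture(seed = 101, n_sources = 12,
                                  samples_per_site = 8,
                                  reads_per_sample = 60))
}

small_result <- function() {
  cached_fixture("small_result", {
    fx <- small_world()
    suppressMessages(most_wanted_pipeline(fx$reads, fx$metadata, fx$ref_dbs))
  })
}

# the full acceptance world (60 sources, 5 x 40 x 200 reads, 1% error,
# 5% chimeras) at its fixed seed
standard_world <- function() {
  cached_fixture("standard_world", standard_fixture(seed = 42))
}

standard_result <- function() {
  cached_fixture("standard_result", {
    fx <- standard_world()
    suppressMessages(most_wanted_pipeline(fx$reads, fx$metadata, fx$ref_dbs))
  })
}
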