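# Shared fixtures. Expensive interference-model sweeps are computed once per
# test session and cached here so independent test files can reuse them.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

apical_fr <- function() {
  cached("apical_fr", generate_frequency_response(apical_profile()))
}

apical_fr_free <- function() {
  cached("apical_fr_free", remove_middle_ear_delay(apical_fr()))
}

middle_fr <- function() {
  cached("middle_fr", generate_frequency_response(middle_turn_profile()))
}

default_map <- function() place_map()

# Full reproduction run (all model sweeps); shared by the pipeline and
# acceptance tests.
reproduction <- function() {
  cached("reproduction", pipeline_reproduce())
}
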