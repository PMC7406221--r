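# Fixtures are deterministic, so expensive ones are built once per test run
# and shared across files.
.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(name) {
  if (is.null(.fixture_cache[[name]]))
    .fixture_cache[[name]] <- make_fixture(name)
  .fixture_cache[[name]]
}

cached_ml_features <- function() {
  if (is.null(.fixture_cache$ml_features)) {
    fx <- cached_fixture("ml")
    utrs <- extract_utrs(fx$annotation, fx$genome)
    .fixture_cache$ml_features <- list(
      X = count_kmers(utrs),
      y = fx$truth$true_halflife,
      planted = fx$truth$planted_motif)
  }
  .fixture_cache$ml_features
}
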