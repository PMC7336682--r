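# fixture generation is expensive (probe-search certification), so the
# suite shares one instance per (seed, n_torsions)
.fixture_cache <- new.env(parent = emptyenv())

# seeds of the shipped benchmark fixtures (chosen so certification
# passes on the generator's first attempt)
BENCH_SEED_T2 <- 1L
BENCH_SEED_T6 <- 1L

cached_fixture <- function(seed, n_torsions) {
  key <- paste0("s", seed, "t", n_torsions)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- generate_fixture(seed, n_torsions)
  .fixture_cache[[key]]
}
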