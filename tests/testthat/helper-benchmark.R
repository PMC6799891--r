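# the full synthetic benchmark is expensive; run it once and share it
# across the acceptance test blocks
.benchmark_cache <- new.env(parent = emptyenv())

get_benchmark <- function() {
  if (is.null(.benchmark_cache$bm)) {
    .benchmark_cache$bm <- viability_benchmark(seed = 1)
  }
  .benchmark_cache$bm
}
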