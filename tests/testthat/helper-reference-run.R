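# Reference study conditions: the 60 x 60 quarter-degree landscape with the
# planted corridor (boost 0.3), 300 presences per month, fixed seed.
# Computed lazily once and shared by the end-to-end recovery tests.
.ref_cache <- new.env(parent = emptyenv())

reference_run <- function() {
  if (is.null(.ref_cache$res)) {
    cfg <- pipeline_config(seed = 1, importance_month = NULL)
    .ref_cache$res <- suppressWarnings(suppressMessages(run_pipeline(cfg)))
  }
  .ref_cache$res
}
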