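# The default-configuration demo run is expensive (~30 s), so acceptance
# blocks that need it share one memoized execution.

.demo_cache <- new.env(parent = emptyenv())

demo_run <- function() {
  if (is.null(.demo_cache$state)) {
    cfg <- pipeline_config(seed = 7L)
    out <- file.path(tempdir(), "loopscape_demo")
    t0 <- Sys.time()
    st <- suppressWarnings(suppressMessages(run_all(cfg, outdir = out)))
    .demo_cache$elapsed <- as.numeric(difftime(Sys.time(), t0, units = "mins"))
    .demo_cache$state <- st
    .demo_cache$outdir <- out
    .demo_cache$config <- cfg
  }
  .demo_cache
}
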