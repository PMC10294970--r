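# Full preset pipeline runs are expensive; memoize them so every test file
# can share one run per preset.
.pipeline_cache <- new.env(parent = emptyenv())

preset_pipeline_run <- function(preset, seed = 1L) {
  key <- paste0(preset, "_", seed)
  if (is.null(.pipeline_cache[[key]])) {
    out <- file.path(tempdir(), paste0("cytoprint_", key))
    .pipeline_cache[[key]] <- suppressMessages(
      run_pipeline(preset_run_config(preset, seed = seed), output_dir = out))
  }
  .pipeline_cache[[key]]
}

# noise-free, PSF-free variant of a phantom spec (ideal imaging)
ideal_spec <- function(spec) {
  spec$psf_sigma <- c(0, 0, 0)
  spec$noise <- list(type = "none")
  spec
}

# half-maximum threshold segmentation of one channel, largest component
halfmax_mask <- function(stack, channel, fill_radius = 2) {
  img <- get_channel(stack, channel)
  thr <- (max(img) + min(img)) / 2
  m <- threshold_mask(stack, channel, c(thr, 2^stack$bit_depth - 1))
  m <- split_mask(m)[[1]]
  if (fill_radius > 0) m <- fill_mask(m, "volumetric", fill_radius)
  m
}
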