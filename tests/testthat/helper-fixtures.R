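# Shared fixtures, built once per test run.

sched23 <- pib_frame_schedule()
ref23 <- simulate_reference_tac(sched23)

# Small dynamic image with prescribed per-frame values in every voxel.
uniform_dynamic <- function(values, dims = c(3, 3, 3), voxel_mm = 2,
                            schedule = NULL) {
  if (is.null(schedule)) {
    ends <- cumsum(rep(10, length(values)))
    schedule <- frame_schedule(ends - 10, ends)
  }
  arr <- array(rep(values, each = prod(dims)), c(dims, length(values)))
  dynamic_image(arr, voxel_mm, schedule)
}

# Two-region slab atlas filling a grid; region "A" (x <= split) is reference.
slab_atlas <- function(dims = c(8, 8, 8), split = 4, voxel_mm = 2) {
  lab <- array(2L, dims)
  lab[seq_len(split), , ] <- 1L
  pet_atlas(lab,
            data.frame(label = 1:2, name = c("A", "B"),
                       tissue_class = c("reference", "cortical"),
                       is_reference = c(TRUE, FALSE),
                       stringsAsFactors = FALSE),
            voxel_mm)
}

# A noiseless subject on a compact grid, cached for reuse.
noiseless_subject <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      atlas <- make_phantom_atlas(c(20, 20, 20), 4, 4)
      spec <- default_kinetic_spec(atlas, "PIB+", noise_scale = 0,
                                   fdg_noise_sd = 0, region_jitter_sd = 0)
      cache <<- list(atlas = atlas, spec = spec,
                     subject = simulate_subject(atlas, spec, seed = 5))
    }
    cache
  }
})
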