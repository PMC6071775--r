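# Shared phantom builders kept small so the suite stays fast.

# single-pore tomogram phantom at the 3 nm working voxel
pore_spec <- function(rim = 26, pore = 80, tilt = 0, azimuth = 0,
                      noise = 0, seed = 1, shape = c(100, 100, 100)) {
  scene_spec(volume_shape = shape, voxel_size = 3,
             pore_specs = list(list(rim_diameter = rim, pore_diameter = pore,
                                    tilt_deg = tilt, azimuth_deg = azimuth)),
             noise_sd = noise, seed = seed)
}

measure_phantom_pore <- function(spec, half_extent = 120, ...) {
  ph <- make_pore_volume(spec)
  ctr <- as.numeric(ph$truth[1, c("z_nm", "y_nm", "x_nm")])
  run_pore_pipeline(ph$volume, ctr, half_extent_nm = half_extent, ...)
}

# flat telophase sheet at SBF-SEM-like pitch (70 nm sections for exact dz)
sheet_spec <- function(gaps = list(), nves = 0, shape = c(8, 120, 200),
                       voxel = c(70, 4.5, 4.5), seed = 3, ...) {
  scene_spec(volume_shape = shape, voxel_size = voxel, gap_specs = gaps,
             vesicle_count = nves, noise_sd = 0, blur_sigma = 0,
             tortuosity_amp = 0, seed = seed, ...)
}

# The two rim-curvature recovery studies are shared by several acceptance
# criteria; compute each once per test run.
.study_cache <- new.env(parent = emptyenv())
cached_pore_study <- function(rim, n = 40, seed = 101) {
  key <- sprintf("rd%s_n%d_seed%d", format(rim), n, seed)
  if (is.null(.study_cache[[key]]))
    .study_cache[[key]] <- simulate_pore_study(n, rim_diameter = rim,
                                               seed = seed)
  .study_cache[[key]]
}
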