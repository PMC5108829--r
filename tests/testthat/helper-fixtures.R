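# Shared small fixtures. Geometries are deliberately tiny: every property
# under test is resolution-independent, so the suite runs on coarse grids.

tiny_geom <- function(n_views = 12L, n_radial = 32L, radial_bin_cm = 0.8,
                      n_slices = 8L, slice_thickness_cm = 1,
                      fov_radius_cm = 12.8) {
  scanner_geometry(n_views, n_radial, radial_bin_cm, n_slices,
    slice_thickness_cm, fov_radius_cm
  )
}

# moderately sampled geometry for reconstruction checks
recon_geom <- function(n_slices = 3L) {
  scanner_geometry(
    n_views = 64L, n_radial = 128L, radial_bin_cm = 0.2,
    n_slices = n_slices, slice_thickness_cm = 0.26, fov_radius_cm = 12.8
  )
}

# calibration study geometry: fine radial bins so the scatter tail is
# well sampled
calib_geom <- function() {
  scanner_geometry(
    n_views = 16L, n_radial = 128L, radial_bin_cm = 0.2,
    n_slices = 8L, slice_thickness_cm = 0.8, fov_radius_cm = 12.8
  )
}

# cylinder trues + self-consistent scatter + prompts under given params
self_consistent_cylinder <- function(geom, params, win = window_config(1, 1),
                                     uew_params = NULL) {
  ph <- build_phantom("uniform_cylinder", geom, diameter_cm = 15)
  trues <- forward_project(ph$activity, geom, mu = ph$mu)
  cfg <- scatter_config(
    mode = "dec_self_consistent", params = params, uew_params = uew_params
  )
  sc <- simulate_scatter(trues, ph$mu, cfg)
  pr <- compose_prompts(trues, sc, win, cfg)
  list(phantom = ph, trues = trues, scatter = sc, prompts = pr, cfg = cfg)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected)) / max(abs(expected)), tol)
}
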