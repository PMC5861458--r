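# Shared synthetic-scene builders. Test scenes place one structure in a
# 4 x 4 um region with the default 100 background localizations per um^2,
# which reproduces the background-dominated composition the median Voronoi
# rule assumes.

scene_roi <- function(width = 4000) roi_rect(width, width)

# one straight filament with a random pose
filament_scene <- function(seed, length_nm = 150, model = imaging_model(),
                           roi = scene_roi()) {
  set.seed(seed)
  f <- simulate_filament(length_nm,
                         direction = stats::runif(1, 0, pi),
                         origin = c(stats::runif(2, -500, 500), 0))
  render_scene(list(f), model, roi, seed = seed + 1)
}

# one globular bundle with background
bundle_scene <- function(seed, n_molecules = 80, sigma = 60,
                         model = imaging_model(), roi = scene_roi()) {
  set.seed(seed)
  b <- simulate_bundle(n_molecules, sigma,
                       center = c(stats::runif(2, -500, 500), 0))
  render_scene(list(b), model, roi, seed = seed + 1)
}

# calibration profile from isolated antibodies on glass, processed with the
# same quality filter + frame linking as real data
make_calibration <- function(seed = 7, n_antibodies = 60,
                             model = imaging_model(background_density_um2 = 0)) {
  roi <- roi_rect(10000, 10000)
  set.seed(seed)
  ab <- lapply(seq_len(n_antibodies), function(i) {
    matrix(c(roi_sample(roi, 1), 0), 1, 3)
  })
  sc <- render_scene(ab, model, roi, seed = seed + 1)
  tab <- add_precision(sc$table, model$psf_sigma_nm, model$pixel_nm,
                       model$background_photons)
  tab <- filter_quality(tab)
  tab <- link_frames(tab)
  gt <- do.call(rbind, ab)
  idx <- FNN::get.knnx(gt[, 1:2, drop = FALSE], cbind(tab$x, tab$y),
                       k = 1)$nn.index[, 1]
  cnt <- tabulate(idx, nbins = n_antibodies)
  calibration_profile(cnt[cnt > 0])
}

# map processed (filtered/merged) localizations back to ground truth via the
# provenance of the nearest raw localization; TRUE = structure, FALSE = background
near_structure <- function(table, scene) {
  raw <- scene$table
  if (!nrow(raw)) return(rep(FALSE, nrow(table)))
  idx <- FNN::get.knnx(cbind(raw$x, raw$y, raw$z),
                       cbind(table$x, table$y, table$z),
                       k = 1)$nn.index[, 1]
  scene$provenance$structure[idx] > 0
}
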