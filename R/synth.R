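#' Imaging model for synthetic SMLM scenes
#'
#' Declares how ground-truth molecule positions become localization tables:
#' antibody displacement, labeling efficiency, blinking, photon statistics
#' feeding the Thompson precision, residual broadening, and uniform
#' background. Defaults emulate the two-color d-STORM acquisition the
#' package targets (median combined precision ~10 nm, ~15 nm antibody
#' stack, ~40 nm empirical FWHM).
#'
#' @param displacement_nm antibody displacement magnitude in nm (default
#'   15, the size of the primary+secondary antibody stack).
#' @param displacement_mode `"fixed"`: uniformly oriented 3D vector of fixed
#'   magnitude (default); `"gaussian"`: isotropic 3D Gaussian with the same
#'   mean magnitude.
#' @param labeling_efficiency probability that a molecule carries a label,
#'   in (0, 1] (default 1).
#' @param blink_type `"geometric"` (default): number of blink events per
#'   fluorophore is 1 + Geometric, parameterized by `blink_median`;
#'   `"fixed"`: exactly `blink_k` events.
#' @param blink_median median blink events per fluorophore (default 8).
#' @param blink_k event count for `blink_type = "fixed"`.
#' @param burst_frames integer range of consecutive frames per blink event
#'   (default 1:3); each frame yields one raw localization, re-merged later
#'   by [link_frames()].
#' @param photon_median,photon_sdlog log-normal photon counts per
#'   localization (median 2000, sdlog 0.4).
#' @param psf_sigma_nm,pixel_nm,background_photons Thompson-precision inputs
#'   (defaults 150 nm, 160 nm, 16 photons/pixel, giving a median combined
#'   precision of ~10 nm at the default photon distribution).
#' @param extra_lateral_sigma_nm residual lateral broadening (nm, default
#'   11) covering steric hindrance, antibody thermal movement and residual
#'   aberrations — the gap between the component-based ~30 nm resolution
#'   estimate and the empirical ~40 nm FWHM.
#' @param axial_factor axial (z) localization noise as a multiple of the
#'   lateral per-axis precision (default 2, typical for astigmatic 3D).
#' @param background_density_um2 uniform background localizations per square
#'   micrometre (default 100).
#' @param z_range_nm axial extent of the acquisition slab for background
#'   localizations (default c(-250, 250)).
#' @param n_frames frames in the acquisition (default 25000).
#' @return object of class `imaging_model`.
#' @export
imaging_model <- function(displacement_nm = 15,
                          displacement_mode = c("fixed", "gaussian"),
                          labeling_efficiency = 1,
                          blink_type = c("geometric", "fixed"),
                          blink_median = 8, blink_k = 1,
                          burst_frames = 1:3,
                          photon_median = 2000, photon_sdlog = 0.4,
                          psf_sigma_nm = 150, pixel_nm = 160,
                          background_photons = 16,
                          extra_lateral_sigma_nm = 11,
                          axial_factor = 2,
                          background_density_um2 = 100,
                          z_range_nm = c(-250, 250),
                          n_frames = 25000) {
  displacement_mode <- match.arg(displacement_mode)
  blink_type <- match.arg(blink_type)
  stopifnot(displacement_nm >= 0, labeling_efficiency > 0,
            labeling_efficiency <= 1, blink_median >= 1, blink_k >= 1,
            photon_median > 0, photon_sdlog >= 0, psf_sigma_nm > 0,
            pixel_nm > 0, background_photons >= 0,
            extra_lateral_sigma_nm >= 0, axial_factor >= 0,
            background_density_um2 >= 0, n_frames >= 1)
  structure(list(displacement_nm = displacement_nm,
                 displacement_mode = displacement_mode,
                 labeling_efficiency = labeling_efficiency,
                 blink_type = blink_type, blink_median = blink_median,
                 blink_k = blink_k, burst_frames = as.integer(burst_frames),
                 photon_median = photon_median, photon_sdlog = photon_sdlog,
                 psf_sigma_nm = psf_sigma_nm, pixel_nm = pixel_nm,
                 background_photons = background_photons,
                 extra_lateral_sigma_nm = extra_lateral_sigma_nm,
                 axial_factor = axial_factor,
                 background_density_um2 = background_density_um2,
                 z_range_nm = z_range_nm, n_frames = n_frames),
            class = "imaging_model")
}

# number of blink events per fluorophore
.draw_blinks <- function(model, n) {
  if (model$blink_type == "fixed") return(rep(model$blink_k, n))
  q <- 2^(-1 / model$blink_median)       # P(X >= m+1) = q^m = 1/2
  1 + stats::rgeom(n, prob = 1 - q)
}

# mean localizations (pre-linking) per labeled molecule
.mean_locs_per_molecule <- function(model) {
  ev <- if (model$blink_type == "fixed") model$blink_k else {
    q <- 2^(-1 / model$blink_median)
    1 / (1 - q)
  }
  ev * mean(model$burst_frames)
}

#' Expected localization count of a rendered scene
#'
#' `n_molecules * efficiency * E[localizations per fluorophore] +
#'  background_density * area`.
#'
#' @param model an [imaging_model()].
#' @param n_molecules ground-truth molecule count.
#' @param roi a [nucleus_roi()].
#' @return expected number of raw localizations.
#' @export
expected_localizations <- function(model, n_molecules, roi) {
  n_molecules * model$labeling_efficiency * .mean_locs_per_molecule(model) +
    model$background_density_um2 * roi$area / 1e6
}

#' Monomer positions along a helical filament
#'
#' Places monomers along a straight or uniformly curved backbone at an
#' axial rise of `pitch / monomers_per_turn` (1.5 nm for the default
#' geometry), with a helical radial offset rotating by
#' `360 / monomers_per_turn` degrees per monomer. A 200 nm filament yields
#' 133 monomers; 9 nm yields 6 (one turn).
#'
#' @param length_nm backbone length in nm, >= 0.
#' @param geometry a [helix_geometry()].
#' @param curvature backbone curvature in 1/nm (0 = straight); positive
#'   curvature bends the backbone on a circle of radius 1/curvature. An
#'   arc longer than the full circle is an error.
#' @param helix_radius_nm radial offset of monomer centers from the
#'   backbone axis (default 3.5).
#' @param origin 3D origin of the backbone.
#' @param direction backbone direction angle in the xy plane, radians.
#' @param phase starting helical phase, radians.
#' @return n x 3 matrix of monomer positions (nm).
#' @export
simulate_filament <- function(length_nm, geometry = helix_geometry(),
                              curvature = 0, helix_radius_nm = 3.5,
                              origin = c(0, 0, 0), direction = 0, phase = 0) {
  if (length_nm < 0) stop("length must be >= 0", call. = FALSE)
  if (abs(curvature) * length_nm > 2 * pi + 1e-12) {
    stop("curvature closes the backbone on itself (|curvature| * length > 2*pi)",
         call. = FALSE)
  }
  rise <- geometry$pitch_nm / geometry$monomers_per_turn
  n <- round(length_nm / rise)
  if (n < 1) return(matrix(numeric(0), 0, 3))
  s <- (seq_len(n) - 1) * rise
  if (abs(curvature) < 1e-12) {
    bx <- s; by <- rep(0, n); theta <- rep(0, n)
  } else {
    R <- 1 / curvature
    bx <- R * sin(s / R); by <- R * (1 - cos(s / R)); theta <- s / R
  }
  phi <- phase + 2 * pi * (seq_len(n) - 1) / geometry$monomers_per_turn
  # in-plane normal is (-sin theta, cos theta); helix offset uses normal + z
  px <- bx + helix_radius_nm * cos(phi) * (-sin(theta))
  py <- by + helix_radius_nm * cos(phi) * cos(theta)
  pz <- helix_radius_nm * sin(phi)
  rot <- cbind(px * cos(direction) - py * sin(direction),
               px * sin(direction) + py * cos(direction), pz)
  sweep(rot, 2, origin, "+")
}

#' Molecule positions of a globular bundle
#'
#' 3D Gaussian cloud of molecules, the model for compact RPA/BrdU bundles.
#'
#' @param n_molecules number of molecules, >= 1.
#' @param sigma_xyz per-axis standard deviations in nm (length 1 or 3).
#' @param center bundle center (3D).
#' @return n x 3 matrix of molecule positions.
#' @export
simulate_bundle <- function(n_molecules, sigma_xyz = 50, center = c(0, 0, 0)) {
  stopifnot(n_molecules >= 1, all(sigma_xyz >= 0))
  sigma_xyz <- rep(sigma_xyz, length.out = 3)
  pts <- cbind(stats::rnorm(n_molecules, center[1], sigma_xyz[1]),
               stats::rnorm(n_molecules, center[2], sigma_xyz[2]),
               stats::rnorm(n_molecules, center[3], sigma_xyz[3]))
  pts
}

# uniformly oriented 3D displacement vectors
.displacements <- function(model, n) {
  if (model$displacement_nm == 0) return(matrix(0, n, 3))
  if (model$displacement_mode == "fixed") {
    u <- stats::runif(n, -1, 1)
    th <- stats::runif(n, 0, 2 * pi)
    r <- sqrt(1 - u^2)
    model$displacement_nm * cbind(r * cos(th), r * sin(th), u)
  } else {
    # per-axis sigma chosen so the mean magnitude matches displacement_nm
    sd <- model$displacement_nm / sqrt(8 / pi)
    matrix(stats::rnorm(3 * n, 0, sd), n, 3)
  }
}

#' Render ground-truth structures into a synthetic localization table
#'
#' Each molecule is labeled with probability `labeling_efficiency`; each
#' label is displaced by a random antibody offset; each fluorophore
#' produces a drawn number of blink events, each a short burst of
#' consecutive frames with one localization per frame; each localization is
#' jittered laterally by its Thompson precision (from a drawn photon count)
#' plus the residual broadening term, and axially by `axial_factor` times
#' the lateral per-axis precision. Uniform background localizations are
#' added at the stated density. Every localization is traceable to a
#' molecule or to background via the provenance table.
#'
#' @param structures list of ground-truth structures: n x 3 matrices of
#'   molecule positions (e.g. from [simulate_filament()] /
#'   [simulate_bundle()]).
#' @param model an [imaging_model()].
#' @param roi a [nucleus_roi()] (required); background is placed uniformly
#'   inside it.
#' @param seed RNG seed; identical seeds give identical scenes.
#' @param channel channel tag for the emitted table.
#' @return object of class `synthetic_scene`: list with `table` (a
#'   [loc_table()]), `provenance` (data.frame `structure`, `molecule`;
#'   structure 0 = background), `structures`, `model`, `roi`, `seed`.
#' @export
render_scene <- function(structures, model = imaging_model(), roi, seed = NULL,
                         channel = "A") {
  if (missing(roi) || is.null(roi)) stop("roi is required", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (is.matrix(structures)) structures <- list(structures)
  rows <- list(); prov <- list()
  mol_offset <- 0
  for (si in seq_along(structures)) {
    pos <- structures[[si]]
    if (!nrow(pos)) next
    labeled <- which(stats::runif(nrow(pos)) <= model$labeling_efficiency)
    if (!length(labeled)) { mol_offset <- mol_offset + nrow(pos); next }
    disp <- .displacements(model, length(labeled))
    fluor <- pos[labeled, , drop = FALSE] + disp
    k <- .draw_blinks(model, length(labeled))
    for (fi in seq_along(labeled)) {
      n_ev <- k[fi]
      bursts <- model$burst_frames[sample.int(length(model$burst_frames),
                                              n_ev, replace = TRUE)]
      starts <- sample.int(model$n_frames, n_ev, replace = TRUE)
      n_loc <- sum(bursts)
      photons <- stats::rlnorm(n_loc, meanlog = log(model$photon_median),
                               sdlog = model$photon_sdlog)
      prec <- thompson_precision(photons, model$psf_sigma_nm, model$pixel_nm,
                                 model$background_photons)
      sx <- sqrt(prec$sigma_x^2 + model$extra_lateral_sigma_nm^2)
      frames <- unlist(lapply(seq_len(n_ev), function(e) {
        starts[e] + seq_len(bursts[e]) - 1
      }))
      rows[[length(rows) + 1]] <- data.frame(
        x = fluor[fi, 1] + stats::rnorm(n_loc, 0, sx),
        y = fluor[fi, 2] + stats::rnorm(n_loc, 0, sx),
        z = fluor[fi, 3] + stats::rnorm(n_loc, 0,
                                        model$axial_factor * prec$sigma_x),
        photons = photons, frame = frames)
      prov[[length(prov) + 1]] <- data.frame(
        structure = rep(si, n_loc), molecule = rep(mol_offset + labeled[fi],
                                                   n_loc))
    }
    mol_offset <- mol_offset + nrow(pos)
  }
  n_bg <- stats::rpois(1, model$background_density_um2 * roi$area / 1e6)
  if (n_bg > 0) {
    bg_xy <- roi_sample(roi, n_bg)
    photons <- stats::rlnorm(n_bg, meanlog = log(model$photon_median),
                             sdlog = model$photon_sdlog)
    rows[[length(rows) + 1]] <- data.frame(
      x = bg_xy[, 1], y = bg_xy[, 2],
      z = stats::runif(n_bg, model$z_range_nm[1], model$z_range_nm[2]),
      photons = photons,
      frame = sample.int(model$n_frames, n_bg, replace = TRUE))
    prov[[length(prov) + 1]] <- data.frame(structure = rep(0L, n_bg),
                                           molecule = rep(NA_integer_, n_bg))
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
               photons = numeric(0), frame = numeric(0))
  df$channel <- channel
  tab <- loc_table(df, pixel_nm = model$pixel_nm, dialect = "synthetic")
  structure(list(table = tab,
                 provenance = if (length(prov)) do.call(rbind, prov) else
                   data.frame(structure = integer(0), molecule = integer(0)),
                 structures = structures, model = model, roi = roi,
                 seed = seed),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  n_bg <- sum(x$provenance$structure == 0)
  cat(sprintf("<synthetic_scene> %d localizations (%d background) from %d structures\n",
              nrow(x$table), n_bg, length(x$structures)))
  invisible(x)
}
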