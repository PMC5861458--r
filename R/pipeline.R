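.pipeline_defaults <- function() {
  list(schema_version = 1L,
       dialect = "generic_csv",
       pixel_nm = 160, psf_sigma_nm = 150, background_photons = 16,
       min_photons = 1000, max_sigma_nm = 15,
       link_gap_frames = 10, link_radius_nm = 50,
       voronoi_threshold = "auto", voronoi_dim = 3,
       neighbor_radius_nm = 100, min_same = 30, min_cross = 10,
       edge_threshold_nm = 30, min_cluster_size = 5,
       c2c_threshold_nm = 200,
       calibration = NULL,
       ripley = FALSE, ripley_radii_nm = seq(0, 500, by = 10),
       n_rand = 100, seed = 1L)
}

#' Pipeline configuration
#'
#' All tunable parameters of the ingest -> denoise -> cluster -> colocalize
#' pipeline in one validated list. Defaults are the published operating
#' point: 1000 photons / 15 nm quality filter, 10-frame linking, median
#' Voronoi threshold, 100 nm neighbor radius with 30/10 same/cross
#' thresholds, 30 nm Delaunay edge threshold, 200 nm C2C colocalization
#' threshold, 100 Ripley randomizations. Unknown keys are rejected.
#'
#' @param ... name = value overrides of the defaults.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- .pipeline_defaults()
  user <- list(...)
  if (length(user) == 1 && is.null(names(user)) && is.list(user[[1]])) {
    user <- user[[1]]
  }
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(user)] <- user
  structure(cfg, class = "pipeline_config")
}

.as_loc <- function(x, cfg) {
  if (is.character(x)) x <- read_localizations(x, cfg$dialect, cfg$pixel_nm)
  stopifnot(inherits(x, "loc_table") || is.data.frame(x))
  x
}

# denoise one channel pair; returns kept tables + stage counts
.denoise_stage <- function(ta, tb, cfg) {
  va <- .voronoi_keep(ta, cfg)
  vb <- if (!is.null(tb)) .voronoi_keep(tb, cfg) else NULL
  ka <- ta[va, , drop = FALSE]
  kb <- if (!is.null(tb)) tb[vb, , drop = FALSE] else NULL
  nf <- neighbor_filter(ka, kb, radius = cfg$neighbor_radius_nm,
                        min_same = cfg$min_same, min_cross = cfg$min_cross)
  out_a <- ka[nf$mask_a$keep, , drop = FALSE]
  rownames(out_a) <- NULL
  res <- list(a = out_a,
              counts_a = c(after_voronoi = sum(va),
                           after_neighbor = sum(nf$mask_a$keep)))
  if (!is.null(tb)) {
    out_b <- kb[nf$mask_b$keep, , drop = FALSE]
    rownames(out_b) <- NULL
    res$b <- out_b
    res$counts_b <- c(after_voronoi = sum(vb),
                      after_neighbor = sum(nf$mask_b$keep))
  }
  res
}

.voronoi_keep <- function(tab, cfg) {
  dim <- cfg$voronoi_dim
  if (dim == 3 && (nrow(tab) < 5 || diff(range(tab$z)) <= .Machine$double.eps)) {
    dim <- 2  # flat (2D) acquisitions fall back to planar tessellation
  }
  ann <- voronoi_annotate(tab, dim = dim)
  voronoi_filter(ann, cfg$voronoi_threshold)$keep
}

.channel_stage <- function(tab, cfg) {
  if (!"sigma" %in% names(tab)) {
    tab <- add_precision(tab, cfg$psf_sigma_nm, cfg$pixel_nm,
                         cfg$background_photons)
  }
  n0 <- nrow(tab)
  tab <- filter_quality(tab, cfg$min_photons, cfg$max_sigma_nm)
  n1 <- nrow(tab)
  tab <- link_frames(tab, cfg$link_gap_frames, cfg$link_radius_nm)
  list(table = tab, counts = c(input = n0, after_quality = n1,
                               after_link = nrow(tab)))
}

#' Run the full analysis pipeline on one or more cells
#'
#' For each cell (one localization table per channel): computes precision
#' and applies the quality filter, merges blinking chains, registers
#' channel B onto A via fiducials when provided, denoises by Voronoi cell
#' volume and neighbor counts, segments each channel with the thresholded
#' Delaunay graph, measures cluster extensions, centroids and molecule
#' estimates, pairs channel-A clusters with channel-B clusters
#' (C2C/P2P/E2P), and optionally computes the bivariate Ripley envelope of
#' the paired centroids inside the cell's nucleus ROI. A manifest records
#' parameters, seed and record counts at every filtering stage.
#'
#' @param cells list of cells; each cell is a list with `a` (loc_table or
#'   CSV path), optional `b`, optional `fiducials` ([fiducial_set()]),
#'   optional `roi` ([nucleus_roi()] or vertex CSV path).
#' @param config a [pipeline_config()].
#' @param out_dir optional directory for CSV outputs.
#' @return object of class `pipeline_result`: per-cell results (`clusters_a`,
#'   `clusters_b`, `cluster_table_a/b`, `pairs`, `ripley`), per-cell
#'   colocalization `fractions`, and the `manifest`.
#' @export
run_pipeline <- function(cells, config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(cells$a)) cells <- list(cells)  # single cell convenience
  if (is.null(names(cells)) || any(!nzchar(names(cells)))) {
    names(cells) <- sprintf("cell%d", seq_along(cells))
  }
  set.seed(config$seed)
  calib <- if (is.null(config$calibration)) NULL else
    if (inherits(config$calibration, "calibration_profile")) config$calibration
    else if (length(config$calibration) > 1)
      calibration_profile(config$calibration)
    else config$calibration
  results <- list(); manifest <- list(config = unclass(config))
  all_pairs <- list()
  for (nm in names(cells)) {
    cell <- cells[[nm]]
    stage <- sprintf("cell %s", nm)
    ta <- .as_loc(cell$a, config)
    tb <- if (!is.null(cell$b)) .as_loc(cell$b, config) else NULL
    roi <- cell$roi
    if (is.character(roi)) roi <- read_roi(roi)
    counts_a <- NULL
    res <- tryCatch({
      sa <- .channel_stage(ta, config)
      counts_a <- sa$counts
      counts_b <- NULL
      if (!is.null(tb)) {
        sb <- .channel_stage(tb, config)
        counts_b <- sb$counts
        if (!is.null(cell$fiducials)) {
          shift <- register_channels(cell$fiducials)
          sb$table <- apply_shift(sb$table, shift)
        }
      }
      dn <- .denoise_stage(sa$table, if (!is.null(tb)) sb$table else NULL,
                           config)
      counts_a <- c(counts_a, dn$counts_a)
      if (!is.null(tb)) counts_b <- c(counts_b, dn$counts_b)
      cs_a <- delaunay_segment(dn$a, config$edge_threshold_nm,
                               config$min_cluster_size)
      tab_a <- .cluster_table(cs_a, calib)
      cs_b <- NULL; tab_b <- NULL; pairs <- NULL; rip <- NULL
      if (!is.null(tb)) {
        cs_b <- delaunay_segment(dn$b, config$edge_threshold_nm,
                                 config$min_cluster_size)
        tab_b <- .cluster_table(cs_b, calib)
        if (nrow(tab_a) && nrow(tab_b)) {
          pairs <- pair_clusters(cs_a, cs_b, config$c2c_threshold_nm)
          all_pairs[[nm]] <- pairs
          if (isTRUE(config$ripley) && !is.null(roi)) {
            rip <- ripley_envelope(tab_a[, c("x", "y")], tab_b[, c("x", "y")],
                                   config$ripley_radii_nm, roi,
                                   n_rand = config$n_rand,
                                   seed = config$seed)
          }
        }
      }
      list(clusters_a = cs_a, clusters_b = cs_b,
           cluster_table_a = tab_a, cluster_table_b = tab_b,
           pairs = pairs, ripley = rip,
           counts = list(a = counts_a, b = counts_b))
    }, error = function(e) {
      stop(sprintf("pipeline aborted at %s: %s (counts so far: a=%s)", stage,
                   conditionMessage(e), paste(counts_a, collapse = "/")),
           call. = FALSE)
    })
    manifest[[nm]] <- res$counts
    results[[nm]] <- res
  }
  fractions <- if (length(all_pairs)) {
    coloc_fraction(do.call(rbind, all_pairs),
                   cell = rep(names(all_pairs),
                              vapply(all_pairs, nrow, 0L)))
  } else NULL
  out <- structure(list(cells = results, fractions = fractions,
                        manifest = manifest, config = config),
                   class = "pipeline_result")
  if (!is.null(out_dir)) .write_pipeline_outputs(out, out_dir)
  out
}

# per-cluster summary table: id, n_locs, centroid, extension, ends, molecules
.cluster_table <- function(cs, calibration = NULL) {
  ids <- cluster_ids(cs)
  cent <- weighted_centroid(cs, ids)
  ext <- cluster_extension(cs, ids)
  out <- merge(cent, ext, by = "cluster")
  out$n_locs <- vapply(out$cluster, function(id) sum(cs$labels == id,
                                                     na.rm = TRUE), 0L)
  out$end1_x <- cs$table$x[out$end1]; out$end1_y <- cs$table$y[out$end1]
  out$end2_x <- cs$table$x[out$end2]; out$end2_y <- cs$table$y[out$end2]
  if (!is.null(calibration)) {
    mol <- estimate_molecules(cs, calibration, ids)
    out$molecules_raw <- mol$molecules_raw[match(out$cluster, mol$cluster)]
    out$molecules <- mol$molecules[match(out$cluster, mol$cluster)]
  }
  out[order(out$cluster), , drop = FALSE]
}

.write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(res$cells)) {
    cell <- res$cells[[nm]]
    utils::write.csv(cell$cluster_table_a,
                     file.path(out_dir, paste0(nm, "_clusters_a.csv")),
                     row.names = FALSE)
    if (!is.null(cell$cluster_table_b)) {
      utils::write.csv(cell$cluster_table_b,
                       file.path(out_dir, paste0(nm, "_clusters_b.csv")),
                       row.names = FALSE)
    }
    if (!is.null(cell$pairs)) {
      utils::write.csv(cell$pairs,
                       file.path(out_dir, paste0(nm, "_pairs.csv")),
                       row.names = FALSE)
    }
    if (!is.null(cell$ripley)) {
      utils::write.csv(as.data.frame(cell$ripley),
                       file.path(out_dir, paste0(nm, "_ripley.csv")),
                       row.names = FALSE)
    }
  }
  if (!is.null(res$fractions)) {
    utils::write.csv(res$fractions, file.path(out_dir, "coloc_fractions.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE,
                       null = "null")
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d cell(s)\n", length(x$cells)))
  for (nm in names(x$cells)) {
    cnt <- x$cells[[nm]]$counts
    cat(sprintf("  %s: A %s", nm, paste(cnt$a, collapse = " -> ")))
    if (!is.null(cnt$b)) cat(sprintf(" | B %s", paste(cnt$b, collapse = " -> ")))
    cat("\n")
  }
  if (!is.null(x$fractions)) {
    cat("  colocalization fractions:\n")
    print(x$fractions, row.names = FALSE)
  }
  invisible(x)
}
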