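#' Construct a localization table
#'
#' A `loc_table` is the universal currency of the pipeline: one row per
#' detected emitter, coordinates in nanometres. Mandatory columns are `x`,
#' `y`, `photons` and `frame`; `z` defaults to 0 (2D acquisitions),
#' `channel` to `"A"`. Optional per-axis precision columns `sigma_x`,
#' `sigma_y` and the combined precision `sigma = sqrt(sigma_x^2 + sigma_y^2)`
#' are filled in by [thompson_precision()] when absent.
#'
#' @param df data.frame with at least `x`, `y`, `photons`, `frame` (nm,
#'   photon counts, non-negative integer frame index).
#' @param pixel_nm camera pixel size in nm, stored as metadata.
#' @param dialect source dialect label, stored as metadata.
#' @return data.frame of class `loc_table`.
#' @export
loc_table <- function(df, pixel_nm = NA_real_, dialect = "generic_csv") {
  df <- as.data.frame(df)
  for (col in c("x", "y", "photons", "frame")) {
    if (!col %in% names(df)) {
      stop("localization table is missing mandatory column '", col, "'",
           call. = FALSE)
    }
  }
  if (!"z" %in% names(df)) df$z <- 0
  if (!"channel" %in% names(df)) df$channel <- "A"
  df$channel <- as.character(df$channel)
  num <- c("x", "y", "z", "photons", "frame")
  for (col in num) df[[col]] <- as.numeric(df[[col]])
  if (nrow(df) > 0) {
    if (any(!is.finite(df$x)) || any(!is.finite(df$y)) || any(!is.finite(df$z)))
      stop("localization coordinates must be finite", call. = FALSE)
    if (any(df$photons < 0)) stop("photon counts must be >= 0", call. = FALSE)
    if (any(df$frame < 0)) stop("frame indices must be >= 0", call. = FALSE)
  }
  if (all(c("sigma_x", "sigma_y") %in% names(df)) && !"sigma" %in% names(df)) {
    df$sigma <- sqrt(df$sigma_x^2 + df$sigma_y^2)
  }
  attr(df, "pixel_nm") <- pixel_nm
  attr(df, "dialect") <- dialect
  class(df) <- c("loc_table", "data.frame")
  df
}

#' @export
print.loc_table <- function(x, ...) {
  cat(sprintf("<loc_table> %d localizations, channels: %s\n", nrow(x),
              paste(sort(unique(x$channel)), collapse = ", ")))
  if (nrow(x) > 0) {
    cat(sprintf("  x: [%.1f, %.1f] nm  y: [%.1f, %.1f] nm  frames: %d..%d\n",
                min(x$x), max(x$x), min(x$y), max(x$y),
                min(x$frame), max(x$frame)))
    if ("sigma" %in% names(x)) {
      cat(sprintf("  median precision sigma: %.2f nm\n",
                  stats::median(x$sigma, na.rm = TRUE)))
    }
  }
  invisible(x)
}

# column header maps per dialect; names are the canonical columns
.dialects <- list(
  generic_csv = c(x = "x_nm", y = "y_nm", z = "z_nm", photons = "photons",
                  frame = "frame", channel = "channel",
                  sigma_x = "sigma_x_nm", sigma_y = "sigma_y_nm"),
  thunderstorm_csv = c(x = "x [nm]", y = "y [nm]", z = "z [nm]",
                       photons = "intensity [photon]", frame = "frame",
                       channel = "channel",
                       sigma_x = "uncertainty_x [nm]",
                       sigma_y = "uncertainty_y [nm]")
)

#' Read a localization table from CSV
#'
#' Supports a generic dialect (columns `x_nm`, `y_nm`, `z_nm`, `photons`,
#' `frame`, `channel`, optional `sigma_x_nm`/`sigma_y_nm`) and a
#' ThunderSTORM-style dialect (`"x [nm]"`, `"y [nm]"`,
#' `"intensity [photon]"`, `"frame"`). All coordinates are taken to be nm.
#'
#' @param path CSV file path.
#' @param dialect `"generic_csv"` or `"thunderstorm_csv"`.
#' @param pixel_nm optional camera pixel size metadata.
#' @return a [loc_table()].
#' @export
read_localizations <- function(path, dialect = c("generic_csv", "thunderstorm_csv"),
                               pixel_nm = NA_real_) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  map <- .dialects[[dialect]]
  out <- list()
  for (canon in names(map)) {
    if (map[[canon]] %in% names(raw)) out[[canon]] <- raw[[map[[canon]]]]
  }
  for (col in c("x", "y", "photons", "frame")) {
    if (is.null(out[[col]])) {
      stop(sprintf("column '%s' (dialect name '%s') is missing from %s",
                   col, map[[col]], path), call. = FALSE)
    }
  }
  loc_table(as.data.frame(out, check.names = FALSE),
            pixel_nm = pixel_nm, dialect = dialect)
}

#' Write a localization table to CSV
#'
#' @param table a [loc_table()].
#' @param path output path.
#' @param dialect output dialect (see [read_localizations()]).
#' @return `path`, invisibly.
#' @export
write_localizations <- function(table, path,
                                dialect = c("generic_csv", "thunderstorm_csv")) {
  dialect <- match.arg(dialect)
  map <- .dialects[[dialect]]
  out <- list()
  for (canon in names(map)) {
    if (canon %in% names(table)) out[[map[[canon]]]] <- table[[canon]]
  }
  utils::write.csv(as.data.frame(out, check.names = FALSE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
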