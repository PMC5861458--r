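#' Helical filament geometry
#'
#' Geometry of the RAD51-type nucleoprotein helix: ~9 nm pitch, 6 monomers
#' per helical turn, each monomer engaging ~3 nt of ssDNA. Axial rise per
#' monomer is therefore pitch / monomers_per_turn = 1.5 nm.
#'
#' @param pitch_nm helical pitch in nm per turn (default 9).
#' @param monomers_per_turn monomers per helical turn (default 6).
#' @param nt_per_monomer nucleotides engaged per monomer (default 3).
#' @return object of class `helix_geometry`.
#' @export
helix_geometry <- function(pitch_nm = 9, monomers_per_turn = 6,
                           nt_per_monomer = 3) {
  stopifnot(pitch_nm > 0, monomers_per_turn > 0, nt_per_monomer > 0)
  structure(list(pitch_nm = pitch_nm, monomers_per_turn = monomers_per_turn,
                 nt_per_monomer = nt_per_monomer),
            class = "helix_geometry")
}

#' Convert filament length to expected monomer and nucleotide counts
#'
#' A filament of measured extension L covers L / pitch helical turns, hence
#' `L / pitch * monomers_per_turn` monomers and `nt_per_monomer` times as
#' many nucleotides. For a 200 nm filament with the default geometry this
#' gives 133.3 monomers (~130 to the nearest ten) engaging ~400 nt of ssDNA.
#'
#' @param length_nm filament length(s) in nm, >= 0. Vectorized.
#' @param geometry a [helix_geometry()].
#' @return data.frame with `length_nm`, `monomers_exact`,
#'   `monomers_nearest_ten`, `nucleotides`.
#' @export
helix_expectation <- function(length_nm, geometry = helix_geometry()) {
  if (any(length_nm < 0)) stop("length must be >= 0", call. = FALSE)
  monomers <- length_nm / geometry$pitch_nm * geometry$monomers_per_turn
  data.frame(length_nm = length_nm,
             monomers_exact = monomers,
             monomers_nearest_ten = round(monomers / 10) * 10,
             nucleotides = monomers * geometry$nt_per_monomer)
}
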