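#' Plasmid geometry
#'
#' A circular plasmid is described by its size in base pairs and its measured
#' intact contour length in nanometers. The nm-per-bp factor implied by the
#' two is used for unit conversion; it is taken from the measurement itself
#' rather than from the canonical B-DNA rise of 0.34 nm/bp, because deposited
#' DNA can calibrate differently.
#'
#' @param length_bp plasmid size in base pairs (positive integer).
#' @param length_nm intact contour length in nanometers (positive).
#' @return An object of class `plasmid_spec` with fields `length_bp`,
#'   `length_nm` and `nm_per_bp`.
#' @examples
#' p <- plasmid_spec(2686, 850)
#' p$nm_per_bp
#' @export
plasmid_spec <- function(length_bp, length_nm) {
  if (!is.numeric(length_bp) || length(length_bp) != 1L || !is.finite(length_bp) ||
      length_bp <= 0 || length_bp != round(length_bp)) {
    stop("`length_bp` must be a single positive integer", call. = FALSE)
  }
  if (!is.numeric(length_nm) || length(length_nm) != 1L || !is.finite(length_nm) ||
      length_nm <= 0) {
    stop("`length_nm` must be a single positive number", call. = FALSE)
  }
  structure(
    list(
      length_bp = as.integer(length_bp),
      length_nm = as.numeric(length_nm),
      nm_per_bp = length_nm / length_bp
    ),
    class = "plasmid_spec"
  )
}

#' The pUC19 cloning plasmid
#'
#' Default target used throughout: pUC19, 2686 bp, with a measured intact
#' contour length of 850 nm (implying about 0.3165 nm/bp).
#'
#' @return A [plasmid_spec()].
#' @export
pUC19 <- function() plasmid_spec(2686L, 850)

#' @export
print.plasmid_spec <- function(x, ...) {
  cat(sprintf("<plasmid_spec> %d bp, %.4g nm intact contour (%.4f nm/bp)\n",
              x$length_bp, x$length_nm, x$nm_per_bp))
  invisible(x)
}

#' Convert between base pairs and nanometers
#'
#' Linear scaling by the plasmid's own nm-per-bp factor (850/2686 for pUC19).
#'
#' @param bp,nm value to convert.
#' @param plasmid a [plasmid_spec()].
#' @return Converted value(s).
#' @examples
#' bp_to_nm(2686)           # 850
#' nm_to_bp(425)            # 1343
#' @export
bp_to_nm <- function(bp, plasmid = pUC19()) {
  stopifnot(inherits(plasmid, "plasmid_spec"))
  bp * plasmid$nm_per_bp
}

#' @rdname bp_to_nm
#' @export
nm_to_bp <- function(nm, plasmid = pUC19()) {
  stopifnot(inherits(plasmid, "plasmid_spec"))
  nm / plasmid$nm_per_bp
}
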