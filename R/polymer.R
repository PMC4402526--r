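#' DNA elasticity parameters
#'
#' Worm-like-chain parameters used to convert tether-length changes to
#' nucleotide counts. Defaults are standard literature values for
#' double-stranded DNA (persistence length 50 nm, stretch modulus 1200 pN,
#' rise 0.34 nm/bp) and single-stranded DNA (persistence length 0.75 nm,
#' contour 0.59 nm/nt) near physiological ionic strength; all are
#' configurable because buffer composition shifts them.
#'
#' @param ds_persistence dsDNA persistence length, nm.
#' @param ds_stretch_modulus dsDNA enthalpic stretch modulus, pN.
#' @param ds_rise dsDNA contour length per base pair, nm.
#' @param ss_persistence ssDNA persistence length, nm.
#' @param ss_contour_per_nt ssDNA contour length per nucleotide, nm.
#' @return an object of class \code{"polymer_params"}.
#' @export
polymer_params <- function(ds_persistence = 50, ds_stretch_modulus = 1200,
                           ds_rise = 0.34, ss_persistence = 0.75,
                           ss_contour_per_nt = 0.59) {
  x <- list(ds_persistence = ds_persistence,
            ds_stretch_modulus = ds_stretch_modulus,
            ds_rise = ds_rise,
            ss_persistence = ss_persistence,
            ss_contour_per_nt = ss_contour_per_nt)
  if (any(vapply(x, function(v) !is.numeric(v) || length(v) != 1L || v <= 0,
                 logical(1)))) {
    stop("all polymer parameters must be positive scalars", call. = FALSE)
  }
  if (ds_rise > ss_contour_per_nt) {
    stop("ds rise per bp cannot exceed ss contour per nt", call. = FALSE)
  }
  structure(x, class = "polymer_params")
}

#' Extension per nucleotide at a given load
#'
#' Average end-to-end distance per nucleotide of stretched DNA at force
#' \code{F}, from high-force worm-like-chain interpolations: for dsDNA the
#' extensible WLC
#' \deqn{x/L = 1 - \tfrac12\sqrt{k_BT/(F P)} + F/S,}
#' and for ssDNA the same inextensible form without the enthalpic term.
#' These interpolations are accurate above a few pN (amply so over the
#' force range where replication is measurable) and degrade at low force;
#' calls that would produce a non-positive extension are rejected.
#'
#' @param force load magnitude, pN (> 0; the interpolation is unreliable
#'   below ~0.1 pN). Vectorized.
#' @param strand \code{"ss"} or \code{"ds"}.
#' @param params a \code{\link{polymer_params}} object.
#' @param kBT thermal energy, pN nm.
#' @return extension per nucleotide (or base pair), nm.
#' @examples
#' extension_per_nt(10, "ss")   # ~0.37 nm/nt
#' extension_per_nt(10, "ds")   # ~0.33 nm/bp
#' @export
extension_per_nt <- function(force, strand = c("ss", "ds"),
                             params = polymer_params(), kBT = kbt()) {
  strand <- match.arg(strand)
  stopifnot(inherits(params, "polymer_params"))
  if (any(force <= 0)) stop("invalid load: force must be > 0 pN", call. = FALSE)
  out <- if (strand == "ss") {
    params$ss_contour_per_nt *
      (1 - 0.5 * sqrt(kBT / (force * params$ss_persistence)))
  } else {
    params$ds_rise *
      (1 - 0.5 * sqrt(kBT / (force * params$ds_persistence)) +
         force / params$ds_stretch_modulus)
  }
  if (any(out <= 0)) {
    stop("WLC interpolation gives non-positive extension at this force; ",
         "the high-force interpolation is unreliable here", call. = FALSE)
  }
  out
}

## Strand type whose spacing divides the distance signal for a given
## replication mode and pulling geometry. Under opposing load, primer
## extension consumes ssDNA template (ss spacing) while strand displacement
## shortens dsDNA (ds spacing); under aiding load the downstream dsDNA grows
## in both modes.
conversion_strand <- function(mode, geometry) {
  mode <- match.arg(mode, c("primer_extension", "strand_displacement"))
  geometry <- match.arg(geometry, c("opposing", "aiding"))
  if (geometry == "aiding") "ds" else if (mode == "primer_extension") "ss" else "ds"
}

#' Convert a tether-length trace to nucleotides incorporated
#'
#' Divides the observed distance change between the beads by the average
#' distance between single- or double-stranded nucleotides at the measured
#' load, per sample. Which spacing applies depends on the replication mode
#' and pulling geometry: under opposing load, primer extension shortens the
#' single-stranded template (ss spacing) and strand displacement shortens
#' duplex (ds spacing); under aiding load the downstream duplex lengthens in
#' both modes (ds spacing). Shortening under opposing load and lengthening
#' under aiding load both map to positive nucleotide counts.
#'
#' @param trace a \code{\link{replication_trace}} or any data frame with
#'   numeric columns \code{time}, \code{delta_x} (nm) and \code{force} (pN,
#'   signed, aiding positive; constant or per-sample).
#' @param mode \code{"primer_extension"} or \code{"strand_displacement"}.
#' @param geometry \code{"opposing"} or \code{"aiding"}; defaults to the
#'   sign of the trace's load.
#' @param params a \code{\link{polymer_params}} object.
#' @param kBT thermal energy, pN nm.
#' @return numeric vector of nucleotides incorporated at each sample.
#' @export
nucleotides_from_distance <- function(trace,
                                      mode = c("strand_displacement",
                                               "primer_extension"),
                                      geometry = NULL,
                                      params = polymer_params(),
                                      kBT = kbt()) {
  mode <- match.arg(mode)
  if (is.null(trace$delta_x) || is.null(trace$force)) {
    stop("trace must carry 'delta_x' and 'force' columns", call. = FALSE)
  }
  if (is.null(geometry)) {
    geometry <- if (mean(trace$force) < 0) "opposing" else "aiding"
  }
  strand <- conversion_strand(mode, geometry)
  spacing <- extension_per_nt(abs(trace$force), strand, params, kBT)
  sgn <- if (geometry == "opposing") -1 else 1
  sgn * trace$delta_x / spacing
}
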