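#' Rate constants of the Brownian-ratchet incorporation cycle
#'
#' Container for the kinetic parameters of the nucleotide-incorporation cycle
#' in which translocation is a reversible thermal step between the
#' pre-translocated and post-translocated states of the dNTP/PPi-free
#' polymerase-DNA complex, rectified by dNTP binding. Forward and backward
#' translocation rates carry Bell-type force dependence over characteristic
#' distances \code{d_T} (pre state to transition state) and \code{d_mT}
#' (transition state to post state).
#'
#' The defaults are the published best-fit values for the Phi29 DNA
#' polymerase replicating under load at 22 degrees C; see
#' \code{\link{phi29_rates}}.
#'
#' @param k_on dNTP binding rate, per uM per s.
#' @param k_off dNTP unbinding rate, per s. The default 0 reflects that the
#'   effective binding coefficient constrains only \code{k_on} when
#'   \code{k_off/k_cat} is negligible.
#' @param k_cat lumped condensation-plus-chemistry rate, per s (rate limiting
#'   at saturating dNTP).
#' @param k_ppi pyrophosphate release rate, per s. Treated as effectively
#'   instantaneous in the three-state cycle; kept for the explicit four-state
#'   variant of the steady-state solver.
#' @param k_T0 forward translocation rate at zero load, per s.
#' @param k_mT0 backward translocation rate at zero load, per s.
#' @param d_T distance from the pre-translocated state to the transition
#'   state, nm.
#' @param d_mT distance from the transition state to the post-translocated
#'   state, nm.
#' @return an object of class \code{"ratchet_rates"} (a named list).
#' @seealso \code{\link{coefficients_from_rates}}, \code{\link{occupancy}},
#'   \code{\link{translocation_landscape}}
#' @export
ratchet_rates <- function(k_on = 5, k_off = 0, k_cat = 120, k_ppi = 1e4,
                          k_T0 = 670, k_mT0 = 420, d_T = 0.35, d_mT = 0.05) {
  x <- list(k_on = k_on, k_off = k_off, k_cat = k_cat, k_ppi = k_ppi,
            k_T0 = k_T0, k_mT0 = k_mT0, d_T = d_T, d_mT = d_mT)
  for (nm in names(x)) {
    if (!is.numeric(x[[nm]]) || length(x[[nm]]) != 1L || !is.finite(x[[nm]])) {
      stop("'", nm, "' must be a finite scalar", call. = FALSE)
    }
  }
  if (k_on <= 0 || k_cat <= 0 || k_ppi <= 0 || k_T0 <= 0 || k_mT0 <= 0) {
    stop("rates k_on, k_cat, k_ppi, k_T0 and k_mT0 must be > 0", call. = FALSE)
  }
  if (k_off < 0) stop("'k_off' must be >= 0", call. = FALSE)
  if (d_T < 0 || d_mT < 0) stop("force distances must be >= 0", call. = FALSE)
  if (k_ppi < 10 * k_cat) {
    warning("k_ppi < 10 * k_cat: PPi release is assumed much faster than catalysis",
            call. = FALSE)
  }
  structure(x, class = "ratchet_rates")
}

#' @export
print.ratchet_rates <- function(x, ...) {
  cat("Brownian-ratchet cycle rates\n")
  cat(sprintf("  k_on  = %g /uM/s   k_off = %g /s   k_cat = %g /s   k_ppi = %g /s\n",
              x$k_on, x$k_off, x$k_cat, x$k_ppi))
  cat(sprintf("  k_T(0) = %g /s   k_-T(0) = %g /s   d_T = %g nm   d_-T = %g nm\n",
              x$k_T0, x$k_mT0, x$d_T, x$d_mT))
  invisible(x)
}

#' Rate constants for the dNTP-binding power-stroke cycle
#'
#' In this scheme (Model 1) translocation is driven directly by nucleotide
#' binding, so the binding and unbinding rates are the only force-dependent
#' rates of the cycle: \code{k_on(F) = k_on0 exp(F d_on / kBT)} and
#' \code{k_off(F) = k_off0 exp(-F d_off / kBT)} with aiding load positive.
#' A direct signature is that the saturating velocity equals \code{k_cat}
#' independently of load.
#'
#' @param k_on0 zero-load dNTP binding rate, per uM per s.
#' @param k_off0 zero-load dNTP unbinding rate, per s.
#' @param k_cat lumped catalytic rate, per s.
#' @param d_on,d_off force distances (nm) on binding and unbinding.
#' @return an object of class \code{"model1_rates"}.
#' @export
model1_rates <- function(k_on0 = 5, k_off0 = 0, k_cat = 120,
                         d_on = 0.35, d_off = 0) {
  if (k_on0 <= 0 || k_cat <= 0) stop("k_on0 and k_cat must be > 0", call. = FALSE)
  if (k_off0 < 0) stop("'k_off0' must be >= 0", call. = FALSE)
  if (d_on < 0 || d_off < 0) stop("force distances must be >= 0", call. = FALSE)
  structure(list(k_on0 = k_on0, k_off0 = k_off0, k_cat = k_cat,
                 d_on = d_on, d_off = d_off),
            class = "model1_rates")
}

#' Rate constants for the PPi-release power-stroke cycle
#'
#' In this scheme (Model 2) translocation is coupled to pyrophosphate
#' release, the only force-dependent step:
#' \code{k_ppi(F) = k_ppi0 exp(F d_ppi / kBT)}. Because PPi release is much
#' faster than the reverse of the rate-limiting step
#' (\code{k_mcat/k_ppi << 1}), the effective binding coefficient
#' \code{K_M/V_max} is then nearly force independent, which is the signature
#' used to discriminate this scheme from the ratchet.
#'
#' @param k_on dNTP binding rate, per uM per s.
#' @param k_off dNTP unbinding rate, per s.
#' @param k_cat lumped catalytic rate, per s.
#' @param k_mcat reverse of the rate-limiting step, per s.
#' @param k_ppi0 zero-load PPi release rate, per s.
#' @param d_ppi force distance on PPi release, nm.
#' @return an object of class \code{"model2_rates"}.
#' @export
model2_rates <- function(k_on = 5, k_off = 0, k_cat = 120, k_mcat = 10,
                         k_ppi0 = 1e4, d_ppi = 0.35) {
  if (k_on <= 0 || k_cat <= 0 || k_ppi0 <= 0) {
    stop("k_on, k_cat and k_ppi0 must be > 0", call. = FALSE)
  }
  if (k_off < 0 || k_mcat < 0) stop("k_off and k_mcat must be >= 0", call. = FALSE)
  if (d_ppi < 0) stop("'d_ppi' must be >= 0", call. = FALSE)
  structure(list(k_on = k_on, k_off = k_off, k_cat = k_cat, k_mcat = k_mcat,
                 k_ppi0 = k_ppi0, d_ppi = d_ppi),
            class = "model2_rates")
}

#' Coefficients of the force-decomposed Michaelis-Menten velocity
#'
#' The steady-state velocity of the incorporation cycle obeys
#' \deqn{1/v = a + b e^{-F d_b/k_BT} + (r + s e^{-F d_s/k_BT})/[dNTP],}
#' with aiding load positive. \code{a + b exp(.)} is \code{1/V_max(F)} and
#' \code{r + s exp(.)} is \code{K_M(F)/V_max(F) = 1/k_b(F)}, the inverse
#' effective dNTP-binding rate. Under the Brownian-ratchet cycle the
#' coefficients map onto rates as \code{a = 1/k_cat}, \code{b = 1/k_T(0)},
#' \code{r = (1 + k_off/k_cat)/k_on}, \code{s/r = k_-T(0)/k_T(0)},
#' \code{d_b = d_T} and \code{d_s = d_T + d_-T}.
#'
#' @param a,b force-independent and force-dependent parts of 1/V_max, s.
#' @param r,s force-independent and force-dependent parts of K_M/V_max,
#'   s (scaled by uM through division by the dNTP concentration).
#' @param d_b,d_s force distances of the two exponentials, nm.
#' @return an object of class \code{"mm_coefficients"} (named numeric vector).
#' @seealso \code{\link{phi29_coefficients}}, \code{\link{velocity_model3}},
#'   \code{\link{rates_from_coefficients}}
#' @export
mm_coefficients <- function(a, b, r, s, d_b, d_s) {
  x <- c(a = a, b = b, r = r, s = s, d_b = d_b, d_s = d_s)
  if (!is.numeric(x) || length(x) != 6L || any(!is.finite(x))) {
    stop("all six coefficients must be finite scalars", call. = FALSE)
  }
  if (a <= 0 || r <= 0) stop("'a' and 'r' must be > 0", call. = FALSE)
  if (b < 0 || s < 0) stop("'b' and 's' must be >= 0", call. = FALSE)
  if (d_b < 0 || d_s < 0) stop("force distances must be >= 0", call. = FALSE)
  structure(x, class = "mm_coefficients")
}

#' @export
print.mm_coefficients <- function(x, digits = 4, ...) {
  cat("Force-decomposed Michaelis-Menten coefficients\n")
  cat(sprintf("  a = %.*g s   b = %.*g s   d_b = %.*g nm\n",
              digits, x[["a"]], digits, x[["b"]], digits, x[["d_b"]]))
  cat(sprintf("  r = %.*g s   s = %.*g s   d_s = %.*g nm\n",
              digits, x[["r"]], digits, x[["s"]], digits, x[["d_s"]]))
  invisible(x)
}

#' Published Phi29 DNA polymerase parameters
#'
#' Best-fit values reported for single Phi29 DNA polymerase molecules
#' replicating double-stranded template under load at 22 degrees C:
#' coefficients a = 0.0084 s, b = 0.0015 s, r = 0.19 s, s = 0.12 s,
#' d_b = 0.35 nm, d_s = 0.40 nm, and the derived cycle rates k_on = 5 /uM/s,
#' k_cat = 120 /s, k_T(0) = 670 /s, k_-T(0) = 420 /s, d_T = 0.35 nm,
#' d_-T = 0.05 nm. These serve as defaults for simulation and as the ground
#' truth for parameter-recovery experiments.
#'
#' @return \code{phi29_coefficients()} an \code{\link{mm_coefficients}}
#'   object; \code{phi29_rates()} a \code{\link{ratchet_rates}} object.
#' @export
phi29_coefficients <- function() {
  mm_coefficients(a = 0.0084, b = 0.0015, r = 0.19, s = 0.12,
                  d_b = 0.35, d_s = 0.40)
}

#' @rdname phi29_coefficients
#' @export
phi29_rates <- function() ratchet_rates()

#' Map ratchet cycle rates to Michaelis-Menten coefficients and back
#'
#' Exact algebra of the three-state cycle (PPi release lumped as
#' instantaneous): \code{a = 1/k_cat}, \code{b = 1/k_T0},
#' \code{r = (1 + k_off/k_cat)/k_on}, \code{s = r k_mT0/k_T0},
#' \code{d_b = d_T}, \code{d_s = d_T + d_mT}. The inverse map recovers the
#' cycle rates from fitted coefficients; \code{k_off} is not identifiable
#' from the coefficients alone and enters through the ratio
#' \code{k_off_over_kcat} (0 by default), while \code{k_ppi} is passed
#' through unchanged.
#'
#' @param rates a \code{\link{ratchet_rates}} object.
#' @param coeffs an \code{\link{mm_coefficients}} object.
#' @param k_off_over_kcat assumed ratio k_off/k_cat (dimensionless).
#' @param k_ppi PPi release rate carried into the reconstructed rates, per s.
#' @return \code{coefficients_from_rates} returns \code{mm_coefficients};
#'   \code{rates_from_coefficients} returns \code{ratchet_rates}. The
#'   round trip is the identity to better than 1e-12 relative.
#' @examples
#' co <- coefficients_from_rates(phi29_rates())
#' rates_from_coefficients(co)
#' @export
coefficients_from_rates <- function(rates) {
  stopifnot(inherits(rates, "ratchet_rates"))
  r <- (1 + rates$k_off / rates$k_cat) / rates$k_on
  mm_coefficients(a = 1 / rates$k_cat,
                  b = 1 / rates$k_T0,
                  r = r,
                  s = r * rates$k_mT0 / rates$k_T0,
                  d_b = rates$d_T,
                  d_s = rates$d_T + rates$d_mT)
}

#' @rdname coefficients_from_rates
#' @export
rates_from_coefficients <- function(coeffs, k_off_over_kcat = 0, k_ppi = 1e4) {
  stopifnot(inherits(coeffs, "mm_coefficients"))
  if (coeffs[["d_s"]] < coeffs[["d_b"]] - 1e-9) {
    stop("d_s < d_b would imply a negative transition-to-post distance",
         call. = FALSE)
  }
  k_cat <- 1 / coeffs[["a"]]
  k_T0 <- 1 / coeffs[["b"]]
  ratchet_rates(k_on = (1 + k_off_over_kcat) / coeffs[["r"]],
                k_off = k_off_over_kcat * k_cat,
                k_cat = k_cat,
                k_ppi = k_ppi,
                k_T0 = k_T0,
                k_mT0 = k_T0 * coeffs[["s"]] / coeffs[["r"]],
                d_T = coeffs[["d_b"]],
                d_mT = max(coeffs[["d_s"]] - coeffs[["d_b"]], 0))
}

#' Serialize kinetic parameter sets to and from flat JSON
#'
#' Rates and coefficient containers are written as a single flat JSON object
#' carrying the documented field names plus a \code{"type"} discriminator,
#' with units as documented (s, /s, /uM/s, nm).
#'
#' @param x a \code{ratchet_rates}, \code{model1_rates}, \code{model2_rates}
#'   or \code{mm_coefficients} object.
#' @param path file to write to / read from.
#' @return \code{read_kinetic_json} returns the reconstructed object.
#' @export
write_kinetic_json <- function(x, path) {
  type <- intersect(class(x),
                    c("ratchet_rates", "model1_rates", "model2_rates",
                      "mm_coefficients"))
  if (length(type) != 1L) stop("unsupported object for kinetic JSON", call. = FALSE)
  obj <- c(list(type = type), as.list(unclass(x)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_kinetic_json
#' @export
read_kinetic_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  type <- obj$type
  obj$type <- NULL
  cons <- switch(type,
                 ratchet_rates = ratchet_rates,
                 model1_rates = model1_rates,
                 model2_rates = model2_rates,
                 mm_coefficients = mm_coefficients,
                 stop("unknown kinetic JSON type: ", type, call. = FALSE))
  do.call(cons, lapply(obj, as.numeric))
}
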