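#' Bell (Arrhenius-like) force dependence of a rate constant
#'
#' A rate whose transition state lies a distance \code{d} along the pulling
#' coordinate is modulated by load as
#' \deqn{k(F) = k(0)\, e^{F d / k_B T}.}
#' The sign convention throughout the package is that positive load aids
#' translocation and negative load hinders it; forward translocation uses
#' \code{d = +d_T} and backward translocation \code{d = -d_mT}, so hindering
#' load slows the forward hop and speeds the backward one.
#'
#' @param k0 zero-load rate, per s (> 0).
#' @param d signed characteristic distance, nm.
#' @param force applied load, pN (signed, aiding positive). Vectorized.
#' @param kBT thermal energy, pN nm.
#' @return rate(s) at the given load, per s.
#' @examples
#' bell_rate(670, 0.35, 0)          # zero load: unchanged
#' bell_rate(670, 0.35, -20)        # hindering load slows the forward hop
#' @export
bell_rate <- function(k0, d, force, kBT = kbt()) {
  if (!is.numeric(k0) || any(k0 <= 0)) stop("'k0' must be > 0", call. = FALSE)
  if (!is.numeric(kBT) || kBT <= 0) stop("'kBT' must be > 0", call. = FALSE)
  k0 * exp(force * d / kBT)
}

## 1/V_max(F) and K_M(F)/V_max(F) from the six coefficients (signed F,
## aiding positive, hence the negative exponent relative to an
## opposing-load-positive convention).
inv_vmax <- function(coeffs, force, kBT = kbt()) {
  coeffs[["a"]] + coeffs[["b"]] * exp(-force * coeffs[["d_b"]] / kBT)
}

inv_kb <- function(coeffs, force, kBT = kbt()) {
  coeffs[["r"]] + coeffs[["s"]] * exp(-force * coeffs[["d_s"]] / kBT)
}

#' Michaelis constant at a given load
#'
#' \code{K_M(F) = (K_M/V_max) * V_max = (r + s e^{-F d_s/kBT}) /
#' (a + b e^{-F d_b/kBT})}, in uM.
#'
#' @inheritParams velocity_model3
#' @return K_M in uM (vectorized over \code{force}).
#' @export
km_at_force <- function(force, coeffs = phi29_coefficients(), kBT = kbt()) {
  inv_kb(coeffs, force, kBT) / inv_vmax(coeffs, force, kBT)
}

#' Closed-form replication velocity of the Brownian-ratchet cycle
#'
#' Steady-state nucleotide-incorporation velocity of the three-state cycle
#' (pre-translocated free, post-translocated free, dNTP-bound) in which the
#' translocation step carries the entire force dependence:
#' \deqn{1/v = a + b e^{-F d_b/k_BT} + \left(r + s e^{-F d_s/k_BT}\right)/[dNTP].}
#' Velocity is strictly increasing in both load (aiding positive) and dNTP
#' concentration, and \code{v -> 1/(a + b e^{-F d_b/kBT}) = V_max(F)} at
#' saturating dNTP.
#'
#' @param force signed load, pN (aiding positive). Vectorized.
#' @param dntp dNTP concentration, uM (>= 0; 0 returns velocity 0).
#'   Vectorized (recycled against \code{force}).
#' @param coeffs an \code{\link{mm_coefficients}} object.
#' @param kBT thermal energy, pN nm.
#' @return velocity in nt/s.
#' @examples
#' velocity_model3(0, 500)     # ~95 nt/s at zero load, saturating dNTP
#' velocity_model3(-10, 500)   # hindering load slows replication
#' @export
velocity_model3 <- function(force, dntp, coeffs = phi29_coefficients(),
                            kBT = kbt()) {
  stopifnot(inherits(coeffs, "mm_coefficients"))
  if (any(dntp < 0)) stop("'dntp' must be >= 0", call. = FALSE)
  n <- max(length(force), length(dntp))
  force <- rep_len(force, n)
  dntp <- rep_len(dntp, n)
  v <- numeric(n)
  pos <- dntp > 0
  inv <- inv_vmax(coeffs, force[pos], kBT) + inv_kb(coeffs, force[pos], kBT) / dntp[pos]
  v[pos] <- 1 / inv
  v
}

#' Closed-form velocity of the dNTP-binding power-stroke cycle
#'
#' Model 1: translocation is driven by nucleotide binding, so only
#' \code{k_on(F)} and \code{k_off(F)} depend on load and
#' \deqn{1/v = 1/k_{cat} + \frac{1}{k_{on}(F)[dNTP]}
#'   \left(1 + k_{off}(F)/k_{cat}\right).}
#' The saturating velocity equals \code{k_cat} at every load, the signature
#' that rules this scheme out when \code{1/V_max} is observed to depend on
#' force.
#'
#' @param force signed load, pN (aiding positive). Vectorized.
#' @param dntp dNTP concentration, uM.
#' @param rates a \code{\link{model1_rates}} object.
#' @param kBT thermal energy, pN nm.
#' @return velocity in nt/s.
#' @export
velocity_model1 <- function(force, dntp, rates = model1_rates(), kBT = kbt()) {
  stopifnot(inherits(rates, "model1_rates"))
  if (any(dntp < 0)) stop("'dntp' must be >= 0", call. = FALSE)
  n <- max(length(force), length(dntp))
  force <- rep_len(force, n)
  dntp <- rep_len(dntp, n)
  v <- numeric(n)
  pos <- dntp > 0
  kon <- bell_rate(rates$k_on0, rates$d_on, force[pos], kBT)
  koff <- if (rates$k_off0 > 0) {
    bell_rate(rates$k_off0, -rates$d_off, force[pos], kBT)
  } else 0
  inv <- 1 / rates$k_cat + (1 + koff / rates$k_cat) / (kon * dntp[pos])
  v[pos] <- 1 / inv
  v
}

#' Closed-form velocity of the PPi-release power-stroke cycle
#'
#' Model 2: translocation is coupled to pyrophosphate release, the only
#' force-dependent rate, giving
#' \deqn{1/v = \frac{1}{k_{ppi}(F)} + \frac{1}{k_{cat}}
#'   \left(1 + \frac{k_{-cat}}{k_{ppi}(F)}\right) +
#'   \frac{1}{k_{on}[dNTP]}\left[1 + \frac{k_{off}}{k_{cat}}
#'   \left(1 + \frac{k_{-cat}}{k_{ppi}(F)}\right)\right].}
#' Because \code{k_mcat/k_ppi(F) << 1} over the experimental force range,
#' \code{K_M/V_max} is nearly force independent under this scheme.
#'
#' @param force signed load, pN (aiding positive). Vectorized.
#' @param dntp dNTP concentration, uM.
#' @param rates a \code{\link{model2_rates}} object.
#' @param kBT thermal energy, pN nm.
#' @return velocity in nt/s.
#' @export
velocity_model2 <- function(force, dntp, rates = model2_rates(), kBT = kbt()) {
  stopifnot(inherits(rates, "model2_rates"))
  if (any(dntp < 0)) stop("'dntp' must be >= 0", call. = FALSE)
  n <- max(length(force), length(dntp))
  force <- rep_len(force, n)
  dntp <- rep_len(dntp, n)
  v <- numeric(n)
  pos <- dntp > 0
  kppi <- bell_rate(rates$k_ppi0, rates$d_ppi, force[pos], kBT)
  rev_corr <- 1 + rates$k_mcat / kppi
  inv <- 1 / kppi + rev_corr / rates$k_cat +
    (1 + (rates$k_off / rates$k_cat) * rev_corr) / (rates$k_on * dntp[pos])
  v[pos] <- 1 / inv
  v
}

#' Steady state of a unicyclic kinetic scheme
#'
#' Solves the master equation of an N-state single-cycle scheme at steady
#' state by direct linear solve, returning the state occupancies and the net
#' cycle flux (completed cycles per second). This is the brute-force oracle
#' against which every closed-form velocity in the package can be checked,
#' and it expresses arbitrary variants of the incorporation cycle (e.g. the
#' four-state cycle with explicit PPi release).
#'
#' @param forward forward rates, per s; \code{forward[i]} is the rate from
#'   state i to state i+1 (state N wraps to state 1). Length N >= 2.
#' @param backward backward rates, per s; \code{backward[i]} is the rate
#'   from state i+1 (wrapping) back to state i. Same length as
#'   \code{forward}.
#' @return a list with \code{occupancy} (fractions summing to 1) and
#'   \code{velocity} (net flux around the cycle, cycles per second).
#' @examples
#' # three-state incorporation cycle at zero load, 500 uM dNTP
#' unicycle_steady_state(forward = c(670, 5 * 500, 120),
#'                       backward = c(420, 0, 0))
#' @export
unicycle_steady_state <- function(forward, backward) {
  n <- length(forward)
  if (n < 2L || length(backward) != n) {
    stop("need matching forward/backward rate vectors of length >= 2",
         call. = FALSE)
  }
  if (any(forward < 0) || any(backward < 0)) {
    stop("rates must be >= 0", call. = FALSE)
  }
  if (all(forward == 0)) {
    stop("degenerate cycle: at least one forward rate must be > 0",
         call. = FALSE)
  }
  nxt <- c(2:n, 1L)
  ## generator: A[i, j] = rate j -> i for i != j; columns sum to zero
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    A[nxt[i], i] <- A[nxt[i], i] + forward[i]
    A[i, nxt[i]] <- A[i, nxt[i]] + backward[i]
  }
  diag(A) <- diag(A) - colSums(A)
  ## replace last balance equation with normalization
  A[n, ] <- 1
  b <- c(rep(0, n - 1L), 1)
  p <- tryCatch(solve(A, b), error = function(e) {
    stop("degenerate cycle: singular steady-state system", call. = FALSE)
  })
  if (any(p < -1e-9)) stop("degenerate cycle: negative occupancy", call. = FALSE)
  p <- pmax(p, 0)
  p <- p / sum(p)
  list(occupancy = p, velocity = forward[1L] * p[1L] - backward[1L] * p[2L])
}

## forward/backward rate vectors of the three-state ratchet cycle
## states: 1 pre-translocated free, 2 post-translocated free, 3 dNTP-bound
ratchet_cycle_rates <- function(rates, force, dntp, kBT = kbt()) {
  list(forward = c(bell_rate(rates$k_T0, rates$d_T, force, kBT),
                   rates$k_on * dntp,
                   rates$k_cat),
       backward = c(bell_rate(rates$k_mT0, -rates$d_mT, force, kBT),
                    rates$k_off,
                    0))
}

#' State occupancies of the incorporation cycle
#'
#' Steady-state probabilities of the dNTP/PPi-free states (pre- and
#' post-translocated) and the dNTP-bound state at a given load and dNTP
#' concentration, from the unicyclic master-equation solver. Because the
#' bound state drains only through the catalytic step, the identity
#' \code{M_bound = v / k_cat} holds exactly when PPi release is lumped.
#'
#' @param rates a \code{\link{ratchet_rates}} object.
#' @param force signed load, pN (aiding positive).
#' @param dntp dNTP concentration, uM.
#' @param kBT thermal energy, pN nm.
#' @return a list of class \code{"occupancy_result"} with \code{M_free},
#'   \code{M_bound}, \code{per_state} (named fractions) and \code{velocity}
#'   (nt/s).
#' @examples
#' occupancy(phi29_rates(), force = 0, dntp = 500)
#' @export
occupancy <- function(rates, force, dntp, kBT = kbt()) {
  stopifnot(inherits(rates, "ratchet_rates"))
  cyc <- ratchet_cycle_rates(rates, force, dntp, kBT)
  ss <- unicycle_steady_state(cyc$forward, cyc$backward)
  p <- ss$occupancy
  names(p) <- c("pre_free", "post_free", "bound")
  structure(list(M_free = p[["pre_free"]] + p[["post_free"]],
                 M_bound = p[["bound"]],
                 per_state = p,
                 velocity = ss$velocity),
            class = "occupancy_result")
}

#' @export
print.occupancy_result <- function(x, ...) {
  cat(sprintf("Cycle occupancies: M_free = %.3f, M_bound = %.3f (v = %.3g nt/s)\n",
              x$M_free, x$M_bound, x$velocity))
  print(round(x$per_state, 4))
  invisible(x)
}

#' Free-energy landscape of the translocation step
#'
#' The translocation equilibrium constant at load F is
#' \code{K_delta(F) = k_T(F)/k_-T(F) = K_delta(0) e^{F delta / kBT}} with
#' \code{delta = d_T + d_mT} the pre-to-post equilibrium distance. The
#' free-energy change of translocation is \code{dG_trans = -ln K_delta} (in
#' kBT units; negative when the post state is favored), and opposing load
#' tilts the landscape by the work \code{-F delta} while raising the barrier
#' out of the pre state by \code{-F d_T}.
#'
#' @param rates a \code{\link{ratchet_rates}} object.
#' @param force signed load, pN (aiding positive).
#' @param kBT thermal energy, pN nm.
#' @return a list of class \code{"landscape_result"} with \code{delta} (nm),
#'   \code{K_delta}, \code{dG_trans} (kBT units) and \code{barrier_shift}
#'   (kBT units, \code{-F d_T / kBT}).
#' @examples
#' translocation_landscape(phi29_rates(), force = 0)   # dG ~ -0.46 kBT
#' @export
translocation_landscape <- function(rates, force = 0, kBT = kbt()) {
  stopifnot(inherits(rates, "ratchet_rates"))
  K <- bell_rate(rates$k_T0, rates$d_T, force, kBT) /
    bell_rate(rates$k_mT0, -rates$d_mT, force, kBT)
  structure(list(delta = rates$d_T + rates$d_mT,
                 K_delta = K,
                 dG_trans = -log(K),
                 barrier_shift = -force * rates$d_T / kBT),
            class = "landscape_result")
}

#' @export
print.landscape_result <- function(x, ...) {
  cat(sprintf(
    "Translocation landscape: delta = %.3g nm, K_delta = %.4g, dG_trans = %.4g kBT\n",
    x$delta, x$K_delta, x$dG_trans))
  cat(sprintf("  barrier shift at this load: %.4g kBT\n", x$barrier_shift))
  invisible(x)
}

#' Predicted detachment (rupture) load versus dNTP concentration
#'
#' Polymerase-DNA detachment is observed empirically once the replication
#' velocity drops to about 7 nt/s, independent of dNTP concentration. The
#' predicted rupture load is therefore the hindering load magnitude at which
#' the closed-form velocity falls to \code{v_detach}, found by bracketed
#' root solving on [0, 200] pN (the velocity is strictly monotone in load,
#' so the root is unique). If even the zero-load velocity is at or below
#' \code{v_detach} no root exists and \code{NA} is returned.
#'
#' @param coeffs an \code{\link{mm_coefficients}} object.
#' @param dntp dNTP concentration(s), uM. Vectorized.
#' @param v_detach detachment velocity criterion, nt/s.
#' @param kBT thermal energy, pN nm.
#' @return hindering load magnitude(s) in pN (\code{NA} where no root).
#' @examples
#' rupture_force(phi29_coefficients(), 500)   # ~50 pN at saturating dNTP
#' rupture_force(phi29_coefficients(), 2)     # below criterion: NA
#' @export
rupture_force <- function(coeffs = phi29_coefficients(), dntp, v_detach = 7,
                          kBT = kbt()) {
  stopifnot(inherits(coeffs, "mm_coefficients"))
  if (v_detach <= 0) stop("'v_detach' must be > 0", call. = FALSE)
  vapply(dntp, function(D) {
    if (D <= 0) return(NA_real_)
    if (velocity_model3(0, D, coeffs, kBT) <= v_detach) return(NA_real_)
    root <- stats::uniroot(
      function(f) velocity_model3(-f, D, coeffs, kBT) - v_detach,
      interval = c(0, 200), tol = 1e-6)
    root$root
  }, numeric(1))
}
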