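#' Replication trace container
#'
#' A uniformly sampled optical-tweezers replication record: time (s),
#' tether-length change (nm) and signed load (pN, aiding positive). Ground
#' truth known for synthetic traces (injected pause intervals, the
#' noise-free nucleotide series, a detachment flag) travels in attributes so
#' detectors can be scored against it.
#'
#' @param time sample times, s (strictly increasing, uniform to 1%).
#' @param delta_x tether-length change, nm.
#' @param force signed load, pN; scalar or per-sample.
#' @param pauses optional 2-column matrix of ground-truth pause intervals
#'   (start, end) in s.
#' @param detachment optional list describing a detachment event.
#' @param config optional generating \code{\link{sim_config}}.
#' @param nt_true optional noise-free nucleotide counts.
#' @return a data frame of class \code{"replication_trace"}.
#' @export
replication_trace <- function(time, delta_x, force, pauses = NULL,
                              detachment = NULL, config = NULL,
                              nt_true = NULL) {
  n <- length(time)
  if (length(delta_x) != n) stop("time and delta_x lengths differ", call. = FALSE)
  force <- rep_len(force, n)
  if (n >= 2L) {
    dt <- diff(time)
    if (any(dt <= 0)) stop("time must be strictly increasing", call. = FALSE)
    if (max(dt) - min(dt) > 0.01 * mean(dt)) {
      stop("sampling must be uniform to 1%", call. = FALSE)
    }
  }
  out <- data.frame(time = time, delta_x = delta_x, force = force)
  attr(out, "pauses") <- pauses
  attr(out, "detachment") <- detachment
  attr(out, "config") <- config
  attr(out, "nt_true") <- nt_true
  class(out) <- c("replication_trace", "data.frame")
  out
}

#' @export
print.replication_trace <- function(x, ...) {
  det <- attr(x, "detachment")
  cat(sprintf(
    "Replication trace: %d samples over %.2f s, load %.1f to %.1f pN\n",
    nrow(x), diff(range(x$time)), min(x$force), max(x$force)))
  np <- if (is.null(attr(x, "pauses"))) 0L else nrow(attr(x, "pauses"))
  cat(sprintf("  ground-truth pauses: %d; detachment: %s\n", np,
              if (!is.null(det) && isTRUE(det$detached)) {
                sprintf("yes at %.1f pN", det$force)
              } else "no"))
  invisible(x)
}

#' Simulation configuration
#'
#' Bundles everything needed to generate a synthetic replication trace with
#' the statistical structure of constant-force or force-ramp ("no feedback")
#' optical-tweezers measurements: the kinetic scheme, substrate
#' concentration, load schedule, template geometry (a 229-nt single-stranded
#' stretch followed by 3487 bp of duplex), 60 Hz Gaussian-noise sampling,
#' and load-independent off-pathway pauses entering as a Poisson process
#' with exponentially distributed durations.
#'
#' @param rates a \code{\link{ratchet_rates}} object.
#' @param dntp dNTP concentration, uM.
#' @param schedule load schedule: \code{constant_force(F)} or
#'   \code{force_ramp(stiffness, start)}.
#' @param mode replication mode; sets the template stretch replicated
#'   (229 nt for primer extension, 3487 bp for strand displacement) and the
#'   distance-to-nucleotide conversion.
#' @param template named vector with \code{ss_nt} and \code{ds_bp}.
#' @param sample_rate sampling frequency, Hz.
#' @param noise_sd per-sample Gaussian measurement noise, nm.
#' @param pause_entry_rate off-pathway pause entries, per s of active time.
#' @param pause_mean_duration mean pause duration, s.
#' @param v_detach detachment velocity criterion for ramp mode, nt/s.
#' @param seed integer seed; identical configurations (including seed)
#'   reproduce identical traces.
#' @param polymer a \code{\link{polymer_params}} object.
#' @param kBT thermal energy, pN nm.
#' @return an object of class \code{"sim_config"}.
#' @export
sim_config <- function(rates = phi29_rates(), dntp = 500,
                       schedule = constant_force(-10),
                       mode = c("strand_displacement", "primer_extension"),
                       template = c(ss_nt = 229, ds_bp = 3487),
                       sample_rate = 60, noise_sd = 2,
                       pause_entry_rate = 0.05, pause_mean_duration = 1,
                       v_detach = 7, seed = NULL,
                       polymer = polymer_params(), kBT = kbt()) {
  mode <- match.arg(mode)
  stopifnot(inherits(rates, "ratchet_rates"), inherits(polymer, "polymer_params"))
  if (sample_rate <= 0) stop("'sample_rate' must be > 0", call. = FALSE)
  if (noise_sd < 0) stop("'noise_sd' must be >= 0", call. = FALSE)
  if (pause_entry_rate < 0 || pause_mean_duration < 0) {
    stop("pause parameters must be >= 0", call. = FALSE)
  }
  if (dntp < 0) stop("'dntp' must be >= 0", call. = FALSE)
  if (!is.list(schedule) || is.null(schedule$type)) {
    stop("'schedule' must come from constant_force() or force_ramp()",
         call. = FALSE)
  }
  structure(list(rates = rates, dntp = dntp, schedule = schedule, mode = mode,
                 template = template, sample_rate = sample_rate,
                 noise_sd = noise_sd, pause_entry_rate = pause_entry_rate,
                 pause_mean_duration = pause_mean_duration,
                 v_detach = v_detach, seed = seed, polymer = polymer,
                 kBT = kBT),
            class = "sim_config")
}

#' @rdname sim_config
#' @param force constant signed load, pN.
#' @export
constant_force <- function(force) {
  list(type = "constant", force = force)
}

#' @rdname sim_config
#' @param stiffness trap stiffness, pN/nm; in ramp ("no feedback") mode the
#'   hindering load grows by stiffness times the accumulated tether
#'   shortening.
#' @param start starting load, pN (signed).
#' @export
force_ramp <- function(stiffness = 0.1, start = -3) {
  if (stiffness <= 0) stop("'stiffness' must be > 0", call. = FALSE)
  list(type = "ramp", stiffness = stiffness, force = start)
}

#' Gillespie simulation of the incorporation cycle
#'
#' Exact stochastic simulation of the three-state ratchet cycle
#' (pre-translocated free, post-translocated free, dNTP-bound) with
#' force-dependent translocation propensities. The mechanical position
#' advances by one nucleotide on each pre-to-post translocation and retreats
#' on the reverse hop, so position equals completed cycles plus one while
#' the enzyme sits past the translocation step; with no dNTP the position
#' rattles between 0 and 1 and the cycle never closes.
#'
#' @param rates a \code{\link{ratchet_rates}} object.
#' @param force signed load, pN (aiding positive).
#' @param dntp dNTP concentration, uM.
#' @param n_nucleotides stop after this many completed cycles (>= 1).
#' @param seed optional integer seed.
#' @param max_events safety cap on the number of simulated transitions.
#' @param kBT thermal energy, pN nm.
#' @return a list with \code{events} (data frame: \code{time}, \code{state}
#'   in \{pre_free, post_free, bound\}, \code{position}), \code{stalled}
#'   (TRUE if total propensity vanished before completion) and
#'   \code{completed} (cycles finished).
#' @export
simulate_cycle <- function(rates, force, dntp, n_nucleotides, seed = NULL,
                           max_events = NULL, kBT = kbt()) {
  stopifnot(inherits(rates, "ratchet_rates"))
  if (n_nucleotides < 1) stop("'n_nucleotides' must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(max_events)) max_events <- 200L * n_nucleotides + 10000L
  k_T <- bell_rate(rates$k_T0, rates$d_T, force, kBT)
  k_mT <- bell_rate(rates$k_mT0, -rates$d_mT, force, kBT)
  k_bind <- rates$k_on * dntp

  cap <- 4096L
  ev_time <- numeric(cap); ev_state <- integer(cap); ev_pos <- integer(cap)
  n_ev <- 0L
  push <- function(t, s, p) {
    n_ev <<- n_ev + 1L
    if (n_ev > cap) {
      cap <<- cap * 2L
      length(ev_time) <<- cap; length(ev_state) <<- cap; length(ev_pos) <<- cap
    }
    ev_time[n_ev] <<- t; ev_state[n_ev] <<- s; ev_pos[n_ev] <<- p
  }

  state <- 1L   # 1 pre_free, 2 post_free, 3 bound
  t <- 0; completed <- 0L; stalled <- FALSE
  push(0, state, 0L)
  while (completed < n_nucleotides && n_ev < max_events) {
    if (state == 1L) {
      props <- c(k_T, 0, 0)          # translocate forward
    } else if (state == 2L) {
      props <- c(0, k_mT, k_bind)    # back-translocate | bind dNTP
    } else {
      props <- c(rates$k_off, 0, rates$k_cat)  # unbind | catalyse
    }
    tot <- sum(props)
    if (tot <= 0) { stalled <- TRUE; break }
    t <- t + stats::rexp(1L, tot)
    which_ev <- sample.int(3L, 1L, prob = props)
    if (state == 1L) {
      state <- 2L
    } else if (state == 2L) {
      state <- if (which_ev == 2L) 1L else 3L
    } else {
      if (which_ev == 1L) {
        state <- 2L
      } else {
        state <- 1L
        completed <- completed + 1L
      }
    }
    push(t, state, completed + (state != 1L))
  }
  idx <- seq_len(n_ev)
  list(events = data.frame(
         time = ev_time[idx],
         state = c("pre_free", "post_free", "bound")[ev_state[idx]],
         position = ev_pos[idx]),
       stalled = stalled,
       completed = completed)
}

## Poisson pause process over an active-time span: returns matrix with
## active start times and durations
draw_pauses <- function(t_active_end, entry_rate, mean_duration) {
  if (entry_rate <= 0 || mean_duration <= 0 || t_active_end <= 0) {
    return(matrix(numeric(0), ncol = 2,
                  dimnames = list(NULL, c("start_active", "duration"))))
  }
  n <- stats::rpois(1L, entry_rate * t_active_end)
  if (n == 0L) {
    return(matrix(numeric(0), ncol = 2,
                  dimnames = list(NULL, c("start_active", "duration"))))
  }
  starts <- sort(stats::runif(n, 0, t_active_end))
  cbind(start_active = starts,
        duration = stats::rexp(n, 1 / mean_duration))
}

## Dilate active-time event times by inserting pauses; returns wall-clock
## event times and wall-clock pause intervals
insert_pauses <- function(t_active, pauses) {
  if (nrow(pauses) == 0L) {
    return(list(time = t_active,
                intervals = matrix(numeric(0), ncol = 2,
                                   dimnames = list(NULL, c("start", "end")))))
  }
  shift_before <- c(0, cumsum(pauses[, "duration"]))[seq_len(nrow(pauses))]
  wall_start <- pauses[, "start_active"] + shift_before
  wall_end <- wall_start + pauses[, "duration"]
  shift <- vapply(t_active, function(t) {
    sum(pauses[pauses[, "start_active"] < t, "duration"])
  }, numeric(1))
  list(time = t_active + shift,
       intervals = cbind(start = wall_start, end = wall_end))
}

#' Synthesize a noisy replication trace
#'
#' Runs the Gillespie cycle simulation under the configured load schedule,
#' injects off-pathway pauses by dilating the active-time event log,
#' samples the mechanical position at the instrument rate, converts
#' position to tether-length change through the worm-like-chain spacing
#' (shortening under opposing load, lengthening under aiding load) and adds
#' Gaussian measurement noise. In ramp mode the load is updated from the
#' trap stiffness and accumulated length change after every incorporation,
#' and the trace ends with a flagged detachment event when the smoothed
#' stepping velocity first drops below the detachment criterion.
#'
#' @param config a \code{\link{sim_config}}.
#' @return a \code{\link{replication_trace}} with ground-truth attributes
#'   (\code{pauses}, \code{nt_true}, \code{detachment}, \code{config}).
#' @examples
#' tr <- synthesize_trace(sim_config(dntp = 500, schedule = constant_force(-10),
#'                                   seed = 1))
#' print(tr)
#' @export
synthesize_trace <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n_nt <- if (config$mode == "primer_extension") {
    config$template[["ss_nt"]]
  } else {
    config$template[["ds_bp"]]
  }
  geometry <- if (config$schedule$force < 0) "opposing" else "aiding"
  strand <- conversion_strand(config$mode, geometry)
  sgn <- if (geometry == "opposing") -1 else 1

  if (config$schedule$type == "constant") {
    F0 <- config$schedule$force
    sim <- simulate_cycle(config$rates, F0, config$dntp, n_nt, seed = NULL,
                          kBT = config$kBT)
    pos_t <- sim$events$time
    pos <- sim$events$position
    spacing <- extension_per_nt(abs(F0), strand, config$polymer, config$kBT)
    dx_events <- sgn * pos * spacing
    force_events <- rep(F0, length(pos))
    detach <- list(detached = FALSE)
  } else {
    ramp <- ramp_gillespie(config, n_nt, strand, sgn)
    pos_t <- ramp$time; pos <- ramp$position
    dx_events <- ramp$delta_x; force_events <- ramp$force
    detach <- ramp$detachment
  }

  pl <- draw_pauses(max(pos_t), config$pause_entry_rate,
                    config$pause_mean_duration)
  dil <- insert_pauses(pos_t, pl)
  wall_t <- dil$time

  # sample past the final event so the last incorporation is captured
  n_samp <- ceiling(max(wall_t) * config$sample_rate) + 1L
  t_samp <- (seq_len(n_samp) - 1L) / config$sample_rate
  idx <- findInterval(t_samp, wall_t)
  idx[idx < 1L] <- 1L
  nt_true <- pos[idx]
  dx <- dx_events[idx]
  force_samp <- force_events[idx]
  noise <- if (config$noise_sd > 0) {
    stats::rnorm(length(t_samp), 0, config$noise_sd)
  } else 0

  if (isTRUE(detach$detached)) detach$time <- max(wall_t)
  replication_trace(time = t_samp, delta_x = dx + noise, force = force_samp,
                    pauses = dil$intervals, detachment = detach,
                    config = config, nt_true = nt_true)
}

## Gillespie with load updated after each event from trap stiffness x
## accumulated length change; stops on smoothed-velocity detachment
ramp_gillespie <- function(config, n_nt, strand, sgn) {
  rates <- config$rates
  kBT <- config$kBT
  stiff <- config$schedule$stiffness
  F0 <- config$schedule$force
  smooth_k <- 30L  # incorporations over which stepping velocity is smoothed

  cap <- 4096L
  ev_t <- numeric(cap); ev_pos <- integer(cap); ev_dx <- numeric(cap)
  ev_F <- numeric(cap); n_ev <- 0L
  push <- function(t, p, dx, f) {
    n_ev <<- n_ev + 1L
    if (n_ev > cap) {
      cap <<- cap * 2L
      length(ev_t) <<- cap; length(ev_pos) <<- cap
      length(ev_dx) <<- cap; length(ev_F) <<- cap
    }
    ev_t[n_ev] <<- t; ev_pos[n_ev] <<- p; ev_dx[n_ev] <<- dx; ev_F[n_ev] <<- f
  }

  state <- 1L; t <- 0; completed <- 0L
  Fcur <- F0
  dx <- 0
  inc_times <- numeric(n_nt)
  detach <- list(detached = FALSE)
  push(0, 0L, 0, Fcur)
  max_events <- 400L * n_nt + 10000L
  while (completed < n_nt && n_ev < max_events) {
    k_T <- bell_rate(rates$k_T0, rates$d_T, Fcur, kBT)
    k_mT <- bell_rate(rates$k_mT0, -rates$d_mT, Fcur, kBT)
    if (state == 1L) {
      props <- c(k_T, 0, 0)
    } else if (state == 2L) {
      props <- c(0, k_mT, rates$k_on * config$dntp)
    } else {
      props <- c(rates$k_off, 0, rates$k_cat)
    }
    tot <- sum(props)
    if (tot <= 0) break
    t <- t + stats::rexp(1L, tot)
    which_ev <- sample.int(3L, 1L, prob = props)
    if (state == 1L) state <- 2L
    else if (state == 2L) state <- if (which_ev == 2L) 1L else 3L
    else if (which_ev == 1L) state <- 2L
    else { state <- 1L; completed <- completed + 1L; inc_times[completed] <- t }

    pos <- completed + (state != 1L)
    spacing <- extension_per_nt(max(abs(Fcur), 0.5), strand, config$polymer, kBT)
    dx <- sgn * pos * spacing
    # no-feedback mode: load magnitude grows with accumulated length change
    Fcur <- F0 + (if (F0 < 0) -1 else 1) * stiff * abs(dx)
    push(t, pos, dx, Fcur)

    if (completed >= smooth_k) {
      v_smooth <- smooth_k / (t - inc_times[completed - smooth_k + 1L])
      if (v_smooth < config$v_detach) {
        detach <- list(detached = TRUE, force = Fcur, position = pos)
        break
      }
    }
  }
  idx <- seq_len(n_ev)
  list(time = ev_t[idx], position = ev_pos[idx], delta_x = ev_dx[idx],
       force = ev_F[idx], detachment = detach)
}

#' Force-velocity dataset container
#'
#' @param force signed load, pN.
#' @param dntp dNTP concentration, uM.
#' @param velocity mean pause-free velocity, nt/s.
#' @param sem standard error of the mean velocity, nt/s.
#' @param n number of replicates behind each record.
#' @return a data frame of class \code{"fv_dataset"}.
#' @export
fv_dataset <- function(force, dntp, velocity, sem, n = 1L) {
  out <- data.frame(force = force, dntp = dntp, velocity = velocity,
                    sem = sem, n = n)
  if (any(out$n > 1 & !(out$sem > 0))) {
    stop("records with n > 1 must carry sem > 0", call. = FALSE)
  }
  class(out) <- c("fv_dataset", "data.frame")
  out
}

#' Synthesize a force-velocity dataset
#'
#' Draws per-condition mean velocities around the Brownian-ratchet closed
#' form: each record is the mean of \code{n_replicates} Gaussian draws with
#' relative standard deviation \code{rel_noise}, and carries the replicate
#' SEM. With \code{rel_noise = 0} the dataset lies exactly on the closed
#' form.
#'
#' @param coeffs an \code{\link{mm_coefficients}} object (ground truth).
#' @param forces grid of signed loads, pN.
#' @param dntps grid of dNTP concentrations, uM.
#' @param rel_noise relative standard deviation of a single replicate.
#' @param n_replicates replicates per (force, dNTP) condition.
#' @param seed optional integer seed.
#' @param kBT thermal energy, pN nm.
#' @return an \code{\link{fv_dataset}}.
#' @examples
#' synthesize_fv_dataset(phi29_coefficients(), forces = c(-20, -10, 0),
#'                       dntps = c(10, 100, 500), rel_noise = 0.08, seed = 1)
#' @export
synthesize_fv_dataset <- function(coeffs = phi29_coefficients(),
                                  forces = seq(-30, 20, by = 5),
                                  dntps = c(5, 10, 50, 100, 200, 500),
                                  rel_noise = 0.08, n_replicates = 8,
                                  seed = NULL, kBT = kbt()) {
  stopifnot(inherits(coeffs, "mm_coefficients"))
  if (length(forces) == 0L || length(dntps) == 0L) {
    stop("empty force or dNTP grid", call. = FALSE)
  }
  if (rel_noise < 0) stop("'rel_noise' must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(force = forces, dntp = dntps)
  truth <- velocity_model3(grid$force, grid$dntp, coeffs, kBT)
  if (rel_noise == 0) {
    # exact records: no replicate scatter, so each row is a single value
    return(fv_dataset(grid$force, grid$dntp, truth, sem = 0, n = 1L))
  }
  draws <- matrix(stats::rnorm(nrow(grid) * n_replicates,
                               mean = rep(truth, n_replicates),
                               sd = rep(rel_noise * truth, n_replicates)),
                  nrow = nrow(grid))
  v <- rowMeans(draws)
  sem <- apply(draws, 1L, stats::sd) / sqrt(n_replicates)
  fv_dataset(grid$force, grid$dntp, v, sem, n = n_replicates)
}
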