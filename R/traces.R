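#' Sliding-window instantaneous velocity
#'
#' Centered least-squares slope of the nucleotide count over a sliding
#' window of \code{window_points} samples (50 points by default, matching
#' the windows used for 60 Hz tweezers records). The result has
#' \code{length(nt) - window_points + 1} elements; the attribute
#' \code{"centers"} gives the fractional sample index at each window
#' center, so center times are \code{(centers - 1) / sample_rate}.
#'
#' @param nt nucleotide-count series (uniformly sampled).
#' @param sample_rate sampling frequency, Hz.
#' @param window_points window length in samples (>= 2).
#' @return numeric vector of velocities, nt/s, with attribute
#'   \code{"centers"}.
#' @examples
#' nt <- 50 * (0:299) / 60                   # perfect 50 nt/s ramp
#' v <- instantaneous_velocity(nt, 60)
#' range(v)                                  # 50 everywhere
#' @export
instantaneous_velocity <- function(nt, sample_rate = 60, window_points = 50L) {
  n <- length(nt)
  w <- as.integer(window_points)
  if (w < 2L) stop("'window_points' must be >= 2", call. = FALSE)
  if (n <= w) {
    stop("insufficient data: series must be longer than the window",
         call. = FALSE)
  }
  dt <- 1 / sample_rate
  ## rolling sums via cumsum: slope_j = 12/(w(w^2-1) dt) * sum (k - kbar) y
  cs <- c(0, cumsum(nt))
  csk <- c(0, cumsum(seq_len(n) * nt))
  j <- seq_len(n - w + 1L)
  A <- cs[j + w] - cs[j]              # sum of y over window starting at j
  B <- csk[j + w] - csk[j]            # sum of i*y
  kbar <- j + (w - 1) / 2             # mean sample index in window
  slope <- (B - kbar * A) * 12 / (w * (w^2 - 1) * dt)
  attr(slope, "centers") <- kbar
  slope
}

#' Velocity histogram with two-Gaussian mixture fit
#'
#' Histograms instantaneous velocities in 5 nt/s bins and fits a
#' two-component Gaussian to the counts by nonlinear least squares, one
#' component initialized at zero (the paused state) and one at the robust
#' positive mode (the active state). Component weights are relative areas.
#' If the two-component fit cannot converge, or the data show no positive
#' mode, a single-component fit is returned and flagged.
#'
#' @param v instantaneous velocities, nt/s.
#' @param bin_width histogram bin width, nt/s.
#' @return an object of class \code{"velocity_distribution"}: list with
#'   \code{bin_centers}, \code{counts}, \code{components} (data frame with
#'   \code{mean}, \code{sd}, \code{weight}, \code{amplitude}),
#'   \code{converged} and \code{fallback}.
#' @export
velocity_distribution <- function(v, bin_width = 5) {
  v <- v[is.finite(v)]
  if (length(v) < 10L) stop("too few velocity samples", call. = FALSE)
  lo <- floor(min(v) / bin_width) * bin_width
  hi <- ceiling(max(v) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo - bin_width / 2, hi + bin_width / 2, by = bin_width)
  h <- graphics::hist(v, breaks = breaks, plot = FALSE)
  x <- h$mids
  y <- h$counts

  ## robust positive mode: largest bin clearly away from zero
  pos <- which(x > 2 * bin_width)
  has_pos_mode <- length(pos) > 0 && max(y[pos]) >= max(3, 0.02 * max(y))
  has_zero_mass <- any(y[abs(x) <= 2 * bin_width] > 0)
  fit <- NULL
  if (has_pos_mode && !has_zero_mass) {
    ## fully active trace: a single positive component carries all weight
    m2_0 <- x[pos[which.max(y[pos])]]
    single <- tryCatch(
      minpack.lm::nlsLM(y ~ A2 * exp(-(x - m2)^2 / (2 * s2^2)),
                        start = list(A2 = max(y), m2 = m2_0, s2 = 2 * bin_width),
                        lower = c(0, bin_width, bin_width / 4),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    p <- if (!is.null(single)) stats::coef(single) else
      c(A2 = max(y), m2 = m2_0, s2 = 2 * bin_width)
    comp <- data.frame(mean = c(NA, p[["m2"]]), sd = c(NA, abs(p[["s2"]])),
                       weight = c(0, 1), amplitude = c(NA, p[["A2"]]),
                       row.names = c("zero", "positive"))
    out <- list(bin_centers = x, counts = y, components = comp,
                converged = !is.null(single), fallback = FALSE, fit = single)
    class(out) <- "velocity_distribution"
    return(out)
  }
  if (has_pos_mode) {
    m2_0 <- x[pos[which.max(y[pos])]]
    start <- list(A1 = max(y[x <= 2 * bin_width], 1), m1 = 0, s1 = bin_width,
                  A2 = max(y[pos]), m2 = m2_0, s2 = 2 * bin_width)
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ A1 * exp(-(x - m1)^2 / (2 * s1^2)) +
          A2 * exp(-(x - m2)^2 / (2 * s2^2)),
        start = start,
        lower = c(A1 = 0, m1 = -3 * bin_width, s1 = bin_width / 4,
                  A2 = 0, m2 = bin_width, s2 = bin_width / 4),
        upper = c(A1 = Inf, m1 = 3 * bin_width, s1 = Inf,
                  A2 = Inf, m2 = max(x) + bin_width, s2 = Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  }

  if (!is.null(fit)) {
    p <- stats::coef(fit)
    area <- c(p[["A1"]] * abs(p[["s1"]]), p[["A2"]] * abs(p[["s2"]]))
    comp <- data.frame(mean = c(p[["m1"]], p[["m2"]]),
                       sd = abs(c(p[["s1"]], p[["s2"]])),
                       weight = area / sum(area),
                       amplitude = c(p[["A1"]], p[["A2"]]),
                       row.names = c("zero", "positive"))
    out <- list(bin_centers = x, counts = y, components = comp,
                converged = TRUE, fallback = FALSE, fit = fit)
  } else {
    ## single-Gaussian fallback around the global mode
    m0 <- x[which.max(y)]
    single <- tryCatch(
      minpack.lm::nlsLM(y ~ A1 * exp(-(x - m1)^2 / (2 * s1^2)),
                        start = list(A1 = max(y), m1 = m0, s1 = bin_width),
                        lower = c(0, min(x), bin_width / 4),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    comp <- if (!is.null(single)) {
      p <- stats::coef(single)
      data.frame(mean = c(p[["m1"]], NA), sd = c(abs(p[["s1"]]), NA),
                 weight = c(1, 0), amplitude = c(p[["A1"]], NA),
                 row.names = c("zero", "positive"))
    } else {
      data.frame(mean = c(mean(v), NA), sd = c(stats::sd(v), NA),
                 weight = c(1, 0), amplitude = c(max(y), NA),
                 row.names = c("zero", "positive"))
    }
    out <- list(bin_centers = x, counts = y, components = comp,
                converged = !is.null(single), fallback = TRUE, fit = single)
  }
  class(out) <- "velocity_distribution"
  out
}

#' @export
print.velocity_distribution <- function(x, ...) {
  cat("Instantaneous-velocity distribution\n")
  if (x$fallback) cat("  (two-component fit unavailable; single-component fallback)\n")
  print(round(x$components, 3))
  invisible(x)
}

#' Detect off-pathway pauses in a nucleotide series
#'
#' Flags maximal runs where the magnitude of the sliding-window
#' instantaneous velocity stays below a threshold for at least
#' \code{min_duration} seconds. By default the threshold is the midpoint
#' between the two component means of the fitted velocity mixture; if that
#' fit is unavailable an explicit threshold must be supplied. Also returns
#' the average rates with pauses included (plain line fit) and with pause
#' intervals excised (line fit over concatenated active segments).
#'
#' @param nt nucleotide-count series.
#' @param sample_rate sampling frequency, Hz.
#' @param min_duration minimum pause duration, s (0.4-0.8 s is the usable
#'   resolution at 60 Hz with 50-point windows).
#' @param v_threshold velocity threshold, nt/s; \code{NULL} derives it from
#'   the mixture fit.
#' @param window_points sliding window length for the velocity estimate.
#' @return an object of class \code{"pause_set"}: list with
#'   \code{intervals} (2-column matrix of start/end times, s),
#'   \code{density} (pauses per 100 nt), \code{with_pauses_rate},
#'   \code{without_pauses_rate} (nt/s) and \code{threshold}.
#' @export
detect_pauses <- function(nt, sample_rate = 60, min_duration = 0.4,
                          v_threshold = NULL, window_points = 50L) {
  v <- instantaneous_velocity(nt, sample_rate, window_points)
  centers <- attr(v, "centers")
  t_centers <- (centers - 1) / sample_rate
  if (is.null(v_threshold)) {
    dist <- velocity_distribution(v)
    cm <- dist$components
    if (dist$fallback || is.na(cm["positive", "mean"])) {
      stop("velocity mixture fit failed; supply 'v_threshold' explicitly",
           call. = FALSE)
    }
    # midpoint of the two component means; a fully active trace has no zero
    # component, in which case the paused state is taken to sit at 0
    zero_mean <- if (is.na(cm["zero", "mean"])) 0 else cm["zero", "mean"]
    v_threshold <- (zero_mean + cm["positive", "mean"]) / 2
  }
  below <- abs(v) < v_threshold
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & (r$lengths >= min_duration * sample_rate)
  intervals <- cbind(start = t_centers[starts[keep]],
                     end = t_centers[ends[keep]])

  time <- (seq_along(nt) - 1) / sample_rate
  with_rate <- unname(stats::coef(stats::lm(nt ~ time))[2L])
  without_rate <- excised_rate(nt, time, intervals)
  total_nt <- max(nt) - min(nt)
  density <- if (total_nt > 0) 100 * nrow(intervals) / total_nt else NA_real_
  structure(list(intervals = intervals, density = density,
                 with_pauses_rate = with_rate,
                 without_pauses_rate = without_rate,
                 threshold = v_threshold, min_duration = min_duration),
            class = "pause_set")
}

## slope over pause-excised, time-stitched data
excised_rate <- function(nt, time, intervals) {
  if (is.null(intervals) || nrow(intervals) == 0L) {
    return(unname(stats::coef(stats::lm(nt ~ time))[2L]))
  }
  in_pause <- rep(FALSE, length(time))
  excised_before <- numeric(length(time))
  for (i in seq_len(nrow(intervals))) {
    in_pause <- in_pause | (time >= intervals[i, 1L] & time <= intervals[i, 2L])
    dur <- intervals[i, 2L] - intervals[i, 1L]
    excised_before <- excised_before + dur * (time > intervals[i, 2L])
  }
  act <- !in_pause
  if (sum(act) < 2L) stop("undefined rate: no active samples remain", call. = FALSE)
  t_st <- time[act] - excised_before[act]
  unname(stats::coef(stats::lm(nt[act] ~ t_st))[2L])
}

#' @export
print.pause_set <- function(x, ...) {
  cat(sprintf("Pause set: %d pauses (threshold %.1f nt/s, min %.2f s)\n",
              nrow(x$intervals), x$threshold, x$min_duration))
  cat(sprintf("  rate with pauses %.2f nt/s, without pauses %.2f nt/s; %.2f pauses/100 nt\n",
              x$with_pauses_rate, x$without_pauses_rate, x$density))
  invisible(x)
}

#' Average replication rate of a trace
#'
#' Least-squares slope of the nucleotide count versus time; with a
#' \code{\link{detect_pauses}} result supplied, pause intervals are excised
#' and the remaining active segments are stitched before the fit, giving
#' the pause-free rate.
#'
#' @param nt nucleotide-count series.
#' @param sample_rate sampling frequency, Hz.
#' @param exclude optional \code{pause_set} whose intervals are excised.
#' @return rate in nt/s.
#' @export
average_rate <- function(nt, sample_rate = 60, exclude = NULL) {
  if (length(nt) < 2L) stop("undefined rate: need at least 2 samples", call. = FALSE)
  time <- (seq_along(nt) - 1) / sample_rate
  if (is.null(exclude)) {
    return(unname(stats::coef(stats::lm(nt ~ time))[2L]))
  }
  stopifnot(inherits(exclude, "pause_set"))
  excised_rate(nt, time, exclude$intervals)
}

#' Full analysis of one replication trace
#'
#' Converts a trace to nucleotides, computes instantaneous velocities, the
#' velocity-distribution mixture, pauses and average rates. This is the
#' per-trace pipeline behind \code{\link{cmd_analyze}}.
#'
#' @param trace a \code{\link{replication_trace}}.
#' @param mode replication mode for the distance conversion.
#' @param params a \code{\link{polymer_params}}.
#' @param window_points sliding-window length.
#' @param min_duration minimum pause duration, s.
#' @param kBT thermal energy, pN nm.
#' @return a list of class \code{"trace_report"} with elements \code{nt},
#'   \code{velocity}, \code{distribution}, \code{pauses} and \code{rates}.
#' @export
analyze_trace <- function(trace, mode = c("strand_displacement",
                                          "primer_extension"),
                          params = polymer_params(), window_points = 50L,
                          min_duration = 0.4, kBT = kbt()) {
  mode <- match.arg(mode)
  sample_rate <- 1 / mean(diff(trace$time))
  nt <- nucleotides_from_distance(trace, mode = mode, params = params, kBT = kBT)
  v <- instantaneous_velocity(nt, sample_rate, window_points)
  dist <- velocity_distribution(v)
  pauses <- tryCatch(
    detect_pauses(nt, sample_rate, min_duration = min_duration,
                  window_points = window_points),
    error = function(e) NULL)
  rates <- list(
    with_pauses = average_rate(nt, sample_rate),
    without_pauses = if (!is.null(pauses)) pauses$without_pauses_rate else NA_real_)
  structure(list(nt = nt, velocity = v, distribution = dist, pauses = pauses,
                 rates = rates, sample_rate = sample_rate,
                 force = stats::median(trace$force)),
            class = "trace_report")
}

#' @export
print.trace_report <- function(x, ...) {
  cat(sprintf("Trace report (median load %.1f pN)\n", x$force))
  cat(sprintf("  rate with pauses %.2f nt/s, without %.2f nt/s\n",
              x$rates$with_pauses, x$rates$without_pauses))
  if (!is.null(x$pauses)) {
    cat(sprintf("  pauses: %d\n", nrow(x$pauses$intervals)))
  }
  print(x$distribution)
  invisible(x)
}

#' Pool per-trace rates into force bins
#'
#' Averages trace rates over all traces at similar load values (within
#' \code{half_width} pN), the pooling rule used to build force-velocity
#' records from constant-force measurements.
#'
#' @param forces per-trace loads, pN.
#' @param rates per-trace rates, nt/s.
#' @param centers bin centers, pN; defaults to multiples of
#'   \code{2 * half_width} spanning the data.
#' @param half_width pooling half-width, pN.
#' @return data frame with \code{force}, \code{velocity}, \code{sem},
#'   \code{n}.
#' @export
pool_rates_by_force <- function(forces, rates, centers = NULL,
                                half_width = 2.5) {
  if (is.null(centers)) {
    step <- 2 * half_width
    centers <- seq(floor(min(forces) / step) * step,
                   ceiling(max(forces) / step) * step, by = step)
  }
  rows <- lapply(centers, function(cc) {
    sel <- abs(forces - cc) <= half_width
    if (!any(sel)) return(NULL)
    r <- rates[sel]
    data.frame(force = cc, velocity = mean(r),
               sem = if (length(r) > 1) stats::sd(r) / sqrt(length(r)) else NA_real_,
               n = length(r))
  })
  do.call(rbind, rows)
}
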