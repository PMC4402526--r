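#' Michaelis-Menten fit at a single load
#'
#' Weighted (1/SEM^2) nonlinear least-squares fit of
#' \code{v = V_max [dNTP]/(K_M + [dNTP])} to the records of a
#' force-velocity dataset at one load, with standard errors from the fit
#' covariance.
#'
#' @param data an \code{\link{fv_dataset}} (or compatible data frame).
#' @param force the load to restrict to, pN; \code{NULL} if \code{data} is
#'   already a single-force slice.
#' @param tol force-matching tolerance, pN.
#' @return a list of class \code{"mm_fit"}: \code{force}, \code{vmax},
#'   \code{km}, \code{se_vmax}, \code{se_km}, \code{converged}.
#' @examples
#' d <- synthesize_fv_dataset(rel_noise = 0, forces = 0,
#'                            dntps = c(5, 10, 50, 100, 200, 500))
#' fit_mm_at_force(d)   # V_max ~ 101 nt/s, K_M ~ 31 uM at zero load
#' @export
fit_mm_at_force <- function(data, force = NULL, tol = 1e-6) {
  if (!is.null(force)) data <- data[abs(data$force - force) <= tol, ]
  if (length(unique(data$dntp)) < 3L) {
    stop("need at least 3 dNTP levels at this force", call. = FALSE)
  }
  F0 <- stats::median(data$force)
  w <- mm_weights(data)
  vmax0 <- max(data$velocity) * 1.1
  km0 <- max(min(data$dntp[data$velocity >= vmax0 / 2], max(data$dntp)), 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(velocity ~ Vmax * dntp / (Km + dntp),
                      data = as.data.frame(data),
                      start = list(Vmax = vmax0, Km = km0),
                      weights = w,
                      lower = c(1e-6, 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(force = F0, vmax = NA_real_, km = NA_real_,
                          se_vmax = NA_real_, se_km = NA_real_,
                          converged = FALSE),
                     class = "mm_fit"))
  }
  p <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) c(NA, NA))
  structure(list(force = F0, vmax = p[["Vmax"]], km = p[["Km"]],
                 se_vmax = se[[1L]], se_km = se[[2L]], converged = TRUE,
                 fit = fit),
            class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("MM fit at %.1f pN: V_max = %.2f +/- %.2f nt/s, K_M = %.2f +/- %.2f uM\n",
              x$force, x$vmax, x$se_vmax, x$km, x$se_km))
  invisible(x)
}

## 1/sem^2 weights, falling back to unit weights when SEMs are absent
mm_weights <- function(data) {
  if (is.null(data$sem) || any(!is.finite(data$sem)) || any(data$sem <= 0)) {
    rep(1, nrow(data))
  } else {
    1 / data$sem^2
  }
}

## ---- parameterization of the three coupling schemes --------------------
## All three are constrained cases of
##   1/v = a + b e^{-F d_b/kBT} + (r + s e^{-F d_s/kBT}) / D
## model 1 (binding power stroke, k_off = 0): b = 0, r = 0      -> (a, s, d_s)
## model 2 (PPi-release power stroke, k_off = 0): s = 0          -> (a, b, d_b, r)
## model 3 (Brownian ratchet): all six free
model_par_names <- function(model) {
  switch(as.character(model),
         "1" = c("log_a", "log_s", "d_s"),
         "2" = c("log_a", "log_b", "d_b", "log_r"),
         "3" = c("log_a", "log_b", "log_r", "log_s", "d_b", "d_s"),
         stop("'model' must be 1, 2 or 3", call. = FALSE))
}

theta_to_coef <- function(theta, model) {
  co <- c(a = 0, b = 0, r = 0, s = 0, d_b = 0, d_s = 0)
  if (model == 1L) {
    co[c("a", "s", "d_s")] <- c(exp(theta[1:2]), theta[3L])
    co["r"] <- 1e-12   # keep the container's positivity invariant
  } else if (model == 2L) {
    co[c("a", "b", "d_b", "r")] <- c(exp(theta[1:2]), theta[3L], exp(theta[4L]))
  } else {
    co[c("a", "b", "r", "s")] <- exp(theta[1:4])
    co[c("d_b", "d_s")] <- theta[5:6]
  }
  co
}

predict_inv_v <- function(co, force, dntp, kBT) {
  co[["a"]] + co[["b"]] * exp(-force * co[["d_b"]] / kBT) +
    (co[["r"]] + co[["s"]] * exp(-force * co[["d_s"]] / kBT)) / dntp
}

## heuristic starting point in theta space
start_theta <- function(data, model, kBT) {
  vmax_guess <- max(data$velocity)
  a0 <- 0.8 / vmax_guess
  b0 <- 0.2 / vmax_guess
  ## crude K_M/V_max from low-concentration records at mild load
  mild <- data[abs(data$force) <= stats::quantile(abs(data$force), 0.5), ]
  r0 <- tryCatch({
    lowd <- mild[mild$dntp <= stats::median(mild$dntp), ]
    est <- stats::median((1 / lowd$velocity - a0 - b0) * lowd$dntp)
    max(est / 2, 1e-3)
  }, error = function(e) 0.1)
  switch(as.character(model),
         "1" = c(log(a0 + b0), log(2 * r0), 0.4),
         "2" = c(log(a0), log(b0), 0.4, log(2 * r0)),
         "3" = c(log(a0), log(b0), log(r0), log(r0 * 0.6), 0.35, 0.4))
}

fit_once <- function(theta0, data, model, w, kBT) {
  lower <- rep(-Inf, length(theta0))
  upper <- rep(Inf, length(theta0))
  d_idx <- grep("^d_", model_par_names(model))
  lower[d_idx] <- 0
  upper[d_idx] <- 2
  resfun <- function(theta) {
    co <- theta_to_coef(theta, model)
    sqrt(w) * (1 / predict_inv_v(co, data$force, data$dntp, kBT) - data$velocity)
  }
  out <- tryCatch(
    minpack.lm::nls.lm(par = theta0, fn = resfun, lower = lower, upper = upper,
                       control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL)
  if (is.null(out)) return(NULL)
  list(theta = out$par, rss = sum(out$fvec^2), info = out$info,
       hessian = out$hessian)
}

#' Global fit of force-velocity data to a translocation-coupling model
#'
#' Fits all (load, dNTP) records simultaneously by weighted (1/SEM^2)
#' nonlinear least squares to the force-decomposed Michaelis-Menten
#' velocity of the chosen coupling scheme: the dNTP-binding power stroke
#' (\code{model = 1}), the PPi-release power stroke (\code{model = 2}) or
#' the Brownian ratchet (\code{model = 3}); the first two are the
#' force-flat-\code{1/V_max} and force-flat-\code{K_M/V_max} constrained
#' cases of the full six-coefficient family. Positive coefficients are
#' fitted in log space and force distances on [0, 2] nm; Levenberg-
#' Marquardt is restarted from \code{n_starts} perturbed initializations
#' and the best solution kept, which guards against the coefficient
#' exchange degeneracy at weak force dependence. Uncertainties come from
#' the fit covariance and, if \code{n_boot > 0}, from seeded case-resampled
#' bootstrap. For the ratchet, cycle rates and the translocation landscape
#' are derived from the coefficients through their exact algebraic
#' relations.
#'
#' @param data an \code{\link{fv_dataset}} (or data frame with
#'   \code{force}, \code{dntp}, \code{velocity} and optionally \code{sem}).
#'   Needs at least 2 dNTP levels and 3 loads.
#' @param model 1, 2 or 3.
#' @param weights \code{"sem"} for 1/SEM^2 weighting (default) or
#'   \code{"none"}.
#' @param n_starts number of multi-start initializations.
#' @param n_boot bootstrap replicates for confidence intervals (0 = none).
#' @param seed integer seed for the multi-start jitter and bootstrap.
#' @param kBT thermal energy, pN nm.
#' @return an object of class \code{"ratchet_fit"}; see
#'   \code{\link{summary.ratchet_fit}}, \code{\link{predict.ratchet_fit}}.
#' @examples
#' d <- synthesize_fv_dataset(rel_noise = 0)
#' fit <- ratchet_fit(d, model = 3)
#' coef(fit)
#' @export
ratchet_fit <- function(data, model = 3, weights = c("sem", "none"),
                        n_starts = 10, n_boot = 0, seed = NULL, kBT = kbt()) {
  weights <- match.arg(weights)
  model <- as.integer(model)
  req <- c("force", "dntp", "velocity")
  if (!all(req %in% names(data))) {
    stop("data must carry columns force, dntp, velocity", call. = FALSE)
  }
  data <- as.data.frame(data)
  if (length(unique(data$dntp)) < 2L || length(unique(data$force)) < 3L) {
    stop("unidentifiable design: need >= 2 dNTP levels and >= 3 forces",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  w <- if (weights == "sem") mm_weights(data) else rep(1, nrow(data))

  theta0 <- start_theta(data, model, kBT)
  k <- length(theta0)
  best <- fit_once(theta0, data, model, w, kBT)
  tries <- 1L
  for (i in seq_len(max(n_starts - 1L, 0L))) {
    jit <- theta0
    log_idx <- grep("^log_", model_par_names(model))
    d_idx <- grep("^d_", model_par_names(model))
    jit[log_idx] <- jit[log_idx] + stats::rnorm(length(log_idx), 0, 1)
    jit[d_idx] <- stats::runif(length(d_idx), 0, 1)
    cand <- fit_once(jit, data, model, w, kBT)
    tries <- tries + 1L
    if (!is.null(cand) && (is.null(best) || cand$rss < best$rss)) best <- cand
  }
  if (is.null(best)) stop("global fit failed from every start", call. = FALSE)

  co <- theta_to_coef(best$theta, model)
  fitted_v <- 1 / predict_inv_v(co, data$force, data$dntp, kBT)
  resid_w <- sqrt(w) * (fitted_v - data$velocity)
  n <- nrow(data)

  ## delta-method SEs on the natural-scale coefficients
  se <- rep(NA_real_, 6)
  names(se) <- c("a", "b", "r", "s", "d_b", "d_s")
  cov_theta <- tryCatch(2 * best$rss / max(n - k, 1) * solve(best$hessian),
                        error = function(e) NULL)
  if (!is.null(cov_theta)) {
    nmsp <- model_par_names(model)
    sd_theta <- sqrt(pmax(diag(cov_theta), 0))
    for (j in seq_along(nmsp)) {
      nm <- sub("^log_", "", nmsp[j])
      se[nm] <- if (grepl("^log_", nmsp[j])) co[[nm]] * sd_theta[j] else sd_theta[j]
    }
  }

  boot <- NULL
  if (n_boot > 0) {
    boot <- matrix(NA_real_, n_boot, 6,
                   dimnames = list(NULL, c("a", "b", "r", "s", "d_b", "d_s")))
    for (bb in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      bfit <- fit_once(best$theta, data[idx, ], model, w[idx], kBT)
      if (!is.null(bfit)) boot[bb, ] <- theta_to_coef(bfit$theta, model)
    }
  }

  derived <- NULL
  if (model == 3L) {
    coeffs <- mm_coefficients(co[["a"]], co[["b"]], co[["r"]], co[["s"]],
                              co[["d_b"]], co[["d_s"]])
    derived <- tryCatch({
      rr <- rates_from_coefficients(coeffs)
      land <- translocation_landscape(rr, force = 0, kBT = kBT)
      list(rates = rr, delta = land$delta, K_delta0 = land$K_delta,
           dG_trans = land$dG_trans)
    }, error = function(e) NULL)
  }

  ## Gaussian log-likelihood with known per-record SEMs (unit sd otherwise)
  sem_eff <- if (weights == "sem") 1 / sqrt(w) else rep(1, n)
  ll <- -0.5 * sum(resid_w^2) - sum(log(sem_eff)) - n / 2 * log(2 * pi)

  structure(list(coefficients = co, se = se, model = model, data = data,
                 weights = w, weighting = weights, fitted = fitted_v,
                 residuals_w = resid_w, rss = best$rss, n = n, k = k,
                 logLik = ll, aic = 2 * k - 2 * ll, boot = boot,
                 derived = derived, n_starts = tries, kBT = kBT,
                 call = match.call()),
            class = "ratchet_fit")
}

#' @export
coef.ratchet_fit <- function(object, ...) object$coefficients

#' @export
fitted.ratchet_fit <- function(object, ...) object$fitted

#' @export
residuals.ratchet_fit <- function(object, type = c("weighted", "raw"), ...) {
  type <- match.arg(type)
  if (type == "weighted") object$residuals_w
  else object$fitted - object$data$velocity
}

#' @export
logLik.ratchet_fit <- function(object, ...) {
  structure(object$logLik, df = object$k, nobs = object$n, class = "logLik")
}

#' @export
print.ratchet_fit <- function(x, digits = 4, ...) {
  nm <- c("dNTP-binding power stroke (Model 1)",
          "PPi-release power stroke (Model 2)",
          "Brownian ratchet (Model 3)")[x$model]
  cat("Global force-velocity fit:", nm, "\n")
  cat(sprintf("  %d records, weighted RSS = %.4g, AIC = %.2f\n",
              x$n, x$rss, x$aic))
  print(round(x$coefficients, 6))
  if (!is.null(x$derived)) {
    d <- x$derived
    cat(sprintf(
      "  derived: k_cat = %.3g /s, k_T(0) = %.3g /s, k_-T(0) = %.3g /s, k_on = %.3g /uM/s\n",
      d$rates$k_cat, d$rates$k_T0, d$rates$k_mT0, d$rates$k_on))
    cat(sprintf("  delta = %.3g nm, K_delta(0) = %.3g, dG_trans = %.3g kBT\n",
                d$delta, d$K_delta0, d$dG_trans))
  }
  invisible(x)
}

#' Summarize a global force-velocity fit
#'
#' @param object a \code{\link{ratchet_fit}}.
#' @param level confidence level for bootstrap intervals.
#' @param ... unused.
#' @return a \code{"summary.ratchet_fit"} object: coefficient table (with
#'   SEs and bootstrap CIs when available), derived rates, goodness of fit.
#' @export
summary.ratchet_fit <- function(object, level = 0.95, ...) {
  tab <- data.frame(estimate = object$coefficients, se = object$se)
  if (!is.null(object$boot)) {
    qs <- apply(object$boot, 2L, stats::quantile,
                probs = c((1 - level) / 2, 1 - (1 - level) / 2), na.rm = TRUE)
    tab$ci_lo <- qs[1L, rownames(tab)]
    tab$ci_hi <- qs[2L, rownames(tab)]
  }
  out <- list(table = tab, model = object$model, rss = object$rss,
              aic = object$aic, n = object$n, k = object$k,
              derived = object$derived, level = level,
              n_boot = if (is.null(object$boot)) 0L else nrow(object$boot))
  class(out) <- "summary.ratchet_fit"
  out
}

#' @export
print.summary.ratchet_fit <- function(x, ...) {
  cat(sprintf("Model %d global fit: n = %d, k = %d, weighted RSS = %.4g, AIC = %.2f\n",
              x$model, x$n, x$k, x$rss, x$aic))
  print(round(x$table, 6))
  if (x$n_boot > 0) cat(sprintf("  (bootstrap CIs from %d case resamples)\n", x$n_boot))
  if (!is.null(x$derived)) {
    cat("Derived cycle parameters:\n")
    print(x$derived$rates)
    cat(sprintf("  delta = %.3g nm, K_delta(0) = %.3g, dG_trans = %.3g kBT\n",
                x$derived$delta, x$derived$K_delta0, x$derived$dG_trans))
  }
  invisible(x)
}

#' @export
confint.ratchet_fit <- function(object, parm, level = 0.95, ...) {
  nms <- names(object$coefficients)
  if (missing(parm)) parm <- nms
  if (!is.null(object$boot)) {
    qs <- apply(object$boot[, parm, drop = FALSE], 2L, stats::quantile,
                probs = c((1 - level) / 2, 1 - (1 - level) / 2), na.rm = TRUE)
    out <- t(qs)
  } else {
    z <- stats::qnorm(1 - (1 - level) / 2)
    est <- object$coefficients[parm]
    se <- object$se[parm]
    out <- cbind(est - z * se, est + z * se)
  }
  colnames(out) <- paste0(100 * c((1 - level) / 2, 1 - (1 - level) / 2), " %")
  out
}

#' @export
vcov.ratchet_fit <- function(object, ...) {
  if (is.null(object$boot)) {
    stop("refit with n_boot > 0 for a coefficient covariance", call. = FALSE)
  }
  stats::cov(object$boot, use = "complete.obs")
}

#' Predict from a fitted coupling model
#'
#' @param object a \code{\link{ratchet_fit}}.
#' @param newdata data frame with \code{force} (pN) and, for velocity
#'   predictions, \code{dntp} (uM); defaults to the fitted data.
#' @param type \code{"velocity"} (nt/s), \code{"inv_vmax"} (s), \code{"km"}
#'   (uM), \code{"km_over_vmax"} (s) or \code{"rupture"} (pN; needs
#'   \code{dntp} and optional \code{v_detach}).
#' @param v_detach detachment criterion for \code{type = "rupture"}, nt/s.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.ratchet_fit <- function(object, newdata = NULL,
                                type = c("velocity", "inv_vmax", "km",
                                         "km_over_vmax", "rupture"),
                                v_detach = 7, ...) {
  type <- match.arg(type)
  if (is.null(newdata)) newdata <- object$data
  co <- object$coefficients
  kBT <- object$kBT
  cobj <- mm_coefficients(co[["a"]], max(co[["b"]], 1e-12), co[["r"]],
                          max(co[["s"]], 1e-12), co[["d_b"]], co[["d_s"]])
  switch(type,
         velocity = velocity_model3(newdata$force, newdata$dntp, cobj, kBT),
         inv_vmax = inv_vmax(cobj, newdata$force, kBT),
         km = km_at_force(newdata$force, cobj, kBT),
         km_over_vmax = inv_kb(cobj, newdata$force, kBT),
         rupture = rupture_force(cobj, newdata$dntp, v_detach, kBT))
}

#' Simulate datasets from a fitted model
#'
#' Draws new velocity observations around the fitted values, using each
#' record's SEM as its sampling standard deviation (unit SD where SEMs are
#' absent), in the style of \code{\link[stats]{simulate}}.
#'
#' @param object a \code{\link{ratchet_fit}}.
#' @param nsim number of simulated datasets.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return data frame with one column per simulation.
#' @export
simulate.ratchet_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  sdv <- 1 / sqrt(object$weights)
  out <- as.data.frame(replicate(nsim, stats::rnorm(object$n, object$fitted, sdv)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Plot a force-velocity fit
#'
#' Plots the measured velocities against load, one symbol per dNTP level,
#' with the fitted model curves overlaid.
#'
#' @param x a \code{\link{ratchet_fit}}.
#' @param ... passed to \code{plot}.
#' @export
plot.ratchet_fit <- function(x, ...) {
  d <- x$data
  lv <- sort(unique(d$dntp))
  cols <- grDevices::hcl.colors(length(lv), "viridis")
  graphics::plot(d$force, d$velocity, pch = 19,
                 col = cols[match(d$dntp, lv)],
                 xlab = "load (pN, aiding positive)",
                 ylab = "velocity (nt/s)", ...)
  if (!is.null(d$sem) && all(is.finite(d$sem))) {
    graphics::arrows(d$force, d$velocity - d$sem, d$force, d$velocity + d$sem,
                     angle = 90, code = 3, length = 0.02,
                     col = cols[match(d$dntp, lv)])
  }
  fg <- seq(min(d$force), max(d$force), length.out = 100)
  for (i in seq_along(lv)) {
    graphics::lines(fg, predict(x, data.frame(force = fg, dntp = lv[i])),
                    col = cols[i])
  }
  graphics::legend("topleft", legend = paste(lv, "uM"), col = cols,
                   lty = 1, pch = 19, bty = "n", cex = 0.8)
  invisible(x)
}

#' Model prediction curves from fitted coefficients
#'
#' Evaluates \code{1/V_max(F)}, \code{K_M(F)}, \code{K_M/V_max(F)} on a
#' force grid and the predicted rupture load on a dNTP grid.
#'
#' @param coeffs an \code{\link{mm_coefficients}} object.
#' @param forces force grid, pN.
#' @param dntps dNTP grid for the rupture curve, uM.
#' @param v_detach detachment criterion, nt/s.
#' @param kBT thermal energy, pN nm.
#' @return list with data frames \code{mm} (force, inv_vmax, km,
#'   km_over_vmax) and \code{rupture} (dntp, force).
#' @export
model_predictions <- function(coeffs, forces = seq(-30, 20, by = 1),
                              dntps = c(2, 5, 10, 50, 100, 200, 500),
                              v_detach = 7, kBT = kbt()) {
  stopifnot(inherits(coeffs, "mm_coefficients"))
  list(mm = data.frame(force = forces,
                       inv_vmax = inv_vmax(coeffs, forces, kBT),
                       km = km_at_force(forces, coeffs, kBT),
                       km_over_vmax = inv_kb(coeffs, forces, kBT)),
       rupture = data.frame(dntp = dntps,
                            force = rupture_force(coeffs, dntps, v_detach, kBT)))
}

#' Discriminate the three coupling models on force-velocity data
#'
#' Fits all three schemes globally, ranks them by AIC, and runs the two
#' targeted force-dependence tests that carry the mechanistic signal:
#' the weighted-regression slope of \code{log 1/V_max(F)} versus load
#' (zero under the binding power stroke) and of \code{log K_M/V_max(F)}
#' versus load (zero under the PPi-release power stroke when
#' \code{k_mcat/k_ppi << 1}), with bootstrap confidence intervals obtained
#' by resampling records within each force and repeating the per-force
#' Michaelis-Menten fits.
#'
#' @param data an \code{\link{fv_dataset}}.
#' @param n_boot bootstrap replicates for the slope CIs.
#' @param n_starts multi-start initializations per global fit.
#' @param seed integer seed.
#' @param level confidence level for the slope CIs.
#' @param kBT thermal energy, pN nm.
#' @return an object of class \code{"model_discrimination"}: \code{fits}
#'   (list of \code{ratchet_fit}s), \code{table} (model, k, rss, aic,
#'   delta_aic), \code{best}, and \code{slopes} with estimates and CIs.
#' @export
discriminate_models <- function(data, n_boot = 200, n_starts = 10,
                                seed = NULL, level = 0.95, kBT = kbt()) {
  if (!is.null(seed)) set.seed(seed)
  fits <- lapply(1:3, function(m) {
    ratchet_fit(data, model = m, n_starts = n_starts, kBT = kBT)
  })
  tab <- data.frame(model = 1:3,
                    k = vapply(fits, function(f) f$k, numeric(1)),
                    rss = vapply(fits, function(f) f$rss, numeric(1)),
                    aic = vapply(fits, function(f) f$aic, numeric(1)))
  tab$delta_aic <- tab$aic - min(tab$aic)
  tab <- tab[order(tab$aic), ]
  best <- tab$model[1L]

  slopes <- slope_tests(data, n_boot = n_boot, level = level)
  structure(list(fits = fits, table = tab, best = best, slopes = slopes),
            class = "model_discrimination")
}

## per-force MM fits -> weighted slopes of log(1/Vmax) and log(Km/Vmax) vs F
mm_profile_slopes <- function(data) {
  forces <- sort(unique(data$force))
  prof <- lapply(forces, function(f) {
    tryCatch(fit_mm_at_force(data, force = f),
             error = function(e) list(converged = FALSE))
  })
  ok <- vapply(prof, function(p) isTRUE(p$converged) && p$vmax > 0 && p$km > 0,
               logical(1))
  prof <- prof[ok]
  if (length(prof) < 3L) return(c(vmax_slope = NA_real_, kb_slope = NA_real_))
  F <- vapply(prof, function(p) p$force, numeric(1))
  y1 <- log(1 / vapply(prof, function(p) p$vmax, numeric(1)))
  y2 <- log(vapply(prof, function(p) p$km / p$vmax, numeric(1)))
  w1 <- vapply(prof, function(p) {
    if (is.finite(p$se_vmax) && p$se_vmax > 0) (p$vmax / p$se_vmax)^2 else 1
  }, numeric(1))
  c(vmax_slope = unname(stats::coef(stats::lm(y1 ~ F, weights = w1))[2L]),
    kb_slope = unname(stats::coef(stats::lm(y2 ~ F))[2L]))
}

slope_tests <- function(data, n_boot = 200, level = 0.95) {
  est <- mm_profile_slopes(data)
  boot <- matrix(NA_real_, n_boot, 2, dimnames = list(NULL, names(est)))
  for (b in seq_len(n_boot)) {
    idx <- unlist(lapply(split(seq_len(nrow(data)), data$force), function(ii) {
      sample(ii, length(ii), replace = TRUE)
    }), use.names = FALSE)
    boot[b, ] <- mm_profile_slopes(data[idx, ])
  }
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  ci <- apply(boot, 2L, stats::quantile, probs = probs, na.rm = TRUE)
  list(estimate = est, ci = t(ci), n_boot = n_boot, level = level,
       vmax_force_dependent = !(ci[1L, "vmax_slope"] <= 0 &&
                                  ci[2L, "vmax_slope"] >= 0),
       kb_force_dependent = !(ci[1L, "kb_slope"] <= 0 &&
                                ci[2L, "kb_slope"] >= 0))
}

#' @export
print.model_discrimination <- function(x, ...) {
  cat("Model discrimination by AIC\n")
  print(x$table, row.names = FALSE)
  cat(sprintf("Best model: %d\n", x$best))
  cat(sprintf("log 1/V_max vs F slope: %.4g [%.4g, %.4g] -> %sforce dependent\n",
              x$slopes$estimate[["vmax_slope"]],
              x$slopes$ci["vmax_slope", 1L], x$slopes$ci["vmax_slope", 2L],
              if (x$slopes$vmax_force_dependent) "" else "NOT "))
  cat(sprintf("log K_M/V_max vs F slope: %.4g [%.4g, %.4g] -> %sforce dependent\n",
              x$slopes$estimate[["kb_slope"]],
              x$slopes$ci["kb_slope", 1L], x$slopes$ci["kb_slope", 2L],
              if (x$slopes$kb_force_dependent) "" else "NOT "))
  invisible(x)
}
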