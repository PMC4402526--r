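## Shared helper: read a delimited table with informative parse errors
read_delim_checked <- function(path, n_cols, what) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  nf <- utils::count.fields(path, sep = "", comment.char = "#")
  bad <- which(nf != n_cols)
  if (length(bad) > 0) {
    stop(sprintf("malformed %s file '%s': line %d has %d fields (expected %d)",
                 what, path, bad[1L], nf[bad[1L]], n_cols), call. = FALSE)
  }
  tab <- utils::read.table(path, header = TRUE, comment.char = "#")
  num_ok <- vapply(tab, is.numeric, logical(1))
  if (!all(num_ok)) {
    first_bad_col <- names(tab)[!num_ok][1L]
    bad_row <- which(is.na(suppressWarnings(as.numeric(tab[[first_bad_col]]))))[1L]
    stop(sprintf("malformed %s file '%s': non-numeric value in column '%s' near line %d",
                 what, path, first_bad_col, bad_row + 1L), call. = FALSE)
  }
  tab
}

#' Read and write force-velocity datasets
#'
#' Datasets travel as whitespace-delimited text with a header row and
#' columns \code{force_pN}, \code{dntp_uM}, \code{velocity_nt_s},
#' \code{sem_nt_s} (and optionally \code{n}).
#'
#' @param path file path.
#' @param x an \code{\link{fv_dataset}}.
#' @return \code{read_fv} returns an \code{\link{fv_dataset}};
#'   \code{write_fv} returns \code{path} invisibly.
#' @export
read_fv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  n_cols <- length(strsplit(trimws(first), "[ \t]+")[[1L]])
  if (!n_cols %in% 4:5) {
    stop("malformed force-velocity file '", path,
         "': line 1 must name 4 or 5 columns", call. = FALSE)
  }
  tab <- read_delim_checked(path, n_cols, "force-velocity")
  req <- c("force_pN", "dntp_uM", "velocity_nt_s", "sem_nt_s")
  if (!all(req %in% names(tab))) {
    stop("force-velocity file must have columns ",
         paste(req, collapse = ", "), call. = FALSE)
  }
  fv_dataset(tab$force_pN, tab$dntp_uM, tab$velocity_nt_s, tab$sem_nt_s,
             n = if ("n" %in% names(tab)) tab$n else 1L)
}

#' @rdname read_fv
#' @export
write_fv <- function(x, path) {
  out <- data.frame(force_pN = x$force, dntp_uM = x$dntp,
                    velocity_nt_s = x$velocity, sem_nt_s = x$sem, n = x$n)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write replication traces
#'
#' Traces travel as whitespace-delimited text with header columns
#' \code{time_s}, \code{delta_x_nm}, \code{force_pN}, accompanied by a JSON
#' sidecar (\code{<path>.json}) holding the generating configuration and
#' ground-truth annotations for synthetic traces.
#'
#' @param path trace file path (sidecar at \code{paste0(path, ".json")}).
#' @param trace a \code{\link{replication_trace}}.
#' @return \code{read_trace} returns a \code{replication_trace};
#'   \code{write_trace} returns \code{path} invisibly.
#' @export
read_trace <- function(path) {
  tab <- read_delim_checked(path, 3L, "trace")
  req <- c("time_s", "delta_x_nm", "force_pN")
  if (!all(req %in% names(tab))) {
    stop("trace file must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  pauses <- NULL; detachment <- NULL
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$pauses) && length(meta$pauses) > 0) {
      pauses <- matrix(unlist(meta$pauses), ncol = 2,
                       dimnames = list(NULL, c("start", "end")))
    }
    detachment <- meta$detachment
  }
  replication_trace(tab$time_s, tab$delta_x_nm, tab$force_pN,
                    pauses = pauses, detachment = detachment)
}

#' @rdname read_trace
#' @export
write_trace <- function(trace, path) {
  out <- data.frame(time_s = trace$time, delta_x_nm = trace$delta_x,
                    force_pN = trace$force)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  cfg <- attr(trace, "config")
  meta <- list(
    pauses = if (!is.null(attr(trace, "pauses"))) {
      unname(apply(attr(trace, "pauses"), 1L, function(r) as.list(unname(r)),
                   simplify = FALSE))
    } else list(),
    detachment = attr(trace, "detachment"),
    config = if (!is.null(cfg)) {
      list(dntp = cfg$dntp, schedule = cfg$schedule, mode = cfg$mode,
           sample_rate = cfg$sample_rate, noise_sd = cfg$noise_sd,
           pause_entry_rate = cfg$pause_entry_rate,
           pause_mean_duration = cfg$pause_mean_duration,
           v_detach = cfg$v_detach, seed = cfg$seed, kBT = cfg$kBT,
           rates = unclass(cfg$rates), polymer = unclass(cfg$polymer))
    } else NULL)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Write a fit report as JSON and a readable rate table
#'
#' Serializes the fitted coefficients, their uncertainties, the derived
#' cycle parameters and goodness-of-fit to JSON, and formats a two-column
#' text table (coefficients on the left, derived rates on the right) in
#' the layout conventional for this analysis.
#'
#' @param fit a \code{\link{ratchet_fit}}.
#' @param path output JSON path; the text table goes to
#'   \code{sub(".json", ".txt", path)} if \code{txt = TRUE}.
#' @param txt also write the text table.
#' @return \code{path}, invisibly.
#' @export
write_fit_report <- function(fit, path, txt = TRUE) {
  s <- summary(fit)
  rep <- list(model = fit$model,
              coefficients = as.list(fit$coefficients),
              se = as.list(fit$se),
              rss = fit$rss, aic = fit$aic, n = fit$n, k = fit$k,
              n_starts = fit$n_starts,
              ci = if (!is.null(s$table$ci_lo)) {
                list(lo = as.list(stats::setNames(s$table$ci_lo, rownames(s$table))),
                     hi = as.list(stats::setNames(s$table$ci_hi, rownames(s$table))))
              } else NULL,
              derived = if (!is.null(fit$derived)) {
                list(rates = unclass(fit$derived$rates),
                     delta = fit$derived$delta,
                     K_delta0 = fit$derived$K_delta0,
                     dG_trans = fit$derived$dG_trans)
              } else NULL)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA, null = "null")
  if (txt) {
    writeLines(format_rate_table(fit), sub("\\.json$", ".txt", path))
  }
  invisible(path)
}

#' @rdname write_fit_report
#' @export
format_rate_table <- function(fit) {
  co <- fit$coefficients
  left <- c(sprintf("a (s)      %10.4g", co[["a"]]),
            sprintf("b (s)      %10.4g", co[["b"]]),
            sprintf("r (s)      %10.4g", co[["r"]]),
            sprintf("s (s)      %10.4g", co[["s"]]),
            sprintf("d_b (nm)   %10.4g", co[["d_b"]]),
            sprintf("d_s (nm)   %10.4g", co[["d_s"]]))
  if (is.null(fit$derived)) return(c("Best-fit coefficients", left))
  d <- fit$derived
  right <- c(sprintf("k_on (/uM/s)   %10.4g", d$rates$k_on),
             sprintf("k_cat (/s)     %10.4g", d$rates$k_cat),
             sprintf("k_T(0) (/s)    %10.4g", d$rates$k_T0),
             sprintf("k_-T(0) (/s)   %10.4g", d$rates$k_mT0),
             sprintf("K_delta(0)     %10.4g", d$K_delta0),
             sprintf("d_T (nm)       %10.4g", d$rates$d_T),
             sprintf("d_-T (nm)      %10.4g", d$rates$d_mT),
             sprintf("delta (nm)     %10.4g", d$delta),
             sprintf("dG_trans (kBT) %10.4g", d$dG_trans))
  n <- max(length(left), length(right))
  length(left) <- n; length(right) <- n
  left[is.na(left)] <- strrep(" ", 22L)
  right[is.na(right)] <- ""
  c("Best-fit coefficients          Derived cycle parameters",
    paste(format(left, width = 28L), right))
}
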