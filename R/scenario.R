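#' Normalize an activation-type time course
#'
#' Maps a series to the convention used for nuclear NF-kB activity curves:
#' the resting value (earliest time) maps to 0 and the peak to 1,
#' \eqn{y(t) = (x(t) - x(0)) / (\max x - x(0))}.
#'
#' @param value Numeric series (ordered in time; the first element is the
#'   resting baseline).
#' @return Normalized series.
#' @export
normalize_activation <- function(value) {
  stopifnot(is.numeric(value), length(value) >= 1L, all(is.finite(value)))
  rng <- max(value) - value[1]
  if (rng <= 0)
    stop("degenerate series: maximum does not exceed the resting baseline")
  (value - value[1]) / rng
}

#' Normalize a depletion-type time course
#'
#' Maps a series to the convention used for total IkBa curves: the resting
#' value (earliest time) maps to 1 and the post-degradation minimum to 0,
#' \eqn{y(t) = (x(t) - \min x) / (x(0) - \min x)}. Recovery overshoot above
#' the resting level yields values > 1 (the map is unclamped).
#'
#' @param value Numeric series (first element is the resting baseline).
#' @return Normalized series.
#' @export
normalize_depletion <- function(value) {
  stopifnot(is.numeric(value), length(value) >= 1L, all(is.finite(value)))
  rng <- value[1] - min(value)
  if (rng <= 0)
    stop("degenerate series: no depletion below the resting baseline")
  (value - min(value)) / rng
}

#' Build a normalized time-course data set
#'
#' Container for experimental (or synthetic) normalized time courses of the
#' two model observables. The normalization convention is tied to the
#' observable: `nuclear_nfkb` uses the activation convention,
#' `total_ikba` the depletion convention.
#'
#' @param observable Character vector, `"nuclear_nfkb"` or `"total_ikba"`.
#' @param time_min Times in minutes (strictly increasing within each
#'   observable).
#' @param value_normalized Normalized values.
#' @return Data frame of class `timecourse_data`.
#' @export
timecourse_data <- function(observable, time_min, value_normalized) {
  stopifnot(all(observable %in% c("nuclear_nfkb", "total_ikba")),
            length(observable) == length(time_min),
            length(time_min) == length(value_normalized),
            all(is.finite(value_normalized)))
  for (obs in unique(observable)) {
    tt <- time_min[observable == obs]
    if (any(diff(tt) <= 0))
      stop("times must be strictly increasing within observable ", obs)
  }
  structure(data.frame(observable = observable, time_min = time_min,
                       value_normalized = value_normalized),
            class = c("timecourse_data", "data.frame"))
}

#' Read a normalized time-course data file
#'
#' Delimited text with columns `observable`, `time_min`, `value_normalized`.
#'
#' @param path File path.
#' @return A `timecourse_data` data frame.
#' @export
read_timecourse <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  timecourse_data(tab$observable, tab$time_min, tab$value_normalized)
}

#' Write a normalized time-course data file
#'
#' @param data A `timecourse_data` data frame.
#' @param path Output path.
#' @export
write_timecourse <- function(data, path) {
  utils::write.table(data, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# normalized model curves of a trajectory at given times
normalized_model_at <- function(trajectory, observable, times) {
  stopifnot(inherits(trajectory, "nfkb_trajectory"))
  if (any(times < min(trajectory$time)) || any(times > max(trajectory$time)))
    stop("data time outside the simulated span")
  raw <- switch(observable,
                nuclear_nfkb = normalize_activation(trajectory$nuclear_nfkb),
                total_ikba = normalize_depletion(trajectory$total_ikba),
                stop("unknown observable: ", observable))
  stats::approx(trajectory$time, raw, xout = times)$y
}

#' Scan trajectories over total NF-kB abundance
#'
#' Simulates the feedback module at each abundance multiplier, each run
#' independently equilibrated before stimulation. Reproduces the model
#' experiment in which cell lines differ only in their RelA expression level.
#'
#' @param params Adapted `nfkb_params` (its `nfkb_scale` is overridden).
#' @param curve An `ikk_curve`.
#' @param scales Positive abundance multipliers
#'   (default `c(2, 1.5, 1, 0.5, 0.2)`).
#' @param t_end,dt_out Simulation window (min).
#' @return Object of class `nfkb_scan`: list with `scales`, `trajectories`,
#'   `kind = "nfkb_scale"`.
#' @export
scan_total_nfkb <- function(params, curve, scales = c(2, 1.5, 1, 0.5, 0.2),
                            t_end = 240, dt_out = 1) {
  stopifnot(all(scales > 0), !anyDuplicated(scales))
  run_scan(params, curve, scales, "nfkb_scale", t_end, dt_out)
}

#' Scan trajectories over the induced IkBa mRNA production rate
#'
#' Simulates the module with the NF-kB-dependent IkBa mRNA production term
#' scaled down, emulating a transcription-activation defect. Only the induced
#' IkBa term is scaled; basal IkBa production and the other isoforms are
#' untouched.
#'
#' @inheritParams scan_total_nfkb
#' @param scales Multipliers in (0, 1] (default `c(1, 0.25, 0.125, 0.0625)`).
#' @return An `nfkb_scan` with `kind = "kmrna_scale"`.
#' @export
scan_kmrna <- function(params, curve, scales = c(1, 0.25, 0.125, 0.0625),
                       t_end = 240, dt_out = 1) {
  stopifnot(all(scales > 0), all(scales <= 1), !anyDuplicated(scales))
  run_scan(params, curve, scales, "kmrna_scale", t_end, dt_out)
}

run_scan <- function(params, curve, scales, kind, t_end, dt_out) {
  trajectories <- lapply(scales, function(s) {
    p <- params
    p[[kind]] <- s
    tryCatch(simulate_nfkb(p, curve, t_end = t_end, dt_out = dt_out),
             error = function(e)
               stop(sprintf("scan failed at %s = %g: %s", kind, s,
                            conditionMessage(e)), call. = FALSE))
  })
  structure(list(scales = scales, trajectories = trajectories, kind = kind),
            class = "nfkb_scan")
}

#' @export
print.nfkb_scan <- function(x, ...) {
  cat(sprintf("Feedback-module scan over %s: %s\n", x$kind,
              paste(x$scales, collapse = ", ")))
  invisible(x)
}

#' Combined RMSD between a trajectory and normalized time-course data
#'
#' Normalizes the model's nuclear NF-kB (activation convention) and total
#' IkBa (depletion convention) curves, interpolates them at the data times,
#' and pools the squared residuals of both observables with equal weight per
#' data point: \eqn{RMSD = \sqrt{\mathrm{mean}(r_i^2)}} over all points.
#'
#' @param trajectory An `nfkb_trajectory` spanning all data times.
#' @param data A `timecourse_data` data frame.
#' @return Non-negative RMSD in normalized units.
#' @export
combined_rmsd <- function(trajectory, data) {
  stopifnot(inherits(data, "data.frame"), nrow(data) >= 1L)
  residuals <- unlist(lapply(unique(data$observable), function(obs) {
    d <- data[data$observable == obs, ]
    normalized_model_at(trajectory, obs, d$time_min) - d$value_normalized
  }))
  sqrt(mean(residuals^2))
}

#' Select the scan scale that best matches time-course data
#'
#' Scores every trajectory of a scan against the data by [combined_rmsd()]
#' and returns the argmin. Ties (within `tie_tol`) are broken toward the
#' larger scale and flagged.
#'
#' @param scan An `nfkb_scan`.
#' @param data A `timecourse_data` data frame.
#' @param tie_tol Absolute RMSD difference treated as a tie (default 1e-12).
#' @return Object of class `scale_fit`: list with `rmsd` (named by scale),
#'   `best_scale`, `tie` (logical), `kind`.
#' @export
select_best_scale <- function(scan, data, tie_tol = 1e-12) {
  stopifnot(inherits(scan, "nfkb_scan"), length(scan$scales) >= 1L)
  rmsd <- vapply(scan$trajectories, combined_rmsd, numeric(1), data = data)
  names(rmsd) <- as.character(scan$scales)
  best <- min(rmsd)
  contenders <- scan$scales[rmsd <= best + tie_tol]
  structure(list(rmsd = rmsd, best_scale = max(contenders),
                 tie = length(contenders) > 1L, kind = scan$kind,
                 n_points = nrow(data)),
            class = "scale_fit")
}

#' @export
print.scale_fit <- function(x, ...) {
  cat(sprintf("Scale selection over %s (%d data points)\n", x$kind,
              x$n_points))
  tab <- data.frame(scale = names(x$rmsd), rmsd = round(unname(x$rmsd), 4))
  print(tab, row.names = FALSE)
  cat(sprintf("best scale: %s%s\n", format(x$best_scale),
              if (x$tie) " (tie broken toward the larger scale)" else ""))
  invisible(x)
}

#' @export
coef.scale_fit <- function(object, ...) c(best_scale = object$best_scale)

#' @export
summary.scale_fit <- function(object, ...) {
  cat(sprintf("combined RMSD by %s:\n", object$kind))
  print(round(object$rmsd, 4))
  cat(sprintf("best: %g (RMSD %.4f)\n", object$best_scale,
              min(object$rmsd)))
  invisible(object)
}
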