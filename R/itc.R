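#' Gibbs free energy of dissociation from a dissociation constant
#'
#' Converts a dissociation constant into the standard free energy of binding,
#' \eqn{\Delta G = RT \ln K_d}, with \eqn{K_d} expressed in molar units
#' (standard state 1 M) and \eqn{R = 1.9872 \times 10^{-3}} kcal/(mol K).
#' For nanomolar-range affinities the result is negative (favourable binding).
#'
#' @param kd_nM Dissociation constant in nM. Must be positive.
#' @param temperature Absolute temperature in K (default 298.15, i.e. 25 C).
#' @return Free energy in kcal/mol.
#' @examples
#' delta_g(57.0)    # approx -9.88 kcal/mol
#' delta_g(1e9)     # Kd = 1 M => 0
#' @export
delta_g <- function(kd_nM, temperature = 298.15) {
  stopifnot(is.numeric(kd_nM), is.numeric(temperature), temperature > 0)
  if (any(!is.finite(kd_nM)) || any(kd_nM <= 0))
    stop("'kd_nM' must be finite and positive")
  R <- 1.9872e-3 # kcal/(mol K)
  R * temperature * log(kd_nM * 1e-9)
}

#' Entropic term from Kd and enthalpy
#'
#' Thermodynamic linkage \eqn{T\Delta S = \Delta H - \Delta G}, with
#' \eqn{\Delta G} computed by [delta_g()]. This is the identity that ties the
#' three thermodynamic columns of an ITC summary table together.
#'
#' @param kd_nM Dissociation constant in nM.
#' @param dh_kcal Binding enthalpy in kcal/mol.
#' @inheritParams delta_g
#' @return T-delta-S in kcal/mol.
#' @examples
#' tds_from(244.4, -7.2)  # approx 1.8 kcal/mol
#' @export
tds_from <- function(kd_nM, dh_kcal, temperature = 298.15) {
  stopifnot(is.numeric(dh_kcal))
  dh_kcal - delta_g(kd_nM, temperature)
}

#' Check the internal thermodynamic consistency of a binding table
#'
#' For each record with a quantified Kd, enthalpy and entropic term, recomputes
#' \eqn{T\Delta S} from Kd and \eqn{\Delta H} via [tds_from()] and reports the
#' absolute residual against the tabulated value. Rows with any missing field
#' (e.g. "no binding" entries) are flagged and skipped.
#'
#' @param records Data frame with columns `label`, `kd_nM`, `dh_kcal`,
#'   `tds_kcal` and optionally `temperature` (K; default 298.15).
#' @param tolerance Maximum allowed absolute residual in kcal/mol.
#' @return Data frame with columns `label`, `tds_tabulated`, `tds_computed`,
#'   `residual`, `pass`, plus attributes `all_pass` (logical) and `skipped`
#'   (labels of incomplete rows). An empty record set passes vacuously with
#'   a warning.
#' @export
check_table_consistency <- function(records, tolerance = 0.1) {
  stopifnot(is.data.frame(records), tolerance >= 0)
  needed <- c("label", "kd_nM", "dh_kcal", "tds_kcal")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  temp <- if ("temperature" %in% names(records)) records$temperature else
    rep(298.15, nrow(records))
  complete <- is.finite(records$kd_nM) & is.finite(records$dh_kcal) &
    is.finite(records$tds_kcal)
  skipped <- records$label[!complete]
  rec <- records[complete, , drop = FALSE]
  temp <- temp[complete]
  if (nrow(rec) == 0L) {
    warning("no complete records; consistency check is vacuous")
    out <- data.frame(label = character(), tds_tabulated = numeric(),
                      tds_computed = numeric(), residual = numeric(),
                      pass = logical())
    attr(out, "all_pass") <- TRUE
    attr(out, "skipped") <- skipped
    return(out)
  }
  computed <- tds_from(rec$kd_nM, rec$dh_kcal, temp)
  residual <- abs(computed - rec$tds_kcal)
  out <- data.frame(label = rec$label, tds_tabulated = rec$tds_kcal,
                    tds_computed = computed, residual = residual,
                    pass = residual <= tolerance)
  attr(out, "all_pass") <- all(out$pass)
  attr(out, "skipped") <- skipped
  out
}

#' Affinity fold change between two dissociation constants
#'
#' Ratio of two dissociation constants, reported with the rounding convention
#' used when quoting "n-fold" affinity differences: nearest integer for large
#' changes, one decimal for subtle ones.
#'
#' @param kd_num,kd_den Numerator and denominator Kd (same units), positive.
#' @param rounding `"integer"` (nearest whole fold), `"one_decimal"`, or
#'   `"none"`.
#' @return The (rounded) fold change.
#' @examples
#' fold_change(244.4, 57.0)                    # 4
#' fold_change(386.8, 244.4, "one_decimal")    # 1.6
#' @export
fold_change <- function(kd_num, kd_den, rounding = c("integer", "one_decimal", "none")) {
  rounding <- match.arg(rounding)
  stopifnot(is.numeric(kd_num), is.numeric(kd_den))
  if (any(kd_den <= 0) || any(kd_num <= 0))
    stop("dissociation constants must be positive")
  r <- kd_num / kd_den
  switch(rounding,
         integer = round(r),
         one_decimal = round(r, 1),
         none = r)
}

#' Construct an ITC injection schedule
#'
#' @param cell_volume_mL Calorimeter cell volume in mL.
#' @param cell_conc_uM Concentration of the species in the cell (the binder),
#'   in micromolar.
#' @param syringe_conc_uM Concentration of the titrant in the syringe (uM).
#' @param injection_volumes_uL Vector of injection volumes in microlitres
#'   (length >= 2).
#' @return An object of class `itc_schedule`.
#' @export
itc_schedule <- function(cell_volume_mL, cell_conc_uM, syringe_conc_uM,
                         injection_volumes_uL) {
  stopifnot(length(cell_volume_mL) == 1L, cell_volume_mL > 0,
            length(cell_conc_uM) == 1L, cell_conc_uM > 0,
            length(syringe_conc_uM) == 1L, syringe_conc_uM > 0,
            length(injection_volumes_uL) >= 2L,
            all(injection_volumes_uL > 0))
  structure(list(cell_volume_mL = cell_volume_mL,
                 cell_conc_uM = cell_conc_uM,
                 syringe_conc_uM = syringe_conc_uM,
                 injection_volumes_uL = as.numeric(injection_volumes_uL)),
            class = "itc_schedule")
}

#' Default 25-injection titration schedule
#'
#' A typical VP-ITC run for a tight peptide-domain interaction: one small
#' 5.5 uL priming injection followed by 24 injections of 11.5 uL, with the
#' binder at 14 uM in a 1.4 mL cell and titrant at 177 uM in the syringe.
#'
#' @return An `itc_schedule`.
#' @export
default_itc_schedule <- function() {
  itc_schedule(cell_volume_mL = 1.4, cell_conc_uM = 14,
               syringe_conc_uM = 177,
               injection_volumes_uL = c(5.5, rep(11.5, 24)))
}

#' @export
print.itc_schedule <- function(x, ...) {
  cat("ITC injection schedule\n")
  cat(sprintf("  cell: %.3g mL at %.3g uM; syringe: %.3g uM\n",
              x$cell_volume_mL, x$cell_conc_uM, x$syringe_conc_uM))
  v <- x$injection_volumes_uL
  cat(sprintf("  %d injections, volumes %.3g-%.3g uL (total %.3g uL)\n",
              length(v), min(v), max(v), sum(v)))
  invisible(x)
}

# Running total concentrations in the cell after each injection, using the
# standard perfusion approximation: the cell is always full, each injection
# displaces an equal volume of perfectly mixed solution.
itc_running_concentrations <- function(schedule) {
  v0 <- schedule$cell_volume_mL * 1e3 # uL
  dv <- schedule$injection_volumes_uL
  k <- length(dv)
  M <- numeric(k)
  X <- numeric(k)
  m_prev <- schedule$cell_conc_uM
  x_prev <- 0
  for (i in seq_len(k)) {
    f <- dv[i] / v0
    M[i] <- m_prev * (1 - f)
    X[i] <- x_prev * (1 - f) + schedule$syringe_conc_uM * f
    m_prev <- M[i]
    x_prev <- X[i]
  }
  list(macromolecule_uM = M, titrant_uM = X, displaced_fraction = dv / v0)
}

# Closed-form bound titrant concentration for one-site binding:
# quadratic in totals with n binding sites per macromolecule.
one_site_bound <- function(n, kd_uM, M_uM, X_uM) {
  sites <- n * M_uM
  b <- sites + X_uM + kd_uM
  disc <- pmax(b^2 - 4 * sites * X_uM, 0)
  (b - sqrt(disc)) / 2
}

#' Forward model of one-site ITC injection heats
#'
#' Computes the heat evolved per injection for a single-site binding model:
#' the bound-complex concentration after each injection follows the quadratic
#' closed form in total concentrations; running totals account for the volume
#' displaced from the perfusion cell; the per-injection heat is the change in
#' cell heat content corrected for displaced complex.
#'
#' @param params List or `itc_params` with `n` (stoichiometry), `kd_nM`
#'   (dissociation constant, nM) and `dh_kcal` (enthalpy, kcal/mol).
#' @param schedule An [itc_schedule()].
#' @return Numeric vector of per-injection heats in microcalories.
#' @examples
#' q <- predict_heats(list(n = 1, kd_nM = 57, dh_kcal = -5.9),
#'                    default_itc_schedule())
#' @export
predict_heats <- function(params, schedule) {
  stopifnot(inherits(schedule, "itc_schedule"))
  n <- params$n; kd_nM <- params$kd_nM; dh <- params$dh_kcal
  stopifnot(is.numeric(n), n > 0, is.numeric(kd_nM), kd_nM > 0,
            is.numeric(dh))
  conc <- itc_running_concentrations(schedule)
  bound <- one_site_bound(n, kd_nM * 1e-3, conc$macromolecule_uM,
                          conc$titrant_uM)
  v0 <- schedule$cell_volume_mL
  # heat content of the cell in ucal: uM * mL * kcal/mol = ucal
  Q <- bound * v0 * dh
  q_prev <- 0
  heats <- numeric(length(Q))
  for (i in seq_along(Q)) {
    heats[i] <- Q[i] - q_prev * (1 - conc$displaced_fraction[i])
    q_prev <- Q[i]
  }
  heats
}

#' Fit a one-site binding model to ITC injection heats
#'
#' Nonlinear least squares of the [predict_heats()] forward model to a vector
#' of measured per-injection heats, estimating the stoichiometry n, the
#' dissociation constant and the binding enthalpy. The first injection is
#' excluded by default (its effective volume is unreliable on perfusion
#' instruments). Kd is fitted on the log scale for stability; asymptotic
#' standard errors come from the fit Jacobian.
#'
#' @param heats Numeric vector of per-injection heats (ucal), same length as
#'   the schedule's injection list.
#' @param schedule An [itc_schedule()].
#' @param init List with starting values `n`, `kd_nM`, `dh_kcal`.
#' @param exclude_first Drop the first injection from the residuals
#'   (default TRUE).
#' @return An object of class `itc_fit` with components `coefficients`
#'   (n, kd_nM, dh_kcal), `se`, `residuals`, `fitted`, `schedule`,
#'   `excluded`, and the underlying `nls` object.
#' @export
fit_one_site <- function(heats, schedule,
                         init = list(n = 1, kd_nM = 100, dh_kcal = -6),
                         exclude_first = TRUE) {
  stopifnot(inherits(schedule, "itc_schedule"),
            length(heats) == length(schedule$injection_volumes_uL))
  if (sum(is.finite(heats)) < 5L)
    stop("need at least 5 informative injections")
  if (stats::sd(heats, na.rm = TRUE) < 1e-12 * max(1, abs(mean(heats, na.rm = TRUE))) ||
      all(abs(heats) < 1e-12))
    stop("degenerate (flat) heats: one-site fit is unidentifiable")
  idx <- seq_along(heats)
  if (exclude_first) idx <- idx[-1L]
  obs <- heats[idx]
  model_fun <- function(n, log_kd, dh) {
    predict_heats(list(n = n, kd_nM = exp(log_kd), dh_kcal = dh),
                  schedule)[idx]
  }
  fit <- minpack.lm::nlsLM(
    obs ~ model_fun(n, log_kd, dh),
    start = list(n = init$n, log_kd = log(init$kd_nM), dh = init$dh_kcal),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- stats::coef(fit)
  se <- summary(fit)$coefficients[, "Std. Error"]
  kd <- exp(est[["log_kd"]])
  coefs <- c(n = est[["n"]], kd_nM = kd, dh_kcal = est[["dh"]])
  # delta method for Kd: se(kd) = kd * se(log kd)
  ses <- c(n = unname(se[["n"]]), kd_nM = kd * unname(se[["log_kd"]]),
           dh_kcal = unname(se[["dh"]]))
  structure(list(coefficients = coefs, se = ses,
                 residuals = stats::residuals(fit),
                 fitted = stats::fitted(fit),
                 heats = heats, schedule = schedule,
                 excluded = if (exclude_first) 1L else integer(0),
                 nls = fit),
            class = "itc_fit")
}

#' @export
coef.itc_fit <- function(object, ...) object$coefficients

#' @export
print.itc_fit <- function(x, ...) {
  cat("One-site ITC fit\n")
  cf <- x$coefficients; se <- x$se
  cat(sprintf("  n      = %.3f +/- %.3f\n", cf[["n"]], se[["n"]]))
  cat(sprintf("  Kd     = %.1f +/- %.1f nM\n", cf[["kd_nM"]], se[["kd_nM"]]))
  cat(sprintf("  dH     = %.2f +/- %.2f kcal/mol\n",
              cf[["dh_kcal"]], se[["dh_kcal"]]))
  tds <- tds_from(cf[["kd_nM"]], cf[["dh_kcal"]])
  cat(sprintf("  TdS    = %.2f kcal/mol (at 298.15 K)\n", tds))
  cat(sprintf("  RMS residual %.3g ucal over %d injections%s\n",
              sqrt(mean(x$residuals^2)), length(x$residuals),
              if (length(x$excluded)) " (first excluded)" else ""))
  invisible(x)
}

#' @export
summary.itc_fit <- function(object, ...) {
  cf <- object$coefficients
  out <- list(coefficients = cbind(estimate = cf, std_error = object$se),
              delta_g = delta_g(cf[["kd_nM"]]),
              tds = tds_from(cf[["kd_nM"]], cf[["dh_kcal"]]),
              c_parameter = cf[["n"]] * object$schedule$cell_conc_uM /
                (cf[["kd_nM"]] * 1e-3),
              rms_residual = sqrt(mean(object$residuals^2)))
  class(out) <- "summary.itc_fit"
  out
}

#' @export
print.summary.itc_fit <- function(x, ...) {
  cat("One-site ITC fit summary\n")
  print(round(x$coefficients, 4))
  cat(sprintf("dG = %.2f, TdS = %.2f kcal/mol; Wiseman c = %.1f; RMS resid %.3g ucal\n",
              x$delta_g, x$tds, x$c_parameter, x$rms_residual))
  invisible(x)
}

#' @export
predict.itc_fit <- function(object, schedule = object$schedule, ...) {
  cf <- object$coefficients
  predict_heats(list(n = cf[["n"]], kd_nM = cf[["kd_nM"]],
                     dh_kcal = cf[["dh_kcal"]]), schedule)
}

#' @export
residuals.itc_fit <- function(object, ...) object$residuals

#' @export
plot.itc_fit <- function(x, ...) {
  obs_idx <- seq_along(x$heats)
  plot(obs_idx, x$heats, xlab = "injection", ylab = "heat (ucal)",
       main = "One-site ITC fit", ...)
  lines(obs_idx, predict(x), col = "red")
  if (length(x$excluded))
    points(x$excluded, x$heats[x$excluded], pch = 4, col = "grey40")
  invisible(x)
}

#' Read an ITC binding summary table
#'
#' Reads a delimited text table with columns `label`, `salt_mM`, `kd_nM`,
#' `kd_err`, `dh_kcal`, `dh_err`, `tds_kcal`, `tds_err`. Non-numeric entries
#' such as "NB" (no binding) become NA.
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_binding_table <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  num_cols <- setdiff(names(tab), c("label"))
  for (cl in num_cols) tab[[cl]] <- suppressWarnings(as.numeric(tab[[cl]]))
  tab
}
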