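# State vector layout for the 17-species feedback module:
# free NF-kB in each compartment, then per IkB isoform the free protein and
# the NF-kB complex in each compartment plus the mRNA.
species_names <- function() {
  c("nfkb_c", "nfkb_n",
    as.vector(vapply(ISOFORMS, function(i)
      paste0(c("ikb_", "ikb_", "complex_", "complex_", "mrna_"), i,
             c("_c", "_n", "_c", "_n", "")),
      character(5))))
}

#' Initial (empty) species state
#'
#' All NF-kB free in the cytoplasm, no IkB protein or mRNA. Used as the
#' starting point for equilibration.
#'
#' @param params An adapted `nfkb_params`.
#' @return Named numeric state vector (uM).
#' @export
initial_state <- function(params) {
  s <- stats::setNames(numeric(17L), species_names())
  s["nfkb_c"] <- params$total_nfkb * params$nfkb_scale
  s
}

#' Volume-weighted total NF-kB in a state
#'
#' Sums every NF-kB-containing species, weighting nuclear concentrations by
#' 1/volume_ratio so the result is in cytoplasmic-volume-equivalent uM. Along
#' any valid trajectory this is conserved and equals
#' `total_nfkb * nfkb_scale`.
#'
#' @param state Named state vector or matrix with species columns.
#' @param params The `nfkb_params` used.
#' @return Total NF-kB (uM, cytoplasmic equivalents).
#' @export
total_nfkb_in <- function(state, params) {
  kv <- params$volume_ratio
  cyt <- c("nfkb_c", paste0("complex_", ISOFORMS, "_c"))
  nuc <- c("nfkb_n", paste0("complex_", ISOFORMS, "_n"))
  if (is.matrix(state)) {
    rowSums(state[, cyt, drop = FALSE]) +
      rowSums(state[, nuc, drop = FALSE]) / kv
  } else {
    sum(state[cyt]) + sum(state[nuc]) / kv
  }
}

#' Time derivatives of the feedback-module species
#'
#' Mass-action association/dissociation of NF-kB with each IkB isoform in both
#' compartments, first-order nuclear transport (with the cytoplasmic:nuclear
#' volume ratio applied so that mass is conserved), basal and IKK-activity-
#' scaled IkB degradation (free and NF-kB-bound; IKK acts in the cytoplasm),
#' IkB mRNA production via the additive transcription term driven by nuclear
#' NF-kB (with `kmrna_scale` on the IkBalpha induced term only), first-order
#' mRNA decay and translation. Degradation of a complex releases its NF-kB.
#'
#' @param t Time (min), passed to the IKK curve.
#' @param state Named species vector (uM).
#' @param params Adapted `nfkb_params` (unadapted sets are rejected).
#' @param curve An `ikk_curve`.
#' @return Named vector of time derivatives (uM/min).
#' @export
nfkb_derivatives <- function(t, state, params, curve) {
  if (!isTRUE(params$adapted))
    stop("parameters must be adapted (see adapt_parameters) before use")
  kv <- params$volume_ratio
  ikk <- ikk_activity(curve, t)
  d <- stats::setNames(numeric(length(state)), names(state))
  Nc <- state[["nfkb_c"]]; Nn <- state[["nfkb_n"]]

  # NF-kB shuttling
  d["nfkb_c"] <- -params$imp_nfkb * Nc + params$exp_nfkb * Nn / kv
  d["nfkb_n"] <- params$imp_nfkb * kv * Nc - params$exp_nfkb * Nn

  for (i in ISOFORMS) {
    Ic <- state[[paste0("ikb_", i, "_c")]]
    In <- state[[paste0("ikb_", i, "_n")]]
    Cc <- state[[paste0("complex_", i, "_c")]]
    Cn <- state[[paste0("complex_", i, "_n")]]
    M  <- state[[paste0("mrna_", i)]]
    ka <- params$assoc[[i]]; kd <- params$dissoc[[i]]
    degb_c <- params$deg_bound_basal[[i]] + params$deg_bound_ikk[[i]] * ikk
    degf_c <- params$deg_free_basal[[i]] + params$deg_free_ikk[[i]] * ikk

    d[paste0("mrna_", i)] <- transcription_rate(params, i, Nn) -
      params$mrna_degradation[[i]] * M

    d[paste0("ikb_", i, "_c")] <- params$translation[[i]] * M -
      degf_c * Ic - ka * Ic * Nc + kd * Cc -
      params$imp_ikb[[i]] * Ic + params$exp_ikb[[i]] * In / kv

    d[paste0("ikb_", i, "_n")] <- params$imp_ikb[[i]] * kv * Ic -
      params$exp_ikb[[i]] * In - params$deg_free_basal[[i]] * In -
      ka * In * Nn + kd * Cn

    d[paste0("complex_", i, "_c")] <- ka * Ic * Nc - kd * Cc -
      degb_c * Cc + params$exp_complex[[i]] * Cn / kv

    d[paste0("complex_", i, "_n")] <- ka * In * Nn - kd * Cn -
      params$deg_bound_basal[[i]] * Cn - params$exp_complex[[i]] * Cn

    # NF-kB released by complex turnover / dissociation, consumed by binding
    d["nfkb_c"] <- d["nfkb_c"] + kd * Cc + degb_c * Cc - ka * Ic * Nc
    d["nfkb_n"] <- d["nfkb_n"] + kd * Cn +
      params$deg_bound_basal[[i]] * Cn - ka * In * Nn
  }
  d
}

rhs_desolve <- function(t, state, parms) {
  list(nfkb_derivatives(t, state, parms$params, parms$curve))
}

solver_defaults <- list(rtol = 1e-6, atol = 1e-9)

#' Equilibrate the model at basal IKK activity
#'
#' Integrates from the empty initial state with IKK held at the curve's basal
#' level until the maximum absolute derivative falls below `ss_tol`,
#' producing the resting-cell state used as the initial condition for
#' stimulated simulations.
#'
#' @param params Adapted `nfkb_params`.
#' @param curve The `ikk_curve` whose `basal` level defines rest.
#' @param ss_tol Steady-state tolerance on max |dx/dt| (uM/min).
#' @param horizon Maximum equilibration time (min).
#' @return Named steady-state vector with attribute `residual` (max |dx/dt|).
#' @export
equilibrate <- function(params, curve, ss_tol = 1e-8, horizon = 4000) {
  basal_curve <- constant_ikk_curve(curve$basal, t_end = horizon)
  state <- initial_state(params)
  t_done <- 0
  chunk <- 500
  repeat {
    sol <- deSolve::lsoda(state, c(0, chunk), rhs_desolve,
                          parms = list(params = params, curve = basal_curve),
                          rtol = solver_defaults$rtol,
                          atol = solver_defaults$atol)
    state <- clip_state(sol[nrow(sol), -1])
    t_done <- t_done + chunk
    res <- max(abs(nfkb_derivatives(0, state, params, basal_curve)))
    if (res < ss_tol) break
    if (t_done >= horizon)
      stop(sprintf("equilibration did not converge within %g min (residual %.3g uM/min)",
                   horizon, res))
  }
  attr(state, "residual") <- res
  state
}

clip_state <- function(state, tol = 1e-9) {
  neg <- state < 0
  if (any(state < -tol))
    stop(sprintf("negative concentration beyond tolerance: min = %.3g",
                 min(state)))
  state[neg] <- 0
  state
}

#' Simulate the feedback module under an IKK input
#'
#' Equilibrates at the curve's basal IKK level, then integrates the full model
#' from t = 0 (stimulation onset) with the time-varying IKK activity, using an
#' adaptive stiff-capable solver. Output includes the derived observables:
#' nuclear NF-kB and volume-weighted total IkBalpha protein (free plus bound,
#' both compartments).
#'
#' @param params Adapted `nfkb_params`.
#' @param curve An `ikk_curve`.
#' @param t_end Final time (min).
#' @param dt_out Output grid spacing (min).
#' @param init Optional pre-equilibrated initial state (skips equilibration).
#' @return Object of class `nfkb_trajectory`: a list with `time` (min),
#'   `species` (matrix, one column per species), `nuclear_nfkb`,
#'   `total_ikba`, `params`, `curve`.
#' @export
simulate_nfkb <- function(params, curve, t_end = 360, dt_out = 1,
                          init = NULL) {
  stopifnot(inherits(curve, "ikk_curve"), t_end > 0, dt_out > 0)
  if (is.null(init)) init <- equilibrate(params, curve)
  times <- seq(0, t_end, by = dt_out)
  sol <- deSolve::lsoda(init, times, rhs_desolve,
                        parms = list(params = params, curve = curve),
                        rtol = solver_defaults$rtol,
                        atol = solver_defaults$atol)
  if (attr(sol, "istate")[1] < 0)
    stop(sprintf("integration failed near t = %.1f min", max(sol[, "time"])))
  sp <- sol[, -1, drop = FALSE]
  sp[sp < 0 & sp > -1e-9] <- 0
  if (any(sp < 0))
    stop(sprintf("negative concentration beyond tolerance at output: %.3g",
                 min(sp)))
  tot <- total_nfkb_in(sp, params)
  target <- params$total_nfkb * params$nfkb_scale
  drift <- max(abs(tot - target)) / target
  if (drift > 1e-5)
    stop(sprintf("NF-kB conservation drift %.3g exceeds tolerance", drift))
  structure(list(time = sol[, "time"], species = sp,
                 nuclear_nfkb = sp[, "nfkb_n"],
                 total_ikba = total_ikb_in(sp, params, "a"),
                 params = params, curve = curve),
            class = "nfkb_trajectory")
}

#' Volume-weighted total protein of one IkB isoform
#'
#' Free plus NF-kB-bound protein over both compartments, nuclear species
#' weighted by 1/volume_ratio (cytoplasmic-volume-equivalent uM).
#'
#' @param state State vector or species matrix.
#' @param params The `nfkb_params` used.
#' @param isoform `"a"`, `"b"` or `"e"`.
#' @return Total protein (uM).
#' @export
total_ikb_in <- function(state, params, isoform = "a") {
  kv <- params$volume_ratio
  cyt <- paste0(c("ikb_", "complex_"), isoform, "_c")
  nuc <- paste0(c("ikb_", "complex_"), isoform, "_n")
  if (is.matrix(state)) {
    rowSums(state[, cyt, drop = FALSE]) +
      rowSums(state[, nuc, drop = FALSE]) / kv
  } else {
    sum(state[cyt]) + sum(state[nuc]) / kv
  }
}

#' @export
print.nfkb_trajectory <- function(x, ...) {
  cat(sprintf("NF-kB feedback trajectory: %d points over 0-%g min\n",
              length(x$time), max(x$time)))
  cat(sprintf("  nuclear NF-kB: rest %.4g, peak %.4g uM at %g min\n",
              x$nuclear_nfkb[1], max(x$nuclear_nfkb),
              x$time[which.max(x$nuclear_nfkb)]))
  cat(sprintf("  total IkBa: rest %.4g, min %.4g uM at %g min, final %.4g\n",
              x$total_ikba[1], min(x$total_ikba),
              x$time[which.min(x$total_ikba)],
              x$total_ikba[length(x$total_ikba)]))
  invisible(x)
}

#' @export
as.data.frame.nfkb_trajectory <- function(x, ...) {
  data.frame(time_min = x$time, x$species,
             nuclear_nfkb = x$nuclear_nfkb, total_ikba = x$total_ikba)
}

#' @export
plot.nfkb_trajectory <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  plot(x$time, x$nuclear_nfkb, type = "l", xlab = "time (min)",
       ylab = "nuclear NF-kB (uM)", main = "NF-kB feedback module", ...)
  plot(x$time, x$total_ikba, type = "l", xlab = "time (min)",
       ylab = "total IkBa (uM)", ...)
  invisible(x)
}

#' Write a trajectory to delimited text
#'
#' @param trajectory An `nfkb_trajectory`.
#' @param path Output path (tab-separated; `time_min`, every species,
#'   `nuclear_nfkb`, `total_ikba`).
#' @export
write_trajectory <- function(trajectory, path) {
  utils::write.table(as.data.frame(trajectory), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
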