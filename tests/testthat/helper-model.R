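# Shared fixtures. Expensive simulations are computed once per test run and
# cached in this environment.
.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, expr, envir = .cache)
  get(key, envir = .cache)
}

default_traj <- function() {
  cached("default_traj", {
    simulate_nfkb(default_parameters(), default_ikk_curve(), t_end = 240)
  })
}

default_kmrna_scan <- function() {
  cached("kmrna_scan", {
    scan_kmrna(default_parameters(), default_ikk_curve())
  })
}

default_nfkb_scan <- function() {
  cached("nfkb_scan", {
    scan_total_nfkb(default_parameters(), default_ikk_curve())
  })
}

packaged_binding_table <- function() {
  read_binding_table(system.file("extdata", "itc_binding_summary.tsv",
                                 package = "nfkbcbp"))
}

# Independent fixed-step classical Runge-Kutta reference integrator,
# used as the oracle against the adaptive solver.
rk4_integrate <- function(state, times, params, curve) {
  out <- matrix(NA_real_, nrow = length(times), ncol = length(state),
                dimnames = list(NULL, names(state)))
  out[1, ] <- state
  for (k in seq_len(length(times) - 1L)) {
    t0 <- times[k]
    h <- times[k + 1L] - t0
    y <- out[k, ]
    k1 <- nfkb_derivatives(t0, y, params, curve)
    k2 <- nfkb_derivatives(t0 + h / 2, y + h / 2 * k1, params, curve)
    k3 <- nfkb_derivatives(t0 + h / 2, y + h / 2 * k2, params, curve)
    k4 <- nfkb_derivatives(t0 + h, y + h * k3, params, curve)
    out[k + 1L, ] <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  out
}
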