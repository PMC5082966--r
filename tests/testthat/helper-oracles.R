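# Shared fixtures and independent reference integrators for the tests.

ms_ref <- function(model = "MS") fixture_params("ms2003", model = model)
pm_ref <- function(model = "MS") fixture_params("pacemaker", model = model)

# Reference solution via deSolve (adaptive lsoda at tight tolerance),
# independent of the package's backward Euler stepper.  `branch` can force
# the gate branch ("open"/"close") to mimic the stepper's frozen-branch
# treatment over a single step; NULL switches by vm as in the model.
desolve_reference <- function(params, times, init = c(0, 1),
                              stim_onsets = numeric(0), amplitude = 1,
                              duration = 0.4, branch = NULL) {
  rhs <- function(t, y, p) {
    j <- if (any(t >= stim_onsets & t < stim_onsets + duration)) amplitude
         else 0
    d <- cell_rhs(params, y[1], min(max(y[2], 0), 1), j)
    dh <- if (is.null(branch)) d$dh_dt
          else if (branch == "open") (1 - y[2]) / params$tau_open
          else -y[2] / params$tau_close
    list(c(d$dvm_dt, dh))
  }
  out <- deSolve::lsoda(init, times, rhs, NULL, rtol = 1e-10, atol = 1e-12,
                        maxsteps = 1e6)
  tibble::tibble(time = out[, 1], vm = out[, 2], h = out[, 3])
}

# Synthetic triangular pulse trace crossing `thr` once on the way up and
# once on the way down; returns the trace and the exact crossing times.
triangle_trace <- function(peak = 1, width = 10, thr = 0.13, dt = 0.5) {
  tt <- seq(0, 3 * width, by = dt)
  vm <- pmax(0, peak * (1 - abs(tt - width) / width))
  up <- width * thr / peak
  down <- 2 * width - up
  list(trace = tibble::tibble(time = tt, vm = vm), t_up = up, t_down = down)
}
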