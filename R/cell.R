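#' Stimulus train
#'
#' A train of identical external current pulses.  Each pulse adds a constant
#' `amplitude` (1/ms) to `dvm/dt` over `[onset, onset + duration)`; a time
#' step receives the current when its midpoint lies in the window.
#'
#' @param onsets Strictly increasing onset times (ms).
#' @param amplitude Current density (1/ms), non-negative.  The default
#'   1.0/ms together with the 0.4 ms default duration is the standard
#'   single-cell pacing pulse used throughout the package.
#' @param duration Pulse width (ms), positive.
#' @return A `stimulus_train` object.
#' @export
stimulus_train <- function(onsets, amplitude = 1.0, duration = 0.4) {
  onsets <- as.numeric(onsets)
  if (length(onsets) && any(diff(onsets) <= 0))
    stop("`onsets` must be strictly increasing", call. = FALSE)
  if (duration <= 0) stop("`duration` must be positive", call. = FALSE)
  if (amplitude < 0) stop("`amplitude` must be non-negative", call. = FALSE)
  if (length(onsets) > 1 && any(diff(onsets) < duration))
    stop("stimulus windows must not overlap", call. = FALSE)
  structure(list(onsets = onsets, amplitude = amplitude,
                 duration = duration),
            class = "stimulus_train")
}

#' Solver settings
#'
#' Settings for the backward Euler / Newton time integrator.  The default
#' step of 0.005 ms resolves the upstroke (time scale `tau_in`, a few tenths
#' of a ms) with comfortable margin; `dt = 0.05` ms is still adequate for
#' activation counting (see the sweep functions).
#'
#' @param dt Time step (ms).
#' @param newton_tol Residual tolerance of the implicit solve.
#' @param newton_max_iter Maximum Newton iterations per step.
#' @param record_dt Sampling interval of the recorded trace (ms); must be a
#'   multiple of `dt`.  Defaults to `dt`.
#' @return A `solver_settings` object.
#' @export
solver_settings <- function(dt = 0.005, newton_tol = 1e-10,
                            newton_max_iter = 50L, record_dt = NULL) {
  if (dt <= 0) stop("`dt` must be positive", call. = FALSE)
  if (newton_tol <= 0) stop("`newton_tol` must be positive", call. = FALSE)
  if (newton_max_iter < 1) stop("`newton_max_iter` must be >= 1",
                                call. = FALSE)
  if (is.null(record_dt)) record_dt <- dt
  stride <- record_dt / dt
  if (abs(stride - round(stride)) > 1e-8)
    stop("`record_dt` must be an integer multiple of `dt`", call. = FALSE)
  structure(list(dt = dt, newton_tol = newton_tol,
                 newton_max_iter = as.integer(newton_max_iter),
                 record_dt = record_dt, stride = as.integer(round(stride))),
            class = "solver_settings")
}

#' One backward Euler step
#'
#' Advances a single `(vm, h)` state by one implicit step.  The gate branch
#' is frozen from the incoming `vm` (so the linear `h` update is solved in
#' closed form) and the `vm` update is a scalar Newton solve on the cubic.
#'
#' @param state Numeric length-2 vector `c(vm, h)`.
#' @param params An [model_params()] object.
#' @param j_stim Applied current density (1/ms).
#' @param settings A [solver_settings()] object.
#' @return The updated `c(vm, h)`.
#' @export
step_backward_euler <- function(state, params, j_stim = 0,
                                settings = solver_settings()) {
  assert_params(params)
  out <- be_step_cpp(model_code(params), param_vec(params),
                     state[[1]], state[[2]], j_stim, settings$dt,
                     settings$newton_tol, settings$newton_max_iter)
  c(vm = out[1], h = out[2])
}

#' Simulate a single cell
#'
#' Integrates the ionic model from rest (or a supplied initial state) under
#' a stimulus train, recording a uniformly sampled trace.
#'
#' @param params An [model_params()] object.
#' @param stimulus A [stimulus_train()]; use
#'   `stimulus_train(numeric(0))` for an unstimulated run.
#' @param t_end Simulation horizon (ms).
#' @param settings A [solver_settings()] object.
#' @param init Initial state `c(vm, h)`; default the resting point `(0, 1)`.
#' @return A `cell_trace`: a tibble with columns `time`, `vm`, `h` and
#'   attributes `params` and `settings`.
#' @examples
#' p <- fixture_params("pacemaker", model = "mMS")
#' tr <- simulate_cell(p, stimulus_train(0), t_end = 1200,
#'                     settings = solver_settings(dt = 0.05))
#' nrow(tidy(measure_apd(tr)))   # a single action potential
#' @export
simulate_cell <- function(params, stimulus, t_end,
                          settings = solver_settings(),
                          init = c(0, 1)) {
  assert_params(params)
  if (!inherits(stimulus, "stimulus_train"))
    stop("`stimulus` must be a stimulus_train()", call. = FALSE)
  if (t_end <= 0) stop("`t_end` must be positive", call. = FALSE)
  res <- simulate_cell_cpp(model_code(params), param_vec(params),
                           init[[1]], init[[2]], settings$dt, t_end,
                           stimulus$onsets, stimulus$amplitude,
                           stimulus$duration, settings$newton_tol,
                           settings$newton_max_iter, settings$stride)
  out <- tibble::tibble(
    time = seq(0, by = settings$record_dt,
               length.out = length(res$vm)),
    vm = res$vm, h = res$h
  )
  attr(out, "params") <- params
  attr(out, "settings") <- settings
  class(out) <- c("cell_trace", class(out))
  out
}

# Interpolated threshold-crossing times of a sampled trace.
# direction +1: vm[k] < thr <= vm[k+1]; direction -1: vm[k] >= thr > vm[k+1].
crossing_times <- function(time, vm, thr, direction = 1) {
  n <- length(vm)
  if (n < 2) return(numeric(0))
  a <- vm[-n]; b <- vm[-1]
  idx <- if (direction > 0) which(a < thr & b >= thr)
         else which(a >= thr & b < thr)
  time[idx] + (time[idx + 1] - time[idx]) * (thr - vm[idx]) /
    (vm[idx + 1] - vm[idx])
}

# Merge crossing times closer than `debounce` ms into their first element.
debounce_times <- function(times, debounce) {
  if (length(times) < 2) return(times)
  keep <- logical(length(times))
  keep[1] <- TRUE
  last <- times[1]
  for (i in 2:length(times)) {
    if (times[i] - last > debounce) keep[i] <- TRUE
    last <- times[i]
  }
  times[keep]
}

#' Detect activations in a trace
#'
#' Returns the times of upward crossings of the activation threshold,
#' linearly interpolated between samples.  A trace that starts at or above
#' the threshold counts an activation at its first sample.  Consecutive
#' crossings closer than `debounce` ms are merged (guarding against
#' numerical chatter at the threshold).
#'
#' @param trace A `cell_trace` tibble (columns `time`, `vm`), or any data
#'   frame with those columns.
#' @param v_gate Threshold; defaults to the `v_gate` of the trace's
#'   parameter attribute.
#' @param debounce Merge window (ms).
#' @return Numeric vector of activation times (ms).
#' @export
detect_activations <- function(trace, v_gate = NULL, debounce = 5) {
  if (is.null(v_gate)) v_gate <- attr(trace, "params")$v_gate
  if (is.null(v_gate)) stop("`v_gate` is required", call. = FALSE)
  up <- crossing_times(trace$time, trace$vm, v_gate, 1)
  if (nrow(trace) && trace$vm[1] >= v_gate) up <- c(trace$time[1], up)
  debounce_times(up, debounce)
}

#' Measure action potential durations
#'
#' Pairs each (debounced) upward crossing of the threshold with the next
#' downward crossing; the APD is the elapsed time with `vm >= v_gate`.  An
#' interval still above threshold at the end of the trace is reported with
#' `open = TRUE` and excluded from APD statistics.
#'
#' @inheritParams detect_activations
#' @return An `apd_summary` object.  `tidy()` returns the per-beat tibble
#'   (`t_up`, `t_down`, `apd`, `open`); `glance()` returns a one-row tibble
#'   with `n_activations`, `n_apd`, `apd_mean`, `apd_min`, `apd_max`.
#' @export
measure_apd <- function(trace, v_gate = NULL, debounce = 5) {
  if (is.null(v_gate)) v_gate <- attr(trace, "params")$v_gate
  if (is.null(v_gate)) stop("`v_gate` is required", call. = FALSE)
  ups <- detect_activations(trace, v_gate, debounce)
  downs <- crossing_times(trace$time, trace$vm, v_gate, -1)
  t_up <- numeric(0); t_down <- numeric(0); open <- logical(0)
  last_down <- -Inf
  for (u in ups) {
    if (u < last_down) next # still inside the previous interval
    d <- downs[downs > u]
    if (length(d)) {
      t_up <- c(t_up, u); t_down <- c(t_down, d[1]); open <- c(open, FALSE)
      last_down <- d[1]
    } else {
      t_up <- c(t_up, u); t_down <- c(t_down, NA_real_); open <- c(open, TRUE)
      last_down <- Inf
    }
  }
  intervals <- tibble::tibble(
    t_up = t_up, t_down = t_down,
    apd = t_down - t_up, open = open
  )
  structure(
    list(intervals = intervals, activation_times = ups,
         n_activations = length(ups), v_gate = v_gate),
    class = "apd_summary"
  )
}

#' @export
print.apd_summary <- function(x, ...) {
  cat("<apd_summary>", x$n_activations, "activation(s)\n")
  print(x$intervals)
  invisible(x)
}

#' @export
tidy.apd_summary <- function(x, ...) x$intervals

#' @export
glance.apd_summary <- function(x, ...) {
  closed <- x$intervals$apd[!x$intervals$open]
  tibble::tibble(
    n_activations = x$n_activations,
    n_apd = length(closed),
    apd_mean = if (length(closed)) mean(closed) else NA_real_,
    apd_min = if (length(closed)) min(closed) else NA_real_,
    apd_max = if (length(closed)) max(closed) else NA_real_
  )
}

#' Classify pacemaker behaviour of a single-stimulus run
#'
#' A parameter set is a pacemaker when a single stimulus elicits more than
#' one depolarisation: the cell re-excites itself without further input.
#'
#' @param summary An [measure_apd()] result from a single-stimulus run.
#' @return `TRUE` if more than one activation was detected.
#' @export
classify_pacemaker <- function(summary) {
  if (!inherits(summary, "apd_summary"))
    stop("`summary` must come from measure_apd()", call. = FALSE)
  summary$n_activations > 1L
}

#' @export
autoplot.cell_trace <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), c("vm", "h"),
                              names_to = "variable", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~variable, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (ms)", y = NULL) +
    ggplot2::theme_minimal()
}
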