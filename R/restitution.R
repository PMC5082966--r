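#' Analytic leading-order APD and restitution
#'
#' Under the time-scale separation `tau_in << tau_out << tau_open,
#' tau_close`, the action potential duration (APD, the time with
#' `vm >= v_gate`) is, at leading order, the time the gate takes to decay
#' from its value at activation down to the model's `h_min`:
#' \deqn{APD_{max} = \tau_{close}\,\ln(1/h_{min})}
#' after full recovery, and after a diastolic interval `DI`
#' \deqn{h(DI) = 1 - (1 - h_{min}) e^{-DI/\tau_{open}}, \qquad
#'       APD(DI) = \tau_{close}\,\ln\left(h(DI)/h_{min}\right).}
#' The model enters only through its `h_min` ([h_min()]), so with
#' `v_gate = v_gate_star(params)` the MS and mMS curves coincide exactly.
#' At `v_gate = 1` the mMS `h_min` equals 1 and the predicted APD is 0 ms —
#' consistent with the APD definition, which the MS analytic curve (blind to
#' `v_gate`) cannot reproduce.
#'
#' @param params An [model_params()] object.
#' @param di Diastolic interval(s), ms, non-negative (vectorised).
#' @return `apd_max_analytic()`: the asymptotic APD after full recovery
#'   (ms).  `h_after_di()`: the gate value recovered after `di`.
#'   `restitution_analytic()`: the APD elicited after `di` (ms).
#' @examples
#' p <- fixture_params("pacemaker", model = "mMS")
#' apd_max_analytic(p)          # 347.05 ms
#' restitution_analytic(p, 100) # 295.82 ms
#' @export
apd_max_analytic <- function(params) {
  hm <- h_min(params)
  if (hm > 1)
    stop("model is unexcitable (h_min > 1): no action potential exists",
         call. = FALSE)
  params$tau_close * log(1 / hm)
}

#' @rdname apd_max_analytic
#' @export
h_after_di <- function(params, di) {
  if (any(di < 0)) stop("`di` must be non-negative", call. = FALSE)
  hm <- h_min(params)
  1 - (1 - hm) * exp(-di / params$tau_open)
}

#' @rdname apd_max_analytic
#' @export
restitution_analytic <- function(params, di) {
  hm <- h_min(params)
  if (hm > 1)
    stop("model is unexcitable (h_min > 1): no action potential exists",
         call. = FALSE)
  params$tau_close * log(h_after_di(params, di) / hm)
}

#' s1-s2 restitution protocol
#'
#' Conditions the cell with `n_s1` stimuli at the basic cycle length `s1`
#' (to reach a limit cycle), then — restarting from the conditioned state
#' each time — applies one final `s1` beat followed by a single premature
#' stimulus at coupling interval `s2`, and measures the APD it elicits.
#' The diastolic interval is `DI = s2 - APD1`, with `APD1` the APD of the
#' final conditioning beat.  The default `s2` sequence is geometric:
#' 900 ms shrinking by 2% per point, truncated at 200 ms.
#'
#' The defaults (`s1 = 1000` ms, `n_s1 = 100`) reproduce the full protocol;
#' for quick exploratory runs a reduced `n_s1` (>= 24) and a coarser `dt`
#' (<= 0.05 ms) give visually identical curves.
#'
#' @param params An [model_params()] object.
#' @param settings A [solver_settings()] object.
#' @param s1 Conditioning cycle length (ms).
#' @param n_s1 Number of conditioning stimuli.
#' @param s2 Premature coupling intervals (ms), descending.
#' @param amplitude,duration Stimulus pulse (1/ms, ms).
#' @return A `restitution_curve` tibble with columns `s2`, `apd1`, `di`,
#'   `apd`, `captured`.  `di` and `apd` are `NA` when the premature beat
#'   fails to capture.
#' @export
s1s2_restitution <- function(params,
                             settings = solver_settings(record_dt = 0.05),
                             s1 = 1000, n_s1 = 100,
                             s2 = s1s2_default_s2(),
                             amplitude = 1.0, duration = 0.4) {
  assert_params(params)
  if (h_min(params) >= 1)
    stop("model is unexcitable (h_min >= 1)", call. = FALSE)
  # Condition up to the onset of the final s1 beat.
  cond_end <- (n_s1 - 1) * s1
  cond <- simulate_cell_cpp(model_code(params), param_vec(params), 0, 1,
                            settings$dt, cond_end,
                            seq(0, by = s1, length.out = n_s1 - 1),
                            amplitude, duration, settings$newton_tol,
                            settings$newton_max_iter,
                            max(settings$stride, 1000L))
  state <- cond$final
  tail_ms <- 2 * apd_max_analytic(params) + 200
  rows <- purrr::map(s2, function(s2i) {
    res <- simulate_cell_cpp(model_code(params), param_vec(params),
                             state[1], state[2], settings$dt,
                             s2i + tail_ms, c(0, s2i), amplitude, duration,
                             settings$newton_tol, settings$newton_max_iter,
                             settings$stride)
    tr <- tibble::tibble(
      time = seq(0, by = settings$record_dt, length.out = length(res$vm)),
      vm = res$vm)
    iv <- tidy(measure_apd(tr, params$v_gate))
    iv1 <- iv[iv$t_up < s2i, , drop = FALSE]
    apd1 <- if (nrow(iv1)) iv1$apd[1] else NA_real_
    iv2 <- iv[iv$t_up >= s2i & !iv$open, , drop = FALSE]
    if (nrow(iv2) && !is.na(apd1)) {
      tibble::tibble(s2 = s2i, apd1 = apd1, di = s2i - apd1,
                     apd = iv2$apd[1], captured = TRUE)
    } else {
      tibble::tibble(s2 = s2i, apd1 = apd1, di = NA_real_,
                     apd = NA_real_, captured = FALSE)
    }
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("restitution_curve", class(out))
  attr(out, "params") <- params
  out
}

#' @rdname s1s2_restitution
#' @export
s1s2_default_s2 <- function(s2_max = 900, ratio = 0.98, s2_min = 200) {
  n <- floor(log(s2_min / s2_max) / log(ratio)) + 1
  s2 <- s2_max * ratio^(0:n)
  s2[s2 >= s2_min]
}

#' @export
autoplot.restitution_curve <- function(object, ...) {
  dat <- dplyr::filter(tibble::as_tibble(object), .data$captured)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$di, y = .data$apd)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::labs(x = "DI (ms)", y = "APD (ms)") +
    ggplot2::theme_minimal()
}

#' Classify a pacing response from its last beats
#'
#' Classifies the steady-state response of a periodically paced cell from
#' the APDs attributable to the last four stimuli:
#'
#' * `"1:1"` — four activations, all APDs equal to within `tol_ms`;
#' * `"2:2"` (alternans) — four activations, APDs alternating between two
#'   levels separated by more than `tol_ms`;
#' * `"2:1"` (block) — exactly two activations with a single APD level;
#' * `"no_capture"` — no activations at all;
#' * `"unknown"` — any other pattern (never silently coerced).
#'
#' @param last_apds APD values (ms) measured in the last-4-stimuli window.
#' @param n_activations Number of activations in that window.
#' @param tol_ms Equality tolerance (ms).  Default 1 ms: well below both
#'   the 2 ms pacing-period resolution of [scan_dynamic_restitution()] and
#'   reported alternans amplitudes (tens to hundreds of ms).
#' @return A single classification string.
#' @export
classify_behaviour <- function(last_apds, n_activations, tol_ms = 1) {
  if (n_activations == 0) return("no_capture")
  a <- last_apds
  if (n_activations == 4 && length(a) == 4) {
    if (max(a) - min(a) <= tol_ms) return("1:1")
    if (abs(a[1] - a[3]) <= tol_ms && abs(a[2] - a[4]) <= tol_ms &&
        abs(a[1] - a[2]) > tol_ms) return("2:2")
  }
  if (n_activations == 2 && length(a) == 2 &&
      abs(a[1] - a[2]) <= tol_ms) return("2:1")
  "unknown"
}

#' Dynamic restitution at one pacing period
#'
#' Paces the cell from rest with `n_stimuli` stimuli at period `s`, then
#' measures the APDs attributable to the last four stimuli and classifies
#' the response with [classify_behaviour()].
#'
#' @param params An [model_params()] object.
#' @param s Pacing period (ms); must exceed the stimulus duration.
#' @param n_stimuli Number of stimuli (default 104: 100 conditioning plus
#'   the 4 measured).
#' @param settings A [solver_settings()] object.
#' @param tol_ms APD-equality tolerance for classification (ms).
#' @param amplitude,duration Stimulus pulse (1/ms, ms).
#' @return A `dynamic_restitution` object: a list with `s`, `last_apds`,
#'   `n_activations_last4`, `behaviour` and the full interval table.
#' @export
dynamic_restitution <- function(params, s, n_stimuli = 104,
                                settings = solver_settings(record_dt = 0.05),
                                tol_ms = 1, amplitude = 1.0,
                                duration = 0.4) {
  assert_params(params)
  if (s <= duration) stop("`s` must exceed the stimulus duration",
                          call. = FALSE)
  if (n_stimuli < 8) stop("`n_stimuli` must be >= 8", call. = FALSE)
  onsets <- seq(0, by = s, length.out = n_stimuli)
  tail_ms <- max(400, 1.5 * apd_max_analytic(params))
  t_end <- onsets[n_stimuli] + tail_ms
  res <- simulate_cell_cpp(model_code(params), param_vec(params), 0, 1,
                           settings$dt, t_end, onsets, amplitude, duration,
                           settings$newton_tol, settings$newton_max_iter,
                           settings$stride)
  tr <- tibble::tibble(
    time = seq(0, by = settings$record_dt, length.out = length(res$vm)),
    vm = res$vm)
  # The measurement window spans the last four pacing periods,
  # [onset_101, onset_104 + s); an APD whose upstroke falls inside the
  # window is measured in full even if it repolarises after it.
  window_start <- onsets[n_stimuli - 3] - 1e-9
  window_end <- onsets[n_stimuli] + s - 1e-9
  summ <- measure_apd(tr, params$v_gate)
  acts <- summ$activation_times
  iv <- summ$intervals
  last <- iv[iv$t_up >= window_start & iv$t_up < window_end & !iv$open, ,
             drop = FALSE]
  n_act <- sum(acts >= window_start & acts < window_end)
  structure(
    list(s = s, last_apds = last$apd, n_activations_last4 = n_act,
         behaviour = classify_behaviour(last$apd, n_act, tol_ms),
         intervals = iv, params = params),
    class = "dynamic_restitution"
  )
}

#' @export
print.dynamic_restitution <- function(x, ...) {
  cat(sprintf("<dynamic_restitution> S = %g ms: %s\n", x$s, x$behaviour))
  cat("  last-window APDs:",
      paste(signif(x$last_apds, 6), collapse = ", "), "\n")
  invisible(x)
}

#' Pacing-period scan of the dynamic restitution
#'
#' Decrements the pacing period `S` — by default from 700 ms to 300 ms in
#' 100 ms steps and then from 280 ms in 2 ms steps — running
#' [dynamic_restitution()] at each period, until the first `S` at which
#' not every stimulus of the measurement window produces an APD — the
#' onset of 2:1 block or, at extreme rates, total loss of capture; the
#' scan stops there.  Reports the bifurcation period (largest `S`
#' classified `"2:2"`) and that first failure period `s_no_apd`.
#'
#' @param params An [model_params()] object.
#' @param settings,n_stimuli,tol_ms,amplitude,duration Passed to
#'   [dynamic_restitution()].
#' @param s_coarse,s_fine_from,s_fine_step,s_floor Scan schedule (ms).
#' @return A `restitution_scan` object.  `tidy()` gives the per-period
#'   table (`s`, `n_activations_last4`, `apd_1`..`apd_4`, `behaviour`);
#'   `glance()` a one-row tibble with `s_bifurcation` and `s_no_apd`.
#' @examples
#' \donttest{
#' p <- fixture_params("ms2003", model = "mMS")
#' scan <- scan_dynamic_restitution(p)
#' glance(scan)   # s_bifurcation = 270, s_no_apd = 256
#' }
#' @export
scan_dynamic_restitution <- function(params,
                                     settings = solver_settings(record_dt = 0.05),
                                     n_stimuli = 104, tol_ms = 1,
                                     amplitude = 1.0, duration = 0.4,
                                     s_coarse = seq(700, 300, by = -100),
                                     s_fine_from = 280, s_fine_step = 2,
                                     s_floor = 100) {
  assert_params(params)
  s_values <- c(s_coarse,
                seq(s_fine_from, s_floor, by = -s_fine_step))
  rows <- list()
  s_no_apd <- NA_real_
  for (s in s_values) {
    dr <- dynamic_restitution(params, s, n_stimuli, settings, tol_ms,
                              amplitude, duration)
    apds <- c(dr$last_apds, rep(NA_real_, 4))[1:4]
    rows[[length(rows) + 1]] <- tibble::tibble(
      s = s, n_activations_last4 = dr$n_activations_last4,
      apd_1 = apds[1], apd_2 = apds[2], apd_3 = apds[3], apd_4 = apds[4],
      behaviour = dr$behaviour
    )
    if (length(dr$last_apds) < 4 || dr$n_activations_last4 < 4) {
      s_no_apd <- s
      break
    }
  }
  table <- dplyr::bind_rows(rows)
  bif <- table$s[table$behaviour == "2:2"]
  structure(
    list(table = table,
         s_bifurcation = if (length(bif)) max(bif) else NA_real_,
         s_no_apd = s_no_apd, params = params),
    class = "restitution_scan"
  )
}

#' @export
print.restitution_scan <- function(x, ...) {
  cat("<restitution_scan>", nrow(x$table), "pacing periods\n")
  cat("  bifurcation (largest S with 2:2):", x$s_bifurcation, "ms\n")
  cat("  first S with a non-producing stimulus:", x$s_no_apd, "ms\n")
  invisible(x)
}

#' @export
tidy.restitution_scan <- function(x, ...) x$table

#' @export
glance.restitution_scan <- function(x, ...) {
  tibble::tibble(s_bifurcation = x$s_bifurcation, s_no_apd = x$s_no_apd,
                 n_periods = nrow(x$table))
}

#' @export
autoplot.restitution_scan <- function(object, ...) {
  long <- tidyr::pivot_longer(object$table,
                              dplyr::starts_with("apd_"),
                              names_to = "beat", values_to = "apd")
  ggplot2::ggplot(dplyr::filter(long, !is.na(.data$apd)),
                  ggplot2::aes(x = .data$s, y = .data$apd,
                               shape = .data$beat)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "pacing period S (ms)", y = "APD (ms)") +
    ggplot2::theme_minimal()
}
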