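#' Robustness-study grid specification
#'
#' Inclusive arithmetic ranges over the four time constants, swept at a
#' fixed `v_gate`.  The defaults are the robustness-study grid used by the
#' package's pacemaker census: `tau_in` 0.05-0.5 by 0.05, `tau_out` 0.5-10
#' by 0.5, `tau_open` and `tau_close` 60-220 by 10 (all ms), `v_gate` 0.13
#' — 10 x 20 x 17 x 17 = 57,800 parameter sets.
#'
#' @param tau_in,tau_out,tau_open,tau_close Length-3 numeric
#'   `c(min, max, step)` for each axis (ms).
#' @param v_gate Fixed activation threshold for every set.
#' @return A `sweep_spec` object.
#' @export
sweep_spec <- function(tau_in = c(0.05, 0.5, 0.05),
                       tau_out = c(0.5, 10, 0.5),
                       tau_open = c(60, 220, 10),
                       tau_close = c(60, 220, 10),
                       v_gate = 0.13) {
  axes <- list(tau_in = tau_in, tau_out = tau_out,
               tau_open = tau_open, tau_close = tau_close)
  for (nm in names(axes)) {
    ax <- axes[[nm]]
    if (length(ax) != 3 || ax[3] <= 0 || ax[1] > ax[2])
      stop("`", nm, "` must be c(min, max, step) with step > 0 and ",
           "min <= max", call. = FALSE)
    k <- (ax[2] - ax[1]) / ax[3]
    if (abs(k - round(k)) > 1e-8)
      stop("`", nm, "`: (max - min) must be a multiple of step",
           call. = FALSE)
  }
  structure(c(axes, list(v_gate = v_gate)), class = "sweep_spec")
}

# Inclusive sequence by integer index arithmetic (no cumulative drift).
axis_seq <- function(ax) ax[1] + (0:round((ax[2] - ax[1]) / ax[3])) * ax[3]

#' Build the parameter grid
#'
#' Cartesian product of the four inclusive axis sequences, ordered with
#' `tau_in` outermost and `tau_close` innermost.
#'
#' @param spec A [sweep_spec()].
#' @return A tibble with columns `tau_in`, `tau_out`, `tau_open`,
#'   `tau_close` and one row per parameter set.
#' @examples
#' nrow(build_grid(sweep_spec()))  # 57800
#' @export
build_grid <- function(spec = sweep_spec()) {
  if (!inherits(spec, "sweep_spec"))
    stop("`spec` must be a sweep_spec()", call. = FALSE)
  tidyr::expand_grid(
    tau_in = axis_seq(spec$tau_in),
    tau_out = axis_seq(spec$tau_out),
    tau_open = axis_seq(spec$tau_open),
    tau_close = axis_seq(spec$tau_close)
  )
}

#' Drop unexcitable parameter sets
#'
#' Removes sets with `h_min^MS = 4 tau_in / tau_out >= 1`: for these the
#' nullcline branches never exist and no action potential can be produced,
#' so pacemaker classification is meaningless.
#'
#' @param grid A tibble with columns `tau_in` and `tau_out`.
#' @return The retained rows.
#' @examples
#' nrow(filter_excitable(build_grid()))  # 52598
#' @export
filter_excitable <- function(grid) {
  dplyr::filter(grid, 4 * .data$tau_in / .data$tau_out < 1)
}

#' Pacemaker census over a parameter grid
#'
#' For every parameter set, applies a single stimulus at `t = 0` (1.0/ms
#' for 0.4 ms), integrates 1200 ms with backward Euler, counts debounced
#' upward `v_gate` crossings, and labels the set a pacemaker when more than
#' one depolarisation occurred.  Sets are integrated independently in
#' compiled code, so the labels are identical for any chunking of the grid.
#'
#' The default `dt` of 0.05 ms is ample for activation counting (pacemaker
#' periods are hundreds of ms); `dt = 0.005` ms reproduces the
#' full-fidelity single-cell solver and can be used to audit labels on a
#' subsample.
#'
#' @param grid A tibble of parameter sets (columns `tau_in`, `tau_out`,
#'   `tau_open`, `tau_close`), e.g. from [build_grid()] +
#'   [filter_excitable()].
#' @param model `"MS"` or `"mMS"`.
#' @param v_gate Fixed threshold for every set.
#' @param dt Time step (ms).
#' @param t_end Horizon (ms).
#' @param amplitude,duration Stimulus pulse (1/ms, ms).
#' @param debounce Crossing merge window (ms).
#' @return A `pacemaker_sweep` object.  `tidy()` returns the grid with
#'   `n_activations` and `pacemaker` columns; `glance()` a one-row tibble
#'   with `n_sets`, `n_pacemaker`, `prop_pacemaker`.
#' @export
run_sweep <- function(grid, model = c("MS", "mMS"), v_gate = 0.13,
                      dt = 0.05, t_end = 1200, amplitude = 1.0,
                      duration = 0.4, debounce = 5) {
  model <- match.arg(model)
  need <- c("tau_in", "tau_out", "tau_open", "tau_close")
  if (!all(need %in% names(grid)))
    stop("`grid` needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  tau <- as.matrix(grid[, need])
  n_act <- sweep_cpp(if (model == "mMS") 1L else 0L, tau, v_gate, dt,
                     t_end, amplitude, duration, debounce, 1e-10, 50L)
  labels <- tibble::as_tibble(grid)
  labels$n_activations <- n_act
  labels$pacemaker <- n_act > 1L
  structure(
    list(labels = labels, model = model, v_gate = v_gate, dt = dt,
         t_end = t_end),
    class = "pacemaker_sweep"
  )
}

#' @export
print.pacemaker_sweep <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<pacemaker_sweep> %s model, %d sets, dt = %g ms\n",
              x$model, g$n_sets, x$dt))
  cat(sprintf("  pacemaker: %d (%.2f%%)\n", g$n_pacemaker,
              100 * g$prop_pacemaker))
  invisible(x)
}

#' @export
tidy.pacemaker_sweep <- function(x, ...) x$labels

#' @export
glance.pacemaker_sweep <- function(x, ...) {
  tibble::tibble(
    model = x$model,
    n_sets = nrow(x$labels),
    n_pacemaker = sum(x$labels$pacemaker, na.rm = TRUE),
    n_failed = sum(is.na(x$labels$n_activations)),
    prop_pacemaker = sum(x$labels$pacemaker, na.rm = TRUE) / nrow(x$labels)
  )
}

#' @export
autoplot.pacemaker_sweep <- function(object, ...) {
  dat <- dplyr::summarise(
    dplyr::group_by(object$labels, .data$tau_in, .data$tau_out),
    frac = mean(.data$pacemaker, na.rm = TRUE), .groups = "drop")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$tau_out, y = .data$tau_in,
                                    fill = .data$frac)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "pacemaker\nfraction",
                                  limits = c(0, 1)) +
    ggplot2::labs(x = "tau_out (ms)", y = "tau_in (ms)",
                  title = paste(object$model, "pacemaker census")) +
    ggplot2::theme_minimal()
}
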