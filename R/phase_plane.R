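#' Minimum gate value on the non-trivial nullcline
#'
#' The cubic nullcline `dvm/dt = 0` (for zero stimulus) has two non-trivial
#' branches `vm-` and `vm+` that exist only for `h` above a model-dependent
#' minimum:
#' \deqn{h_{min}^{MS} = 4\tau_{in}/\tau_{out}, \qquad
#'       h_{min}^{mMS} = \left(1 + \frac{\tau_{out}}{4\tau_{in}}
#'       (1-v_{gate})^2\right)^{-1}.}
#' `h_min >= 1` means the branches never exist for admissible `h` and the
#' model cannot sustain an action potential.
#'
#' @param params An [model_params()] object; the formula is chosen by its
#'   `model` field (the generalized model with `a = lambda = 0` is MS).
#' @return The minimum nullcline `h` (dimensionless).
#' @export
h_min <- function(params) {
  assert_params(params)
  if (params$model == "mMS") {
    1 / (1 + params$tau_out / (4 * params$tau_in) * (1 - params$v_gate)^2)
  } else {
    4 * params$tau_in / params$tau_out
  }
}

#' Nullcline branches of the ionic model
#'
#' Closed-form left (`vm-`) and right (`vm+`) branches of the non-trivial
#' `vm` nullcline:
#' \deqn{MS:\quad v_m^\pm(h) = \tfrac12\left(1 \pm
#'       \sqrt{1 - h_{min}^{MS}/h}\right)}
#' \deqn{mMS:\quad v_m^\pm(h) = \tfrac12\left(1 + v_{gate} \pm
#'       (1-v_{gate})\sqrt{1 - \frac{1-h}{h}
#'       \frac{h_{min}^{mMS}}{1-h_{min}^{mMS}}}\right)}
#' The trivial nullcline `vm = 0` is implicit and not returned.  At
#' `h = h_min` both branches merge into a single point; below it a domain
#' error is raised.  A radicand within 1e-14 below zero is clamped to 0 to
#' absorb round-off at the merge point.
#'
#' @param params An [model_params()] object.
#' @param h Gate values in `[h_min, 1]` (vectorised).
#' @return A tibble with columns `h`, `vm_minus`, `vm_plus`.
#' @examples
#' p <- fixture_params("ms2003", model = "MS")
#' nullclines(p, h = c(h_min(p), 0.5, 1))
#' @export
nullclines <- function(params, h = seq(h_min(params), 1, length.out = 201)) {
  assert_params(params)
  hm <- h_min(params)
  if (hm >= 1)
    stop("model is unexcitable: h_min = ", signif(hm, 6), " >= 1",
         call. = FALSE)
  if (any(h > 1)) stop("`h` must not exceed 1", call. = FALSE)
  if (params$model == "mMS") {
    rad <- 1 - (1 - h) / h * hm / (1 - hm)
  } else {
    rad <- 1 - hm / h
  }
  bad <- rad < -1e-14
  if (any(bad))
    stop("nullcline branches do not exist for h < h_min = ",
         signif(hm, 6), call. = FALSE)
  s <- sqrt(pmax(rad, 0))
  if (params$model == "mMS") {
    vg <- params$v_gate
    vm_minus <- 0.5 * (1 + vg - (1 - vg) * s)
    vm_plus <- 0.5 * (1 + vg + (1 - vg) * s)
  } else {
    vm_minus <- 0.5 * (1 - s)
    vm_plus <- 0.5 * (1 + s)
  }
  tibble::tibble(h = h, vm_minus = vm_minus, vm_plus = vm_plus)
}

#' Characteristic points of the phase plane
#'
#' The four named points of the `(vm, h)` phase plane:
#'
#' * `rest` (P0): the resting state `(0, 1)`, identical for both models.
#' * `depolarized` (P1): the end of the upstroke from rest, `(vm+(1), 1)`
#'   — `(1, 1)` for mMS.
#' * `merge` (P2): the point where the `vm-` and `vm+` branches meet,
#'   `((1+v_gate)/2, h_min)` for mMS and `(1/2, h_min)` for MS; near this
#'   point a trajectory "falls off" the nullcline into repolarisation.
#' * `threshold` (P3): the minimum potential on `vm-` at full recovery,
#'   `(vm-(1), 1)` — `(v_gate, 1)` for mMS; a stimulus must lift `vm`
#'   above this point to elicit an action potential from rest.
#'
#' @param params An [model_params()] object.
#' @return A tibble with columns `point`, `vm`, `h`.
#' @export
characteristic_points <- function(params) {
  assert_params(params)
  hm <- h_min(params)
  if (hm >= 1)
    stop("model is unexcitable: h_min = ", signif(hm, 6), " >= 1",
         call. = FALSE)
  at1 <- nullclines(params, h = 1)
  merge_vm <- if (params$model == "mMS") (1 + params$v_gate) / 2 else 0.5
  tibble::tibble(
    point = c("rest", "depolarized", "merge", "threshold"),
    vm = c(0, at1$vm_plus, merge_vm, at1$vm_minus),
    h = c(1, 1, hm, 1)
  )
}

#' Threshold value equalising the two models' restitution
#'
#' The activation threshold
#' \deqn{v_{gate}^* = 1 - \sqrt{1 - h_{min}^{MS}}}
#' is the value at which `h_min` of the mMS model equals `h_min` of the MS
#' model with the same time constants, making the two analytic restitution
#' curves (and `APD_max`) identical.
#'
#' @param params An [model_params()] object (only `tau_in` and `tau_out`
#'   are used).
#' @return The threshold (dimensionless).
#' @examples
#' v_gate_star(fixture_params("ms2003"))  # 0.105573
#' @export
v_gate_star <- function(params) {
  assert_params(params)
  hm <- 4 * params$tau_in / params$tau_out
  if (hm >= 1)
    stop("v_gate* undefined: h_min of the MS model is >= 1", call. = FALSE)
  1 - sqrt(1 - hm)
}

#' Phase-plane plot
#'
#' Draws the nullcline branches and characteristic points of a model, with
#' an optional simulated trajectory overlaid.
#'
#' @param params An [model_params()] object.
#' @param trace Optional `cell_trace` tibble from [simulate_cell()].
#' @return A ggplot object.
#' @export
plot_phase_plane <- function(params, trace = NULL) {
  nc <- nullclines(params)
  long <- tidyr::pivot_longer(nc, c("vm_minus", "vm_plus"),
                              names_to = "branch", values_to = "vm")
  pts <- characteristic_points(params)
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$vm, y = .data$h)) +
    ggplot2::geom_path(ggplot2::aes(linetype = .data$branch)) +
    ggplot2::geom_vline(xintercept = params$v_gate, colour = "grey50",
                        linetype = "dashed") +
    ggplot2::geom_point(data = pts, colour = "red") +
    ggplot2::labs(x = "vm (dimensionless)", y = "h",
                  title = paste(params$model, "phase plane")) +
    ggplot2::theme_minimal()
  if (!is.null(trace))
    p <- p + ggplot2::geom_path(data = trace, colour = "steelblue",
                                alpha = 0.8)
  p
}
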