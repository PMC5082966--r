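#' Ionic model parameter sets
#'
#' Constructs a validated parameter set for the two-variable cardiac ionic
#' models supported by the package:
#'
#' * `"MS"` — the Mitchell & Schaeffer (2003) model,
#'   \deqn{dv_m/dt = h v_m^2 (1-v_m)/\tau_{in} - v_m/\tau_{out} + J_{stim}.}
#' * `"mMS"` — the modified model, in which the cubic is shifted so that its
#'   middle root sits at `v_gate` and the outward current is gated by the
#'   complement of the recovery variable,
#'   \deqn{dv_m/dt = h v_m (v_m - v_{gate})(1-v_m)/\tau_{in} -
#'         (1-h) v_m/\tau_{out} + J_{stim}.}
#' * `"generalized"` — the excitability-controlled form
#'   \deqn{dv_m/dt = h (v_m+a)(v_m+a-\lambda)(1-v_m)/\tau_{in} -
#'         v_m/\tau_{out} + J_{stim},}
#'   of which MS is the case \eqn{a = \lambda = 0}.
#'
#' All three share the gate equation
#' \deqn{dh/dt = (1-h)/\tau_{open} \; (v_m \le v_{gate}), \quad
#'       dh/dt = -h/\tau_{close} \; (v_m > v_{gate}).}
#' The tie at `vm == v_gate` belongs to the opening branch.
#'
#' Voltage is dimensionless (rest at 0, plateau near 1); the four time
#' constants are in milliseconds and set the speed of the four phases of the
#' action potential (depolarisation, plateau, repolarisation, recovery).
#'
#' @param model One of `"MS"`, `"mMS"`, `"generalized"`.
#' @param tau_in,tau_out,tau_open,tau_close Positive time constants (ms).
#' @param v_gate Dimensionless activation threshold, in `[0, 1]`.  A value of
#'   1 is accepted (it is the degenerate limit in which no action potential
#'   can be elicited) but triggers a warning.
#' @param a,lambda Dimensionless excitability parameters of the generalized
#'   form; must be 0 for `"MS"` and are ignored by `"mMS"`.
#' @return An object of class `ionic_params` (a named list).
#' @examples
#' p <- model_params("mMS", 0.3, 6, 120, 150, v_gate = 0.13)
#' cell_rhs(p, vm = 0, h = 1)   # rest state is a fixed point
#' @export
model_params <- function(model = c("mMS", "MS", "generalized"),
                         tau_in, tau_out, tau_open, tau_close,
                         v_gate = 0.13, a = 0, lambda = 0) {
  model <- match.arg(model)
  taus <- c(tau_in = tau_in, tau_out = tau_out,
            tau_open = tau_open, tau_close = tau_close)
  if (any(!is.finite(taus)) || any(taus <= 0))
    stop("all four time constants must be finite and strictly positive",
         call. = FALSE)
  if (!is.finite(v_gate) || v_gate < 0 || v_gate > 1)
    stop("`v_gate` must lie in [0, 1]", call. = FALSE)
  if (v_gate == 1)
    warning("v_gate = 1: the excitation threshold equals the plateau ",
            "potential, so no action potential can be elicited",
            call. = FALSE)
  if (model == "MS" && (a != 0 || lambda != 0))
    stop("the MS model requires a = lambda = 0; ",
         "use model = \"generalized\" for non-zero values", call. = FALSE)
  if (model == "mMS" && (a != 0 || lambda != 0))
    stop("`a` and `lambda` do not apply to the mMS model", call. = FALSE)
  structure(
    list(model = model, tau_in = tau_in, tau_out = tau_out,
         tau_open = tau_open, tau_close = tau_close, v_gate = v_gate,
         a = a, lambda = lambda),
    class = "ionic_params"
  )
}

#' @export
print.ionic_params <- function(x, ...) {
  cat("<ionic_params> model:", x$model, "\n")
  cat(sprintf(
    "  tau_in = %g  tau_out = %g  tau_open = %g  tau_close = %g ms\n",
    x$tau_in, x$tau_out, x$tau_open, x$tau_close))
  cat(sprintf("  v_gate = %g", x$v_gate))
  if (x$model == "generalized")
    cat(sprintf("  a = %g  lambda = %g", x$a, x$lambda))
  cat("\n")
  invisible(x)
}

# Encoding used by the compiled stepper: 0 = generalised/MS, 1 = mMS.
model_code <- function(params) if (params$model == "mMS") 1L else 0L

param_vec <- function(params) {
  c(params$tau_in, params$tau_out, params$tau_open, params$tau_close,
    params$v_gate, params$a, params$lambda)
}

assert_params <- function(params) {
  if (!inherits(params, "ionic_params"))
    stop("`params` must be created with model_params() or fixture_params()",
         call. = FALSE)
  invisible(params)
}

#' Right-hand side of the ionic model
#'
#' Evaluates the time derivatives of the trans-membrane potential and the
#' gate variable for a parameter set, at one or more states.  Inputs are
#' vectorised over `vm`, `h` and `j_stim`.
#'
#' @param params An [model_params()] object.
#' @param vm Trans-membrane potential (dimensionless).
#' @param h Gate variable in `[0, 1]`.
#' @param j_stim Applied stimulus current density (1/ms); default 0.
#' @return A tibble with columns `vm`, `h`, `dvm_dt`, `dh_dt`.
#' @export
cell_rhs <- function(params, vm, h, j_stim = 0) {
  assert_params(params)
  n <- max(length(vm), length(h), length(j_stim))
  vm <- rep_len(vm, n); h <- rep_len(h, n); j_stim <- rep_len(j_stim, n)
  if (any(h < 0 | h > 1)) stop("`h` must lie in [0, 1]", call. = FALSE)
  if (params$model == "mMS") {
    dvm <- h * vm * (vm - params$v_gate) * (1 - vm) / params$tau_in -
      (1 - h) * vm / params$tau_out + j_stim
  } else {
    u <- vm + params$a
    dvm <- h * u * (u - params$lambda) * (1 - vm) / params$tau_in -
      vm / params$tau_out + j_stim
  }
  open <- gate_branch(params, vm) == "open"
  dh <- ifelse(open, (1 - h) / params$tau_open, -h / params$tau_close)
  tibble::tibble(vm = vm, h = h, dvm_dt = dvm, dh_dt = dh)
}

#' Gate branch in force at a potential
#'
#' The recovery variable opens (`(1-h)/tau_open`) while `vm <= v_gate` and
#' closes (`-h/tau_close`) while `vm > v_gate`; the tie at equality belongs
#' to the opening branch.
#'
#' @inheritParams cell_rhs
#' @return A character vector of `"open"` / `"close"`, one per element of
#'   `vm`.
#' @export
gate_branch <- function(params, vm) {
  assert_params(params)
  ifelse(vm <= params$v_gate, "open", "close")
}

#' Built-in parameter sets
#'
#' Named parameter sets used throughout the package's examples and tests:
#'
#' * `"ms2003"` — the set published by Mitchell & Schaeffer (2003)
#'   (`tau_in` 0.3, `tau_out` 6, `tau_open` 120, `tau_close` 150,
#'   `v_gate` 0.13).  The MS model is pacemaker-free here.
#' * `"pacemaker"` — a set (`tau_in` 0.1, `tau_out` 9, `tau_open` 100,
#'   `tau_close` 120, `v_gate` 0.13) for which the MS model self-oscillates
#'   after a single stimulus while the mMS model does not.
#' * `"tissue"` — the set used for the 2D monodomain examples (`tau_in`
#'   0.15, `tau_out` 6.5, `tau_open` 90, `tau_close` 85, `v_gate` 0.13),
#'   returned with a `diffusivity` attribute of 1.75 cm^2/s.
#' * `"sweep_grid"` — not a single set but the [sweep_spec()] defining the
#'   robustness-study grid over the four time constants.
#'
#' @param name One of `"ms2003"`, `"pacemaker"`, `"tissue"`, `"sweep_grid"`.
#' @param model Model variant to attach to the returned set (ignored for
#'   `"sweep_grid"`).
#' @return An `ionic_params` object, or a `sweep_spec` for `"sweep_grid"`.
#' @export
fixture_params <- function(name = c("ms2003", "pacemaker", "tissue",
                                    "sweep_grid"),
                           model = c("mMS", "MS", "generalized")) {
  name <- match.arg(name)
  model <- match.arg(model)
  switch(name,
    ms2003 = model_params(model, 0.3, 6, 120, 150, v_gate = 0.13),
    pacemaker = model_params(model, 0.1, 9, 100, 120, v_gate = 0.13),
    tissue = {
      p <- model_params(model, 0.15, 6.5, 90, 85, v_gate = 0.13)
      attr(p, "diffusivity") <- 1.75 # cm^2/s
      p
    },
    sweep_grid = sweep_spec()
  )
}

#' Serialise parameters to and from JSON
#'
#' The flat JSON schema has keys `model`, `tau_in`, `tau_out`, `tau_open`,
#' `tau_close`, `v_gate`, `a`, `lambda`; time constants in ms, the rest
#' dimensionless.
#'
#' @param params An [model_params()] object.
#' @param path File to write to / read from.
#' @return `params_write_json()` returns `params` invisibly;
#'   `params_read_json()` returns an `ionic_params` object.
#' @export
params_write_json <- function(params, path) {
  assert_params(params)
  x <- list(model = params$model, tau_in = params$tau_in,
            tau_out = params$tau_out, tau_open = params$tau_open,
            tau_close = params$tau_close, v_gate = params$v_gate,
            a = params$a, lambda = params$lambda)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(params)
}

#' @rdname params_write_json
#' @export
params_read_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- if (identical(x$model, "generalized")) "generalized" else x$model
  model_params(model, x$tau_in, x$tau_out, x$tau_open, x$tau_close,
               v_gate = x$v_gate,
               a = if (is.null(x$a)) 0 else x$a,
               lambda = if (is.null(x$lambda)) 0 else x$lambda)
}
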