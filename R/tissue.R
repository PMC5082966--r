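#' Tissue model parameters
#'
#' Geometry, diffusivity and time discretisation for the monodomain model
#' \deqn{\partial v_m/\partial t = D \nabla^2 v_m + I_{ion}(v_m, h) +
#'       J_{stim}}
#' on a homogeneous isotropic rectangular slab with zero-flux boundaries,
#' discretised on a structured grid (5-point Laplacian, nodes at spacing
#' `dx`).  Time stepping uses Godunov splitting: a per-node ionic backward
#' Euler step followed by an implicit (backward Euler) diffusion step.
#'
#' `diffusivity` is given in the conventional cm^2/s and converted to
#' cm^2/ms internally (1.75 cm^2/s = 1.75e-3 cm^2/ms).
#'
#' @param ionic An [model_params()] object.
#' @param lx,ly Domain size (cm); both must be multiples of `dx`.  `ly = 0`
#'   gives a 1D cable.
#' @param dx Grid spacing (cm).
#' @param diffusivity Isotropic diffusivity (cm^2/s).
#' @param dt Time step (ms).
#' @param t_end Simulation horizon (ms).
#' @return A `tissue_params` object.
#' @export
tissue_params <- function(ionic, lx = 5, ly = 5, dx = 0.02,
                          diffusivity = 1.75, dt = 0.1, t_end = 3500) {
  assert_params(ionic)
  if (dx <= 0 || diffusivity <= 0 || lx <= 0 || ly < 0 || dt <= 0)
    stop("`dx`, `diffusivity`, `lx`, `dt` must be positive and `ly` >= 0",
         call. = FALSE)
  nx <- round(lx / dx) + 1L
  ny <- if (ly == 0) 1L else round(ly / dx) + 1L
  if (abs((nx - 1) * dx - lx) > 1e-9 ||
      (ny > 1 && abs((ny - 1) * dx - ly) > 1e-9))
    stop("`lx` and `ly` must be integer multiples of `dx`", call. = FALSE)
  structure(
    list(ionic = ionic, lx = lx, ly = ly, dx = dx, nx = nx, ny = ny,
         diffusivity = diffusivity, dt = dt, t_end = t_end),
    class = "tissue_params"
  )
}

#' Rectangular region stimulus
#'
#' A constant current `amplitude` (1/ms) applied to every node whose
#' coordinates lie in the closed box, during `[onset, onset + duration)`.
#'
#' @param xmin,xmax,ymin,ymax Box bounds (cm).
#' @param onset Start time (ms).
#' @param amplitude Current density (1/ms).
#' @param duration Pulse width (ms).
#' @return A `region_stimulus` object.
#' @export
region_stimulus <- function(xmin, xmax, ymin, ymax, onset,
                            amplitude = 2.0, duration = 0.6) {
  if (xmax < xmin || ymax < ymin || duration <= 0)
    stop("invalid stimulus box or duration", call. = FALSE)
  structure(list(xmin = xmin, xmax = xmax, ymin = ymin, ymax = ymax,
                 onset = onset, amplitude = amplitude, duration = duration),
            class = "region_stimulus")
}

#' Cross-field stimulation protocol
#'
#' The standard spiral-initiation protocol: a first stimulus on the left
#' edge (`x` in `[0, 0.2]` cm, full height) at `t = 0`, and a second on the
#' bottom edge (`y` in `[0, 0.25]` cm, full width) at `t = t_s2`, both with
#' amplitude 2.0/ms for 0.6 ms.  The second pulse, timed into the
#' repolarisation tail of the first wave, launches a spiral (re-entrant)
#' wave.
#'
#' @param params A [tissue_params()] object; the domain must be at least
#'   0.2 cm wide and 0.25 cm tall.
#' @param t_s2 Onset of the second stimulus (ms).
#' @return A list of two [region_stimulus()] objects.
#' @export
crossfield_stimuli <- function(params, t_s2 = 290) {
  if (!inherits(params, "tissue_params"))
    stop("`params` must be a tissue_params()", call. = FALSE)
  if (params$lx < 0.2 || params$ly < 0.25)
    stop("domain smaller than the cross-field stimulus regions",
         call. = FALSE)
  list(
    s1 = region_stimulus(0, 0.2, 0, params$ly, onset = 0),
    s2 = region_stimulus(0, params$lx, 0, 0.25, onset = t_s2)
  )
}

# 1D Neumann (zero-flux) Laplacian stencil matrix, n x n.
laplacian_1d <- function(n) {
  if (n == 1) return(Matrix::Matrix(0, 1, 1, sparse = TRUE))
  main <- c(-1, rep(-2, n - 2), -1)
  Matrix::bandSparse(n, n, k = c(-1, 0, 1),
                     diagonals = list(rep(1, n - 1), main, rep(1, n - 1)),
                     symmetric = FALSE)
}

#' Simulate the monodomain tissue model
#'
#' Integrates the reaction-diffusion system with Godunov splitting (ionic
#' step, then implicit diffusion step; both backward Euler).  Node `(i, j)`
#' sits at coordinates `((i-1) dx, (j-1) dx)`.  The factorised implicit
#' diffusion operator preserves the spatial mean exactly (zero-flux
#' boundaries).
#'
#' @param params A [tissue_params()] object.
#' @param stimuli A list of [region_stimulus()] objects.
#' @param probes A data frame with columns `x`, `y` (cm); each probe is
#'   snapped to the nearest node and its `(vm, h)` recorded every step.
#'   Defaults to the domain centre and the point at 3/4 of each dimension.
#' @param snapshot_times Times (ms) at which the full `vm` field is stored.
#' @param ionic_on If `FALSE` the reaction term is skipped (pure
#'   diffusion), useful for conservation checks.
#' @param init Optional list with matrices `vm` and `h` (`nx` x `ny`)
#'   overriding the resting initial state.
#' @return A `tissue_result`: list with `probes` (tibble: `time`, `probe`,
#'   `x`, `y`, `vm`, `h`), `snapshots` (named list of `nx` x `ny`
#'   matrices), `params`, `stimuli`.
#' @export
simulate_monodomain <- function(params, stimuli = list(),
                                probes = NULL, snapshot_times = numeric(0),
                                ionic_on = TRUE, init = NULL) {
  if (!inherits(params, "tissue_params"))
    stop("`params` must be a tissue_params()", call. = FALSE)
  nx <- params$nx; ny <- params$ny; n <- nx * ny
  dx <- params$dx; dt <- params$dt
  d_ms <- params$diffusivity / 1000 # cm^2/s -> cm^2/ms
  xs <- (seq_len(nx) - 1) * dx
  ys <- (seq_len(ny) - 1) * dx

  alpha <- d_ms * dt / dx^2
  lap <- if (ny == 1) laplacian_1d(nx) else {
    Matrix::kronecker(Matrix::Diagonal(ny), laplacian_1d(nx)) +
      Matrix::kronecker(laplacian_1d(ny), Matrix::Diagonal(nx))
  }
  a_mat <- Matrix::Diagonal(n) - alpha * lap
  fac <- Matrix::Cholesky(Matrix::forceSymmetric(a_mat), LDL = FALSE)

  # Stimulus node masks and step windows.
  coord_x <- rep(xs, times = ny)
  coord_y <- rep(ys, each = nx)
  stim_info <- lapply(stimuli, function(s) {
    if (!inherits(s, "region_stimulus"))
      stop("`stimuli` must be region_stimulus() objects", call. = FALSE)
    idx <- which(coord_x >= s$xmin - 1e-12 & coord_x <= s$xmax + 1e-12 &
                 coord_y >= s$ymin - 1e-12 & coord_y <= s$ymax + 1e-12)
    if (!length(idx))
      stop("stimulus box contains no grid nodes", call. = FALSE)
    list(idx = idx, onset = s$onset, end = s$onset + s$duration,
         amp = s$amplitude)
  })

  if (is.null(probes)) {
    probes <- tibble::tibble(x = c(params$lx / 2, 0.75 * params$lx),
                             y = c(params$ly / 2, 0.75 * params$ly))
  }
  pi_idx <- vapply(seq_len(nrow(probes)), function(k) {
    i <- which.min(abs(xs - probes$x[k]))
    j <- which.min(abs(ys - probes$y[k]))
    as.integer((j - 1L) * nx + i)
  }, integer(1))

  vm <- if (!is.null(init)) as.numeric(init$vm) else rep(0, n)
  h <- if (!is.null(init)) as.numeric(init$h) else rep(1, n)

  n_steps <- round(params$t_end / dt)
  snap_steps <- round(snapshot_times / dt)
  snapshots <- list()
  n_probe <- length(pi_idx)
  probe_vm <- matrix(NA_real_, n_steps + 1, n_probe)
  probe_h <- matrix(NA_real_, n_steps + 1, n_probe)
  probe_vm[1, ] <- vm[pi_idx]; probe_h[1, ] <- h[pi_idx]

  mcode <- model_code(params$ionic)
  pvec <- param_vec(params$ionic)
  jbuf <- numeric(n)
  for (k in seq_len(n_steps)) {
    tmid <- (k - 0.5) * dt
    active <- Filter(function(s) tmid >= s$onset && tmid < s$end, stim_info)
    if (ionic_on) {
      if (length(active)) {
        jbuf[] <- 0
        for (s in active) jbuf[s$idx] <- jbuf[s$idx] + s$amp
        st <- ionic_step_field_cpp(mcode, pvec, vm, h, jbuf, dt, 1e-10, 50L)
      } else {
        st <- ionic_step_field_cpp(mcode, pvec, vm, h, numeric(n), dt,
                                   1e-10, 50L)
      }
      vm <- st$vm; h <- st$h
    } else if (length(active)) {
      jbuf[] <- 0
      for (s in active) jbuf[s$idx] <- jbuf[s$idx] + s$amp
      vm <- vm + dt * jbuf
    }
    vm <- as.numeric(Matrix::solve(fac, vm, system = "A"))
    probe_vm[k + 1, ] <- vm[pi_idx]; probe_h[k + 1, ] <- h[pi_idx]
    if (k %in% snap_steps)
      snapshots[[sprintf("t=%g", k * dt)]] <- matrix(vm, nx, ny)
    if (k %% 200 == 0) utils::flush.console()
  }

  probe_tbl <- purrr::map_dfr(seq_len(n_probe), function(p) {
    tibble::tibble(
      time = seq(0, by = dt, length.out = n_steps + 1),
      probe = p, x = xs[(pi_idx[p] - 1L) %% nx + 1L],
      y = ys[(pi_idx[p] - 1L) %/% nx + 1L],
      vm = probe_vm[, p], h = probe_h[, p]
    )
  })
  structure(
    list(probes = probe_tbl, snapshots = snapshots, params = params,
         stimuli = stimuli),
    class = "tissue_result"
  )
}

#' @export
print.tissue_result <- function(x, ...) {
  cat(sprintf("<tissue_result> %s, %g x %g cm, dx = %g cm, t_end = %g ms\n",
              x$params$ionic$model, x$params$lx, x$params$ly,
              x$params$dx, x$params$t_end))
  cat("  probes:", length(unique(x$probes$probe)),
      " snapshots:", length(x$snapshots), "\n")
  invisible(x)
}

#' Classify the tissue response after cross-field stimulation
#'
#' Inspects the probe traces after the second (spiral-initiating) stimulus:
#'
#' * `"sustained_activity"` — activations at some probe continue into the
#'   final 10% of `[t_s2, t_end]` (the re-entrant/pacemaker activity never
#'   stops);
#' * `"terminated_reentry"` — repeated post-`s2` activations occur but
#'   cease before that final window;
#' * `"no_reentry"` — at most the single `s2` wave passage is seen.
#'
#' @param result A `tissue_result` from [simulate_monodomain()], or a probe
#'   tibble with columns `time`, `probe`, `vm`.
#' @param v_gate Activation threshold; defaults to the ionic parameter set
#'   of `result`.
#' @param t_s2 Onset time of the second stimulus (ms); defaults to the
#'   latest stimulus onset in `result`.
#' @param t_end End of the simulation (ms).
#' @return A single classification string.
#' @export
classify_tissue_outcome <- function(result, v_gate = NULL, t_s2 = NULL,
                                    t_end = NULL) {
  if (inherits(result, "tissue_result")) {
    if (is.null(v_gate)) v_gate <- result$params$ionic$v_gate
    if (is.null(t_s2))
      t_s2 <- max(vapply(result$stimuli, `[[`, numeric(1), "onset"))
    if (is.null(t_end)) t_end <- result$params$t_end
    probes <- result$probes
  } else probes <- result
  if (is.null(v_gate) || is.null(t_s2) || is.null(t_end))
    stop("`v_gate`, `t_s2` and `t_end` are required", call. = FALSE)
  window_start <- t_end - 0.1 * (t_end - t_s2)
  per_probe <- split(probes, probes$probe)
  n_post <- 0L; sustained <- FALSE
  for (tr in per_probe) {
    acts <- detect_activations(tr, v_gate)
    post <- acts[acts > t_s2]
    n_post <- max(n_post, length(post))
    if (any(post >= window_start)) sustained <- TRUE
  }
  if (sustained) return("sustained_activity")
  if (n_post >= 2L) return("terminated_reentry")
  "no_reentry"
}
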