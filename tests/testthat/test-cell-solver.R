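test_that("stimulus and settings constructors validate their inputs", {
  expect_error(stimulus_train(c(10, 5)), "increasing")
  expect_error(stimulus_train(c(0, 0.2), duration = 0.4), "overlap")
  expect_error(stimulus_train(0, amplitude = -1), "non-negative")
  expect_error(solver_settings(dt = 0), "positive")
  expect_error(solver_settings(dt = 0.01, record_dt = 0.025), "multiple")
  s <- solver_settings(dt = 0.01, record_dt = 0.05)
  expect_equal(s$stride, 5L)
})

test_that("the rest state is a fixed point of the implicit map", {
  for (model in c("MS", "mMS")) {
    p <- ms_ref(model)
    out <- step_backward_euler(c(0, 1), p, 0, solver_settings(dt = 0.1))
    expect_equal(unname(out), c(0, 1))
  }
})

test_that("one backward Euler step is within O(dt^2) of the exact flow", {
  # oracle: adaptive high-order integration with the gate branch frozen the
  # same way the stepper freezes it (from the incoming vm)
  p <- pm_ref("mMS")
  ref <- desolve_reference(p, c(0, 0.005), init = c(0.5, 1),
                           branch = "close")
  be <- step_backward_euler(c(0.5, 1), p, 0, solver_settings(dt = 0.005))
  expect_lt(abs(be[["vm"]] - ref$vm[2]), 1e-4)
  expect_lt(abs(be[["h"]] - ref$h[2]), 1e-6)
})

test_that("backward Euler is consistent: (x' - x)/dt converges to the RHS", {
  p <- ms_ref("MS")
  state <- c(0.3, 0.8)
  r <- cell_rhs(p, state[1], state[2])
  errs <- vapply(c(1e-3, 1e-4, 1e-5), function(dt) {
    out <- step_backward_euler(state, p, 0, solver_settings(dt = dt))
    max(abs((out - state) / dt - c(r$dvm_dt, r$dh_dt)))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 1e-3)
})

test_that("the implicit h update matches its exponential solution to O(dt^2)", {
  p <- ms_ref("MS")
  h0 <- 0.6
  err_close <- vapply(c(0.1, 0.05, 0.025), function(dt) {
    be <- step_backward_euler(c(0.5, h0), p, 0, solver_settings(dt = dt))
    abs(be[["h"]] - h0 * exp(-dt / p$tau_close))
  }, numeric(1))
  # halving dt should shrink the error ~4x
  expect_true(all(err_close[-3] / err_close[-1] > 3))
  err_open <- vapply(c(0.1, 0.05, 0.025), function(dt) {
    be <- step_backward_euler(c(0.05, h0), p, 0, solver_settings(dt = dt))
    abs(be[["h"]] - (1 - (1 - h0) * exp(-dt / p$tau_open)))
  }, numeric(1))
  expect_true(all(err_open[-3] / err_open[-1] > 3))
})

test_that("activation detection interpolates threshold crossings", {
  tri <- triangle_trace(peak = 1, width = 10, thr = 0.13)
  expect_equal(detect_activations(tri$trace, 0.13), tri$t_up)
  # double pulse: two ordered crossings
  tr2 <- tri$trace
  tr2b <- dplyr::mutate(tr2, time = time + max(tr2$time) + 0.5)
  both <- dplyr::bind_rows(tr2, tr2b)
  expect_equal(detect_activations(both, 0.13),
               c(tri$t_up, tri$t_up + max(tr2$time) + 0.5))
  # monotone trace below threshold: nothing
  flat <- tibble::tibble(time = 0:100, vm = seq(0, 0.1, length.out = 101))
  expect_equal(detect_activations(flat, 0.13), numeric(0))
  # trace starting above threshold counts an activation at its first sample
  high <- tibble::tibble(time = 0:10, vm = c(rep(0.5, 5), rep(0, 6)))
  expect_equal(detect_activations(high, 0.13)[1], 0)
})

test_that("measure_apd pairs crossings and reports square-pulse widths", {
  w <- 37.5
  tt <- seq(0, 100, by = 0.5)
  sq <- tibble::tibble(time = tt, vm = as.numeric(tt >= 10 & tt < 10 + w))
  iv <- tidy(measure_apd(sq, 0.5))
  expect_equal(nrow(iv), 1)
  expect_equal(iv$apd, w, tolerance = 1e-10)
  tri <- triangle_trace()
  iv2 <- tidy(measure_apd(tri$trace, 0.13))
  expect_equal(iv2$apd, tri$t_down - tri$t_up)
  none <- measure_apd(tibble::tibble(time = 0:10, vm = rep(0, 11)), 0.13)
  expect_equal(nrow(tidy(none)), 0)
  # unterminated interval flagged open and excluded from statistics
  ramp <- tibble::tibble(time = 0:10, vm = seq(0, 1, length.out = 11))
  summ <- measure_apd(ramp, 0.5)
  expect_true(tidy(summ)$open)
  expect_equal(glance(summ)$n_apd, 0)
})

test_that("single-stimulus activation counts reproduce the published runs", {
  st <- stimulus_train(0)
  cfg <- solver_settings(dt = 0.005, record_dt = 0.05)
  # original MS-2003 parameters: pacemaker-free
  n1 <- measure_apd(simulate_cell(ms_ref("MS"), st, 1200, cfg))
  expect_equal(n1$n_activations, 1)
  expect_false(classify_pacemaker(n1))
  # pacemaker parameter set: MS self-reactivates (4 beats), mMS does not
  n2 <- measure_apd(simulate_cell(pm_ref("MS"), st, 1200, cfg))
  expect_equal(n2$n_activations, 4)
  expect_true(classify_pacemaker(n2))
  n3 <- measure_apd(simulate_cell(pm_ref("mMS"), st, 1200, cfg))
  expect_equal(n3$n_activations, 1)
  expect_false(classify_pacemaker(n3))
})

test_that("measured mMS APD is within 15% of the leading-order APD_max", {
  p <- pm_ref("mMS")
  tr <- simulate_cell(p, stimulus_train(0), 700,
                      solver_settings(dt = 0.005, record_dt = 0.05))
  apd <- tidy(measure_apd(tr))$apd[1]
  expect_lt(abs(apd - apd_max_analytic(p)) / apd_max_analytic(p), 0.15)
})

test_that("dt refinement changes vm by under 1% of its amplitude", {
  p <- ms_ref("MS")
  tr1 <- simulate_cell(p, stimulus_train(0), 500,
                       solver_settings(dt = 0.005, record_dt = 0.05))
  tr2 <- simulate_cell(p, stimulus_train(0), 500,
                       solver_settings(dt = 0.0005, record_dt = 0.05))
  expect_lt(max(abs(tr1$vm - tr2$vm)), 0.01 * max(abs(tr2$vm)))
})

test_that("unstimulated solutions stay inside the physical box", {
  set.seed(9)
  corners <- expand.grid(tau_in = c(0.05, 0.5), tau_out = c(0.5, 10),
                         tau_open = c(60, 220), tau_close = c(60, 220))
  for (model in c("MS", "mMS")) {
    for (i in seq_len(nrow(corners))) {
      p <- model_params(model, corners$tau_in[i], corners$tau_out[i],
                        corners$tau_open[i], corners$tau_close[i])
      init <- c(runif(1), runif(1))
      tr <- simulate_cell(p, stimulus_train(numeric(0)), 50,
                          solver_settings(dt = 0.01), init = init)
      expect_true(all(tr$vm >= -1e-6 & tr$vm <= 1 + 1e-6))
      expect_true(all(tr$h >= 0 & tr$h <= 1))
    }
  }
})

test_that("the mMS recovery never reaches the left nullcline branch", {
  # numerical form of the no-pacemaker argument: while vm < v_gate the
  # trajectory stays left of vm-(h)
  p <- pm_ref("mMS")
  tr <- simulate_cell(p, stimulus_train(0), 1200,
                      solver_settings(dt = 0.005, record_dt = 0.05))
  iv <- tidy(measure_apd(tr))
  rec <- tr[tr$time > iv$t_down[1] & tr$vm < p$v_gate &
              tr$h >= h_min(p) + 1e-9, ]
  expect_gt(nrow(rec), 1000)
  vm_minus <- nullclines(p, h = rec$h)$vm_minus
  expect_true(all(rec$vm < vm_minus))
})

test_that("traces round-trip through CSV bitwise", {
  p <- ms_ref("MS")
  tr <- simulate_cell(p, stimulus_train(0), 5, solver_settings(dt = 0.05))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(tr, path)
  back <- read_trace_csv(path)
  expect_identical(back$vm, tr$vm)
  expect_identical(back$h, tr$h)
  expect_identical(back$time, tr$time)
  # empty table gives a header-only file
  write_table_csv(tr[0, c("time", "vm", "h")], path)
  expect_equal(readLines(path), "time,vm,h")
})
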