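tissue_ref <- function(model = "mMS", ...) {
  p <- fixture_params("tissue", model = model)
  tissue_params(p, diffusivity = attr(p, "diffusivity"), ...)
}

test_that("geometry and stimulus validation", {
  p <- fixture_params("tissue")
  expect_error(tissue_params(p, lx = 1, dx = 0.03), "multiples")
  expect_error(region_stimulus(1, 0, 0, 1, onset = 0), "invalid")
  tp <- tissue_ref(lx = 0.1, ly = 0.1, dx = 0.05, t_end = 1)
  expect_error(crossfield_stimuli(tp), "smaller")
  tp2 <- tissue_ref(lx = 5, ly = 5, dx = 0.5, t_end = 1)
  st <- crossfield_stimuli(tp2)
  expect_equal(st$s1[c("xmin", "xmax", "ymin", "ymax", "onset")],
               list(xmin = 0, xmax = 0.2, ymin = 0, ymax = 5, onset = 0))
  expect_equal(st$s2[c("xmin", "xmax", "ymin", "ymax", "onset")],
               list(xmin = 0, xmax = 5, ymin = 0, ymax = 0.25,
                    onset = 290))
  expect_equal(st$s1$amplitude, 2.0)
  expect_equal(st$s2$duration, 0.6)
})

test_that("an unstimulated slab stays at rest", {
  tp <- tissue_ref(lx = 0.5, ly = 0.5, dx = 0.05, t_end = 50)
  r <- simulate_monodomain(tp, list(), snapshot_times = 50)
  expect_true(all(r$snapshots[["t=50"]] == 0))
  expect_true(all(r$probes$vm == 0) && all(r$probes$h == 1))
})

test_that("the implicit diffusion step conserves total vm exactly", {
  tp <- tissue_ref(lx = 1, ly = 1, dx = 0.05, t_end = 20)
  set.seed(1)
  n <- tp$nx
  init <- list(vm = matrix(runif(n * n), n, n), h = matrix(1, n, n))
  r <- simulate_monodomain(tp, list(), ionic_on = FALSE, init = init,
                           snapshot_times = 20)
  expect_lt(abs(sum(r$snapshots[["t=20"]]) - sum(init$vm)) / sum(init$vm),
            1e-10)
})

test_that("a spatially uniform stimulus reproduces the 0D solution", {
  # diffusion vanishes by symmetry, so every node must follow the cell ODE
  p <- fixture_params("tissue", model = "mMS")
  tp <- tissue_ref("mMS", lx = 0.4, ly = 0.4, dx = 0.05, t_end = 400)
  stim <- list(region_stimulus(0, 0.4, 0, 0.4, onset = 0, amplitude = 1,
                               duration = 0.4))
  r <- simulate_monodomain(tp, stim, probes = data.frame(x = 0.2, y = 0.2))
  tr0 <- simulate_cell(p, stimulus_train(0, 1, 0.4), 400,
                       solver_settings(dt = tp$dt))
  expect_lt(max(abs(r$probes$vm - tr0$vm)), 1e-10)
  expect_lt(max(abs(r$probes$h - tr0$h)), 1e-10)
})

test_that("a planar wave travels at a constant, mesh-robust velocity", {
  stc <- list(region_stimulus(0, 0.1, 0, 0, onset = 0, amplitude = 2,
                              duration = 0.6))
  tpc <- tissue_ref("mMS", lx = 2, ly = 0, dx = 0.02, t_end = 60)
  rc <- simulate_monodomain(tpc, stc,
                            probes = data.frame(x = c(0.8, 1.2, 1.6),
                                                y = 0))
  acts <- vapply(split(rc$probes, rc$probes$probe),
                 function(tr) detect_activations(tr, 0.13)[1], numeric(1))
  cv1 <- 0.4 / (acts[2] - acts[1])
  cv2 <- 0.4 / (acts[3] - acts[2])
  expect_gt(cv1, 0)
  expect_lt(abs(cv2 - cv1) / cv1, 0.05)
  # halving dx moves a distal activation time by well under 5%
  tpf <- tissue_ref("mMS", lx = 2, ly = 0, dx = 0.01, t_end = 60)
  rf <- simulate_monodomain(tpf, stc, probes = data.frame(x = 1.6, y = 0))
  tf <- detect_activations(rf$probes, 0.13)[1]
  expect_lt(abs(tf - acts[3]) / acts[3], 0.05)
})

test_that("tissue outcomes are classified from post-s2 probe activity", {
  mk <- function(pulse_times, t_end = 1000, dt = 1) {
    tt <- seq(0, t_end, by = dt)
    vm <- rep(0, length(tt))
    for (tp in pulse_times) vm[tt >= tp & tt < tp + 20] <- 1
    tibble::tibble(time = tt, probe = 1, vm = vm)
  }
  # one paced beat then silence: no reentry
  expect_equal(classify_tissue_outcome(mk(50), v_gate = 0.13, t_s2 = 290,
                                       t_end = 1000), "no_reentry")
  # repeated post-s2 beats that cease before the final window
  expect_equal(classify_tissue_outcome(mk(c(50, 320, 420, 520)),
                                       v_gate = 0.13, t_s2 = 290,
                                       t_end = 1000), "terminated_reentry")
  # activity running into the final 10% of the interval
  expect_equal(classify_tissue_outcome(mk(c(50, 320, 520, 720, 960)),
                                       v_gate = 0.13, t_s2 = 290,
                                       t_end = 1000), "sustained_activity")
})

test_that("tissue parameters are pacemaker-free in a single cell and cable", {
  cfg <- solver_settings(dt = 0.01, record_dt = 0.05)
  for (model in c("MS", "mMS")) {
    p <- fixture_params("tissue", model = model)
    summ <- measure_apd(simulate_cell(p, stimulus_train(0), 1200, cfg))
    expect_equal(summ$n_activations, 1)
    # 1D cable: a single edge stimulus elicits exactly one wave passage
    tpc <- tissue_ref(model, lx = 2, ly = 0, dx = 0.02, t_end = 1200)
    stc <- list(region_stimulus(0, 0.1, 0, 0, onset = 0, amplitude = 2,
                                duration = 0.6))
    rc <- simulate_monodomain(tpc, stc,
                              probes = data.frame(x = c(1, 1.8), y = 0))
    for (tr in split(rc$probes, rc$probes$probe))
      expect_equal(length(detect_activations(tr, p$v_gate)), 1)
  }
})
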