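test_that("the forward model is deterministic", {
  r1 <- run_simulation(default_config(), cycles = 3, dt = 1)
  r2 <- run_simulation(default_config(), cycles = 3, dt = 1)
  expect_identical(r1$hemo, r2$hemo)
  expect_identical(r1$strain, r2$strain)
})

test_that("halving the step changes peak LV pressure by < 0.5 mmHg", {
  r1 <- run_simulation(default_config(), cycles = 8, dt = 1)
  r2 <- run_simulation(default_config(), cycles = 8, dt = 0.5)
  expect_lt(
    abs(summarize_hemodynamics(r1)$p_lv_max - summarize_hemodynamics(r2)$p_lv_max),
    0.5
  )
})

test_that("configuration validation rejects bad engine settings", {
  expect_error(run_simulation(default_config(), dt = 2), "time step")
  expect_error(run_simulation(default_config(), cycles = 3, transient = 5),
    "transient")
  expect_error(
    as_model_config(list(mechanics = list(segments = data.frame(
      name = "mid_anterior", k_act = 1.5
    )))),
    "contractility"
  )
})

test_that("baseline waveforms are physiological", {
  res <- baseline_run()
  rows <- which(res$time >= 9 * 900)
  h <- res$hemo[rows, ]
  # one ejection per cycle and biphasic (E and A wave) filling
  ej_runs <- rle(h$q_aortic > 0)
  expect_equal(sum(ej_runs$values), 1)
  fill <- h$q_mitral
  peaks <- sum(diff(sign(diff(fill))) == -2 & fill[2:(length(fill) - 1)] > 20)
  expect_gte(peaks, 2)
  s <- summarize_hemodynamics(res)
  expect_true(s$edv > s$esv && s$ef > 0 && s$ef < 100)
})

test_that("blood volume is conserved to < 0.1 mL over 20 cycles", {
  res <- cached("run20", run_simulation(default_config(), cycles = 20, dt = 1))
  vols <- res$hemo[, c(
    "v_lv", "v_rv", "v_ra", "v_la", "v_ao", "v_sa", "v_sv",
    "v_vc", "v_pa", "v_pc", "v_pu"
  )]
  total <- rowSums(vols)
  expect_lt(max(total) - min(total), 0.1)
})

test_that("valve flows are non-negative at every sample", {
  res <- cached("run20", run_simulation(default_config(), cycles = 20, dt = 1))
  expect_true(all(res$hemo$q_mitral >= 0))
  expect_true(all(res$hemo$q_aortic >= 0))
  expect_true(all(res$hemo$q_tricuspid >= 0))
  expect_true(all(res$hemo$q_pulmonary >= 0))
})

test_that("the simulation settles on a limit cycle (< 0.5% beat-to-beat)", {
  res <- cached("run20", run_simulation(default_config(), cycles = 20, dt = 1))
  peaks <- vapply(17:20, function(k) {
    rows <- res$time >= (k - 1) * 900 & res$time <= k * 900
    max(res$hemo$p_lv[rows])
  }, numeric(1))
  expect_lt(max(abs(diff(peaks))) / peaks[1], 0.005)
})

test_that("strain returns to its reference between consecutive cycles", {
  res <- cached("run20", run_simulation(default_config(), cycles = 20, dt = 1))
  # compare fiber lengths at consecutive cycle reference times
  i1 <- which.min(abs(res$time - 18 * 900))
  i2 <- which.min(abs(res$time - 19 * 900))
  drift <- 100 * abs(res$lengths[i2, ] - res$lengths[i1, ]) / res$lengths[i1, ]
  expect_true(all(drift < 0.5))
})

test_that("isovolumic phases conserve cavity volume", {
  res <- baseline_run()
  rows <- which(res$time >= 9 * 900)
  h <- res$hemo[rows, ]
  iso <- which(h$q_mitral == 0 & h$q_aortic == 0)
  iso <- iso[iso > 1 & iso < nrow(h)]
  # with valves closed, wall motion is exactly offset by cavity-node
  # storage: the reported LV volume does not change
  runs <- split(iso, cumsum(c(1, diff(iso) != 1)))
  for (r in runs) {
    expect_lt(max(h$v_lv[r]) - min(h$v_lv[r]), 0.02)
  }
  # and the net segment flow equals the (small) cavity-node storage rate
  lv <- aha_segments()
  sum_q <- rowSums(res$seg_flows[rows, lv])
  e_cav <- res$config$mechanics$cavity$lv$e
  dp <- c(NA, diff(h$p_lv)) / (res$dt / 1000)
  expect_equal(sum_q[iso], (dp / e_cav)[iso], tolerance = 0.15)
})

test_that("the aortic flow integral matches EDV - ESV", {
  res <- baseline_run()
  rows <- which(res$time >= 9 * 900)
  h <- res$hemo[rows, ]
  sv_flow <- sum(h$q_aortic) * res$dt / 1000
  s <- summarize_hemodynamics(res)
  expect_equal(sv_flow, s$stroke_volume, tolerance = 0.05)
})

test_that("segment power balances load power plus resistive losses", {
  res <- baseline_run()
  rows <- which(res$time >= 9 * 900)
  dt <- res$dt / 1000
  seg_tab <- res$config$mechanics$segments
  h <- res$hemo[rows, ]
  lhs <- 0
  rhs <- 0
  for (i in seq_len(nrow(seg_tab))) {
    p <- as.list(seg_tab[i, ])
    p$lt_slope <- res$config$mechanics$lt_slope
    p$lt_max <- res$config$mechanics$lt_max
    nm <- p$name
    u <- res$drive[rows, nm]
    l <- res$lengths[rows, nm]
    q <- res$seg_flows[rows, nm]
    t_tot <- active_tension(u, l, p) + passive_tension(l / p$l0 - 1, p)
    p_seg <- t_tot / p$area_w
    load <- septal_load(nm, h$p_lv, h$p_rv)
    lhs <- lhs + sum(p_seg * q) * dt
    rhs <- rhs + sum(load * q) * dt + sum(p$r_h * q^2) * dt
  }
  expect_equal(lhs, rhs, tolerance = 0.02)
})

test_that("equal parameters and simultaneous activation give identical strains", {
  res <- run_simulation(simultaneous_lv_config(), cycles = 8, dt = 1)
  fs <- final_strain(res)
  spread <- apply(fs$strain, 1, function(r) diff(range(r)))
  expect_lt(max(spread), 1)
})

test_that("baseline LV strain minima fall inside a 30 ms window", {
  res <- baseline_run()
  fs <- final_strain(res)
  tmin <- apply(fs$strain, 2, function(x) fs$time[which.min(x)])
  expect_lt(diff(range(tmin)), 30)
})

test_that("reducing one segment's contractility reduces its peak shortening monotonically", {
  peaks <- vapply(c(1, 0.6, 0.3, 0), function(k) {
    cfg <- as_model_config(list(mechanics = list(segments = data.frame(
      name = "mid_anterior", k_act = k
    ))))
    res <- run_simulation(cfg, cycles = 7, dt = 1)
    min(final_strain(res)$strain[, "mid_anterior"])
  }, numeric(1))
  expect_true(all(diff(peaks) > 0)) # less negative as k_act decreases
})

test_that("summaries reject degenerate volume traces", {
  res <- baseline_run()
  fake <- res
  fake$hemo$v_lv <- 70
  expect_error(summarize_hemodynamics(fake), "EDV")
})
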