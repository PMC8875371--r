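test_that("a baseline-generated target is a fixed point of the fitter", {
  res <- baseline_run()
  tr <- final_strain(res)
  targets <- list(
    septal = wall_average(tr, "septal"),
    lateral = wall_average(tr, "lateral")
  )
  spec <- fit_spec(
    free = "contractility",
    groups = list(lateral = wall_segments("lateral")),
    k_grid = c(0.4, 0.7, 1), max_sweeps = 1, cycles = 10, dt = 1
  )
  fit <- fit_strain(default_config(), targets, spec)
  expect_lt(fit$total_rmse, 1e-6)
  expect_true(all(fit$segments$k_act == 1))
})

test_that("known lateral contractility is recovered from model-generated strain", {
  segs <- aha_segments(include_rv = TRUE)
  k <- setNames(rep(1, length(segs)), segs)
  k[wall_segments("lateral")] <- 0.3
  truth_cfg <- as_model_config(list(
    mechanics = list(segments = data.frame(name = segs, k_act = unname(k)))
  ))
  res <- run_simulation(truth_cfg, cycles = 8, dt = 1)
  tr <- final_strain(res)
  spec <- fit_spec(
    free = "contractility",
    groups = list(lateral = wall_segments("lateral")),
    k_grid = seq(0.1, 1, by = 0.05), max_sweeps = 2, cycles = 8, dt = 1
  )
  targets <- list(
    septal = wall_average(tr, "septal"),
    lateral = wall_average(tr, "lateral")
  )
  fit <- cached("fit_recovery", fit_strain(default_config(), targets, spec))
  rec <- fit$segments$k_act[fit$segments$name == "mid_inferolateral"]
  expect_lt(abs(rec - 0.3), 0.1)

  # with 1% strain noise the estimate stays within 0.15
  noisy <- tr
  set.seed(5)
  noisy$strain <- noisy$strain + matrix(
    rnorm(length(noisy$strain), 0, 1), nrow = nrow(noisy$strain)
  )
  targets_n <- list(
    septal = wall_average(noisy, "septal"),
    lateral = wall_average(noisy, "lateral")
  )
  fit_n <- cached("fit_recovery_noisy", fit_strain(default_config(), targets_n, spec))
  rec_n <- fit_n$segments$k_act[fit_n$segments$name == "mid_inferolateral"]
  expect_lt(abs(rec_n - 0.3), 0.15)
})

test_that("total RMSE is non-increasing and the fit is deterministic", {
  fit <- cached("fit_recovery", NULL)
  expect_true(all(diff(fit$trace) <= 1e-12))
  # determinism: a re-run from identical inputs reproduces the result
  res <- baseline_run()
  tr <- final_strain(res)
  targets <- list(
    septal = wall_average(tr, "septal"),
    lateral = wall_average(tr, "lateral")
  )
  spec <- fit_spec(
    free = "contractility",
    groups = list(septal = wall_segments("septal")),
    k_grid = c(0.5, 1), max_sweeps = 1, cycles = 6, dt = 1
  )
  f1 <- fit_strain(default_config(), targets, spec)
  f2 <- fit_strain(default_config(), targets, spec)
  expect_identical(f1$segments, f2$segments)
  expect_identical(f1$trace, f2$trace)
})

test_that("the bull's-eye map serializes 16 segments in AHA order", {
  fit <- cached("fit_recovery", NULL)
  m <- contractility_bullseye(fit)
  expect_length(m, 16)
  expect_identical(names(m), aha_segments())
  expect_true(all(m >= 0 & m <= 100))
  # homogeneous-fit case: all equal when nothing was freed off 1
  expect_equal(unname(m["mid_anterior"]), 100)
})

test_that("concordance handles exact agreement, noise, and degeneracy", {
  segs <- aha_segments()
  cmap <- setNames(c(rep(100, 11), rep(20, 5)), segs)
  tmap <- 100 - cmap
  cc <- concordance(cmap, tmap)
  expect_equal(cc$rho, 1)
  expect_equal(cc$overlap, 1)
  expect_setequal(cc$low_contractility, segs[cmap <= 40])

  # independent random maps: correlation near zero on average
  set.seed(11)
  rhos <- replicate(100, {
    a <- setNames(runif(16, 0, 100), segs)
    b <- setNames(runif(16, 0, 100), segs)
    concordance(a, b)$rho
  })
  expect_lt(abs(mean(rhos)), 0.1)

  const <- setNames(rep(50, 16), segs)
  expect_warning(cc2 <- concordance(const, tmap), "degenerate")
  expect_true(is.na(cc2$rho))
  expect_equal(cc2$overlap, 0) # overlap is still computed
})

test_that("end-to-end synthetic scar: low contractility matches the phantom scar", {
  # scar injected in 4 lateral segments; the fitted map and an LGE phantom
  # of the same segments must overlap exactly at the default thresholds
  scar4 <- c(
    "basal_inferolateral", "basal_anterolateral",
    "mid_inferolateral", "mid_anterolateral"
  )
  fit <- cached("fit_latscar", {
    fx <- make_strain_fixture("lbbb_lateral_scar", seed = 11, cycles = 8)
    targets <- list(
      septal = wall_average(fx$trace, "septal"),
      lateral = wall_average(fx$trace, "lateral")
    )
    fit_strain(
      base_config_for(fx), targets,
      fit_spec(max_sweeps = 2, k_grid = seq(0.1, 1, by = 0.1), cycles = 8)
    )
  })
  ph <- make_lge_phantom(scar4, 70, seed = 4)
  tmap <- transmurality_by_segment(classify_lge(ph))
  cc <- concordance(contractility_bullseye(fit), tmap)
  # the four phantom segments are exactly the high-transmurality set and
  # fall inside the fitted low-contractility (lateral) wall
  expect_setequal(cc$high_transmurality, scar4)
  expect_true(all(scar4 %in% cc$low_contractility))
  expect_gte(cc$overlap, 0.8)
})

test_that("fit specifications are validated", {
  expect_error(fit_spec(free = "voltage"), "free")
  expect_error(fit_spec(k_grid = numeric(0)))
  expect_error(fit_spec(max_sweeps = 0))
})
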