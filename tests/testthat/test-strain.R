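mk_trace <- function(t, cols) {
  strain_trace(time = t, strain = do.call(cbind, cols))
}

test_that("wall averages are unweighted means over the defined segments", {
  t <- seq(0, 800, by = 10)
  base <- -18 * sin(pi * pmin(t, 400) / 400)
  segs <- wall_segments("septal")
  same <- setNames(rep(list(base), 5), segs)
  w <- wall_average(mk_trace(t, same), "septal")
  expect_equal(w$strain, base)
  expect_equal(sort(w$segments), sort(segs))
  # constant curves average arithmetically
  consts <- setNames(as.list(c(-10, -20, -15, -5, -25)), segs)
  cc <- lapply(consts, function(v) rep(v, length(t)))
  expect_equal(unique(wall_average(mk_trace(t, cc), "septal")$strain), -15)
  # permutation invariance
  w2 <- wall_average(mk_trace(t, cc[c(3, 1, 5, 2, 4)]), "septal")
  expect_equal(w2$strain, wall_average(mk_trace(t, cc), "septal")$strain)
})

test_that("wall definitions use exactly the five named segments each", {
  expect_setequal(wall_segments("septal"), c(
    "apical_septal", "mid_inferoseptal", "basal_inferoseptal",
    "mid_anteroseptal", "basal_anteroseptal"
  ))
  expect_setequal(wall_segments("lateral"), c(
    "apical_lateral", "mid_inferolateral", "basal_inferolateral",
    "mid_anterolateral", "basal_anterolateral"
  ))
  expect_length(intersect(wall_segments("septal"), wall_segments("lateral")), 0)
  expect_length(wall_segments("remaining"), 6)
  # missing segment reported by name
  t <- 0:10
  part <- setNames(rep(list(rep(-1, 11)), 4), wall_segments("septal")[1:4])
  expect_error(wall_average(mk_trace(t, part), "septal"), "basal_anteroseptal")
})

test_that("strain trace construction validates its inputs", {
  expect_error(strain_trace(c(0, 1, 1), matrix(0, 3, 1,
    dimnames = list(NULL, "mid_anterior"))), "increasing")
  expect_error(strain_trace(0:2, matrix(c(0, NA, 0), 3, 1,
    dimnames = list(NULL, "mid_anterior"))), "finite")
  expect_error(strain_trace(0:2, matrix(0, 3, 1,
    dimnames = list(NULL, "made_up"))), "accepted names")
})

test_that("RMSE behaves as a metric on the resampled grid", {
  t <- seq(0, 900, by = 5)
  a <- list(time = t, strain = -15 * sin(pi * t / 900))
  b <- list(time = t, strain = a$strain + 2)
  expect_equal(strain_rmse(a, a), 0)
  expect_equal(strain_rmse(a, b), 2, tolerance = 1e-9)
  set.seed(42)
  curves <- replicate(6, list(
    time = t, strain = cumsum(rnorm(length(t), 0, 0.5))
  ), simplify = FALSE)
  for (i in 1:5) {
    x <- curves[[i]]
    y <- curves[[i + 1]]
    z <- curves[[sample(6, 1)]]
    expect_equal(strain_rmse(x, y), strain_rmse(y, x)) # symmetry
    expect_gte(
      strain_rmse(x, y) + strain_rmse(y, z),
      strain_rmse(x, z) - 1e-9
    ) # triangle inequality
  }
  # different RR: cycle normalization aligns the curves
  a2 <- list(time = t * 1.2, strain = a$strain)
  expect_equal(strain_rmse(a, a2), 0, tolerance = 1e-9)
  expect_error(
    strain_rmse(a, list(time = t + 5000, strain = a$strain),
      normalize_time = FALSE),
    "non-overlapping"
  )
})

test_that("sample RMSE of pure noise matches its chi-distribution scale", {
  t <- seq(0, 900, length.out = 200)
  base <- list(time = t, strain = -18 * sin(pi * t / 900))
  set.seed(7)
  vals <- replicate(50, {
    noisy <- list(time = t, strain = base$strain + rnorm(200, 0, 1.5))
    strain_rmse(base, noisy)
  })
  expect_true(all(vals > 1.2 & vals < 1.8))
  expect_equal(mean(vals), 1.5, tolerance = 0.03)
})

test_that("monotone shortening is not a septal flash", {
  t <- seq(0, 900, by = 5)
  mono <- list(time = t, strain = -18 * sin(pi * pmin(t, 500) / 1000))
  f <- detect_features(mono, c(150, 450))
  expect_false(f$septal_flash)
  expect_equal(f$rebound_stretch, 0)
})

test_that("template morphologies carry the documented flash pattern", {
  flags <- vapply(
    c("lbbb_nonischemic", "lbbb_lateral_scar", "lbbb_anteroseptal_scar"),
    function(nm) {
      fx <- make_strain_fixture(nm, mode = "template", seed = 1, noise_sd = 0)
      sw <- wall_average(fx$trace, "septal")
      detect_features(sw, fx$ejection)$septal_flash
    },
    logical(1)
  )
  expect_identical(unname(flags), c(TRUE, FALSE, TRUE))
  # lateral scar: septal deformation exceeds the non-ischemic case
  sp <- function(nm) {
    fx <- make_strain_fixture(nm, mode = "template", seed = 1, noise_sd = 0)
    max(abs(wall_average(fx$trace, "septal")$strain))
  }
  expect_gt(sp("lbbb_lateral_scar"), sp("lbbb_nonischemic"))
})

test_that("adding a positive bump before valve closure never reduces rebound", {
  t <- seq(0, 900, by = 5)
  y <- -6 * exp(-(t - 120)^2 / (2 * 40^2)) - 10 * exp(-(t - 450)^2 / (2 * 90^2))
  base <- list(time = t, strain = y)
  window <- c(180, 420)
  r0 <- detect_features(base, window)$rebound_stretch
  for (amp in c(1, 3, 5)) {
    bumped <- list(
      time = t,
      strain = y + amp * exp(-(t - 300)^2 / (2 * 30^2))
    )
    r1 <- detect_features(bumped, window)$rebound_stretch
    expect_gte(r1, r0 - 1e-9)
    r0 <- r1
  }
})

test_that("feature windows outside the curve support are rejected", {
  t <- seq(100, 500, by = 5)
  c0 <- list(time = t, strain = -10 * sin(pi * (t - 100) / 400))
  expect_error(detect_features(c0, c(50, 400)), "alignment")
  expect_error(detect_features(c0, c(400, 300)), "alignment")
})
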