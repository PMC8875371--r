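#' Specify a strain-personalization problem
#'
#' The personalization mimics a one-parameter-at-a-time manual adjustment:
#' deterministic cyclic coordinate descent in which each free parameter is
#' grid-scanned within its bounds, keeping the value that minimizes the sum
#' of septal- and lateral-wall RMSE. Parameters are freed per wall group
#' (septal 5, lateral 5, remaining 6 segments) by default, which keeps the
#' problem identifiable from two target curves; per-segment freeing is
#' available when 16 target traces exist.
#'
#' @param free parameter categories to free, scanned in the declared order:
#'   `"delay"` (electromechanical onset delay per group), `"contractility"`
#'   (`k_act` per group), `"tau"` (global relaxation constant), `"passive"`
#'   (global passive stiffness scale factor).
#' @param groups named list mapping group name to segment names.
#' @param delay_grid candidate added delays (ms) on top of the baseline
#'   electromechanical delay.
#' @param k_grid candidate contractility fractions.
#' @param tau_grid candidate relaxation time constants (ms).
#' @param passive_grid candidate passive-scale multipliers.
#' @param max_sweeps maximum full sweeps over all free parameters.
#' @param tol stop when a full sweep improves total RMSE by less than this
#'   (% strain).
#' @param cycles,dt simulation settings for objective evaluations.
#' @param refine after the grid scan, polish each contractility with a
#'   bounded 1-D derivative-free minimization (off by default).
#' @return list of class `fit_spec`.
#' @export
fit_spec <- function(free = c("delay", "contractility"),
                     groups = list(
                       septal = wall_segments("septal"),
                       lateral = wall_segments("lateral"),
                       remaining = wall_segments("remaining")
                     ),
                     delay_grid = seq(0, 45, by = 15),
                     k_grid = seq(0.1, 1, by = 0.05),
                     tau_grid = c(25, 33, 45, 60),
                     passive_grid = c(0.5, 0.75, 1, 1.5),
                     max_sweeps = 3, tol = 0.05,
                     cycles = 8, dt = 1, refine = FALSE) {
  stopifnot(
    all(free %in% c("delay", "contractility", "tau", "passive")),
    length(delay_grid) > 0, length(k_grid) > 0,
    all(is.finite(c(delay_grid, k_grid, tau_grid, passive_grid))),
    max_sweeps >= 1, tol >= 0
  )
  structure(
    list(
      free = free, groups = groups, delay_grid = delay_grid,
      k_grid = k_grid, tau_grid = tau_grid, passive_grid = passive_grid,
      max_sweeps = max_sweeps, tol = tol, cycles = cycles, dt = dt,
      refine = refine
    ),
    class = "fit_spec"
  )
}

set_fit_param <- function(cfg, param, value) {
  seg <- cfg$mechanics$segments
  if (param$type == "delay") {
    idx <- seg$name %in% param$segments
    seg$t_delay[idx] <- param$base_value + value
  } else if (param$type == "contractility") {
    seg$k_act[seg$name %in% param$segments] <- value
  } else if (param$type == "tau") {
    seg$tau_r[!seg$name %in% rv_segments()] <- value
  } else if (param$type == "passive") {
    idx <- !seg$name %in% rv_segments()
    seg$k_p1[idx] <- param$base_kp1[idx] * value
  }
  cfg$mechanics$segments <- seg
  cfg
}

#' Personalize a model to septal and lateral strain targets
#'
#' Deterministic cyclic coordinate descent over the free parameters of
#' `spec`, in the declared order (delays, contractility, driving time
#' constant, passive scale). Each parameter is scanned over its grid, the
#' model is re-simulated, and the value minimizing septal + lateral wall
#' RMSE is kept; a failed simulation scores `Inf` and is skipped. Sweeps
#' stop when the total RMSE improvement falls below `spec$tol` or the sweep
#' budget is exhausted. Total RMSE is non-increasing across accepted steps,
#' and identical inputs yield identical results.
#'
#' @param config starting `model_config` (typically an LBBB configuration at
#'   the patient's RR; see [profile_config()]).
#' @param targets list with `septal` and `lateral` `wall_curve` objects.
#' @param spec a `fit_spec`.
#' @param verbose print per-parameter progress.
#' @return list of class `fit_result`: `config` (fitted), `segments`
#'   (fitted table), `rmse` (named: septal, lateral), `total_rmse`,
#'   `contractility` (16-segment map, %), `delays` (16-segment
#'   electromechanical onset map, ms), `trace` (objective after each
#'   accepted parameter update), `n_eval` (simulation count), `converged`.
#' @export
fit_strain <- function(config, targets, spec = fit_spec(), verbose = FALSE) {
  cfg <- as_model_config(config)
  stopifnot(inherits(spec, "fit_spec"),
    is.list(targets), !is.null(targets$septal), !is.null(targets$lateral))

  n_eval <- 0L
  last_sim <- NULL
  objective <- function(cc) {
    n_eval <<- n_eval + 1L
    res <- tryCatch(
      run_simulation(cc, cycles = spec$cycles, dt = spec$dt),
      error = function(e) NULL
    )
    if (is.null(res)) {
      return(list(total = Inf, sep = Inf, lat = Inf, res = NULL))
    }
    tr <- final_strain(res)
    sep <- strain_rmse(wall_average(tr, "septal"), targets$septal)
    lat <- strain_rmse(wall_average(tr, "lateral"), targets$lateral)
    list(total = sep + lat, sep = sep, lat = lat, res = res)
  }

  base_seg <- cfg$mechanics$segments
  params <- list()
  for (f in spec$free) {
    if (f %in% c("delay", "contractility")) {
      for (g in names(spec$groups)) {
        params[[paste(f, g, sep = ".")]] <- list(
          type = f, group = g, segments = spec$groups[[g]],
          grid = if (f == "delay") spec$delay_grid else spec$k_grid,
          base_value = stats::median(
            base_seg$t_delay[base_seg$name %in% spec$groups[[g]]]
          ),
          base_kp1 = base_seg$k_p1
        )
      }
    } else {
      params[[f]] <- list(
        type = f, segments = character(0),
        grid = if (f == "tau") spec$tau_grid else spec$passive_grid,
        base_value = 0, base_kp1 = base_seg$k_p1
      )
    }
  }

  cur <- objective(cfg)
  best <- cur$total
  trace <- best
  converged <- FALSE
  for (sweep in seq_len(spec$max_sweeps)) {
    sweep_start <- best
    for (pn in names(params)) {
      p <- params[[pn]]
      scores <- vapply(p$grid, function(v) {
        objective(set_fit_param(cfg, p, v))$total
      }, numeric(1))
      if (all(!is.finite(scores))) next
      j <- which.min(scores) # ties: first (lowest) grid value wins
      if (scores[j] < best) {
        best <- scores[j]
        cfg <- set_fit_param(cfg, p, p$grid[j])
        if (verbose) {
          message(sprintf("  %s = %.3g -> RMSE %.3f", pn, p$grid[j], best))
        }
      }
      trace <- c(trace, best)
    }
    if (sweep_start - best < spec$tol) {
      converged <- TRUE
      break
    }
  }

  if (spec$refine) {
    for (pn in names(params)) {
      p <- params[[pn]]
      if (p$type != "contractility") next
      opt <- optimize(
        function(v) objective(set_fit_param(cfg, p, v))$total,
        interval = range(spec$k_grid), tol = 0.01
      )
      if (opt$objective < best) {
        best <- opt$objective
        cfg <- set_fit_param(cfg, p, opt$minimum)
        trace <- c(trace, best)
      }
    }
  }

  final <- objective(cfg)
  seg <- cfg$mechanics$segments
  lv <- aha_segments()
  onsets <- final$res$activation[[spec$cycles]][lv]
  delays <- onsets + seg$t_delay[match(lv, seg$name)]
  structure(
    list(
      config = cfg, segments = seg,
      rmse = c(septal = final$sep, lateral = final$lat),
      total_rmse = final$total,
      contractility = setNames(100 * seg$k_act[match(lv, seg$name)], lv),
      delays = setNames(delays, lv),
      trace = trace, n_eval = n_eval, converged = converged
    ),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(
    "<fit_result> RMSE septal %.2f%% lateral %.2f%% (%d simulations%s)\n",
    x$rmse["septal"], x$rmse["lateral"], x$n_eval,
    if (x$converged) ", converged" else ""
  ))
  invisible(x)
}

#' 16-segment contractility map from a fit
#'
#' Contractility (% of nominal peak active tension) per LV segment in AHA
#' order, ready for bull's-eye display or CSV serialization.
#'
#' @param fit a `fit_result`.
#' @return named numeric vector of length 16 (percent).
#' @export
contractility_bullseye <- function(fit) {
  stopifnot(inherits(fit, "fit_result"))
  fit$contractility[aha_segments()]
}

#' Concordance between contractility and scar transmurality maps
#'
#' Computes (a) the Spearman rank correlation between contractility deficit
#' (100 - contractility) and LGE transmurality, and (b) the Jaccard overlap
#' between the low-contractility segment set and the high-transmurality
#' segment set at the given thresholds.
#'
#' @param contractility named 16-segment contractility map (%).
#' @param transmurality named 16-segment transmurality map (%).
#' @param low contractility threshold (%) below-or-equal which a segment is
#'   "low contractility".
#' @param high transmurality threshold (%) at-or-above which a segment is
#'   "high transmurality".
#' @return list with `rho` (Spearman correlation of deficit vs
#'   transmurality; `NA` with a warning if either map is constant),
#'   `overlap` (Jaccard fraction; `NaN` if both sets are empty), and the
#'   two index sets.
#' @export
concordance <- function(contractility, transmurality, low = 40, high = 60) {
  segs <- aha_segments()
  stopifnot(all(segs %in% names(contractility)), all(segs %in% names(transmurality)))
  cmap <- contractility[segs]
  tmap <- transmurality[segs]
  deficit <- 100 - cmap
  rho <- if (length(unique(cmap)) < 2 || length(unique(tmap)) < 2) {
    warning("degenerate (constant) map: rank correlation undefined")
    NA_real_
  } else {
    stats::cor(deficit, tmap, method = "spearman")
  }
  low_set <- segs[cmap <= low]
  high_set <- segs[tmap >= high]
  uni <- union(low_set, high_set)
  overlap <- if (length(uni) == 0) NaN else length(intersect(low_set, high_set)) / length(uni)
  list(rho = rho, overlap = overlap, low_contractility = low_set,
    high_transmurality = high_set)
}

#' Baseline configuration for fitting a patient dataset
#'
#' Chooses an LBBB network when the QRS is wide (> 120 ms), sets the RR
#' interval from the dataset, and maps the QRS width to a trans-septal
#' myocardial conduction delay via the package's calibrated linear rule.
#'
#' @param dataset a `patient_dataset` (or list with `rr` and `qrs`).
#' @return a `model_config`.
#' @export
base_config_for <- function(dataset) {
  lbbb <- dataset$qrs > 120
  myo <- if (lbbb) max(10, round(29 + (dataset$qrs - 135) / 3)) else 1
  as_model_config(list(
    conduction = list(rr = dataset$rr, lbbb = lbbb, myocardial_delay = myo)
  ))
}
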