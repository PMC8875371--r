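#' Construct a strain trace object
#'
#' A strain trace is a set of per-segment longitudinal strain time series on
#' a common, strictly increasing, cycle-relative time grid. Strain follows
#' the echocardiographic convention: percent, negative for shortening.
#'
#' @param time time grid (ms, cycle-relative), strictly increasing.
#' @param strain numeric matrix (time x segments) with AHA segment names as
#'   column names.
#' @return object of class `strain_trace`.
#' @export
strain_trace <- function(time, strain) {
  strain <- as.matrix(strain)
  if (length(time) != nrow(strain)) stop("time and strain dimensions differ")
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  if (any(!is.finite(strain))) stop("strain values must be finite")
  known <- aha_segments(include_rv = TRUE)
  bad <- setdiff(colnames(strain), known)
  if (length(bad)) {
    stop(
      "unknown segment name(s): ", paste(bad, collapse = ", "),
      "; accepted names are: ", paste(known, collapse = ", ")
    )
  }
  structure(list(time = time, strain = strain), class = "strain_trace")
}

#' @export
print.strain_trace <- function(x, ...) {
  cat(
    "<strain_trace> ", ncol(x$strain), " segments, ", length(x$time),
    " samples over ", round(max(x$time) - min(x$time)), " ms\n",
    sep = ""
  )
  invisible(x)
}

#' Wall-averaged strain curve
#'
#' The septal and lateral wall curves are the pointwise unweighted means of
#' the five strain curves of their constituent segments (see
#' [wall_segments()]).
#'
#' @param trace a `strain_trace` containing (at least) the five segments of
#'   the requested wall.
#' @param wall `"septal"` or `"lateral"`.
#' @return object of class `wall_curve`: list with `time`, `strain`, `wall`,
#'   `segments`.
#' @export
wall_average <- function(trace, wall = c("septal", "lateral")) {
  wall <- match.arg(wall)
  segs <- wall_segments(wall)
  missing <- setdiff(segs, colnames(trace$strain))
  if (length(missing)) {
    stop(
      "wall '", wall, "' is missing segment(s): ",
      paste(missing, collapse = ", ")
    )
  }
  structure(
    list(
      time = trace$time,
      strain = rowMeans(trace$strain[, segs, drop = FALSE]),
      wall = wall, segments = segs
    ),
    class = "wall_curve"
  )
}

#' @export
print.wall_curve <- function(x, ...) {
  cat(
    "<wall_curve> ", x$wall, " wall (", length(x$segments),
    " segments), peak ", sprintf("%.1f", x$strain[which.max(abs(x$strain))],
    ), "%\n",
    sep = ""
  )
  invisible(x)
}

as_wall_curve <- function(x) {
  if (inherits(x, "wall_curve")) return(x)
  stopifnot(is.list(x), !is.null(x$time), !is.null(x$strain))
  structure(
    list(
      time = x$time, strain = x$strain,
      wall = if (is.null(x$wall)) "unknown" else x$wall,
      segments = x$segments
    ),
    class = "wall_curve"
  )
}

#' Root-mean-square error between two strain curves
#'
#' Both curves are resampled by linear interpolation onto a common grid of
#' `n` points. By default the grid is cycle-normalized (fraction of each
#' curve's own time support), so curves from beats of different length are
#' compared over one cycle; set `normalize_time = FALSE` to compare on the
#' overlapping absolute time support instead.
#'
#' @param sim,obs `wall_curve` objects (or lists with `time` and `strain`).
#' @param n number of resampling points.
#' @param normalize_time resample on a fraction-of-cycle axis.
#' @return RMSE in % strain.
#' @export
strain_rmse <- function(sim, obs, n = 200, normalize_time = TRUE) {
  sim <- as_wall_curve(sim)
  obs <- as_wall_curve(obs)
  if (normalize_time) {
    fs <- (sim$time - min(sim$time)) / diff(range(sim$time))
    fo <- (obs$time - min(obs$time)) / diff(range(obs$time))
    grid <- seq(0, 1, length.out = n)
    a <- approx(fs, sim$strain, grid)$y
    b <- approx(fo, obs$strain, grid)$y
  } else {
    lo <- max(min(sim$time), min(obs$time))
    hi <- min(max(sim$time), max(obs$time))
    if (hi <= lo) stop("alignment error: curves have non-overlapping time supports")
    grid <- seq(lo, hi, length.out = n)
    a <- approx(sim$time, sim$strain, grid)$y
    b <- approx(obs$time, obs$strain, grid)$y
  }
  sqrt(mean((a - b)^2))
}

#' Detect LBBB deformation pattern features on a wall curve
#'
#' Quantifies the septal-flash morphology: pre-ejection shortening is the
#' magnitude of the strain minimum reached before aortic valve opening;
#' rebound stretch is the maximal re-lengthening above that early minimum
#' before valve closure. The flash flag requires both to exceed their
#' thresholds.
#'
#' @param curve a `wall_curve`.
#' @param window ejection window `c(t_open, t_close)` in the curve's time
#'   base (ms), e.g. from [ejection_window()].
#' @param shorten_threshold minimal pre-ejection shortening (%) for a flash.
#' @param rebound_threshold minimal rebound stretch (%) for a flash.
#' @return list of class `pattern_features`: `septal_flash` (logical),
#'   `pre_ejection_shortening`, `rebound_stretch`, `peak_strain`,
#'   `time_to_peak`.
#' @export
detect_features <- function(curve, window, shorten_threshold = 1.5,
                            rebound_threshold = 1.0) {
  curve <- as_wall_curve(curve)
  t <- curve$time
  y <- curve$strain
  if (window[1] < min(t) || window[2] > max(t) || window[2] <= window[1]) {
    stop("alignment error: ejection window outside curve support")
  }
  pre <- which(t <= window[1])
  sys <- which(t <= window[2])
  i_min <- pre[which.min(y[pre])]
  # a genuine pre-ejection dip requires the curve to fall below its value at
  # cycle start; the relaxation tail of the previous beat (which starts low
  # and rises) must not count as pre-ejection shortening
  dipped <- y[i_min] < y[pre[1]] - 0.5 && y[i_min] < 0
  pre_short <- if (dipped) abs(y[i_min]) else 0
  # rebound: maximal re-lengthening above the early minimum, after it but
  # before valve closure
  later <- sys[sys >= i_min]
  rebound <- if (dipped) max(0, max(y[later]) - y[i_min]) else 0
  flash <- pre_short >= shorten_threshold && rebound >= rebound_threshold
  i_peak <- which.max(abs(y))
  structure(
    list(
      septal_flash = flash,
      pre_ejection_shortening = pre_short,
      rebound_stretch = rebound,
      peak_strain = y[i_peak],
      time_to_peak = t[i_peak]
    ),
    class = "pattern_features"
  )
}

#' @export
print.pattern_features <- function(x, ...) {
  cat(sprintf(
    paste0(
      "septal flash            : %s\n",
      "pre-ejection shortening : %.2f %%\n",
      "rebound stretch         : %.2f %%\n",
      "peak strain             : %.2f %% at %.0f ms\n"
    ),
    if (x$septal_flash) "yes" else "no",
    x$pre_ejection_shortening, x$rebound_stretch, x$peak_strain, x$time_to_peak
  ))
  invisible(x)
}
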