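#' Default ECG waveform templates
#'
#' Each automaton contributes a parametric asymmetric-Gaussian wave placed at
#' its activation onset; ventricular automata additionally contribute a
#' repolarization wave placed at the end of their absolute refractory period.
#' Amplitudes are in arbitrary millivolt-like units; only timing quantities
#' (in particular QRS width) are treated as quantitative.
#'
#' @return nested list of per-class template parameters (`amp` amplitude,
#'   `sl`/`sr` left/right Gaussian widths in ms, plus the `t_wave` template).
#' @export
ecg_templates <- function() {
  list(
    atrial = list(amp = 0.12, sl = 14, sr = 18),
    ventricular_lv = list(amp = 1.0, sl = 7, sr = 13),
    ventricular_rv = list(amp = -0.35, sl = 7, sr = 13),
    t_wave = list(amp = 0.035, sl = 30, sr = 40)
  )
}

asym_gauss <- function(t, t0, amp, sl, sr) {
  s <- ifelse(t < t0, sl, sr)
  amp * exp(-(t - t0)^2 / (2 * s^2))
}

#' Synthesize an ECG from conduction events
#'
#' Sums the per-node template waveforms placed at each activation onset
#' (P waves for atrial automata, QRS contributions for the ventricular wall
#' segments) and a repolarization (T) wave placed at the end of each
#' ventricular segment's absolute refractory period.
#'
#' @param events event data frame from [advance()].
#' @param network the `conduction_network` that produced the events (supplies
#'   per-node ARP durations for T-wave placement).
#' @param templates template list as from [ecg_templates()].
#' @param sample_period sample period (ms).
#' @param until trace duration (ms); defaults to last event + 500 ms.
#' @return object of class `ecg_trace`: list with `time` (ms), `signal`
#'   (mV, arbitrary calibration) and `sample_period`.
#' @export
synthesize_ecg <- function(events, network, templates = ecg_templates(),
                           sample_period = 1, until = NULL) {
  if (!is.numeric(sample_period) || sample_period <= 0) {
    stop("sample_period must be > 0")
  }
  if (is.null(until)) {
    until <- if (nrow(events)) max(events$time) + 500 else 1000
  }
  time <- seq(0, until, by = sample_period)
  signal <- numeric(length(time))
  if (nrow(events)) {
    cls <- node_class(events$node)
    lv <- aha_segments()
    for (k in seq_len(nrow(events))) {
      nd <- events$node[k]
      t0 <- events$time[k]
      if (cls[k] == "atrial") {
        tp <- templates$atrial
        signal <- signal + asym_gauss(time, t0, tp$amp, tp$sl, tp$sr)
      } else if (cls[k] == "ventricular") {
        tp <- if (nd %in% lv) templates$ventricular_lv else templates$ventricular_rv
        signal <- signal + asym_gauss(time, t0, tp$amp, tp$sl, tp$sr)
        arp <- network$nodes$t_arp[match(nd, network$nodes$id)]
        tw <- templates$t_wave
        t_rep <- t0 + events$udp[k] + arp
        signal <- signal + asym_gauss(time, t_rep, tw$amp, tw$sl, tw$sr)
      }
    }
  }
  structure(
    list(time = time, signal = signal, sample_period = sample_period),
    class = "ecg_trace"
  )
}

#' @export
print.ecg_trace <- function(x, ...) {
  cat(
    "<ecg_trace> ", length(x$time), " samples @ ", x$sample_period,
    " ms (", max(x$time), " ms)\n",
    sep = ""
  )
  invisible(x)
}

#' Measure QRS width from an ECG trace
#'
#' Detects ventricular complexes as contiguous runs where the absolute signal
#' exceeds a fraction of the global peak absolute amplitude, merges runs
#' separated by short gaps, discards low-amplitude complexes (P and T waves),
#' and returns the mean complex width.
#'
#' @param ecg an `ecg_trace`.
#' @param frac detection threshold as a fraction of peak |amplitude|.
#' @param merge_gap merge super-threshold runs separated by less than this
#'   gap (ms) into one complex.
#' @param peak_frac keep only complexes whose own peak reaches this fraction
#'   of the global peak (rejects P/T deflections).
#' @return mean QRS width (ms).
#' @export
measure_qrs <- function(ecg, frac = 0.05, merge_gap = 40, peak_frac = 0.5) {
  x <- abs(ecg$signal)
  pk <- max(x)
  if (!is.finite(pk) || pk <= 0) stop("no ventricular complex detected: flat trace")
  above <- x >= frac * pk
  if (!any(above)) stop("no ventricular complex detected")
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  # merge runs separated by < merge_gap
  gap_samples <- merge_gap / ecg$sample_period
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1) {
    for (k in 2:nrow(runs)) {
      if (runs$start[k] - merged$end[nrow(merged)] <= gap_samples) {
        merged$end[nrow(merged)] <- runs$end[k]
      } else {
        merged <- rbind(merged, runs[k, ])
      }
    }
  }
  peaks <- vapply(
    seq_len(nrow(merged)),
    function(k) max(x[merged$start[k]:merged$end[k]]),
    numeric(1)
  )
  keep <- peaks >= peak_frac * pk
  if (!any(keep)) stop("no ventricular complex detected")
  merged <- merged[keep, , drop = FALSE]
  widths <- (ecg$time[merged$end] - ecg$time[merged$start]) + ecg$sample_period
  mean(widths)
}
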