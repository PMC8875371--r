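#' Run the closed-loop electromechanical simulation
#'
#' Couples the four sub-models: the discrete-event conduction simulation is
#' run first (there is no mechano-electrical feedback), its activation onsets
#' are quantized to the integration grid, and the continuous states (segment
#' fiber lengths and piston flows, cavity nodes, atria and circulation
#' chambers) are integrated with fixed-step RK4. The forward model contains
#' no randomness: identical configurations give identical results.
#'
#' @param config a `model_config` (see [default_config()], [as_model_config()],
#'   [load_config()]), or a plain list of overrides.
#' @param cycles,dt,transient optional overrides of the engine section.
#' @return object of class `sim_result` with elements `time` (ms), `hemo`
#'   (data frame of pressures, volumes and valve flows), `lengths`, `strain`
#'   and `drive` (time x 19 segment matrices; strain in %, referenced per
#'   cycle to the first ventricular activation), `ecg`, `events`,
#'   `activation` (per-cycle activation maps), and run metadata.
#' @export
#' @examples
#' \donttest{
#' res <- run_simulation(default_config(), cycles = 8, dt = 1)
#' summarize_hemodynamics(res)
#' }
run_simulation <- function(config = default_config(), cycles = NULL,
                           dt = NULL, transient = NULL) {
  cfg <- as_model_config(config)
  if (!is.null(cycles)) {
    cfg$engine$cycles <- cycles
    cfg$engine$transient <- min(cfg$engine$transient, cycles - 1)
  }
  if (!is.null(dt)) cfg$engine$dt <- dt
  if (!is.null(transient)) cfg$engine$transient <- transient
  validate_config(cfg)

  rr <- cfg$conduction$rr
  dt <- cfg$engine$dt
  n_cycles <- cfg$engine$cycles
  t_end <- rr * n_cycles
  n_steps <- round(t_end / dt)

  net <- build_network(
    rr = rr, lbbb = isTRUE(cfg$conduction$lbbb),
    myocardial_delay = cfg$conduction$myocardial_delay,
    phases = cfg$conduction$phases,
    links = cfg$conduction$links,
    rrp_response = cfg$conduction$rrp_response,
    event_cap = cfg$conduction$event_cap
  )
  events <- advance(net, t_end)

  seg_tab <- cfg$mechanics$segments
  segs <- seg_tab$name
  quant <- function(x) round(x / dt) * dt  # events applied at step boundaries
  act <- lapply(segs, function(s) quant(events$time[events$node == s]))
  seg_list <- as.list(seg_tab[setdiff(names(seg_tab), "name")])
  seg_list$type <- ifelse(
    segs %in% septal_load_segments() & !isFALSE(cfg$mechanics$septal_coupling),
    1L, ifelse(segs %in% rv_segments(), 2L, 0L)
  )
  seg_list$lt_slope <- cfg$mechanics$lt_slope
  seg_list$lt_max <- cfg$mechanics$lt_max

  atria <- list(
    ra = cfg$mechanics$atria$ra, la = cfg$mechanics$atria$la,
    ra_act = quant(events$time[events$node == "RA"]),
    la_act = quant(events$time[events$node == "LA"])
  )
  cav <- cfg$mechanics$cavity
  ch_order <- c("ao", "sys_art", "sys_ven", "vc", "pa", "pul_cap", "pu")
  ch <- cfg$circulation$chambers
  chambers <- list(
    e = vapply(ch_order, function(k) ch[[k]]$e, numeric(1)),
    v0 = vapply(ch_order, function(k) ch[[k]]$v0, numeric(1))
  )
  links <- unlist(cfg$circulation$links[c(
    "ao_sys_art", "sys_art_sys_ven", "sys_ven_vc", "vc_ra",
    "pa_pul_cap", "pul_cap_pu", "pu_la"
  )])
  valves <- unlist(cfg$circulation$valves[c(
    "mitral", "aortic", "tricuspid", "pulmonary"
  )])

  y0 <- c(
    seg_tab$l0 * ifelse(seg_list$type == 2L, cav$rv$l_init_rel, cav$lv$l_init_rel),
    rep(0, length(segs)),
    cav$lv$v_init, cav$rv$v_init,
    ch$ra$v_init, ch$la$v_init,
    vapply(ch_order, function(k) ch[[k]]$v_init, numeric(1))
  )

  core <- .core_run(
    seg = seg_list, act = act, atria = atria,
    cavity = cav, chambers = chambers,
    links = unname(links), valves = unname(valves),
    y0 = y0, dt = dt, n_steps = n_steps, record_every = 1L
  )
  out <- core$out
  n <- length(segs)
  hemo_names <- c(
    "time", "p_lv", "p_rv", "p_ra", "p_la", "p_ao", "p_sa", "p_sv", "p_vc",
    "p_pa", "p_pc", "p_pu", "v_lv", "v_rv", "v_ra", "v_la", "v_ao", "v_sa",
    "v_sv", "v_vc", "v_pa", "v_pc", "v_pu", "q_mitral", "q_aortic",
    "q_tricuspid", "q_pulmonary"
  )
  nh <- length(hemo_names)
  hemo <- as.data.frame(out[, seq_len(nh)])
  names(hemo) <- hemo_names
  lengths <- out[, nh + seq_len(n), drop = FALSE]
  flows <- out[, nh + n + seq_len(n), drop = FALSE]
  drive <- out[, nh + 2 * n + seq_len(n), drop = FALSE]
  colnames(lengths) <- colnames(flows) <- colnames(drive) <- segs

  time <- hemo$time
  cycle_of <- pmin(floor(time / rr) + 1L, n_cycles)
  strain <- cycle_referenced_strain(lengths, time, events, rr, n_cycles, segs)

  activation <- lapply(seq_len(n_cycles), function(k) activation_times(events, k))

  res <- structure(
    list(
      time = time, hemo = hemo, lengths = lengths, seg_flows = flows,
      drive = drive, strain = strain, events = events,
      activation = activation, cycle = cycle_of,
      ecg = synthesize_ecg(events, net, sample_period = max(dt, 1), until = t_end),
      config = cfg, network = net,
      rr = rr, dt = dt, n_cycles = n_cycles, transient = cfg$engine$transient
    ),
    class = "sim_result"
  )
  res
}

# Strain (%) referenced, within each cycle, to the fiber length at the time
# of the first ventricular electrical activation of that cycle (mirrors
# R-wave gating of echocardiographic strain).
cycle_referenced_strain <- function(lengths, time, events, rr, n_cycles, segs) {
  vent <- events[node_class(events$node) == "ventricular", ]
  strain <- lengths
  for (k in seq_len(n_cycles)) {
    t0 <- (k - 1) * rr
    t1 <- k * rr
    tv <- vent$time[vent$time >= t0 & vent$time < t1]
    t_ref <- if (length(tv)) min(tv) else t0
    i_ref <- which.min(abs(time - t_ref))
    rows <- which(time >= t0 & (time < t1 | (k == n_cycles & time <= t1)))
    ref <- lengths[i_ref, ]
    strain[rows, ] <- 100 * sweep(
      lengths[rows, , drop = FALSE], 2, ref, "-"
    ) / rep(ref, each = length(rows))
  }
  strain
}

#' @export
print.sim_result <- function(x, ...) {
  cat(
    "<sim_result> ", x$n_cycles, " cycles @ RR ", x$rr, " ms, dt ", x$dt,
    " ms, ", length(x$time), " samples\n",
    sep = ""
  )
  invisible(x)
}

final_cycle_rows <- function(result) {
  t0 <- (result$n_cycles - 1) * result$rr
  which(result$time >= t0)
}

#' Hemodynamic summary of the final steady-state cycle
#'
#' Extrema are computed over the final simulated cycle only; earlier cycles
#' are regarded as transient.
#'
#' @param result a `sim_result`.
#' @return list of class `hemo_summary`: `p_lv_max`, `p_ao_max`, `p_ao_min`
#'   (mmHg), `edv`, `esv`, `stroke_volume` (mL), `ef` (%).
#' @export
summarize_hemodynamics <- function(result) {
  stopifnot(inherits(result, "sim_result"))
  if (result$n_cycles <= result$transient) {
    stop("no post-transient cycle: increase cycles or reduce transient")
  }
  rows <- final_cycle_rows(result)
  h <- result$hemo[rows, ]
  edv <- max(h$v_lv)
  esv <- min(h$v_lv)
  if (edv <= esv) stop("invariant violation: EDV must exceed ESV")
  s <- list(
    p_lv_max = max(h$p_lv),
    p_ao_max = max(h$p_ao),
    p_ao_min = min(h$p_ao),
    edv = edv, esv = esv,
    stroke_volume = edv - esv,
    ef = 100 * (edv - esv) / edv
  )
  class(s) <- "hemo_summary"
  s
}

#' @export
print.hemo_summary <- function(x, ...) {
  cat(sprintf(
    paste0(
      "Peak LV pressure : %6.1f mmHg\n",
      "Aortic pressure  : %6.1f / %.1f mmHg\n",
      "LV volume        : %6.1f / %.1f mL (EDV/ESV)\n",
      "Stroke volume    : %6.1f mL   EF %.1f %%\n"
    ),
    x$p_lv_max, x$p_ao_max, x$p_ao_min, x$edv, x$esv, x$stroke_volume, x$ef
  ))
  invisible(x)
}

#' Extract the final-cycle strain traces
#'
#' @param result a `sim_result`.
#' @param segments segment names to keep (default: the 16 LV segments plus,
#'   optionally, the RV layers present in the simulation).
#' @param include_rv include the three RV segments.
#' @return a `strain_trace` (see [strain_trace()]): time is cycle-relative ms.
#' @export
final_strain <- function(result, include_rv = FALSE) {
  rows <- final_cycle_rows(result)
  segs <- aha_segments(include_rv = include_rv)
  t0 <- (result$n_cycles - 1) * result$rr
  strain_trace(
    time = result$time[rows] - t0,
    strain = result$strain[rows, segs, drop = FALSE]
  )
}

#' Aortic ejection window of the final cycle
#'
#' First and last time (cycle-relative, ms) with positive aortic valve flow
#' on the final simulated cycle.
#'
#' @param result a `sim_result`.
#' @return numeric `c(t_open, t_close)` in ms.
#' @export
ejection_window <- function(result) {
  rows <- final_cycle_rows(result)
  t0 <- (result$n_cycles - 1) * result$rr
  q <- result$hemo$q_aortic[rows]
  open <- which(q > 0)
  if (!length(open)) stop("aortic valve never opened on the final cycle")
  tt <- result$time[rows] - t0
  c(tt[open[1]], tt[open[length(open)]])
}
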