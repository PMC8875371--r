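#' Atrial pressure from a Gaussian-driven time-varying elastance
#'
#' Atrial pressure is a linear function of instantaneous volume whose
#' elastance cycles between a diastolic minimum and a systolic maximum,
#' driven by a Gaussian activation function centred `mu` ms after the
#' atrium's electrical activation:
#' `P = [e_min + g(t) (e_max - e_min)] (v - v0)` with
#' `g(t) = exp(-(t - t_act - mu)^2 / (2 sigma^2))`.
#'
#' @param v instantaneous atrial volume (mL).
#' @param t current time (ms).
#' @param t_act time of the atrium's last electrical activation (ms); `-Inf`
#'   (never activated) yields the diastolic limit.
#' @param params list with `e_min`, `e_max` (mmHg/mL), `v0` (mL), `mu`,
#'   `sigma` (ms).
#' @return pressure (mmHg); negative transmural pressures are permitted.
#' @export
atrial_pressure <- function(v, t, t_act, params) {
  stopifnot(params$e_max >= params$e_min, params$e_min > 0, params$sigma > 0)
  g <- if (is.finite(t_act)) {
    exp(-(t - t_act - params$mu)^2 / (2 * params$sigma^2))
  } else {
    0
  }
  (params$e_min + g * (params$e_max - params$e_min)) * (v - params$v0)
}

#' Electromechanical driving function (normalized twitch)
#'
#' Each wall segment is activated by a driving function triggered by its
#' conduction automaton. The twitch is a piecewise double exponential: it
#' rises from 0 at `t_act + t_delay` with time constant `tau_c` towards a
#' systolic plateau, and from `t_plat` ms after onset relaxes exponentially
#' with time constant `tau_r`. The curve is normalized so its peak (reached
#' at the end of the plateau) equals 1.
#'
#' @param t time (ms); vectorized.
#' @param t_act electrical activation onset of the segment (ms); `NA` or
#'   `-Inf` gives `u = 0`.
#' @param params list (or one row of a segment table) with `t_delay`,
#'   `tau_c`, `tau_r`, `t_plat` in ms.
#' @return drive level in \[0, 1\].
#' @export
emd_drive <- function(t, t_act, params) {
  if (is.na(t_act) || !is.finite(t_act)) {
    return(rep(0, length(t)))
  }
  s <- t - t_act - params$t_delay
  norm <- 1 - exp(-params$t_plat / params$tau_c)
  u <- ifelse(
    s <= 0, 0,
    ifelse(
      s <= params$t_plat,
      (1 - exp(-s / params$tau_c)) / norm,
      exp(-(s - params$t_plat) / params$tau_r)
    )
  )
  u
}

# clipped-linear length-tension factor, = 1 at l = l0
length_tension <- function(ratio, slope = 2, lt_max = 1.6) {
  pmin(pmax(1 + slope * (ratio - 1), 0), lt_max)
}

#' Active wall tension
#'
#' `T_a = k_act * t_max * u * lambda(l / l0)` where `k_act` is the segment's
#' contractility as a fraction of the nominal healthy peak tension `t_max`
#' and `lambda` is a clipped-linear length-tension factor with
#' `lambda(1) = 1`. A fully scarred segment (`k_act = 0`) produces no active
#' tension.
#'
#' @param u drive level in \[0, 1\].
#' @param l current fiber length (cm).
#' @param params list with `k_act`, `t_max`, `l0`, and optionally `lt_slope`,
#'   `lt_max`.
#' @return active tension (tension units).
#' @export
active_tension <- function(u, l, params) {
  stopifnot(all(u >= 0 & u <= 1), all(l > 0))
  slope <- if (is.null(params$lt_slope)) 2 else params$lt_slope
  ltm <- if (is.null(params$lt_max)) 1.6 else params$lt_max
  params$k_act * params$t_max * u * length_tension(l / params$l0, slope, ltm)
}

#' Passive wall tension
#'
#' Exponential stiffening in stretch, linear in compression, continuous in
#' value and slope at the reference length:
#' `T_p = k_p1 (exp(k_p2 e) - 1)` for strain `e >= 0`, and
#' `T_p = k_p1 k_p2 e` for `e < 0`.
#'
#' @param strain dimensionless fiber strain `(l - l0)/l0`, > -1.
#' @param params list with `k_p1` (tension scale) and `k_p2` (exponent).
#' @return passive tension; monotone non-decreasing in `strain`.
#' @export
passive_tension <- function(strain, params) {
  stopifnot(all(strain > -1))
  ifelse(
    strain >= 0,
    params$k_p1 * (exp(params$k_p2 * strain) - 1),
    params$k_p1 * params$k_p2 * strain
  )
}

#' Longitudinal strain from fiber length
#'
#' `strain = 100 (l - l0) / l0` (percent); shortening is negative, following
#' the echocardiographic convention.
#'
#' @param l current fiber length (cm); must be positive.
#' @param l0 reference fiber length (cm).
#' @return longitudinal strain (%).
#' @export
segment_strain <- function(l, l0) {
  if (any(l0 <= 0)) stop("reference length must be positive")
  if (any(l <= 0)) stop("segment state error: non-positive fiber length")
  100 * (l - l0) / l0
}

#' Segment hydraulic flow dynamics
#'
#' The blood column displaced by each wall segment is represented by its
#' resistive and inertial effects: `dq/dt = (p_seg - p_load - r_h q) / l_h`,
#' where the segment pressure derives from total wall tension through the
#' piston coupling `p_seg = (T_a + T_p) / area_w`.
#'
#' @param q current segment flow (mL/s).
#' @param p_seg segment pressure (mmHg), i.e. total tension over `area_w`.
#' @param p_load external load pressure (mmHg): cavity pressure for free-wall
#'   segments, the trans-septal gradient for septal segments
#'   (see [septal_load()]).
#' @param params list with `r_h` (mmHg s/mL) and `l_h` (mmHg s^2/mL, > 0).
#' @return time derivative of `q` (mL/s^2).
#' @export
segment_flow_dynamics <- function(q, p_seg, p_load, params) {
  stopifnot(params$l_h > 0, params$r_h >= 0)
  (p_seg - p_load - params$r_h * q) / params$l_h
}

#' External load pressure per segment type
#'
#' Septal segments (basal/mid anteroseptal, basal/mid inferoseptal, apical
#' septal) are loaded by the pressure gradient across the septum
#' `p_lv - p_rv`; LV free-wall segments by `p_lv`; RV segments by `p_rv`.
#' Early in the cycle, when the septum is activated but LV pressure is still
#' low, this coupling permits the pre-ejection septal motion (septal flash)
#' typical of LBBB.
#'
#' @param segment segment name(s).
#' @param p_lv,p_rv cavity pressures (mmHg).
#' @return load pressure (mmHg) per segment.
#' @export
septal_load <- function(segment, p_lv, p_rv) {
  n <- max(length(segment), length(p_lv), length(p_rv))
  segment <- rep_len(segment, n)
  p_lv <- rep_len(p_lv, n)
  p_rv <- rep_len(p_rv, n)
  ifelse(
    segment %in% septal_load_segments(), p_lv - p_rv,
    ifelse(segment %in% rv_segments(), p_rv, p_lv)
  )
}

#' Ventricular cavity flow balance
#'
#' The cavity hydraulic node collects the flow contribution of every wall
#' segment and the valve flows: `dV_node/dt = sum(q_s) + q_in - q_out`.
#'
#' @param q_segments vector of segment flows (mL/s).
#' @param q_in inflow through the inlet valve (mL/s).
#' @param q_out outflow through the outlet valve (mL/s).
#' @return rate of change of the cavity node volume (mL/s).
#' @export
cavity_flow <- function(q_segments, q_in, q_out) {
  sum(q_segments) + q_in - q_out
}
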