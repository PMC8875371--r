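#' Compliance chamber pressure
#'
#' Each circulatory chamber relates pressure to volume through a linear
#' elastance: `P = e (v - v0)`.
#'
#' @param chamber list with `e` (mmHg/mL, > 0), `v0` (unstressed volume, mL)
#'   and `v` (current volume, mL).
#' @return pressure (mmHg).
#' @export
chamber_pressure <- function(chamber) {
  stopifnot(chamber$e > 0)
  chamber$e * (chamber$v - chamber$v0)
}

#' Resistive link flow
#'
#' Flow between two chambers follows the pressure gradient over the link
#' resistance: `q = (p_up - p_down) / r` (bidirectional).
#'
#' @param p_up,p_down chamber pressures (mmHg).
#' @param r link resistance (mmHg s/mL, > 0).
#' @return flow (mL/s).
#' @export
link_flow <- function(p_up, p_down, r) {
  stopifnot(r > 0)
  (p_up - p_down) / r
}

#' Perfect-diode valve flow
#'
#' Cardiac valves conduct only down their pressure gradient, with no
#' regurgitation: `q = (p_up - p_down)/r_open` if `p_up > p_down`, else 0.
#'
#' @param p_up,p_down pressures upstream/downstream of the valve (mmHg).
#' @param valve list with `r_open` (mmHg s/mL, > 0).
#' @return non-negative flow (mL/s).
#' @export
valve_flow <- function(p_up, p_down, valve) {
  stopifnot(valve$r_open > 0)
  ifelse(p_up > p_down, (p_up - p_down) / valve$r_open, 0)
}
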