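#' Default model configuration
#'
#' Returns the complete baseline configuration of the closed-loop model:
#' conduction network settings, atrial and ventricular-segment mechanical
#' parameters, circulation chamber/link/valve parameters, and integration
#' settings. The shipped baseline was calibrated once so that the healthy
#' simulation reproduces normal resting hemodynamics (systolic LV pressure
#' about 130 mmHg, aortic pressure 60-130 mmHg, LV volume 40-90 mL).
#'
#' Units are ms, mmHg, mL and cm throughout; resistances mmHg s/mL,
#' inertances mmHg s^2/mL, elastances mmHg/mL.
#'
#' @return nested list of class `model_config`.
#' @export
default_config <- function() {
  segs <- aha_segments(include_rv = TRUE)
  is_rv <- segs %in% rv_segments()
  is_apical <- grepl("^apical", segs)
  area <- ifelse(is_rv, 18, ifelse(is_apical, 2.55, 3.85))
  l0 <- ifelse(is_rv, 6, 5)
  sigma_act <- ifelse(is_rv, 32, 234)     # peak active tension / area (mmHg)
  sigma_pas <- ifelse(is_rv, 0.7, 0.8)    # passive tension scale / area (mmHg)
  segments <- data.frame(
    name = segs,
    l0 = l0,
    area_w = area,
    k_act = 1.0,
    t_delay = 30,
    tau_c = 40,
    tau_r = 33,
    t_plat = ifelse(is_rv, 215, 180),
    t_max = sigma_act * area,
    k_p1 = sigma_pas * area,
    k_p2 = ifelse(is_rv, 24, 55),
    r_h = ifelse(is_rv, 0.9, 4.2) / area,   # piston resistance ~ 1/area so wall
    l_h = ifelse(is_rv, 0.0019, 0.0086) / area, # shortening velocity is area-free
    stringsAsFactors = FALSE
  )
  cfg <- list(
    conduction = list(
      rr = 900, lbbb = FALSE, myocardial_delay = 1,
      rrp_response = "scaled", event_cap = 100000, phases = NULL, links = NULL
    ),
    mechanics = list(
      atria = list(
        ra = list(e_min = 0.15, e_max = 0.35, v0 = 10, mu = 80, sigma = 40),
        la = list(e_min = 0.18, e_max = 0.45, v0 = 10, mu = 80, sigma = 40)
      ),
      segments = segments,
      septal_coupling = TRUE,
      lt_slope = 3, lt_max = 1.6,
      cavity = list(
        lv = list(e = 30, v0 = 10, v_offset = 215.75, v_init = 10.3, l_init_rel = 1.08),
        rv = list(e = 18, v0 = 10, v_offset = 255, v_init = 10.3, l_init_rel = 1.08)
      )
    ),
    circulation = list(
      chambers = list(
        ao = list(e = 2.4, v0 = 60, v_init = 99),
        sys_art = list(e = 5.7, v0 = 250, v_init = 266),
        sys_ven = list(e = 0.015, v0 = 2700, v_init = 3400),
        vc = list(e = 0.05, v0 = 100, v_init = 200),
        pa = list(e = 0.45, v0 = 50, v_init = 88),
        pul_cap = list(e = 0.1, v0 = 150, v_init = 260),
        pu = list(e = 0.07, v0 = 300, v_init = 470),
        ra = list(v_init = 37),
        la = list(v_init = 54)
      ),
      links = list(
        ao_sys_art = 0.06, sys_art_sys_ven = 1.37, sys_ven_vc = 0.05,
        vc_ra = 0.01, pa_pul_cap = 0.02, pul_cap_pu = 0.02, pu_la = 0.01
      ),
      valves = list(
        mitral = 0.020, aortic = 0.022, tricuspid = 0.020, pulmonary = 0.022
      )
    ),
    engine = list(dt = 0.5, cycles = 15, transient = 5)
  )
  structure(cfg, class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat(
    "<model_config> RR ", x$conduction$rr, " ms",
    if (isTRUE(x$conduction$lbbb)) " (LBBB)" else "",
    ", ", nrow(x$mechanics$segments), " wall segments, dt ",
    x$engine$dt, " ms, ", x$engine$cycles, " cycles\n",
    sep = ""
  )
  invisible(x)
}

# recursive merge of user values into defaults (lists merged by name,
# leaves replaced); data frames merged row-wise by segment name
merge_config <- function(base, user, path = "") {
  if (is.data.frame(base) && (is.data.frame(user) || is.list(user))) {
    return(merge_segment_table(base, user, path))
  }
  if (!is.list(user) || !is.list(base)) {
    return(user)
  }
  bad <- setdiff(names(user), names(base))
  if (length(bad) && !path %in% c("$conduction$phases", "$conduction$links")) {
    stop("unknown configuration key: ", path, "$", bad[1])
  }
  for (nm in names(user)) {
    base[[nm]] <- merge_config(base[[nm]], user[[nm]], paste0(path, "$", nm))
  }
  base
}

merge_segment_table <- function(base, user, path) {
  user <- as.data.frame(user, stringsAsFactors = FALSE)
  if (is.null(user$name)) stop(path, ": segment table requires a 'name' column")
  bad <- setdiff(user$name, base$name)
  if (length(bad)) stop(path, ": unknown segment name: ", paste(bad, collapse = ", "))
  idx <- match(user$name, base$name)
  for (col in setdiff(names(user), "name")) {
    if (!col %in% names(base)) stop(path, ": unknown segment column: ", col)
    base[[col]][idx] <- user[[col]]
  }
  base
}

#' Load and validate a model configuration file
#'
#' Reads a JSON (or YAML, if the `yaml` package is available) configuration
#' file, merges it over the shipped defaults, and validates the result.
#' An empty file yields the pure-defaults configuration. Segment parameters
#' may be given as a partial table (rows identified by `name`).
#'
#' @param path configuration file (`.json`, `.yaml`/`.yml`).
#' @return a validated `model_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  user <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configurations requires the 'yaml' package")
    }
    yaml::yaml.load_file(path)
  } else {
    txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
    if (!nzchar(trimws(txt))) list() else jsonlite::fromJSON(txt, simplifyVector = TRUE)
  }
  if (is.null(user)) user <- list()
  as_model_config(user)
}

#' Coerce a plain list of overrides into a validated configuration
#'
#' @param overrides nested list with the same shape as [default_config()];
#'   missing entries take default values.
#' @return a validated `model_config`.
#' @export
as_model_config <- function(overrides = list()) {
  if (inherits(overrides, "model_config")) {
    cfg <- overrides
  } else {
    cfg <- merge_config(unclass(default_config()), overrides)
    class(cfg) <- "model_config"
  }
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  seg <- cfg$mechanics$segments
  chk <- function(ok, where, what) {
    if (!all(ok)) stop("configuration error at ", where, ": ", what)
  }
  chk(nrow(seg) == 19 && setequal(seg$name, aha_segments(include_rv = TRUE)),
    "$mechanics$segments", "expected the 16 AHA LV segments plus 3 RV segments")
  chk(seg$k_act >= 0 & seg$k_act <= 1, "$mechanics$segments$k_act",
    "contractility fraction must lie in [0, 1]")
  chk(seg$l0 > 0, "$mechanics$segments$l0", "reference length must be > 0")
  chk(seg$tau_c > 0 & seg$tau_r > 0 & seg$t_plat >= 0,
    "$mechanics$segments$tau_c/tau_r/t_plat",
    "drive time constants must be > 0 and plateau >= 0")
  chk(seg$r_h >= 0 & seg$l_h > 0, "$mechanics$segments$r_h/l_h",
    "hydraulic resistance must be >= 0 and inertance > 0")
  chk(seg$area_w > 0 & seg$t_max >= 0 & seg$k_p1 >= 0 & seg$k_p2 > 0,
    "$mechanics$segments", "tension parameters out of range")
  for (a in c("ra", "la")) {
    at <- cfg$mechanics$atria[[a]]
    chk(at$e_max >= at$e_min && at$e_min > 0 && at$sigma > 0,
      paste0("$mechanics$atria$", a), "requires e_max >= e_min > 0 and sigma > 0")
  }
  for (ch in setdiff(names(cfg$circulation$chambers), c("ra", "la"))) {
    c0 <- cfg$circulation$chambers[[ch]]
    chk(c0$e > 0, paste0("$circulation$chambers$", ch), "elastance must be > 0")
  }
  chk(unlist(cfg$circulation$links) > 0, "$circulation$links",
    "resistances must be > 0")
  chk(unlist(cfg$circulation$valves) > 0, "$circulation$valves",
    "valve resistances must be > 0")
  eng <- cfg$engine
  chk(eng$dt > 0 && eng$dt <= 1, "$engine$dt", "time step must be in (0, 1] ms")
  chk(eng$cycles >= 1 && eng$transient >= 0 && eng$transient < eng$cycles,
    "$engine", "cycles must be >= 1 and transient < cycles")
  invisible(cfg)
}
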