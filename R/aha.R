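#' Standardized ventricular wall segment names
#'
#' The left-ventricular wall is divided into the 16 segments of the AHA
#' standardized segmentation (6 basal, 6 mid, 4 apical); the right-ventricular
#' wall into three layers (basal, median, apical). These 19 names are used
#' consistently across the conduction, mechanics, strain and scar modules.
#'
#' @param include_rv logical; append the three right-ventricular layers.
#' @return character vector of segment names in AHA order (1-16, then RV).
#' @export
#' @examples
#' aha_segments()
aha_segments <- function(include_rv = FALSE) {
  lv <- c(
    "basal_anterior", "basal_anteroseptal", "basal_inferoseptal",
    "basal_inferior", "basal_inferolateral", "basal_anterolateral",
    "mid_anterior", "mid_anteroseptal", "mid_inferoseptal",
    "mid_inferior", "mid_inferolateral", "mid_anterolateral",
    "apical_anterior", "apical_septal", "apical_inferior", "apical_lateral"
  )
  if (include_rv) c(lv, rv_segments()) else lv
}

#' @rdname aha_segments
#' @export
rv_segments <- function() {
  c("rv_basal", "rv_median", "rv_apical")
}

#' Segment membership of the septal and lateral walls
#'
#' Wall-level strain curves average five segments each: the septal wall is
#' apical septum, mid/basal inferoseptum and mid/basal anteroseptum; the
#' lateral wall is apical lateral, mid/basal inferolateral and mid/basal
#' anterolateral.
#'
#' @param wall `"septal"`, `"lateral"`, or `"remaining"` (the six LV segments
#'   in neither wall).
#' @return character vector of segment names.
#' @export
wall_segments <- function(wall = c("septal", "lateral", "remaining")) {
  wall <- match.arg(wall)
  septal <- c(
    "apical_septal", "mid_inferoseptal", "basal_inferoseptal",
    "mid_anteroseptal", "basal_anteroseptal"
  )
  lateral <- c(
    "apical_lateral", "mid_inferolateral", "basal_inferolateral",
    "mid_anterolateral", "basal_anterolateral"
  )
  switch(wall,
    septal = septal,
    lateral = lateral,
    remaining = setdiff(aha_segments(), c(septal, lateral))
  )
}

# Anatomical adjacency of the 19 wall segments: intra-ring neighbours,
# basal<->mid and mid<->apical couplings, the RV basal->apical chain, and the
# trans-septal contacts between RV layers and the septal LV segments.
# Returned as an undirected edge list (each pair once).
segment_adjacency <- function() {
  s <- aha_segments(include_rv = TRUE)
  e <- function(i, j) cbind(s[i], s[j])
  edges <- rbind(
    # basal ring 1-6
    e(1, 2), e(2, 3), e(3, 4), e(4, 5), e(5, 6), e(6, 1),
    # mid ring 7-12
    e(7, 8), e(8, 9), e(9, 10), e(10, 11), e(11, 12), e(12, 7),
    # apical ring 13-16
    e(13, 14), e(14, 15), e(15, 16), e(16, 13),
    # basal <-> mid
    e(1, 7), e(2, 8), e(3, 9), e(4, 10), e(5, 11), e(6, 12),
    # mid <-> apical (4 apical segments fuse neighbouring mid segments)
    e(7, 13), e(8, 14), e(9, 14), e(10, 15), e(11, 16), e(12, 16),
    # RV chain
    e(17, 18), e(18, 19),
    # trans-septal contacts
    e(17, 2), e(17, 3), e(18, 8), e(18, 9), e(19, 14)
  )
  data.frame(a = edges[, 1], b = edges[, 2], stringsAsFactors = FALSE)
}

# Septal LV segments whose external load is the trans-septal pressure
# gradient (p_lv - p_rv) rather than the LV cavity pressure alone.
septal_load_segments <- function() wall_segments("septal")
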