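#' Two-class fuzzy c-means clustering of myocardial intensities
#'
#' Unsupervised classification of myocardial voxels into late-gadolinium-
#' enhanced (LGE) and non-LGE classes by standard fuzzy c-means: class
#' centers are membership^m-weighted means, memberships are inverse-distance
#' weights with fuzzifier exponent `2/(m-1)`. Centers are initialized
#' deterministically at the 25th and 75th intensity percentiles; the LGE
#' class is always the one with the higher final center, so the result is
#' invariant to initial center ordering. The Bezdek objective is checked to
#' be non-increasing at every iteration.
#'
#' @param x numeric vector of voxel intensities (within the myocardial mask).
#' @param m fuzzifier (> 1).
#' @param tol convergence tolerance on the maximum center shift.
#' @param max_iter iteration cap.
#' @return list of class `fcm_result`: `membership` (n x 2 matrix, column 2
#'   = LGE class; rows sum to 1), `centers` (sorted ascending, `[2]` = LGE),
#'   `objective` (trace of the Bezdek functional), `iterations`,
#'   `converged`.
#' @export
fcm2 <- function(x, m = 2, tol = 1e-5, max_iter = 300) {
  x <- as.numeric(x)
  if (length(unique(x)) < 2) {
    stop("degenerate input: fuzzy c-means requires >= 2 distinct intensities")
  }
  stopifnot(m > 1, tol > 0, max_iter >= 1)
  centers <- unname(quantile(x, c(0.25, 0.75)))
  if (centers[1] == centers[2]) centers <- range(x)
  objective <- numeric(0)
  converged <- FALSE
  u <- NULL
  for (it in seq_len(max_iter)) {
    d2 <- cbind((x - centers[1])^2, (x - centers[2])^2)
    d2 <- pmax(d2, 1e-300)
    # membership u_ik proportional to d_ik^{-2/(m-1)}
    w <- d2^(-1 / (m - 1))
    u <- w / rowSums(w)
    um <- u^m
    obj <- sum(um * d2)
    if (length(objective) && obj > tail(objective, 1) + 1e-9) {
      stop("internal error: objective increased") # invariant guard
    }
    objective <- c(objective, obj)
    new_centers <- colSums(um * x) / colSums(um)
    shift <- max(abs(new_centers - centers))
    centers <- new_centers
    if (shift < tol) {
      converged <- TRUE
      break
    }
  }
  ord <- order(centers)
  structure(
    list(
      membership = u[, ord, drop = FALSE],
      centers = centers[ord],
      objective = objective,
      iterations = length(objective),
      converged = converged
    ),
    class = "fcm_result"
  )
}

#' @export
print.fcm_result <- function(x, ...) {
  cat(sprintf(
    "<fcm_result> centers %.3g / %.3g (%d iterations%s)\n",
    x$centers[1], x$centers[2], x$iterations,
    if (x$converged) ", converged" else ""
  ))
  invisible(x)
}

#' Synthetic short-axis LGE image stack
#'
#' Builds an annular-myocardium phantom: each short-axis slice is an annulus
#' whose angular sectors carry 16-segment AHA labels (basal slices carry
#' segments 1-6, mid 7-12, apical 13-16). Scarred segments receive a bright
#' band extending from the subendocardium outward over the requested
#' fraction of wall thickness; seeded Gaussian noise is added everywhere in
#' the mask. Labelled synthetic phantoms stand in for contoured clinical
#' stacks.
#'
#' @param scar_segments character vector of AHA segment names to scar.
#' @param transmurality percent of wall thickness occupied by scar, in
#'   \[0, 100\].
#' @param contrast scar / remote intensity ratio.
#' @param noise_sd noise standard deviation as a fraction of the
#'   scar-to-remote intensity difference.
#' @param seed integer seed (phantoms are reproducible byte-for-byte).
#' @param dim in-plane matrix size.
#' @param slices_per_level short-axis slices per basal/mid/apical level.
#' @return list of class `lge_volume`: `intensity`, `mask`, `label` (arrays
#'   `dim x dim x n_slices`; label holds AHA segment indices 1-16 or 0),
#'   `slice_level`, `spacing` (mm), `scar_segments`, `transmurality`.
#' @export
make_lge_phantom <- function(scar_segments = character(0), transmurality = 0,
                             contrast = 3, noise_sd = 0.05, seed = 1,
                             dim = 64, slices_per_level = 2) {
  stopifnot(transmurality >= 0, transmurality <= 100, contrast > 0, dim >= 16)
  segs <- aha_segments()
  bad <- setdiff(scar_segments, segs)
  if (length(bad)) stop("invalid AHA segment name(s): ", paste(bad, collapse = ", "))
  if (length(scar_segments) == 0 && transmurality > 0) {
    stop("nonzero transmurality requires a non-empty scar segment list")
  }
  levels <- rep(c("basal", "mid", "apical"), each = slices_per_level)
  n_slices <- length(levels)
  intensity <- mask <- label <- array(0, c(dim, dim, n_slices))
  ctr <- (dim + 1) / 2
  r_epi <- 0.42 * dim
  r_endo <- 0.26 * dim
  xy <- expand.grid(x = seq_len(dim), y = seq_len(dim))
  r <- sqrt((xy$x - ctr)^2 + (xy$y - ctr)^2)
  theta <- atan2(xy$y - ctr, xy$x - ctr) %% (2 * pi)
  in_wall <- r >= r_endo & r <= r_epi
  radial_frac <- (r - r_endo) / (r_epi - r_endo)

  # angular sectors anticlockwise from theta = 0; 6 sectors for basal/mid
  # rings, 4 for the apical ring
  ring_segments <- list(
    basal = segs[1:6], mid = segs[7:12], apical = segs[13:16]
  )
  set.seed(seed)
  for (s in seq_len(n_slices)) {
    ring <- levels[s]
    ring_names <- ring_segments[[ring]]
    n_sect <- length(ring_names)
    sect <- pmin(floor(theta / (2 * pi) * n_sect) + 1L, n_sect)
    seg_name <- ring_names[sect]
    lab <- ifelse(in_wall, match(seg_name, segs), 0L)
    base <- ifelse(in_wall, 1, 0)
    scarred <- in_wall & seg_name %in% scar_segments &
      radial_frac <= transmurality / 100
    base[scarred] <- contrast
    noise <- rnorm(length(base), 0, noise_sd * max(contrast - 1, 1))
    base[in_wall] <- base[in_wall] + noise[in_wall]
    intensity[, , s] <- matrix(base, dim, dim)
    mask[, , s] <- matrix(as.numeric(in_wall), dim, dim)
    label[, , s] <- matrix(lab, dim, dim)
  }
  structure(
    list(
      intensity = intensity, mask = mask == 1, label = label,
      slice_level = levels, spacing = c(1.5, 1.5, 8),
      scar_segments = scar_segments, transmurality = transmurality
    ),
    class = "lge_volume"
  )
}

#' @export
print.lge_volume <- function(x, ...) {
  d <- dim(x$intensity)
  cat(
    "<lge_volume> ", d[1], "x", d[2], " x ", d[3], " slices, ",
    sum(x$mask), " myocardial voxels\n",
    sep = ""
  )
  invisible(x)
}

#' Classify an LGE volume with fuzzy c-means
#'
#' Runs [fcm2()] on the masked voxel intensities and returns the hardened
#' (membership > 0.5) LGE classification alongside the fuzzy result. An
#' unsupervised two-class split always exists, even in scar-free tissue
#' where it would only partition the noise; a minimum ratio between the two
#' class centers is therefore required before any voxel is called enhanced.
#'
#' @param volume an `lge_volume`.
#' @param min_contrast minimal bright/dark center ratio for the enhanced
#'   class to be considered real scar; below it no voxel is classified LGE.
#' @param ... passed to [fcm2()].
#' @return list with `fcm` (the `fcm_result`), `lge` (logical array, TRUE =
#'   LGE voxel), `volume`.
#' @export
classify_lge <- function(volume, min_contrast = 1.25, ...) {
  stopifnot(inherits(volume, "lge_volume"))
  idx <- which(volume$mask)
  fcm <- fcm2(volume$intensity[idx], ...)
  lge <- array(FALSE, dim(volume$intensity))
  if (fcm$centers[2] / max(fcm$centers[1], 1e-12) >= min_contrast) {
    lge[idx] <- fcm$membership[, 2] > 0.5
  }
  list(fcm = fcm, lge = lge, volume = volume)
}

#' Per-segment scar transmurality from a classified volume
#'
#' For each slice and each angular position (chord) inside a segment's
#' sector, the fraction of the endocardium-to-epicardium chord classified
#' LGE is computed (voxels are weighted by inverse radius so that the chord
#' is sampled uniformly in wall depth); per-segment transmurality is the
#' mean chord fraction over all chords and slices, in percent.
#'
#' @param classified result of [classify_lge()], or a list with `lge`
#'   (logical array) and `volume` (`lge_volume`).
#' @param n_chords angular chords per full circle used for averaging.
#' @return named numeric vector over the 16 AHA segments (%); segments with
#'   no myocardial voxels are `NA`.
#' @export
transmurality_by_segment <- function(classified, n_chords = 90) {
  vol <- classified$volume
  lge <- classified$lge
  segs <- aha_segments()
  d <- dim(vol$intensity)
  ctr <- (d[1] + 1) / 2
  xy <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]))
  r <- sqrt((xy$x - ctr)^2 + (xy$y - ctr)^2)
  theta <- atan2(xy$y - ctr, xy$x - ctr) %% (2 * pi)
  chord_id <- pmin(floor(theta / (2 * pi) * n_chords) + 1L, n_chords)
  fractions <- setNames(vector("list", length(segs)), segs)
  for (s in seq_len(d[3])) {
    msk <- as.vector(vol$mask[, , s])
    lab <- as.vector(vol$label[, , s])
    lg <- as.vector(lge[, , s])
    in_idx <- which(msk)
    if (!length(in_idx)) next
    key <- chord_id[in_idx]
    w <- 1 / pmax(r[in_idx], 0.5)   # uniform sampling in wall depth
    seg_of_chord <- tapply(lab[in_idx], key, function(v) v[1])
    frac <- tapply(seq_along(in_idx), key, function(ii) {
      sum(lg[in_idx[ii]] * w[ii]) / sum(w[ii])
    })
    for (k in seq_along(frac)) {
      nm <- segs[seg_of_chord[k]]
      fractions[[nm]] <- c(fractions[[nm]], frac[k])
    }
  }
  out <- vapply(fractions, function(f) {
    if (is.null(f)) NA_real_ else 100 * mean(f)
  }, numeric(1))
  out
}

#' Write / read an LGE phantom as plain text
#'
#' The volume is serialized as a long-format CSV (slice, x, y, intensity,
#' mask, label) with a JSON sidecar carrying dimensions, slice levels and
#' voxel spacing.
#'
#' @param volume an `lge_volume`.
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.meta.json`.
#' @return `path` (write) or an `lge_volume` (read).
#' @export
write_lge_volume <- function(volume, path) {
  d <- dim(volume$intensity)
  idx <- which(volume$mask, arr.ind = TRUE)
  df <- data.frame(
    slice = idx[, 3], x = idx[, 1], y = idx[, 2],
    intensity = signif(volume$intensity[volume$mask], 8),
    label = volume$label[volume$mask]
  )
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(
      dim = d, slice_level = volume$slice_level, spacing = volume$spacing,
      scar_segments = volume$scar_segments,
      transmurality = volume$transmurality
    ),
    paste0(path, ".meta.json"),
    auto_unbox = TRUE, digits = 8
  )
  invisible(path)
}

#' @rdname write_lge_volume
#' @export
read_lge_volume <- function(path) {
  meta <- jsonlite::fromJSON(paste0(path, ".meta.json"))
  df <- read.table(path, sep = ",", header = TRUE)
  d <- meta$dim
  intensity <- array(0, d)
  mask <- array(FALSE, d)
  label <- array(0L, d)
  lin <- cbind(df$x, df$y, df$slice)
  intensity[lin] <- df$intensity
  mask[lin] <- TRUE
  label[lin] <- df$label
  structure(
    list(
      intensity = intensity, mask = mask, label = label,
      slice_level = meta$slice_level, spacing = meta$spacing,
      scar_segments = meta$scar_segments, transmurality = meta$transmurality
    ),
    class = "lge_volume"
  )
}
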