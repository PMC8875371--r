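norm_segment_name <- function(x) {
  y <- tolower(x)
  y <- gsub("[^a-z]+", "_", y)
  y <- gsub("^_|_$", "", y)
  # common clinical spellings
  y <- sub("^apical_septum$", "apical_septal", y)
  y <- sub("^apex_", "apical_", y)
  y <- sub("septum$", "septal", y)
  y
}

#' Write a strain trace as a delimited text export
#'
#' Plain tab-delimited text mirroring numerized strain-trace exports: a
#' header row naming the time column and the segments, one row per sample.
#'
#' @param trace a `strain_trace`.
#' @param path output file.
#' @param time_unit `"ms"` or `"s"` for the written time column.
#' @return `path`, invisibly.
#' @export
write_strain_export <- function(trace, path, time_unit = c("ms", "s")) {
  time_unit <- match.arg(time_unit)
  tm <- if (time_unit == "s") trace$time / 1000 else trace$time
  df <- data.frame(time = tm, trace$strain, check.names = FALSE)
  names(df)[1] <- paste0("time_", time_unit)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a delimited strain-trace export
#'
#' Reads tab/comma/whitespace-delimited text with a header row naming the
#' segments. The time column (first column) may be in milliseconds or
#' seconds; the unit is auto-detected by magnitude (a time span below 10 is
#' taken as seconds) and normalized to ms. Trailing non-numeric metadata
#' lines are tolerated. Segment names are normalized to the AHA scheme.
#'
#' @param path input file.
#' @return a `strain_trace`.
#' @export
read_strain_export <- function(path) {
  if (!file.exists(path)) stop("strain export not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) stop("strain export has no data rows")
  delim <- if (grepl("\t", lines[1])) "\t" else if (grepl(",", lines[1])) "," else "[[:space:]]+"
  split1 <- function(s) trimws(strsplit(s, delim)[[1]])
  header <- split1(lines[1])
  rows <- lapply(lines[-1], split1)
  numeric_row <- vapply(
    rows,
    function(r) length(r) == length(header) && !anyNA(suppressWarnings(as.numeric(r))),
    logical(1)
  )
  # data rows are the leading numeric block; trailing metadata is ignored
  last <- if (any(!numeric_row)) which(!numeric_row)[1] - 1L else length(rows)
  if (last < 1) stop("strain export has no numeric data rows")
  mat <- do.call(rbind, lapply(rows[seq_len(last)], as.numeric))
  tm <- mat[, 1]
  if (max(tm) - min(tm) < 10) tm <- tm * 1000 # seconds -> ms
  seg_names <- norm_segment_name(header[-1])
  known <- aha_segments(include_rv = TRUE)
  bad <- setdiff(seg_names, known)
  if (length(bad)) {
    stop(
      "unknown segment name(s) in header: ", paste(bad, collapse = ", "),
      "\naccepted names: ", paste(known, collapse = ", ")
    )
  }
  strain <- mat[, -1, drop = FALSE]
  colnames(strain) <- seg_names
  strain_trace(time = tm, strain = strain)
}

#' Write simulation outputs as tidy delimited files
#'
#' Writes the hemodynamic series (`hemodynamics.csv`), final-cycle strain
#' traces (`strain.txt`), the ECG (`ecg.txt`, two columns: time ms and
#' amplitude) and a JSON summary (`summary.json`) into a directory.
#'
#' @param result a `sim_result`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(
    result$hemo, file.path(dir, "hemodynamics.csv"),
    sep = ",", quote = FALSE, row.names = FALSE
  )
  write_strain_export(
    final_strain(result, include_rv = TRUE),
    file.path(dir, "strain.txt")
  )
  write.table(
    data.frame(time_ms = result$ecg$time, amplitude = result$ecg$signal),
    file.path(dir, "ecg.txt"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  s <- summarize_hemodynamics(result)
  jsonlite::write_json(
    c(unclass(s), list(qrs_ms = tryCatch(measure_qrs(result$ecg), error = function(e) NA))),
    file.path(dir, "summary.json"),
    auto_unbox = TRUE, digits = 6, na = "null"
  )
  invisible(dir)
}
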