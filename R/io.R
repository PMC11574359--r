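# CSV import/export.
#
# Track CSV: one row per localisation, columns
#   track_id, frame, x_um, y_um, channel
# with header; frames consecutive integers within each track. Lines
# starting with '#' are metadata comments.
#
# Distribution CSV (tracking-software-export style): columns
#   bin_centre_nm, concentration_per_ml
# with optional '#key: value' metadata lines.

read_metadata_lines <- function(lines) {
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    ln <- sub("^#\\s*", "", ln)
    if (grepl(":", ln, fixed = TRUE)) {
      key <- trimws(sub(":.*$", "", ln))
      val <- trimws(sub("^[^:]*:", "", ln))
      meta[[key]] <- val
    }
  }
  meta
}

format_metadata <- function(meta) {
  if (length(meta) == 0L) {
    return(character(0))
  }
  vapply(names(meta), function(k) {
    sprintf("# %s: %s", k, format(meta[[k]]))
  }, character(1))
}

#' Read a track CSV
#'
#' Parses and validates a localisation table. Malformed rows and frame
#' gaps are rejected with the offending file line number.
#'
#' @param path CSV file path.
#' @return A track table tibble (`track_id`, `frame`, `x_um`, `y_um`,
#'   `channel`); any `#key: value` metadata lines are attached as the
#'   `metadata` attribute.
#' @export
read_tracks <- function(path) {
  lines <- readLines(path)
  is_comment <- grepl("^#", lines)
  body <- lines[!is_comment]
  body_lineno <- which(!is_comment)
  if (length(body) == 0L) {
    abort(sprintf("'%s' has no header line.", path))
  }
  tracks <- suppressWarnings(readr::read_csv(I(paste(body, collapse = "\n")),
    col_types = readr::cols(
      track_id = readr::col_integer(),
      frame = readr::col_integer(),
      x_um = readr::col_double(),
      y_um = readr::col_double(),
      channel = readr::col_character()
    )
  ))
  need <- c("track_id", "frame", "x_um", "y_um", "channel")
  missing <- setdiff(need, names(tracks))
  if (length(missing)) {
    abort(sprintf(
      "'%s' is missing column(s): %s.", path, paste(missing, collapse = ", ")
    ))
  }
  probs <- readr::problems(tracks)
  if (nrow(probs) > 0L) {
    # problems() rows count from the start of the parsed text incl. header
    idx <- min(probs$row[1], length(body_lineno))
    abort(sprintf(
      "'%s': malformed value at line %d ('%s').",
      path, body_lineno[idx], probs$actual[1]
    ))
  }
  bad_channel <- which(!tracks$channel %in% track_channels)
  if (length(bad_channel)) {
    abort(sprintf(
      "'%s': unknown channel '%s' at line %d.",
      path, tracks$channel[bad_channel[1]], body_lineno[bad_channel[1] + 1L]
    ))
  }
  # frames must be consecutive within each track
  ord <- order(tracks$track_id, tracks$frame)
  tid <- tracks$track_id[ord]
  frm <- tracks$frame[ord]
  same <- tid[-1] == tid[-length(tid)]
  gap <- which(same & (frm[-1] - frm[-length(frm)]) != 1L)
  if (length(gap)) {
    row_in_file <- body_lineno[ord[gap[1] + 1L] + 1L]
    abort(sprintf(
      "'%s': non-consecutive frames in track %s at line %d.",
      path, tid[gap[1] + 1L], row_in_file
    ))
  }
  structure(tracks, metadata = read_metadata_lines(lines))
}

#' Write a track CSV
#'
#' @param tracks Track table.
#' @param path Output file path.
#' @param metadata Optional named list written as leading `#key: value`
#'   comment lines (e.g. seed and config hash).
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path, metadata = list()) {
  check_tracks(tracks)
  header <- format_metadata(metadata)
  csv <- readr::format_csv(tracks[, c("track_id", "frame", "x_um", "y_um", "channel")])
  writeLines(c(header, sub("\n$", "", csv)), path)
  invisible(path)
}

#' Read a size-distribution CSV
#'
#' Validates the bin grid (constant spacing equal to the bin width, bin
#' centres at odd multiples of half the width).
#'
#' @param path CSV file path (`bin_centre_nm`, `concentration_per_ml`,
#'   optional `#key: value` metadata).
#' @return A `size_distribution`; recognised metadata keys (`channel`,
#'   `label`, `n_particles`, `observed_volume`, `bin_width`) populate the
#'   corresponding attributes, and the full metadata list is attached as
#'   the `metadata` attribute.
#' @export
read_distribution <- function(path) {
  lines <- readLines(path)
  meta <- read_metadata_lines(lines)
  body <- lines[!grepl("^#", lines)]
  df <- suppressWarnings(readr::read_csv(I(paste(body, collapse = "\n")),
    col_types = readr::cols(
      bin_centre_nm = readr::col_double(),
      concentration_per_ml = readr::col_double()
    )
  ))
  if (!all(c("bin_centre_nm", "concentration_per_ml") %in% names(df))) {
    abort(sprintf(
      "'%s' must have columns bin_centre_nm, concentration_per_ml.", path
    ))
  }
  w <- as.numeric(meta$bin_width %||% 5)
  if (nrow(df) >= 2L) {
    spacing <- diff(df$bin_centre_nm)
    if (any(abs(spacing - w) > 1e-9)) {
      abort(sprintf("'%s': bin centres are not on a regular %g-nm grid.", path, w))
    }
  }
  off <- (df$bin_centre_nm - w / 2) %% w
  if (any(pmin(off, w - off) > 1e-9)) {
    abort(sprintf(
      "'%s': bin centre %g nm is off the %g-nm grid (centres must be %g + k*%g).",
      path, df$bin_centre_nm[which(pmin(off, w - off) > 1e-9)[1]], w, w / 2, w
    ))
  }
  if (any(df$concentration_per_ml < 0)) {
    abort(sprintf("'%s': negative concentrations.", path))
  }
  out <- new_size_distribution(
    bin_centre = df$bin_centre_nm,
    concentration = df$concentration_per_ml,
    bin_width = w,
    channel = meta$channel %||% NA_character_,
    n_particles = as.integer(meta$n_particles %||% NA),
    observed_volume = as.numeric(meta$observed_volume %||% NA),
    label = meta$label %||% NA_character_
  )
  structure(out, metadata = meta)
}

#' Write a size-distribution CSV
#'
#' @param dist A `size_distribution`.
#' @param path Output file path.
#' @param metadata Extra named metadata merged with the distribution's
#'   own attributes into `#key: value` lines.
#' @return `path`, invisibly.
#' @export
write_distribution <- function(dist, path, metadata = list()) {
  check_distribution(dist)
  meta <- list(
    bin_width = attr(dist, "bin_width"),
    channel = attr(dist, "channel"),
    label = attr(dist, "label"),
    n_particles = attr(dist, "n_particles"),
    observed_volume = attr(dist, "observed_volume")
  )
  meta <- meta[!vapply(meta, function(x) is.null(x) || all(is.na(x)), logical(1))]
  meta <- modifyList(meta, metadata)
  df <- tibble(
    bin_centre_nm = dist$bin_centre,
    concentration_per_ml = dist$concentration
  )
  writeLines(
    c(format_metadata(meta), sub("\n$", "", readr::format_csv(df))),
    path
  )
  invisible(path)
}
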