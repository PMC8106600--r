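.CATCHMENT_FILES <- c(segments = "segments.csv", nodes = "nodes.csv",
                      wwtps = "wwtps.csv", hospitals = "hospitals.csv",
                      gauges = "gauges.csv",
                      monitoring_sites = "monitoring_sites.csv")

.NUMERIC_COLS <- list(
  segments = c("length", "mq", "mnq", "q50", "v_ref", "v_exponent",
               "x", "y", "local_mq"),
  nodes = c("x", "y"),
  wwtps = c("population_connected", "effluent_flow", "x", "y"),
  hospitals = c("patients_per_year", "beds"),
  gauges = c("observed_mq", "observed_mnq"),
  monitoring_sites = character())

.read_table <- function(path, numeric_cols, sep = ",") {
  df <- utils::read.csv(path, sep = sep, colClasses = "character",
                        check.names = TRUE, fileEncoding = "UTF-8")
  for (col in intersect(numeric_cols, names(df))) {
    raw <- df[[col]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & raw != "" & raw != "NA" & is.na(val))
    if (length(bad) > 0)
      stop(sprintf("%s: line %d, column '%s': not a number ('%s')",
                   basename(path), bad[1] + 1, col, raw[bad[1]]),
           call. = FALSE)
    df[[col]] <- val
  }
  df
}

#' Read a catchment database directory
#'
#' Loads the plain-CSV catchment database (`segments.csv`, `nodes.csv` and,
#' when present, `wwtps.csv`, `hospitals.csv`, `gauges.csv`,
#' `monitoring_sites.csv`; UTF-8, header row, decimal point) and validates
#' it.  Parse problems are reported with file, line and column; an invalid
#' catchment raises an error listing every violation.
#'
#' @param directory Path of the database directory.
#' @param sep Field separator: `","` (default) or `";"` for the
#'   semicolon dialect common in German-locale exports.
#' @return A validated [catchment()].
#' @export
read_catchment <- function(directory, sep = ",") {
  if (!dir.exists(directory)) stop("no such directory: ", directory)
  paths <- file.path(directory, .CATCHMENT_FILES)
  names(paths) <- names(.CATCHMENT_FILES)
  for (part in c("segments", "nodes"))
    if (!file.exists(paths[[part]]))
      stop("required file missing: ", .CATCHMENT_FILES[[part]])
  tabs <- list()
  for (part in names(paths)) {
    tabs[[part]] <- if (file.exists(paths[[part]]))
      .read_table(paths[[part]], .NUMERIC_COLS[[part]], sep) else NULL
  }
  ct <- catchment(tabs$segments, tabs$nodes, tabs$wwtps, tabs$hospitals,
                  tabs$gauges, tabs$monitoring_sites)
  rep <- validate_catchment(ct)
  if (nrow(rep) > 0)
    stop("invalid catchment database:\n",
         paste(sprintf("  %s %s: %s", rep$entity, rep$id, rep$rule),
               collapse = "\n"))
  ct
}

# full-precision numeric formatting so write -> read round-trips exactly
.fmt_full <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else sprintf("%.17g", v)
  }, character(1))
  out
}

.write_table <- function(df, path, numeric_cols) {
  out <- df
  for (col in intersect(numeric_cols, names(out)))
    out[[col]] <- .fmt_full(out[[col]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8", na = "")
}

#' Write a catchment database directory
#'
#' Inverse of [read_catchment()]; numeric fields are written with enough
#' digits that a read-back reproduces the doubles bit-exactly.
#'
#' @param ct A [catchment()].
#' @param directory Output directory (created if needed).
#' @return `directory`, invisibly.
#' @export
write_catchment <- function(ct, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  for (part in names(.CATCHMENT_FILES))
    .write_table(ct[[part]], file.path(directory, .CATCHMENT_FILES[[part]]),
                 .NUMERIC_COLS[[part]])
  invisible(directory)
}

#' Read a substance parameter file
#'
#' JSON key-value file with keys matching the [substance()] arguments;
#' `removal` is a nested object keyed by treatment category.
#'
#' @param path Path to the JSON file.
#' @return A [substance()].
#' @export
read_substance <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(substance, cfg)
}

#' Write a substance parameter file
#'
#' @param sub A [substance()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_substance <- function(sub, path) {
  out <- unclass(sub)
  out$removal <- as.list(out$removal)  # keep category names in the JSON
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read long-format monitoring observations
#'
#' Expects columns `site_id`, `value_ng_l` and optionally `date`.
#'
#' @param path Path to observations.csv.
#' @param sep Field separator.
#' @return Named list, site_id -> numeric vector of observations.
#' @export
read_observations <- function(path, sep = ",") {
  df <- .read_table(path, "value_ng_l", sep)
  if (!all(c("site_id", "value_ng_l") %in% names(df)))
    stop("observations file needs columns site_id, value_ng_l")
  split(df$value_ng_l, df$site_id)
}

#' Write a per-segment summary (or comparison) table as CSV
#'
#' Deterministic output: fixed column order, numbers at 6 significant
#' digits, so identical runs give byte-identical files.
#'
#' @param x A summary data.frame from [summarize()] or a
#'   `scenario_comparison` from [compare()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(x, path) {
  out <- as.data.frame(x)
  for (col in names(out))
    if (is.numeric(out[[col]]))
      out[[col]] <- ifelse(is.na(out[[col]]), "",
                           sprintf("%.6g", out[[col]]))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' Export per-segment results as a GeoJSON FeatureCollection
#'
#' One LineString feature per segment (straight line between the segment's
#' end nodes) with the segment id and the chosen value or class columns as
#' properties; suitable for color-coded concentration or scenario-change
#' maps in any GIS.
#'
#' @param x A summary data.frame from [summarize()] or a
#'   `scenario_comparison` from [compare()].
#' @param ct The [catchment()] (provides node coordinates).
#' @param path Optional output path; when given the GeoJSON is written
#'   there (RFC 7946).
#' @param properties Columns of `x` to attach as feature properties
#'   (default: all except `segment_id`).
#' @param breaks Optional numeric breaks; when given, a `bin` property
#'   with the interval index of the first property column is added
#'   (for color-coded class maps).
#' @return The FeatureCollection as a list, invisibly when writing.
#' @export
export_geojson <- function(x, ct, path = NULL,
                           properties = setdiff(names(x), "segment_id"),
                           breaks = NULL) {
  sg <- ct$segments
  nd <- ct$nodes
  rownames(nd) <- nd$node_id
  feats <- vector("list", nrow(x))
  for (i in seq_len(nrow(x))) {
    sid <- x$segment_id[i]
    row <- sg[sg$segment_id == sid, ]
    if (nrow(row) == 0) stop("unknown segment in results: ", sid)
    coords <- list(c(nd[row$from_node, "x"], nd[row$from_node, "y"]),
                   c(nd[row$to_node, "x"], nd[row$to_node, "y"]))
    props <- c(list(segment_id = sid),
               lapply(properties, function(p) x[[p]][i]))
    names(props) <- c("segment_id", properties)
    if (!is.null(breaks))
      props$bin <- findInterval(x[[properties[1]]][i], breaks)
    feats[[i]] <- list(type = "Feature",
                       geometry = list(type = "LineString",
                                       coordinates = coords),
                       properties = props)
  }
  fc <- list(type = "FeatureCollection", features = feats)
  if (!is.null(path)) {
    jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
    return(invisible(fc))
  }
  fc
}
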