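# CSV ingestion and serialization. Two on-disk layouts:
#   samples CSV : record_id,time_min,hr,sbp,map        (one row per sample)
#   manifest CSV: record_id,record_type,event_time_min,
#                 baseline_start_min,baseline_end_min  (one row per record)
#   fiducial CSV: record_id,record_type,time_event_min,time_warning_min
# "NA" is the only missing-value token.

check_columns <- function(df, required, what) {
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop(what, " is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  invisible(df)
}

read_csv_na <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "NA")
}

#' Read a cohort of monitored records from samples + manifest CSVs
#'
#' The samples file holds the vital-sign time series, one row per sample; the
#' manifest holds one row of per-record metadata (record type, event time,
#' baseline window) keyed by `record_id`. Rows are grouped by record and
#' sorted by time; each record is validated (uniform sampling, event time
#' within span, at most one event).
#'
#' @param samples_path Path to the samples CSV
#'   (`record_id,time_min,hr,sbp,map`).
#' @param manifest_path Path to the manifest CSV
#'   (`record_id,record_type,event_time_min,baseline_start_min,baseline_end_min`).
#' @param tol Relative tolerance on sampling uniformity.
#' @return A named list of [record_series()] objects (possibly empty).
#' @export
read_records <- function(samples_path, manifest_path, tol = 1e-6) {
  samples <- read_csv_na(samples_path)
  check_columns(samples, c("record_id", "time_min", "hr", "sbp", "map"),
                paste0("samples file '", samples_path, "'"))
  manifest <- read_csv_na(manifest_path)
  check_columns(manifest,
                c("record_id", "record_type", "event_time_min",
                  "baseline_start_min", "baseline_end_min"),
                paste0("manifest file '", manifest_path, "'"))
  if (anyDuplicated(manifest$record_id)) {
    stop("manifest has duplicated record_id(s): ",
         paste(unique(manifest$record_id[duplicated(manifest$record_id)]),
               collapse = ", "), call. = FALSE)
  }
  if (nrow(samples) == 0L) return(structure(list(), names = character()))
  ids <- unique(samples$record_id)
  unknown <- setdiff(ids, manifest$record_id)
  if (length(unknown)) {
    stop("record(s) present in samples but absent from manifest: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  records <- lapply(ids, function(id) {
    rows <- samples[samples$record_id == id, , drop = FALSE]
    rows <- rows[order(rows$time_min), , drop = FALSE]
    meta <- manifest[manifest$record_id == id, , drop = FALSE]
    bw <- c(meta$baseline_start_min, meta$baseline_end_min)
    if (anyNA(bw)) bw <- NULL
    record_series(
      record_id = id,
      times = rows$time_min, hr = rows$hr, sbp = rows$sbp, map = rows$map,
      record_type = meta$record_type,
      event_time = meta$event_time_min,
      baseline_window = bw, tol = tol
    )
  })
  names(records) <- ids
  records
}

#' Write a cohort of records as samples + manifest CSVs
#'
#' Inverse of [read_records()]: `read_records` applied to the written pair
#' reproduces the cohort field-for-field.
#'
#' @param records Named list of [record_series()] objects.
#' @param samples_path,manifest_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_records <- function(records, samples_path, manifest_path) {
  samples <- do.call(rbind, lapply(records, function(r) {
    data.frame(record_id = r$record_id, time_min = r$times, hr = r$hr,
               sbp = r$sbp,
               map = if (is.null(r$map)) NA_real_ else r$map,
               stringsAsFactors = FALSE)
  }))
  if (is.null(samples)) {
    samples <- data.frame(record_id = character(), time_min = numeric(),
                          hr = numeric(), sbp = numeric(), map = numeric())
  }
  manifest <- do.call(rbind, lapply(records, function(r) {
    bw <- if (is.null(r$baseline_window)) c(NA_real_, NA_real_) else
      r$baseline_window
    data.frame(record_id = r$record_id, record_type = r$record_type,
               event_time_min = r$event_time,
               baseline_start_min = bw[1L], baseline_end_min = bw[2L],
               stringsAsFactors = FALSE)
  }))
  if (is.null(manifest)) {
    manifest <- data.frame(record_id = character(), record_type = character(),
                           event_time_min = numeric(),
                           baseline_start_min = numeric(),
                           baseline_end_min = numeric())
  }
  utils::write.csv(samples, samples_path, row.names = FALSE, na = "NA",
                   quote = FALSE)
  utils::write.csv(manifest, manifest_path, row.names = FALSE, na = "NA",
                   quote = FALSE)
  invisible(c(samples = samples_path, manifest = manifest_path))
}

#' Read a fiducial table from CSV
#'
#' Columns `record_id,record_type,time_event_min,time_warning_min`; the
#' literal token `NA` encodes an undefined fiducial (undefined event time on
#' non-event records, undefined warning onset on warningless records). All
#' [fiducial_table()] invariants are enforced.
#'
#' @param path Path to the fiducial CSV.
#' @return A `fiducial_table` data frame.
#' @export
read_fiducials <- function(path) {
  df <- read_csv_na(path)
  check_columns(df, c("record_id", "record_type", "time_event_min",
                      "time_warning_min"),
                paste0("fiducial file '", path, "'"))
  df$record_id <- as.character(df$record_id)
  df$record_type <- as.character(df$record_type)
  df$time_event_min <- as.numeric(df$time_event_min)
  df$time_warning_min <- as.numeric(df$time_warning_min)
  validate_fiducial_table(df)
}

#' Write a fiducial table to CSV
#'
#' Lossless round trip: `read_fiducials(write_fiducials(x, p))` equals `x`
#' field-for-field, including `NA` patterns and fractional minutes.
#'
#' @param rows A `fiducial_table` data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fiducials <- function(rows, path) {
  rows <- validate_fiducial_table(as.data.frame(rows))
  out <- rows[, c("record_id", "record_type", "time_event_min",
                  "time_warning_min")]
  # format() would truncate; rely on write.csv's full-precision numerics
  utils::write.csv(out, path, row.names = FALSE, na = "NA", quote = FALSE)
  invisible(path)
}

#' Read a flat key-value configuration file
#'
#' One `key = value` pair per line; `#` starts a comment. Recognized keys are
#' `t_min_min`, `t_max_min`, `threshold`, `off_delay_min`,
#' `sample_interval_min`; unspecified keys fall back to the case-study
#' defaults of [framework_config()].
#'
#' @param path Path to the config file.
#' @return A [framework_config()] object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, length, 1L) != 2L
  if (any(bad)) {
    stop("config line(s) not of the form key = value: ",
         paste(lines[bad], collapse = "; "), call. = FALSE)
  }
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- suppressWarnings(as.numeric(trimws(vapply(kv, `[`, "", 2L))))
  if (anyNA(vals)) {
    stop("non-numeric config value for key(s): ",
         paste(keys[is.na(vals)], collapse = ", "), call. = FALSE)
  }
  known <- c("t_min_min", "t_max_min", "threshold", "off_delay_min",
             "sample_interval_min")
  unknown <- setdiff(keys, known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  get_or <- function(key, default) if (key %in% keys) vals[keys == key][1L]
    else default
  framework_config(
    t_min = get_or("t_min_min", 1),
    t_max = get_or("t_max_min", 14),
    threshold = get_or("threshold", 0.9),
    off_delay = get_or("off_delay_min", 10),
    sample_interval = get_or("sample_interval_min", 1)
  )
}

#' Write a framework configuration as a flat key-value file
#'
#' @param config A [framework_config()] object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "framework_config"))
  writeLines(c(
    sprintf("t_min_min = %.17g", config$t_min),
    sprintf("t_max_min = %.17g", config$t_max),
    sprintf("threshold = %.17g", config$threshold),
    sprintf("off_delay_min = %.17g", config$off_delay),
    sprintf("sample_interval_min = %.17g", config$sample_interval)
  ), path)
  invisible(path)
}
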