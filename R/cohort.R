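#' @title Hemodynamic cohort tables
#' @description
#' A cohort is a plain data frame with one row per 20-s averaged monitor
#' sample and columns `patient_id`, `t_s` (seconds from monitoring start),
#' `map`, `sbp`, `dbp` (mmHg), `hr` (beats/min), `score` (prediction index in
#' \[0,100\], `NA` where the index is unavailable), and `quality_ok`
#' (logical sample-quality flag). A "record" is the sub-table of one
#' patient. All downstream stages operate on this shape.
#' @name hemo_cohort
NULL

.cohort_cols <- c("patient_id", "t_s", "map", "sbp", "dbp", "hr",
                  "score", "quality_ok")

empty_cohort <- function() {
  structure(
    data.frame(patient_id = character(), t_s = numeric(), map = numeric(),
               sbp = numeric(), dbp = numeric(), hr = numeric(),
               score = numeric(), quality_ok = logical(),
               stringsAsFactors = FALSE),
    class = c("hemo_cohort", "data.frame")
  )
}

#' Validate and classify a cohort data frame
#'
#' Checks the column set and the structural invariants every stage relies
#' on: timestamps nonnegative and strictly increasing within each patient,
#' MAP positive, scores (where present) in \[0,100\], and `dbp <= map <= sbp`
#' wherever all three pressures are present.
#'
#' @param x Data frame with the cohort columns (see [hemo_cohort]).
#' @return `x`, ordered by patient then time, with class `hemo_cohort`.
#' @export
as_hemo_cohort <- function(x) {
  if (!is.data.frame(x)) stop("cohort must be a data frame", call. = FALSE)
  missing_cols <- setdiff(.cohort_cols, names(x))
  if (length(missing_cols)) {
    stop("cohort is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  x <- as.data.frame(x)[, .cohort_cols]
  x$patient_id <- as.character(x$patient_id)
  x$quality_ok <- as.logical(x$quality_ok)
  if (nrow(x) == 0L) return(structure(x, class = c("hemo_cohort", "data.frame")))
  x <- x[order(x$patient_id, x$t_s), , drop = FALSE]
  rownames(x) <- NULL
  for (col in c("t_s", "map", "sbp", "dbp", "hr")) {
    if (anyNA(x[[col]])) {
      stop("cohort column '", col, "' contains missing values", call. = FALSE)
    }
  }
  if (any(x$t_s < 0)) stop("timestamps must be >= 0", call. = FALSE)
  if (any(x$map <= 0)) stop("MAP must be positive", call. = FALSE)
  sc <- x$score[!is.na(x$score)]
  if (length(sc) && (any(sc < 0) || any(sc > 100))) {
    stop("scores must lie in [0, 100]", call. = FALSE)
  }
  bad_bp <- x$dbp > x$map | x$map > x$sbp
  if (any(bad_bp)) {
    stop("pressure ordering violated (need dbp <= map <= sbp) at row ",
         which(bad_bp)[1L], call. = FALSE)
  }
  dup <- unlist(lapply(split(x$t_s, x$patient_id), function(t) diff(t) <= 0),
                use.names = FALSE)
  if (any(dup)) {
    stop("timestamps must be strictly increasing within each patient",
         call. = FALSE)
  }
  structure(x, class = c("hemo_cohort", "data.frame"))
}

#' Split a cohort into per-patient records
#'
#' @param cohort A [hemo_cohort] data frame.
#' @return Named list of single-patient data frames, time-ordered.
#' @export
split_records <- function(cohort) {
  if (nrow(cohort) == 0L) return(list())
  recs <- split(as.data.frame(cohort), cohort$patient_id)
  lapply(recs, function(r) {
    r <- r[order(r$t_s), , drop = FALSE]
    rownames(r) <- NULL
    r
  })
}

#' Bind per-patient records back into a cohort
#'
#' @param records List of single-patient data frames.
#' @return A [hemo_cohort] data frame.
#' @export
bind_records <- function(records) {
  if (!length(records)) return(empty_cohort())
  out <- do.call(rbind, c(records, list(make.row.names = FALSE)))
  structure(out, class = c("hemo_cohort", "data.frame"))
}

#' Read a cohort from the monitor-export CSV dialect
#'
#' The dialect is UTF-8, comma-separated, dot decimal, one row per sample,
#' header `patient_id,t_s,map,sbp,dbp,hr,score,quality_ok`. Empty `score`
#' cells mean the index was unavailable at that sample and are read as `NA`,
#' never as zero.
#'
#' @param path Path to a CSV file in the dialect above.
#' @return A [hemo_cohort] data frame (empty for a header-only file).
#' @export
read_records <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- tryCatch(
    utils::read.csv(path, colClasses = c(patient_id = "character"),
                    na.strings = "", stringsAsFactors = FALSE),
    error = function(e) stop("malformed CSV '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  missing_cols <- setdiff(.cohort_cols, names(raw))
  if (length(missing_cols)) {
    stop("'", path, "' lacks required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0L) return(empty_cohort())
  for (col in c("t_s", "map", "sbp", "dbp", "hr")) {
    bad <- which(is.na(raw[[col]]))
    if (length(bad)) {
      stop("malformed row at line ", bad[1L] + 1L, " of '", path,
           "': missing '", col, "'", call. = FALSE)
    }
  }
  ql <- tolower(as.character(raw$quality_ok))
  if (!all(ql %in% c("true", "false"))) {
    stop("malformed 'quality_ok' values in '", path,
         "' (expected true/false)", call. = FALSE)
  }
  raw$quality_ok <- ql == "true"
  for (col in c("t_s", "map", "sbp", "dbp", "hr", "score")) {
    raw[[col]] <- as.numeric(raw[[col]])
  }
  # preserve file order per patient: timestamps must already be increasing
  for (pid in unique(raw$patient_id)) {
    t <- raw$t_s[raw$patient_id == pid]
    if (any(diff(t) <= 0)) {
      stop("validation error: non-increasing timestamps for patient '",
           pid, "'", call. = FALSE)
    }
  }
  as_hemo_cohort(raw)
}

#' Write a cohort to the monitor-export CSV dialect
#'
#' Numeric fields are written with 17 significant digits so that
#' `read_records(write_records(x))` reproduces every double exactly. Absent
#' scores become empty cells.
#'
#' @param cohort A [hemo_cohort] data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_records <- function(cohort, path) {
  cohort <- as_hemo_cohort(cohort)
  fmt <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))
  out <- data.frame(
    patient_id = cohort$patient_id,
    t_s = fmt(cohort$t_s), map = fmt(cohort$map), sbp = fmt(cohort$sbp),
    dbp = fmt(cohort$dbp), hr = fmt(cohort$hr), score = fmt(cohort$score),
    quality_ok = ifelse(cohort$quality_ok, "true", "false"),
    stringsAsFactors = FALSE
  )
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write to '", path, "'", call. = FALSE)
  invisible(path)
}

#' Report spacing gaps and physiologic-range violations in a record
#'
#' Report-only: never errors. An inter-sample interval deviating from the
#' nominal spacing by more than the grid tolerance is a gap; MAP outside
#' \[20, 200\] mmHg or HR outside \[20, 250\] beats/min is a range violation.
#'
#' @param record A single-patient data frame.
#' @param cfg A [cohort_config].
#' @return List with data frames `gaps` (columns `after_t_s`, `interval_s`)
#'   and `range_violations` (columns `t_s`, `field`, `value`), plus
#'   `n_samples`.
#' @export
validate_record <- function(record, cfg = cohort_config()) {
  t <- record$t_s
  gaps <- data.frame(after_t_s = numeric(), interval_s = numeric())
  if (length(t) > 1L) {
    dt <- diff(t)
    off <- abs(dt - cfg$sample_interval) > cfg$grid_tolerance
    gaps <- data.frame(after_t_s = t[which(off)], interval_s = dt[off])
  }
  viol <- data.frame(t_s = numeric(), field = character(), value = numeric(),
                     stringsAsFactors = FALSE)
  bad_map <- record$map < 20 | record$map > 200
  bad_hr <- record$hr < 20 | record$hr > 250
  if (any(bad_map)) {
    viol <- rbind(viol, data.frame(t_s = t[bad_map], field = "map",
                                   value = record$map[bad_map]))
  }
  if (any(bad_hr)) {
    viol <- rbind(viol, data.frame(t_s = t[bad_hr], field = "hr",
                                   value = record$hr[bad_hr]))
  }
  list(gaps = gaps, range_violations = viol, n_samples = nrow(record))
}

#' Drop poor-quality samples from a record or cohort
#'
#' Samples flagged `quality_ok = FALSE` are removed outright: their time no
#' longer counts toward monitoring duration and the hole they leave breaks
#' any consecutive-sample run (no interpolation across dropouts).
#'
#' @param record A single-patient data frame or a whole [hemo_cohort].
#' @return The input without flagged rows. Warns if nothing is left.
#' @export
mask_poor_quality <- function(record) {
  out <- record[record$quality_ok, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L && nrow(record) > 0L) {
    warning("all samples flagged poor quality; record is empty after masking",
            call. = FALSE)
  }
  out
}

#' Monitoring duration over usable samples, in minutes
#'
#' Each quality-ok 20-s sample represents 20 s of monitored time, so the
#' duration is the usable-sample count times the sample interval. Masked
#' samples contribute nothing.
#'
#' @param record A single-patient data frame.
#' @param sample_interval Sample spacing in seconds.
#' @return Duration in minutes.
#' @export
monitoring_minutes <- function(record, sample_interval = 20) {
  sum(record$quality_ok) * sample_interval / 60
}
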