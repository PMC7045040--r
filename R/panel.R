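#' Construct a validated daily panel dataset
#'
#' A panel dataset holds daily count records for several subjects in long
#' format: one row per subject-day. The day index `t` is 1-based and gapless
#' within subject; days with an unrecorded count keep their row with
#' `count = NA` (missing is a first-class state, never imputed). The weekday
#' advances cyclically with `t`.
#'
#' @param data Data frame with columns `subject_id`, `t`, `weekday`, `count`.
#' @param subjects Optional data frame of subject-constant covariates
#'   (one row per subject; must contain `subject_id`; typically `gender`,
#'   `age`). Values must be constant within subject by construction.
#' @param validate Run structural validation (recommended).
#' @param allow_negative Accept negative values. Real count data are
#'   non-negative; the synthetic generator lives on an unbounded
#'   linear-Gaussian scale and sets this when rounding is off.
#' @return An object of class `panel_dataset` (a data frame with a
#'   `subjects` attribute carrying per-subject metadata).
#' @export
panel_dataset <- function(data, subjects = NULL, validate = TRUE,
                          allow_negative = FALSE) {
  req <- c("subject_id", "t", "weekday", "count")
  miss <- setdiff(req, names(data))
  if (length(miss)) {
    stop_memlag(paste("missing required columns:", paste(miss, collapse = ", ")),
                "memlag_bad_columns")
  }
  data <- as.data.frame(data)[req]
  data$subject_id <- as.character(data$subject_id)
  data$t <- as.integer(data$t)
  data$weekday <- as.character(data$weekday)
  data$count <- as.numeric(data$count)
  ord <- order(match(data$subject_id, unique(data$subject_id)), data$t)
  data <- data[ord, , drop = FALSE]
  rownames(data) <- NULL

  meta <- subject_metadata(data)
  if (!is.null(subjects)) {
    subjects <- as.data.frame(subjects)
    if (!"subject_id" %in% names(subjects)) {
      stop_memlag("`subjects` must contain a subject_id column", "memlag_bad_columns")
    }
    subjects$subject_id <- as.character(subjects$subject_id)
    if (anyDuplicated(subjects$subject_id)) {
      stop_memlag("duplicate subject ids in `subjects`", "memlag_duplicate_subject")
    }
    meta <- merge(meta, subjects, by = "subject_id", all.x = TRUE, sort = FALSE)
    meta <- meta[match(unique(data$subject_id), meta$subject_id), , drop = FALSE]
    rownames(meta) <- NULL
  }

  out <- structure(data, subjects = meta,
                   class = c("panel_dataset", "data.frame"))
  if (validate) validate_panel(out, allow_negative = allow_negative)
  out
}

subject_metadata <- function(data) {
  ids <- unique(data$subject_id)
  n_days <- vapply(split(data$t, data$subject_id)[ids], length, integer(1))
  first_wd <- vapply(split(data$weekday, data$subject_id)[ids],
                     function(w) w[1L], character(1))
  data.frame(subject_id = ids, n_days = as.integer(n_days),
             start_weekday = first_wd, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Validate panel structure
#'
#' Checks the invariants of a [panel_dataset()]: unique (subject, day) rows,
#' 1-based gapless day indices, cyclic weekday progression, and non-negative
#' counts. Missing counts (`NA`) are allowed anywhere.
#'
#' @param x A `panel_dataset`.
#' @param allow_negative Skip the non-negativity check (synthetic
#'   linear-Gaussian panels).
#' @return `x`, invisibly, or a classed error locating the offending rows.
#' @export
validate_panel <- function(x, allow_negative = FALSE) {
  if (nrow(x) == 0L) return(invisible(x))
  key <- paste(x$subject_id, x$t)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    stop_memlag(sprintf("duplicate (subject, t) record: %s", dup),
                "memlag_duplicate_record")
  }
  bad_count <- if (allow_negative) integer() else
    which(!is.na(x$count) & x$count < 0)
  if (length(bad_count)) {
    stop_memlag(sprintf("negative count at row %d (subject %s, t %d)",
                        bad_count[1L], x$subject_id[bad_count[1L]],
                        x$t[bad_count[1L]]),
                "memlag_negative_count")
  }
  weekday_index(x$weekday)  # errors on invalid labels
  for (id in unique(x$subject_id)) {
    rows <- which(x$subject_id == id)
    tt <- x$t[rows]
    if (tt[1L] != 1L || any(diff(tt) != 1L)) {
      stop_memlag(sprintf("subject %s: day index must be 1-based and gapless", id),
                  "memlag_bad_day_index")
    }
    expected <- weekday_sequence(x$weekday[rows[1L]], length(rows))
    off <- which(x$weekday[rows] != expected)
    if (length(off)) {
      stop_memlag(sprintf("subject %s: weekday sequence not cyclic at t = %d (got %s, expected %s)",
                          id, tt[off[1L]], x$weekday[rows[off[1L]]], expected[off[1L]]),
                  "memlag_bad_weekday_cycle")
    }
  }
  invisible(x)
}

#' Read a long-format panel CSV
#'
#' Reads comma-separated UTF-8 data with a header row. Arbitrary column
#' headers are absorbed by `mapping`; a blank or `NA` count cell becomes a
#' missing day (kept as a row, never imputed). When the file has no weekday
#' column, weekdays are derived by cycling from `start_weekday`.
#'
#' @param path CSV file path.
#' @param mapping Named list mapping the canonical names `subject_id`, `t`,
#'   `weekday`, `count` to the file's column headers. A missing `weekday`
#'   entry means the column is absent and must be derived. May also be a
#'   path to a JSON file holding the same structure.
#' @param start_weekday Start weekday used when the file has no weekday
#'   column: a single label, or a named vector keyed by subject id.
#' @param subjects Optional subject-covariate data frame, see [panel_dataset()].
#' @return A validated `panel_dataset`.
#' @export
read_panel_csv <- function(path,
                           mapping = list(subject_id = "subject_id", t = "t",
                                          weekday = "weekday", count = "count"),
                           start_weekday = NULL, subjects = NULL) {
  if (!file.exists(path)) {
    stop_memlag(sprintf("file not found: %s", path), "memlag_file_not_found")
  }
  if (is.character(mapping) && length(mapping) == 1L) {
    mapping <- jsonlite::read_json(mapping, simplifyVector = TRUE)
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", na.strings = c("NA", ""))
  for (nm in c("subject_id", "t", "count")) {
    col <- mapping[[nm]]
    if (is.null(col) || !col %in% names(raw)) {
      stop_memlag(sprintf("cannot resolve column for '%s'", nm), "memlag_bad_columns")
    }
  }
  df <- data.frame(subject_id = raw[[mapping$subject_id]],
                   t = as.integer(raw[[mapping$t]]),
                   count = as.numeric(raw[[mapping$count]]),
                   stringsAsFactors = FALSE)
  wd_col <- mapping$weekday
  if (!is.null(wd_col) && wd_col %in% names(raw)) {
    df$weekday <- raw[[wd_col]]
  } else {
    if (is.null(start_weekday)) {
      stop_memlag("no weekday column; supply `start_weekday`", "memlag_bad_columns")
    }
    df$weekday <- NA_character_
    for (id in unique(df$subject_id)) {
      rows <- which(df$subject_id == id)
      sw <- if (length(start_weekday) == 1L && is.null(names(start_weekday)))
        start_weekday else start_weekday[[id]]
      df$weekday[rows[order(df$t[rows])]] <- weekday_sequence(sw, length(rows))
    }
  }
  panel_dataset(df[c("subject_id", "t", "weekday", "count")], subjects = subjects)
}

#' Write a panel dataset as CSV
#'
#' Counts are written with full precision (`format(..., digits = 17)` for
#' non-integers) so that `read_panel_csv()` round-trips bit-stably; missing
#' days are written as empty cells.
#'
#' @param x A `panel_dataset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_panel_csv <- function(x, path) {
  out <- as.data.frame(x)
  cnt <- vapply(out$count, function(v) {
    if (is.na(v)) "" else format(v, digits = 17, scientific = FALSE, trim = TRUE)
  }, character(1))
  out$count <- cnt
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Convert a person-level wide table to a longitudinal panel
#'
#' One wide row per subject, one column per day, in day order. Ragged
#' records are supported: trailing empty cells mean the record ended,
#' interior empty cells are missing days. Day columns named `day_<k>` are
#' checked for monotone `k`.
#'
#' @param wide Data frame whose first column (or `id_col`) is the subject id
#'   and remaining columns are days in chronological order.
#' @param id_col Name or index of the subject-id column.
#' @param start_weekday Weekday of day 1: single label or named vector by
#'   subject id.
#' @param subjects Optional subject-covariate data frame.
#' @return A validated `panel_dataset`.
#' @export
to_longitudinal <- function(wide, id_col = 1L, start_weekday = "Mon",
                            subjects = NULL) {
  wide <- as.data.frame(wide)
  if (nrow(wide) == 0L) {
    return(panel_dataset(data.frame(subject_id = character(), t = integer(),
                                    weekday = character(), count = numeric())))
  }
  ids <- as.character(wide[[id_col]])
  day_cols <- setdiff(seq_along(wide), if (is.character(id_col))
    match(id_col, names(wide)) else id_col)
  day_names <- names(wide)[day_cols]
  ks <- suppressWarnings(as.integer(sub("^day[._]?", "", day_names)))
  if (!anyNA(ks) && any(diff(ks) <= 0)) {
    stop_memlag("day columns are not in increasing order", "memlag_bad_day_index")
  }
  if (anyDuplicated(ids)) {
    stop_memlag("duplicate subject ids in wide table", "memlag_duplicate_subject")
  }
  rows <- lapply(seq_along(ids), function(i) {
    vals <- as.numeric(unlist(wide[i, day_cols], use.names = FALSE))
    last <- max(c(0L, which(!is.na(vals))))
    if (last == 0L) return(NULL)
    vals <- vals[seq_len(last)]
    sw <- if (length(start_weekday) == 1L && is.null(names(start_weekday)))
      start_weekday else start_weekday[[ids[i]]]
    data.frame(subject_id = ids[i], t = seq_len(last),
               weekday = weekday_sequence(sw, last), count = vals,
               stringsAsFactors = FALSE)
  })
  panel_dataset(do.call(rbind, rows), subjects = subjects)
}

#' Summarize a panel dataset
#'
#' @param x A `panel_dataset`.
#' @return List with subject count, record-length distribution and mode
#'   (ties broken toward the smallest length), missing fraction, and a
#'   gender/age breakdown when those covariates are present.
#' @export
summarize_panel <- function(x) {
  if (nrow(x) == 0L) {
    stop_memlag("cannot summarize an empty panel", "memlag_empty_panel")
  }
  meta <- attr(x, "subjects")
  lens <- meta$n_days
  tab <- table(lens)
  mode_len <- as.integer(names(tab)[which.max(tab)])  # which.max takes first = smallest
  out <- list(
    n_subjects = nrow(meta),
    n_obs = nrow(x),
    n_missing = sum(is.na(x$count)),
    missing_fraction = mean(is.na(x$count)),
    lengths = lens,
    length_mode = mode_len
  )
  if ("gender" %in% names(meta)) out$gender <- table(meta$gender)
  if ("age" %in% names(meta)) {
    out$age <- c(mean = mean(meta$age, na.rm = TRUE),
                 min = suppressWarnings(min(meta$age, na.rm = TRUE)),
                 max = suppressWarnings(max(meta$age, na.rm = TRUE)))
  }
  structure(out, class = "panel_summary")
}

#' @export
print.panel_summary <- function(x, ...) {
  cat(sprintf("Panel: %d subjects, %d subject-days (%.2f%% missing)\n",
              x$n_subjects, x$n_obs, 100 * x$missing_fraction))
  cat(sprintf("Record lengths %d-%d, mode %d\n",
              min(x$lengths), max(x$lengths), x$length_mode))
  invisible(x)
}

#' @export
print.panel_dataset <- function(x, ...) {
  meta <- attr(x, "subjects")
  cat(sprintf("<panel_dataset> %d subjects, %d rows\n", nrow(meta), nrow(x)))
  print(utils::head(as.data.frame(x)))
  invisible(x)
}
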