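#' Read a capture-record file and its sampling-session calendar
#'
#' Reads a delimited text file of individual capture records from a
#' mark-release-recapture (MRR) survey, validates every row, and builds the
#' session calendar. Required columns: `id`, `date` (ISO-8601), `sex`
#' (`M`/`F` or `male`/`female`), `x`, `y`, `wing` (integer 1--4). Optional
#' columns: `crs` (`metric`, the default, or `geodetic` for lon/lat),
#' `behaviour` (`flying`, `resting`, `feeding`, `interaction`), `family` and
#' `genus` (nectar plant taxon; only permitted on `feeding` rows).
#'
#' Geodetic coordinates are, by default, converted once at ingestion to a
#' local tangent-plane metric projection centred on the data centroid;
#' at the sub-kilometre scale of a typical butterfly study the projection
#' error is negligible. With `project = FALSE` lon/lat values are retained
#' and the geodetic flag is propagated, in which case distance-based
#' analyses will refuse the data and ask for re-ingestion.
#'
#' @param path Path to the delimited capture file (header row required).
#' @param effort Optional sampling-effort table: a data frame (or path to a
#'   delimited file) with columns `date` and `hours`. When given, it defines
#'   the session calendar; every capture date must appear in it. When absent
#'   the calendar is the set of distinct capture dates.
#' @param delim Field delimiter, default `","`.
#' @param project Convert geodetic rows to local planar metres (default TRUE).
#' @return A list with elements `records` (a tibble of validated capture
#'   records, with a `session` index column) and `sessions` (a tibble with
#'   `session`, `date`, `hours`, `gap_days`; `gap_days` is the calendar gap
#'   to the next session and is `NA` for the last one).
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("id,date,sex,x,y,wing",
#'              "a1,2016-07-20,M,10,20,1",
#'              "a1,2016-07-22,M,30,40,2",
#'              "b2,2016-07-22,F,5,5,1"), f)
#' cap <- read_captures(f)
#' cap$sessions
read_captures <- function(path, effort = NULL, delim = ",", project = TRUE) {
  if (!file.exists(path)) stop_mrr(paste0("capture file not found: ", path), "io_error")
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE,
                           col_types = readr::cols(.default = readr::col_character()))
  required <- c("id", "date", "sex", "x", "y", "wing")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop_mrr(paste0("missing required column(s): ",
                    paste(missing_cols, collapse = ", ")), "schema_error")
  }
  n <- nrow(raw)
  rec <- tibble::tibble(
    row = seq_len(n),
    id = raw$id,
    date = as.Date(raw$date),
    sex = normalize_sex(raw$sex),
    x = as.numeric(raw$x),
    y = as.numeric(raw$y),
    crs = if ("crs" %in% names(raw)) raw$crs else "metric",
    wing = suppressWarnings(as.numeric(raw$wing)),
    behaviour = if ("behaviour" %in% names(raw)) raw$behaviour else NA_character_,
    family = if ("family" %in% names(raw)) raw$family else NA_character_,
    genus = if ("genus" %in% names(raw)) raw$genus else NA_character_
  )
  rec$crs[is.na(rec$crs) | rec$crs == ""] <- "metric"

  bad_date <- which(is.na(rec$date))
  if (length(bad_date) > 0)
    stop_mrr(paste0("unparseable date in row(s): ",
                    paste(bad_date, collapse = ", ")), "validation_error")
  bad_sex <- which(is.na(rec$sex))
  if (length(bad_sex) > 0)
    stop_mrr(paste0("unknown sex code in row(s): ",
                    paste(bad_sex, collapse = ", ")), "validation_error")
  bad_wing <- which(!(rec$wing %in% 1:4))
  if (length(bad_wing) > 0)
    stop_mrr(paste0("wing score outside 1-4 in row(s): ",
                    paste(bad_wing, collapse = ", ")), "validation_error")
  rec$wing <- as.integer(rec$wing)
  bad_crs <- which(!rec$crs %in% c("metric", "geodetic"))
  if (length(bad_crs) > 0)
    stop_mrr(paste0("crs must be 'metric' or 'geodetic'; bad row(s): ",
                    paste(bad_crs, collapse = ", ")), "validation_error")
  ok_beh <- c("flying", "resting", "feeding", "interaction")
  bad_beh <- which(!is.na(rec$behaviour) & !rec$behaviour %in% ok_beh)
  if (length(bad_beh) > 0)
    stop_mrr(paste0("unknown behaviour in row(s): ",
                    paste(bad_beh, collapse = ", ")), "validation_error")
  has_flower <- !is.na(rec$family) | !is.na(rec$genus)
  bad_flower <- which(has_flower &
                        (is.na(rec$behaviour) | rec$behaviour != "feeding"))
  if (length(bad_flower) > 0)
    stop_mrr(paste0("nectar taxon recorded on non-feeding row(s): ",
                    paste(bad_flower, collapse = ", ")), "validation_error")

  if (project && any(rec$crs == "geodetic")) {
    g <- rec$crs == "geodetic"
    proj <- project_local(rec$x[g], rec$y[g])
    rec$x[g] <- proj$x
    rec$y[g] <- proj$y
    rec$crs[g] <- "metric"
  }

  if (!is.null(effort)) {
    if (is.character(effort)) {
      effort <- readr::read_delim(effort, delim = delim, show_col_types = FALSE,
                                  progress = FALSE)
    }
    if (!all(c("date", "hours") %in% names(effort)))
      stop_mrr("effort table needs columns 'date' and 'hours'", "schema_error")
    eff <- tibble::tibble(date = as.Date(effort$date),
                          hours = as.numeric(effort$hours)) |>
      dplyr::arrange(.data$date)
    if (anyDuplicated(eff$date) > 0)
      stop_mrr("duplicated dates in effort table", "validation_error")
    if (any(is.na(eff$hours)) || any(eff$hours <= 0))
      stop_mrr("effort hours must be positive for every session", "validation_error")
    missing_dates <- setdiff(as.character(unique(rec$date)), as.character(eff$date))
    if (length(missing_dates) > 0)
      stop_mrr(paste0("capture date(s) not in effort calendar: ",
                      paste(missing_dates, collapse = ", ")), "validation_error")
    cal_dates <- eff$date
    cal_hours <- eff$hours
  } else {
    cal_dates <- sort(unique(rec$date))
    cal_hours <- rep(NA_real_, length(cal_dates))
  }
  sessions <- tibble::tibble(
    session = seq_along(cal_dates),
    date = cal_dates,
    hours = cal_hours,
    gap_days = c(as.integer(diff(cal_dates)), NA_integer_)
  )
  rec$session <- match(rec$date, sessions$date)
  rec$row <- NULL
  list(records = rec, sessions = sessions)
}

# local tangent-plane projection (spherical earth) centred on the centroid
project_local <- function(lon, lat) {
  R <- 6371008.8
  lon0 <- mean(lon)
  lat0 <- mean(lat)
  list(x = R * cos(lat0 * pi / 180) * (lon - lon0) * pi / 180,
       y = R * (lat - lat0) * pi / 180)
}

#' Build per-individual encounter histories
#'
#' Collapses validated capture records into one encounter history per
#' individual: a binary detection vector over the session calendar plus the
#' per-detection payload (location, wing score, behaviour, nectar taxon).
#' Duplicate captures of one individual within a single session collapse to a
#' single detection keeping the first payload; the number of collapsed rows
#' is reported with a message. Conflicting sex codes for one individual are a
#' hard error (marking errors must surface, they are never majority-voted).
#'
#' @param records Validated capture records, as returned by [read_captures()]
#'   or [simulate_mrr()] (must carry a `session` column; if absent it is
#'   derived by matching `date` against `sessions`).
#' @param sessions The session calendar tibble.
#' @return A tibble of class `encounter_histories`: one row per individual
#'   with columns `id`, `sex`, `ch` (detection string such as `"1010"`),
#'   `n_det`, and `detections`, a list-column of per-detection payload
#'   tibbles. The session calendar is attached as attribute `"sessions"`.
#' @export
build_histories <- function(records, sessions) {
  S <- nrow(sessions)
  if (!"session" %in% names(records)) {
    records$session <- match(records$date, sessions$date)
  }
  if (nrow(records) == 0) {
    warn("no capture records: returning an empty history set")
    out <- tibble::tibble(id = character(), sex = character(),
                          ch = character(), n_det = integer(),
                          detections = list())
    return(new_histories(out, sessions, 0L))
  }
  if (any(is.na(records$session)))
    stop_mrr("capture date(s) outside the session calendar", "validation_error")

  sex_conflict <- records |>
    dplyr::distinct(.data$id, .data$sex) |>
    dplyr::count(.data$id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(sex_conflict) > 0)
    stop_mrr(paste0("conflicting sex codes for individual(s): ",
                    paste(sex_conflict$id, collapse = ", ")), "sex_conflict")

  deduped <- records |>
    dplyr::group_by(.data$id, .data$session) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
  n_collapsed <- nrow(records) - nrow(deduped)
  if (n_collapsed > 0)
    inform(paste0("collapsed ", n_collapsed,
                  " within-session duplicate capture(s)"))

  payload_cols <- intersect(
    c("session", "date", "x", "y", "crs", "wing", "behaviour", "family", "genus"),
    names(deduped))
  out <- deduped |>
    dplyr::arrange(.data$id, .data$session) |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(
      sex = .data$sex[1],
      ch = paste(ifelse(seq_len(S) %in% .data$session, "1", "0"), collapse = ""),
      n_det = dplyr::n(),
      detections = list(dplyr::pick(dplyr::all_of(payload_cols))),
      .groups = "drop")
  new_histories(out, sessions, n_collapsed)
}

new_histories <- function(tbl, sessions, n_collapsed) {
  structure(tbl,
            class = c("encounter_histories", class(tibble::tibble())),
            sessions = sessions,
            n_collapsed = n_collapsed)
}

#' Summarize capture and recapture totals
#'
#' Per-sex and overall counts of marked individuals, recaptured individuals
#' (seen in at least two sessions), total capture events, recapture events
#' (detections minus one, summed), and the recapture-frequency distribution
#' keyed by the number of recaptures per individual.
#'
#' @param histories An `encounter_histories` tibble from [build_histories()].
#' @return A list of class `capture_summary` with tibbles `summary` (per sex
#'   plus an `all` row) and `frequencies` (`sex`, `n_recaptures`,
#'   `n_individuals`; individuals never recaptured are not listed).
#' @export
summarize_captures <- function(histories) {
  if (nrow(histories) == 0)
    stop_mrr("empty history set", "validation_error")
  h <- tibble::as_tibble(histories)
  per_sex <- h |>
    dplyr::group_by(.data$sex) |>
    dplyr::summarise(marked = dplyr::n(),
                     recaptured = sum(.data$n_det >= 2),
                     capture_events = sum(.data$n_det),
                     recapture_events = sum(.data$n_det - 1L),
                     .groups = "drop")
  overall <- h |>
    dplyr::summarise(sex = "all", marked = dplyr::n(),
                     recaptured = sum(.data$n_det >= 2),
                     capture_events = sum(.data$n_det),
                     recapture_events = sum(.data$n_det - 1L))
  freq <- h |>
    dplyr::filter(.data$n_det >= 2) |>
    dplyr::count(.data$sex, n_recaptures = .data$n_det - 1L,
                 name = "n_individuals")
  structure(list(summary = dplyr::bind_rows(per_sex, overall),
                 frequencies = freq),
            class = "capture_summary")
}

#' @export
print.capture_summary <- function(x, ...) {
  cat("Capture summary\n")
  print(x$summary)
  cat("\nRecapture-frequency distribution\n")
  print(x$frequencies)
  invisible(x)
}

#' Export encounter histories in the MARK-style .inp dialect
#'
#' Writes one line per individual: the detection string followed by group
#' frequency columns (male, female) and a terminating semicolon, e.g.
#' `"101 1 0;"` for a male seen at sessions 1 and 3 of 3.
#'
#' @param histories An `encounter_histories` tibble.
#' @param path Optional output path; when `NULL` the lines are returned only.
#' @param sexes Group column order, default `c("male", "female")`.
#' @return Invisibly, the character vector of .inp lines.
#' @export
export_inp <- function(histories, path = NULL, sexes = c("male", "female")) {
  h <- tibble::as_tibble(histories)
  freq <- vapply(seq_len(nrow(h)), function(i) {
    paste(as.integer(sexes == h$sex[i]), collapse = " ")
  }, character(1))
  lines <- paste0(h$ch, " ", freq, ";")
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Read a MARK-style .inp capture-history file
#'
#' Round-trip companion to [export_inp()]. Each line must be a detection
#' string followed by one frequency column per group and a semicolon.
#'
#' @param input Path to an .inp file, or a character vector of lines.
#' @param sexes Group names matching the frequency columns.
#' @param expand Return one row per individual (`TRUE`, default) with
#'   synthesized ids, or the aggregated (`ch`, group count) table.
#' @return A tibble: either `id`, `sex`, `ch` (expanded) or `ch` plus one
#'   count column per group.
#' @export
read_inp <- function(input, sexes = c("male", "female"), expand = TRUE) {
  lines <- if (length(input) == 1 && file.exists(input)) readLines(input) else input
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!all(grepl(";\\s*$", lines)))
    stop_mrr("every .inp line must end with ';'", "parse_error")
  lines <- sub(";\\s*$", "", lines)
  parts <- strsplit(lines, "\\s+")
  bad <- which(vapply(parts, length, 1L) != 1 + length(sexes))
  if (length(bad) > 0)
    stop_mrr(paste0("malformed .inp line(s): ", paste(bad, collapse = ", ")),
             "parse_error")
  ch <- vapply(parts, `[[`, character(1), 1)
  counts <- do.call(rbind, lapply(parts, function(p) as.integer(p[-1])))
  colnames(counts) <- sexes
  agg <- tibble::as_tibble(counts)
  agg$ch <- ch
  agg <- agg[, c("ch", sexes)]
  if (!expand) return(agg)
  long <- tidyr::pivot_longer(agg, dplyr::all_of(sexes),
                              names_to = "sex", values_to = "n") |>
    dplyr::filter(.data$n > 0)
  out <- long[rep(seq_len(nrow(long)), long$n), c("ch", "sex")]
  out$id <- sprintf("inp%04d", seq_len(nrow(out)))
  out[, c("id", "sex", "ch")]
}

# detection matrix (individuals x sessions) from a histories tibble
ch_matrix <- function(histories) {
  m <- do.call(rbind, lapply(strsplit(histories$ch, ""), as.integer))
  rownames(m) <- histories$id
  m
}
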