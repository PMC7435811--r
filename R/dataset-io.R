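PLACEMENTS <- c("torso", "right_arm", "left_arm", "right_leg", "left_leg")

UCI_RATE_HZ <- 25
UCI_ROWS <- 125L
UCI_COLS <- 45L  # 5 placements x (acc xyz, gyro xyz, mag xyz)

#' Read one segment file in the daily-activities layout
#'
#' A segment file holds 5 s of readings at 25 Hz: 125 rows of 45
#' comma-separated values, 9 columns per device placement in the order
#' torso, right arm, left arm, right leg, left leg; within a placement the
#' columns are accelerometer x,y,z, gyroscope x,y,z, magnetometer x,y,z.
#' Magnetometer columns are parsed and retained but unused by the
#' recognition pipeline.
#'
#' @param path Path to the segment file (or a character vector of its
#'   lines via `text`).
#' @param text Optional character vector of lines, overriding `path`.
#' @return A tibble with one row per placement: `placement`, list-columns
#'   `accel` and `gyro` of [sensor_window()]s, and `mag`, a plain tibble of
#'   magnetometer readings.
#' @export
read_uci_segment <- function(path = NULL, text = NULL) {
  lines <- if (!is.null(text)) text else readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) != UCI_ROWS) {
    abort(sprintf("segment format error: expected %d data rows, found %d.",
                  UCI_ROWS, length(lines)))
  }
  parts <- strsplit(lines, ",", fixed = TRUE)
  ncols <- lengths(parts)
  if (any(ncols != UCI_COLS)) {
    bad <- which(ncols != UCI_COLS)[1L]
    abort(sprintf(
      "segment format error on line %d: expected %d columns, found %d.",
      bad, UCI_COLS, ncols[bad]))
  }
  vals <- suppressWarnings(vapply(parts, as.numeric, numeric(UCI_COLS)))
  if (any(is.na(vals))) {
    bad <- which(colSums(is.na(vals)) > 0)[1L]
    abort(sprintf("segment parse error: non-numeric value on line %d.", bad))
  }
  m <- t(vals)  # 125 x 45
  rows <- lapply(seq_along(PLACEMENTS), function(p) {
    base <- (p - 1L) * 9L
    blk <- function(off) tibble::tibble(x = m[, base + off + 1L],
                                        y = m[, base + off + 2L],
                                        z = m[, base + off + 3L])
    tibble::tibble(
      placement = PLACEMENTS[p],
      accel = list(sensor_window(blk(0L), "accelerometer", UCI_RATE_HZ)),
      gyro = list(sensor_window(blk(3L), "gyroscope", UCI_RATE_HZ)),
      mag = list(blk(6L)))
  })
  dplyr::bind_rows(rows)
}

#' Write a segment file in the daily-activities layout
#'
#' Inverse of [read_uci_segment()], used to build plain-text fixtures from
#' generated data. Values are written at a fixed decimal precision so
#' repeated writes of the same data are byte-identical.
#'
#' @param segment A tibble as returned by [read_uci_segment()] (a missing
#'   `mag` column is written as zeros).
#' @param path Output path; when `NULL` the lines are returned instead.
#' @param digits Decimal places; default 6.
#' @return `path` (or the lines, when `path` is `NULL`), invisibly.
#' @export
write_uci_segment <- function(segment, path = NULL, digits = 6L) {
  if (!is.data.frame(segment) || nrow(segment) != length(PLACEMENTS) ||
      !all(c("placement", "accel", "gyro") %in% names(segment))) {
    abort("`segment` must have one row per placement with accel and gyro windows.")
  }
  segment <- segment[match(PLACEMENTS, segment$placement), , drop = FALSE]
  if (any(is.na(segment$placement))) {
    abort("`segment` must cover all five placements.")
  }
  cols <- vector("list", length(PLACEMENTS))
  for (p in seq_along(PLACEMENTS)) {
    a <- segment$accel[[p]]; g <- segment$gyro[[p]]
    if (nrow(a) != UCI_ROWS || nrow(g) != UCI_ROWS) {
      abort(sprintf("segment windows must hold exactly %d samples.", UCI_ROWS))
    }
    mg <- if ("mag" %in% names(segment)) segment$mag[[p]] else
      tibble::tibble(x = numeric(UCI_ROWS), y = numeric(UCI_ROWS),
                     z = numeric(UCI_ROWS))
    cols[[p]] <- cbind(a$x, a$y, a$z, g$x, g$y, g$z, mg$x, mg$y, mg$z)
  }
  m <- do.call(cbind, cols)
  fmt <- paste0("%.", digits, "f")
  lines <- apply(m, 1L, function(r) paste(sprintf(fmt, r), collapse = ","))
  if (is.null(path)) return(invisible(lines))
  writeLines(lines, path)
  invisible(path)
}

#' Read a timestamped sensor recording (CSV or JSON)
#'
#' Parses rows of `timestamp_ns, sensor, x, y, z` — the export format of a
#' phone-side recorder sampling both sensors at a nominal rate (100 Hz in
#' the companion recordings) — into one window per sensor. The rate is
#' inferred from the median inter-sample gap; no resampling is performed.
#'
#' @param path Path to a `.csv` file with that header, or a `.json` array
#'   of records with those fields.
#' @return A tibble with one row per sensor: `sensor`, `n`, `rate_hz` and a
#'   `window` list-column of [sensor_window()]s.
#' @export
read_recording <- function(path) {
  df <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    tibble::as_tibble(jsonlite::fromJSON(path))
  } else {
    readr::read_csv(path, col_types = readr::cols(
      timestamp_ns = readr::col_double(),
      sensor = readr::col_character(),
      x = readr::col_double(), y = readr::col_double(),
      z = readr::col_double()))
  }
  if (nrow(df) == 0L) abort("empty recording.")
  need <- c("timestamp_ns", "sensor", "x", "y", "z")
  if (!all(need %in% names(df))) {
    abort(sprintf("recording must have columns %s.", paste(need, collapse = ", ")))
  }
  bad <- setdiff(unique(df$sensor), SENSOR_KINDS)
  if (length(bad)) {
    abort(sprintf("unknown sensor tag '%s' in recording.", bad[1L]))
  }
  out <- lapply(intersect(SENSOR_KINDS, unique(df$sensor)), function(sk) {
    rows <- df[df$sensor == sk, , drop = FALSE]
    ts <- rows$timestamp_ns
    if (is.unsorted(ts)) {
      abort(sprintf("sequencing error: %s timestamps decrease.", sk))
    }
    gap <- if (nrow(rows) > 1L) median(diff(ts)) else 1e9
    rate <- 1e9 / gap
    w <- sensor_window(
      tibble::tibble(t = (ts - ts[1L]) / 1e9,
                     x = rows$x, y = rows$y, z = rows$z),
      sk, sample_rate_hz = rate, duration_s = nrow(rows) / rate)
    tibble::tibble(sensor = sk, n = nrow(rows), rate_hz = rate,
                   window = list(w))
  })
  dplyr::bind_rows(out)
}

#' Write sensor windows as a timestamped recording
#'
#' Inverse of [read_recording()], used to build fixtures. CSV readings are
#' written at a fixed decimal precision (9 places, far below sensor noise)
#' so that write-read-write cycles are byte-stable.
#'
#' @param windows A list of [sensor_window()]s (e.g. one accelerometer and
#'   one gyroscope window).
#' @param path Output `.csv` or `.json` path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(windows, path) {
  rows <- dplyr::bind_rows(lapply(windows, function(w) {
    tibble::tibble(timestamp_ns = round(w$t * 1e9),
                   sensor = attr(w, "sensor_kind"),
                   x = w$x, y = w$y, z = w$z)
  }))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(rows, path, digits = NA)
  } else {
    lines <- sprintf("%.0f,%s,%.9f,%.9f,%.9f", rows$timestamp_ns,
                     rows$sensor, rows$x, rows$y, rows$z)
    writeLines(c("timestamp_ns,sensor,x,y,z", lines), path)
  }
  invisible(path)
}

#' Enrol/test split schemes
#'
#' `every_kth(k)` tags every k-th sample of each user (positions k, 2k, ...
#' in recording order, offset adjustable) as test and the rest as
#' enrolment — with 60 samples and `k = 6` this gives the 50/10 split.
#' `first_n(n)` tags each user's first `n` samples as enrolment and the
#' remainder as test.
#'
#' @param k Period of the test pattern.
#' @param offset 1-based position of the first test sample; default `k`.
#' @param n Enrolment samples per user.
#' @return A `split_scheme` for [make_split()].
#' @export
every_kth <- function(k, offset = k) {
  k <- as.integer(k)
  if (is.na(k) || k < 2L) abort("`k` must be an integer >= 2.")
  structure(list(kind = "every_kth", k = k, offset = as.integer(offset)),
            class = "split_scheme")
}

#' @rdname every_kth
#' @export
first_n <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) abort("`n` must be a positive integer.")
  structure(list(kind = "first_n", n = n), class = "split_scheme")
}

#' Tag a dataset with a deterministic enrol/test split
#'
#' @param dataset A tibble with a `user_id` column (windows or gallery);
#'   samples are split per user in row order (by `sample_id` when present).
#' @param scheme [every_kth()] or [first_n()].
#' @return The dataset with a `split` column of `"enrol"`/`"test"` tags
#'   covering every sample exactly once.
#' @export
make_split <- function(dataset, scheme) {
  if (!inherits(scheme, "split_scheme")) {
    abort("`scheme` must be every_kth() or first_n().")
  }
  if (!"user_id" %in% names(dataset)) abort("`dataset` needs a user_id column.")
  dataset <- tibble::as_tibble(dataset)
  if ("sample_id" %in% names(dataset)) {
    dataset <- dplyr::arrange(dataset, .data$user_id, .data$sample_id)
  }
  tag_user <- function(n) {
    if (scheme$kind == "every_kth") {
      idx <- seq_len(n)
      ifelse((idx - scheme$offset) %% scheme$k == 0L & idx >= scheme$offset,
             "test", "enrol")
    } else {
      if (scheme$n >= n) {
        abort(sprintf(
          "first_n(%d) leaves no test samples for a user with %d samples.",
          scheme$n, n))
      }
      c(rep("enrol", scheme$n), rep("test", n - scheme$n))
    }
  }
  dataset |>
    dplyr::group_by(.data$user_id) |>
    dplyr::mutate(split = tag_user(dplyr::n())) |>
    dplyr::ungroup()
}

#' Assemble a window dataset from a directory of segment files
#'
#' Walks the `aXX/pY/sZZ.txt` directory layout of the daily-activities
#' archive (activity / subject / segment) and collects the windows of one
#' activity at one device placement into the tabular dataset the rest of
#' the pipeline consumes. Only usable when the archive is present locally.
#'
#' @param root Directory containing the `aXX` activity folders.
#' @param activity_id Activity number (1-19).
#' @param placement One of `r toString(PLACEMENTS)`; default `"right_leg"`.
#' @return A windows tibble: `user_id`, `sample_id`, `activity`,
#'   `placement`, `accel`, `gyro`.
#' @export
read_uci_dataset <- function(root, activity_id, placement = "right_leg") {
  placement <- match.arg(placement, PLACEMENTS)
  adir <- file.path(root, sprintf("a%02d", as.integer(activity_id)))
  if (!dir.exists(adir)) abort(sprintf("no such activity directory: %s", adir))
  subjects <- sort(list.dirs(adir, recursive = FALSE))
  if (length(subjects) == 0L) abort(sprintf("no subject folders under %s", adir))
  rows <- list()
  for (sdir in subjects) {
    uid <- basename(sdir)
    files <- sort(list.files(sdir, pattern = "^s[0-9]+\\.txt$",
                             full.names = TRUE))
    for (f in files) {
      seg <- read_uci_segment(f)
      r <- seg[seg$placement == placement, , drop = FALSE]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        user_id = uid,
        sample_id = as.integer(sub("^s0*([0-9]+)\\.txt$", "\\1", basename(f))),
        activity = sprintf("a%02d", as.integer(activity_id)),
        placement = placement,
        accel = r$accel, gyro = r$gyro)
    }
  }
  dplyr::bind_rows(rows)
}
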