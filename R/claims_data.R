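CATEGORY_LEVELS <- c("pharmacy", "practice", "private")

# Accepted spellings for the three centre categories, matched case-insensitively.
CATEGORY_ALIASES <- list(
  pharmacy = c("pharmacy", "pharmacies", "apotheke"),
  practice = c("practice", "doctor", "doctors", "dentist", "doctor's or dentist's office",
               "doctors or dentists office", "office"),
  private  = c("private", "private test centre", "private testing centre", "testcentre")
)

#' Normalise centre category labels
#'
#' Maps free-text category labels (case-insensitive, with documented aliases)
#' onto the canonical levels `"pharmacy"`, `"practice"` (doctor's or dentist's
#' office) and `"private"` (private test centre).
#'
#' @param x Character vector of category labels.
#' @return Factor with levels `pharmacy`, `practice`, `private`.
#' @export
normalise_category <- function(x) {
  lx <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(lx))
  for (canon in names(CATEGORY_ALIASES)) {
    out[lx %in% CATEGORY_ALIASES[[canon]]] <- canon
  }
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    stop("unknown centre category: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  factor(out, levels = CATEGORY_LEVELS)
}

#' Define a study window
#'
#' A study window is the closed date interval covering the claims data.
#' Calendar weeks are consecutive 7-day blocks anchored at the start date
#' (not ISO weeks), indexed from 1, so that the window 2021-04-08 to
#' 2022-08-28 (508 days) spans weeks 1..73.
#'
#' @param start_date,end_date Dates (or ISO 8601 strings) delimiting the window.
#' @return An object of class `study_window` with elements `start_date`,
#'   `end_date`, `n_days`, `n_weeks`.
#' @examples
#' w <- study_window("2021-04-08", "2022-08-28")
#' w$n_weeks  # 73
#' @export
study_window <- function(start_date, end_date) {
  start_date <- as.Date(start_date)
  end_date <- as.Date(end_date)
  if (is.na(start_date) || is.na(end_date)) stop("dates must be parseable as ISO 8601")
  if (start_date > end_date) stop("start_date must not exceed end_date")
  n_days <- as.integer(end_date - start_date) + 1L
  structure(
    list(start_date = start_date, end_date = end_date,
         n_days = n_days, n_weeks = as.integer(ceiling(n_days / 7))),
    class = "study_window")
}

#' @export
print.study_window <- function(x, ...) {
  cat(sprintf("study window %s .. %s (%d days, %d weeks)\n",
              format(x$start_date), format(x$end_date), x$n_days, x$n_weeks))
  invisible(x)
}

#' Calendar-week index of dates within a study window
#'
#' @param dates Date vector.
#' @param window A [study_window()].
#' @return Integer vector of 1-based week indices.
#' @export
week_index <- function(dates, window) {
  stopifnot(inherits(window, "study_window"))
  dates <- as.Date(dates)
  if (any(dates < window$start_date | dates > window$end_date, na.rm = TRUE))
    stop("dates outside the study window")
  as.integer(as.integer(dates - window$start_date) %/% 7L) + 1L
}

#' Leading decimal digit of a positive integer
#'
#' @param n Vector of positive integers.
#' @return Integer vector of digits in 1..9.
#' @examples
#' leading_digit(c(150, 37373, 9))  # 1 3 9
#' @export
leading_digit <- function(n) {
  if (any(n <= 0 | n != floor(n))) stop("leading_digit() requires positive integers")
  # strip trailing digits arithmetically; avoids character round-trips
  n <- as.numeric(n)
  k <- floor(log10(n))
  d <- n %/% 10^k
  # guard floating log10 at exact powers of ten
  d[d == 10] <- 1
  as.integer(d)
}

#' Last decimal digit of a positive integer
#'
#' @param n Vector of positive integers.
#' @return Integer vector of digits in 0..9.
#' @examples
#' last_digit(c(150, 64, 5))  # 0 4 5
#' @export
last_digit <- function(n) {
  if (any(n <= 0 | n != floor(n))) stop("last_digit() requires positive integers")
  as.integer(n %% 10)
}

#' Read a daily claims file
#'
#' Reads delimited text with columns `centre_id,category,date,n_tests,n_positive`
#' (date ISO 8601) and validates every row: counts must be non-negative
#' integers with `n_positive <= n_tests`, dates must parse, categories must be
#' known, a centre must keep one category throughout, and `(centre_id, date)`
#' must be unique — duplicate billing rows are rejected rather than summed,
#' since duplicates in billing data are themselves a fraud signal.
#'
#' @param path Path to the claims file.
#' @param sep Field delimiter (default comma).
#' @return A `data.frame` of validated claim records with class `claims`.
#' @export
read_claims <- function(path, sep = ",") {
  if (!file.exists(path)) stop("claims file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           colClasses = "character", stringsAsFactors = FALSE,
                           strip.white = TRUE)
  needed <- c("centre_id", "category", "date", "n_tests", "n_positive")
  if (!all(needed %in% names(raw)))
    stop("claims file must have columns ", paste(needed, collapse = ", "))
  validate_claims(raw[needed])
}

#' Validate a raw claims table
#'
#' @param df Data frame with character columns `centre_id`, `category`,
#'   `date`, `n_tests`, `n_positive`.
#' @return Validated `claims` data frame.
#' @export
validate_claims <- function(df) {
  n <- nrow(df)
  fail <- function(rows, field, msg) {
    stop(sprintf("claims validation: %s, field '%s', row%s %s", msg, field,
                 if (length(rows) > 1) "s" else "",
                 paste(utils::head(rows, 10), collapse = ", ")), call. = FALSE)
  }
  if (n == 0) {
    out <- data.frame(centre_id = character(), category = factor(levels = CATEGORY_LEVELS),
                      date = as.Date(character()), n_tests = integer(),
                      n_positive = integer(), stringsAsFactors = FALSE)
    class(out) <- c("claims", "data.frame")
    return(out)
  }
  date <- as.Date(df$date, format = "%Y-%m-%d")
  if (anyNA(date)) fail(which(is.na(date)), "date", "malformed date")
  tests <- suppressWarnings(as.numeric(df$n_tests))
  pos <- suppressWarnings(as.numeric(df$n_positive))
  bad <- which(is.na(tests) | tests < 0 | tests != floor(tests))
  if (length(bad)) fail(bad, "n_tests", "not a non-negative integer")
  bad <- which(is.na(pos) | pos < 0 | pos != floor(pos))
  if (length(bad)) fail(bad, "n_positive", "not a non-negative integer")
  bad <- which(pos > tests)
  if (length(bad)) fail(bad, "n_positive", "positives exceed tests")
  category <- tryCatch(normalise_category(df$category), error = function(e) e)
  if (inherits(category, "error")) {
    lx <- tolower(trimws(df$category))
    known <- unlist(CATEGORY_ALIASES)
    fail(which(!lx %in% known), "category", "unknown category")
  }
  key <- paste(df$centre_id, format(date))
  if (anyDuplicated(key)) fail(which(duplicated(key)), "centre_id/date",
                               "duplicate (centre, date) record")
  # one category per centre
  percat <- tapply(as.character(category), df$centre_id,
                   function(v) length(unique(v)))
  if (any(percat > 1)) {
    mixed <- names(percat)[percat > 1]
    fail(which(df$centre_id %in% mixed)[1], "category",
         paste0("centre with inconsistent category (", mixed[1], ")"))
  }
  out <- data.frame(centre_id = as.character(df$centre_id), category = category,
                    date = date, n_tests = as.integer(tests),
                    n_positive = as.integer(pos), stringsAsFactors = FALSE)
  out <- out[order(out$centre_id, out$date), ]
  rownames(out) <- NULL
  class(out) <- c("claims", "data.frame")
  out
}

#' Write a claims file
#'
#' Inverse of [read_claims()]: writes the canonical five-column delimited
#' format with ISO dates.
#'
#' @param claims Validated claims data frame.
#' @param path Output path.
#' @param sep Field delimiter.
#' @export
write_claims <- function(claims, path, sep = ",") {
  df <- data.frame(centre_id = claims$centre_id,
                   category = as.character(claims$category),
                   date = format(claims$date, "%Y-%m-%d"),
                   n_tests = claims$n_tests, n_positive = claims$n_positive)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a labels file
#'
#' Optional external labels per centre: `suspected_conventional` (0/1, the
#' health authority's conventional suspicion) and `corroborated` (0/1/NA; NA
#' means the centre was never investigated).
#'
#' @param path Path to the labels file.
#' @param sep Field delimiter.
#' @return Data frame with columns `centre_id`, `suspected_conventional`,
#'   `corroborated`.
#' @export
read_labels <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  needed <- c("centre_id", "suspected_conventional", "corroborated")
  if (!all(needed %in% names(df)))
    stop("labels file must have columns ", paste(needed, collapse = ", "))
  for (col in needed[-1]) {
    v <- df[[col]]
    if (!all(v %in% c(0L, 1L, NA))) stop("labels column ", col, " must be 0/1/NA")
    df[[col]] <- as.integer(v)
  }
  df[needed]
}

#' Summarise claims per centre
#'
#' Aggregates validated daily claims into one row per centre: number of
#' active days (days with at least one invoiced test), mean daily tests over
#' active days, totals, the leading-digit histogram (digits 1-9) and the
#' last-digit histogram (digits 0-9) of the daily test counts. Days with
#' zero invoiced tests carry no digit information and are excluded from the
#' histograms, the mean, and the active-day count.
#'
#' @param claims Validated claims data frame.
#' @return A `centre_summary` data frame with list-columns `leading_digits`
#'   (length-9 counts) and `last_digits` (length-10 counts), plus
#'   `n_distinct_daily`, the number of distinct daily test counts (a
#'   low-variance diagnostic for the digit screens).
#' @export
summarise_centres <- function(claims) {
  stopifnot(is.data.frame(claims))
  sp <- split(seq_len(nrow(claims)), claims$centre_id)
  rows <- lapply(names(sp), function(id) {
    idx <- sp[[id]]
    tests <- claims$n_tests[idx]
    act <- tests >= 1L
    ta <- tests[act]
    lead <- if (length(ta)) tabulate(leading_digit(ta), 9L) else integer(9)
    last <- if (length(ta)) tabulate(last_digit(ta) + 1L, 10L) else integer(10)
    list(centre_id = id,
         category = as.character(claims$category[idx[1]]),
         n_active_days = sum(act),
         mean_daily_tests = if (any(act)) mean(ta) else NA_real_,
         total_tests = sum(tests),
         total_positive = sum(claims$n_positive[idx]),
         n_distinct_daily = length(unique(ta)),
         leading_digits = lead, last_digits = last)
  })
  out <- data.frame(
    centre_id = vapply(rows, `[[`, "", "centre_id"),
    category = factor(vapply(rows, `[[`, "", "category"), levels = CATEGORY_LEVELS),
    n_active_days = vapply(rows, `[[`, 0L, "n_active_days"),
    mean_daily_tests = vapply(rows, `[[`, 0, "mean_daily_tests"),
    total_tests = vapply(rows, `[[`, 0L, "total_tests"),
    total_positive = vapply(rows, `[[`, 0L, "total_positive"),
    n_distinct_daily = vapply(rows, `[[`, 0L, "n_distinct_daily"),
    stringsAsFactors = FALSE)
  out$leading_digits <- I(lapply(rows, `[[`, "leading_digits"))
  out$last_digits <- I(lapply(rows, `[[`, "last_digits"))
  class(out) <- c("centre_summary", "data.frame")
  out
}
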