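# In-code fixtures shared across test files.

# A small, fast simulation: three categories, ~5 months.
small_config <- function(...) {
  simulation_config(
    n_centres = c(pharmacy = 10L, practice = 30L, private = 30L),
    window = study_window("2021-04-08", "2021-08-31"),
    lifetime_median = 120, lifetime_sdlog = 0.6,
    ...)
}

# Hand-built claims table: `days` is a named list centre_id -> vector of
# daily test counts (0 = closed day kept as an explicit zero row);
# positives default to a fixed rate, rounded down.
toy_claims <- function(days, category = "private", rate = 0.02,
                       start = as.Date("2021-04-08")) {
  rows <- do.call(rbind, lapply(names(days), function(id) {
    v <- days[[id]]
    data.frame(centre_id = id, category = category,
               date = format(start + seq_along(v) - 1, "%Y-%m-%d"),
               n_tests = as.character(v),
               n_positive = as.character(floor(v * rate)),
               stringsAsFactors = FALSE)
  }))
  validate_claims(rows)
}

# Minimal positivity_fit stand-in for testing the flag rule in isolation.
fake_positivity_fit <- function(u, se_u, ids = sprintf("C%03d", seq_along(u))) {
  structure(list(
    model = NULL, beta = c(`(Intercept)` = log(0.02)),
    sigma_u = stats::sd(u), sigma_v = 0,
    ranef_centre = data.frame(centre_id = ids, u = u, se_u = se_u,
                              stringsAsFactors = FALSE),
    ranef_week = NULL, n_rows = length(u), converged = TRUE, boundary = FALSE,
    categories = data.frame(centre_id = ids, category = "private",
                            stringsAsFactors = FALSE)),
    class = "positivity_fit")
}

# Independent brute-force top-fraction sorter used as oracle for the
# ceil-count ranking rule.
brute_top_fraction <- function(centre_id, score, eligible, fraction) {
  df <- data.frame(centre_id, score, eligible)
  el <- df[df$eligible & is.finite(df$score), ]
  k <- ceiling(fraction * nrow(el))
  el <- el[order(-el$score, el$centre_id), ]
  centre_id %in% el$centre_id[seq_len(k)]
}

# Flags table with a prescribed flagged/eligible pattern.
flags_from_pattern <- function(ids, flagged, eligible = rep(TRUE, length(ids)),
                               method = "toy") {
  out <- data.frame(centre_id = ids, category = factor("private",
                    levels = c("pharmacy", "practice", "private")),
                    method = method, eligible = eligible,
                    score = as.numeric(flagged), flagged = flagged,
                    stringsAsFactors = FALSE)
  class(out) <- c("method_flags", "data.frame")
  out
}

# 2x2 agreement table from raw cell counts.
agreement_from_counts <- function(a, b, c, d) {
  ids <- sprintf("C%04d", seq_len(a + b + c + d))
  flagged <- rep(c(TRUE, FALSE, TRUE, FALSE), times = c(a, b, c, d))
  suspected <- rep(c(1L, 1L, 0L, 0L), times = c(a, b, c, d))
  cross_tabulate(flags_from_pattern(ids, flagged),
                 data.frame(centre_id = ids, suspected_conventional = suspected))
}
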