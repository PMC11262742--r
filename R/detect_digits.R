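#' Benford first-digit probability
#'
#' The expected probability that the leading digit of a naturally occurring
#' number equals `d`: \eqn{p_d = \log_{10}(1 + 1/d)}. About 30% for digit 1,
#' about 5% for digit 9; the nine probabilities sum to 1 exactly
#' (telescoping product).
#'
#' @param d Digit(s) in 1..9.
#' @return Probabilities.
#' @examples
#' benford_probability(1)    # 0.30103
#' sum(benford_probability(1:9))  # 1
#' @export
benford_probability <- function(d) {
  if (any(d < 1 | d > 9 | d != floor(d))) stop("digit must be an integer in 1..9")
  log10(1 + 1 / d)
}

#' Chi-squared digit statistic
#'
#' Pearson goodness-of-fit statistic of observed digit counts against
#' expected probabilities: \eqn{\sum_d (O_d - N p_d)^2 / (N p_d)} with
#' \eqn{N = \sum_d O_d}. Used as a ranking score, without a small-count
#' correction or a calibrated p-value.
#'
#' @param counts Integer vector of digit counts (length 9 for first digits,
#'   10 for last digits).
#' @param expected Probability vector of the same length summing to 1.
#' @return The statistic (non-negative scalar).
#' @examples
#' digit_chi2(c(10, 0, 0, 0, 0, 10, 0, 0, 0, 0), rep(0.1, 10))  # 80
#' @export
digit_chi2 <- function(counts, expected) {
  if (length(counts) != length(expected)) stop("counts and expected lengths differ")
  if (any(expected <= 0)) stop("expected probabilities must be positive")
  if (abs(sum(expected) - 1) > 1e-8) stop("expected probabilities must sum to 1")
  N <- sum(counts)
  if (N < 1) stop("need at least one digit observation")
  sum((counts - N * expected)^2 / (N * expected))
}

#' Flag centres by a digit screen
#'
#' Computes a per-centre chi-squared statistic of the daily test counts'
#' digit distribution — leading digits against Benford's law
#' (`screen = "benford_first"`) or last digits against the uniform
#' distribution on 0..9 (`screen = "uniform_last"`) — and flags the top
#' `ceil(flag_fraction * n_eligible)` statistics among eligible centres.
#' Only centres with at least `min_active_days` days of invoiced tests are
#' eligible; a digit distribution over fewer days is not interpretable, so
#' such centres are retained as unflagged and ineligible.
#'
#' Centres whose daily counts take fewer than 5 distinct values get a
#' low-variance diagnostic mark (`low_variance` column): digit screens
#' presuppose enough spread in the underlying data. This is a warning
#' attached to the output, not an exclusion.
#'
#' @param summaries A `centre_summary` from [summarise_centres()].
#' @param screen `"benford_first"` or `"uniform_last"`.
#' @param min_active_days Eligibility threshold, default 30.
#' @param flag_fraction Fraction of eligible centres to flag, default 0.10.
#' @return A `method_flags` data frame (method `benford` or `last_digit`)
#'   with the extra logical column `low_variance`.
#' @export
flag_digit_screen <- function(summaries, screen = c("benford_first", "uniform_last"),
                              min_active_days = 30L, flag_fraction = 0.10) {
  screen <- match.arg(screen)
  stopifnot(min_active_days >= 1, flag_fraction > 0, flag_fraction < 1)
  eligible <- summaries$n_active_days >= min_active_days
  if (!any(eligible)) warning("no centres eligible for the digit screen")
  expected <- if (screen == "benford_first") benford_probability(1:9) else rep(0.1, 10)
  colname <- if (screen == "benford_first") "leading_digits" else "last_digits"
  score <- vapply(seq_len(nrow(summaries)), function(i) {
    if (!eligible[i]) return(NA_real_)
    digit_chi2(summaries[[colname]][[i]], expected)
  }, 0)
  flagged <- flag_top_fraction(summaries$centre_id, score, eligible, flag_fraction)
  out <- new_method_flags(if (screen == "benford_first") "benford" else "last_digit",
                          summaries$centre_id, summaries$category,
                          eligible, score, flagged)
  out$low_variance <- summaries$n_distinct_daily < 5L & summaries$n_active_days >= 1L
  if (any(out$low_variance & eligible))
    warning(sum(out$low_variance & eligible),
            " eligible centre(s) have fewer than 5 distinct daily values; ",
            "digit screens assume sufficient variance")
  out
}

#' Per-centre digit histogram report
#'
#' Observed digit proportions next to their expected distribution, for one
#' centre, as a plain list (JSON-ready).
#'
#' @param summaries A `centre_summary`.
#' @param centre_id Centre to report.
#' @return List with observed counts, proportions and expected probabilities
#'   for both screens.
#' @export
digit_report <- function(summaries, centre_id) {
  i <- match(centre_id, summaries$centre_id)
  if (is.na(i)) stop("unknown centre: ", centre_id)
  lead <- summaries$leading_digits[[i]]
  last <- summaries$last_digits[[i]]
  list(centre_id = centre_id, n_active_days = summaries$n_active_days[i],
       leading = list(digit = 1:9, observed = lead,
                      proportion = if (sum(lead)) lead / sum(lead) else rep(0, 9),
                      expected = benford_probability(1:9)),
       last = list(digit = 0:9, observed = last,
                   proportion = if (sum(last)) last / sum(last) else rep(0, 10),
                   expected = rep(0.1, 10)))
}

#' Benford expected-vs-observed bar plot
#'
#' Side-by-side bars of a centre's observed leading-digit proportions and
#' the Benford expectation.
#'
#' @param summaries A `centre_summary`.
#' @param centre_id Centre to plot; omit to pool all centres.
#' @param ... Passed to [graphics::barplot()].
#' @return Invisibly, the plotted matrix.
#' @export
plot_benford <- function(summaries, centre_id = NULL, ...) {
  counts <- if (is.null(centre_id)) {
    Reduce(`+`, summaries$leading_digits)
  } else {
    i <- match(centre_id, summaries$centre_id)
    if (is.na(i)) stop("unknown centre: ", centre_id)
    summaries$leading_digits[[i]]
  }
  obs <- if (sum(counts)) counts / sum(counts) else rep(0, 9)
  m <- rbind(expected = benford_probability(1:9), observed = obs)
  colnames(m) <- 1:9
  graphics::barplot(m, beside = TRUE, legend.text = TRUE,
                    xlab = "Leading digit", ylab = "Proportion", ...)
  invisible(m)
}
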