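# Round half away from zero, the convention used for the reported
# percentages (base round() rounds half to even).
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Combine method flags across detectors
#'
#' A centre is statistically conspicuous under the `"any"` rule when at
#' least one detector flags it, and under the `"at_least_k"` rule when at
#' least `k` detectors flag it. A centre is eligible for the combination
#' when it is eligible under at least one method.
#'
#' @param flag_tables List of `method_flags` data frames covering the same
#'   centre set.
#' @param rule `"any"` or `"at_least_k"`.
#' @param k Minimum number of flagging methods for `"at_least_k"`.
#' @return A `method_flags` data frame; `score` is the number of methods
#'   flagging the centre.
#' @export
combine_flags <- function(flag_tables, rule = c("any", "at_least_k"), k = 2L) {
  rule <- match.arg(rule)
  if (rule == "any") k <- 1L
  if (k < 1 || k > length(flag_tables))
    stop("k must be between 1 and the number of methods (", length(flag_tables), ")")
  ids <- sort(unique(unlist(lapply(flag_tables, `[[`, "centre_id"))))
  for (ft in flag_tables) {
    if (!setequal(ft$centre_id, ids))
      stop("flag tables must cover the same centre set")
  }
  n_flagging <- rep(0L, length(ids))
  any_elig <- rep(FALSE, length(ids))
  for (ft in flag_tables) {
    m <- match(ids, ft$centre_id)
    n_flagging <- n_flagging + as.integer(ft$flagged[m])
    any_elig <- any_elig | ft$eligible[m]
  }
  m1 <- match(ids, flag_tables[[1]]$centre_id)
  new_method_flags(if (rule == "any") "any_method" else paste0("at_least_", k),
                   ids, flag_tables[[1]]$category[m1],
                   any_elig, as.numeric(n_flagging), n_flagging >= k)
}

#' Cross-tabulate statistical flags against conventional suspicion
#'
#' Builds the 2x2 agreement table between the external (conventional)
#' suspicion label and statistical conspicuousness:
#' `a` = suspected & flagged, `b` = suspected & not flagged,
#' `c` = not suspected & flagged, `d` = not suspected & not flagged.
#'
#' Centres with a missing suspicion label (e.g. pharmacies, whose suspicion
#' data sit with a different supervising authority) are treated as
#' not-suspected by default — the convention that reproduces published
#' margins of 93 suspected vs 814 not suspected out of 907 — or excluded
#' with `missing_label_policy = "exclude"`, in which case the exclusion
#' count is recorded in the `n_excluded` attribute.
#'
#' @param flags A `method_flags` data frame.
#' @param labels Data frame with `centre_id` and `suspected_conventional`
#'   (0/1/NA).
#' @param missing_label_policy `"treat_as_unsuspected"` or `"exclude"`.
#' @return An `agreement_table`: list with counts `a`, `b`, `c`, `d`.
#' @export
cross_tabulate <- function(flags, labels,
                           missing_label_policy = c("treat_as_unsuspected", "exclude")) {
  missing_label_policy <- match.arg(missing_label_policy)
  m <- match(flags$centre_id, labels$centre_id)
  if (!any(!is.na(m))) stop("no centres shared between flags and labels")
  susp <- labels$suspected_conventional[m]
  keep <- rep(TRUE, nrow(flags))
  if (missing_label_policy == "exclude") {
    keep <- !is.na(susp)
  } else {
    susp[is.na(susp)] <- 0L
  }
  f <- flags$flagged[keep]
  s <- susp[keep] == 1L
  out <- structure(list(a = sum(s & f), b = sum(s & !f),
                        c = sum(!s & f), d = sum(!s & !f)),
                   class = "agreement_table")
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' @export
print.agreement_table <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, 2, byrow = TRUE,
              dimnames = list(c("suspected", "not suspected"),
                              c("conspicuous", "not conspicuous")))
  print(m)
  if (isTRUE(attr(x, "n_excluded") > 0))
    cat(attr(x, "n_excluded"), "centre(s) excluded for missing labels\n")
  invisible(x)
}

#' Overlap metrics between conventional and statistical methods
#'
#' From a 2x2 [cross_tabulate()] table, computes the percentage of positive
#' overlap `a/(a+b)` (the sensitivity analogue: share of conventionally
#' suspected centres that are also statistically conspicuous), the
#' percentage of negative overlap `d/(c+d)` (the specificity analogue), and
#' the incremental share `c/(c+d)` (statistically conspicuous centres the
#' conventional process missed, = 100 minus negative overlap). Raw
#' fractions are kept alongside percentages rounded half-up to one decimal.
#'
#' @param table An `agreement_table`.
#' @return An `overlap_metrics` list: `positive_overlap_pct`,
#'   `negative_overlap_pct`, `incremental_share_pct` (rounded, 1 decimal)
#'   and the exact `*_raw` fractions.
#' @export
overlap_metrics <- function(table) {
  stopifnot(inherits(table, "agreement_table"))
  if (table$a + table$b < 1) stop("undefined metric: no suspected centres (a + b = 0)")
  if (table$c + table$d < 1) stop("undefined metric: no unsuspected centres (c + d = 0)")
  pos <- table$a / (table$a + table$b)
  neg <- table$d / (table$c + table$d)
  inc <- table$c / (table$c + table$d)
  structure(list(
    positive_overlap_pct = round_half_up(100 * pos),
    negative_overlap_pct = round_half_up(100 * neg),
    incremental_share_pct = round_half_up(100 * inc),
    positive_overlap_raw = pos, negative_overlap_raw = neg,
    incremental_share_raw = inc),
    class = "overlap_metrics")
}

#' @export
print.overlap_metrics <- function(x, ...) {
  cat(sprintf("positive overlap %.1f%%, negative overlap %.1f%%, incremental share %.1f%%\n",
              x$positive_overlap_pct, x$negative_overlap_pct, x$incremental_share_pct))
  invisible(x)
}

#' Incremental predictive validity of a flag set
#'
#' Partitions the statistically conspicuous centres into those already
#' suspected by the conventional process, those newly identified whose
#' fraud suspicion was corroborated by subsequent investigation, and those
#' newly identified but not corroborated. The incremental predictive
#' validity is the corroborated-new share of all flagged centres.
#'
#' @param flags A `method_flags` data frame.
#' @param labels Data frame with `centre_id`, `suspected_conventional`
#'   (0/1/NA; NA treated as not suspected) and `corroborated` (0/1/NA; must
#'   be non-missing for every flagged, not-previously-suspected centre).
#' @return A `validity_breakdown` list: `n_already_suspected`,
#'   `n_new_corroborated`, `n_new_not_corroborated`, `n_total_conspicuous`,
#'   `incremental_predictive_validity_pct` (1 decimal; `NA` when nothing is
#'   flagged).
#' @export
predictive_validity <- function(flags, labels) {
  m <- match(flags$centre_id, labels$centre_id)
  susp <- labels$suspected_conventional[m]
  susp[is.na(susp)] <- 0L
  corr <- labels$corroborated[m]
  f <- which(flags$flagged)
  new_idx <- f[susp[f] == 0L]
  if (any(is.na(corr[new_idx]))) {
    miss <- flags$centre_id[new_idx][is.na(corr[new_idx])]
    stop("corroboration status missing for flagged, not-previously-suspected centre(s): ",
         paste(utils::head(miss, 10), collapse = ", "))
  }
  n_already <- sum(susp[f] == 1L)
  n_new_corr <- sum(corr[new_idx] == 1L)
  n_new_not <- sum(corr[new_idx] == 0L)
  n_total <- length(f)
  structure(list(
    n_already_suspected = n_already,
    n_new_corroborated = n_new_corr,
    n_new_not_corroborated = n_new_not,
    n_total_conspicuous = n_total,
    incremental_predictive_validity_pct =
      if (n_total > 0) round_half_up(100 * n_new_corr / n_total) else NA_real_),
    class = "validity_breakdown")
}

#' @export
print.validity_breakdown <- function(x, ...) {
  cat(sprintf("conspicuous %d: already suspected %d, new corroborated %d, new not corroborated %d",
              x$n_total_conspicuous, x$n_already_suspected,
              x$n_new_corroborated, x$n_new_not_corroborated))
  if (!is.na(x$incremental_predictive_validity_pct))
    cat(sprintf(" (incremental predictive validity %.1f%%)", x$incremental_predictive_validity_pct))
  cat("\n")
  invisible(x)
}
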