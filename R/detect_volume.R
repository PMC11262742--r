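# Shared top-fraction ranking rule: flag the top ceil(fraction * n_eligible)
# eligible centres by score, ties broken by (score desc, centre_id asc).
# The ceil-count rule (rather than an interpolated quantile cutoff) is what
# reproduces per-stratum flag counts like 6/39/46 out of 60/390/457 at the
# 90th percentile, and 67 of 665 / 52 of 512 at the 10% digit-screen level.
flag_top_fraction <- function(centre_id, score, eligible, fraction) {
  flagged <- logical(length(score))
  elig_idx <- which(eligible & is.finite(score))
  n_elig <- length(elig_idx)
  if (n_elig > 0) {
    k <- ceiling(fraction * n_elig)
    ord <- elig_idx[order(-score[elig_idx], centre_id[elig_idx])]
    flagged[ord[seq_len(k)]] <- TRUE
  }
  flagged
}

new_method_flags <- function(method, centre_id, category, eligible, score, flagged) {
  out <- data.frame(centre_id = centre_id, category = category, method = method,
                    eligible = eligible, score = score, flagged = flagged,
                    stringsAsFactors = FALSE)
  stopifnot(!any(out$flagged & !out$eligible))
  class(out) <- c("method_flags", "data.frame")
  out
}

#' Flag centres with unusually high mean daily test volume
#'
#' Within each centre category, ranks centres by mean invoiced tests per
#' active day and flags the top `ceil((1 - quantile_level) * n)` — i.e. the
#' centres beyond the 90th percentile of their category at the default
#' level. Centres with no active days are ineligible.
#'
#' @param summaries A `centre_summary` from [summarise_centres()].
#' @param quantile_level Percentile limit, default 0.90.
#' @param stratify_by_category Rank within category (default) or overall.
#' @return A `method_flags` data frame: `centre_id`, `category`, `method`,
#'   `eligible`, `score` (mean daily tests), `flagged`.
#' @export
flag_high_volume <- function(summaries, quantile_level = 0.90,
                             stratify_by_category = TRUE) {
  stopifnot(quantile_level > 0, quantile_level < 1)
  eligible <- summaries$n_active_days >= 1L
  score <- summaries$mean_daily_tests
  flagged <- logical(nrow(summaries))
  strata <- if (stratify_by_category) summaries$category else factor(rep("all", nrow(summaries)))
  for (s in levels(droplevels(strata))) {
    in_s <- which(strata == s)
    if (!length(in_s)) {
      warning("empty category stratum: ", s)
      next
    }
    flagged[in_s] <- flag_top_fraction(summaries$centre_id[in_s], score[in_s],
                                       eligible[in_s], 1 - quantile_level)
  }
  new_method_flags("high_volume", summaries$centre_id, summaries$category,
                   eligible, score, flagged)
}
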