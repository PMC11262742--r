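#' Run the full fraud-screening pipeline
#'
#' Runs all four detectors on a claims dataset, combines them under the
#' requested rules, and — when labels are supplied — evaluates each flag set
#' against conventional suspicion (agreement table + overlap metrics) and
#' corroboration (predictive-validity breakdown). Optionally writes every
#' table, a model report and a run manifest to an output directory as
#' delimited text / JSON. Reruns with the same inputs are byte-identical:
#' every stage is deterministic given the data.
#'
#' @param claims Validated claims data frame, or a path to a claims file.
#' @param labels Optional labels data frame or file path
#'   (`centre_id,suspected_conventional,corroborated`).
#' @param window Optional [study_window()] (default: the claims' date range).
#' @param volume_quantile Percentile limit for the high-volume screen.
#' @param positivity_alpha One-sided significance level for the
#'   low-positivity flag.
#' @param min_active_days,flag_fraction Digit-screen eligibility threshold
#'   and flagged fraction.
#' @param combine_k Integer vector of `k` values for at-least-k
#'   combinations (in addition to the any-method union).
#' @param missing_label_policy Passed to [cross_tabulate()].
#' @param out_dir Optional directory to write reports into.
#' @return A `pipeline_result` list: `flags` (named list of `method_flags`
#'   for the four methods, the union and each at-least-k rule),
#'   `positivity_fit`, `evaluation` (per flag set: `agreement`, `overlap`,
#'   `validity`; NULL without labels), `degraded` (TRUE when the positivity
#'   model could not be fitted and the run fell back to three detectors),
#'   and `manifest`.
#' @export
run_pipeline <- function(claims, labels = NULL, window = NULL,
                         volume_quantile = 0.90, positivity_alpha = 0.05,
                         min_active_days = 30L, flag_fraction = 0.10,
                         combine_k = 2L,
                         missing_label_policy = "treat_as_unsuspected",
                         out_dir = NULL) {
  if (is.character(claims)) claims <- read_claims(claims)
  if (is.character(labels)) labels <- read_labels(labels)
  summaries <- summarise_centres(claims)

  flags <- list(
    high_volume = flag_high_volume(summaries, quantile_level = volume_quantile),
    benford = flag_digit_screen(summaries, "benford_first",
                                min_active_days = min_active_days,
                                flag_fraction = flag_fraction),
    last_digit = flag_digit_screen(summaries, "uniform_last",
                                   min_active_days = min_active_days,
                                   flag_fraction = flag_fraction))

  degraded <- FALSE
  pos_fit <- tryCatch(fit_positivity_model(claims, window = window),
                      error = function(e) e)
  if (inherits(pos_fit, "error")) {
    warning("positivity model unavailable (", conditionMessage(pos_fit),
            "); continuing with three detectors", immediate. = TRUE)
    degraded <- TRUE
    pos_fit <- NULL
  } else {
    flags <- c(flags[1], list(low_positivity = flag_low_positivity(pos_fit, positivity_alpha)),
               flags[2:3])
  }

  single <- flags
  flags$any_method <- combine_flags(single, "any")
  for (k in combine_k) {
    if (k >= 2 && k <= length(single))
      flags[[paste0("at_least_", k)]] <- combine_flags(single, "at_least_k", k = k)
  }

  evaluation <- NULL
  if (!is.null(labels)) {
    evaluation <- lapply(flags, function(ft) {
      agr <- cross_tabulate(ft, labels, missing_label_policy = missing_label_policy)
      ov <- tryCatch(overlap_metrics(agr), error = function(e) NULL)
      val <- if ("corroborated" %in% names(labels))
        tryCatch(predictive_validity(ft, labels), error = function(e) NULL)
      else NULL
      list(agreement = agr, overlap = ov, validity = val)
    })
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("claimscreen")),
    n_records = nrow(claims), n_centres = nrow(summaries),
    window = if (is.null(window)) list(start = format(min(claims$date)),
                                       end = format(max(claims$date)))
             else list(start = format(window$start_date), end = format(window$end_date)),
    config = list(volume_quantile = volume_quantile,
                  positivity_alpha = positivity_alpha,
                  min_active_days = min_active_days,
                  flag_fraction = flag_fraction, combine_k = combine_k,
                  missing_label_policy = missing_label_policy),
    degraded = degraded)

  result <- structure(list(flags = flags, positivity_fit = pos_fit,
                           summaries = summaries, evaluation = evaluation,
                           degraded = degraded, manifest = manifest),
                      class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_reports(result, out_dir)
  result
}

#' Write pipeline reports to a directory
#'
#' One delimited flags table per flag set
#' (`flags_<name>.csv`: `centre_id,method,eligible,score,flagged`), an
#' evaluation summary (`evaluation.csv`, Table-2/3-style counts and
#' percentages per flag set), a positivity model report
#' (`positivity_model.json`) and the run manifest (`manifest.json`).
#'
#' @param result A `pipeline_result`.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_pipeline_reports <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (nm in names(result$flags)) {
    p <- file.path(out_dir, paste0("flags_", nm, ".csv"))
    ft <- result$flags[[nm]]
    utils::write.table(
      data.frame(centre_id = ft$centre_id, method = ft$method,
                 eligible = ft$eligible,
                 score = ifelse(is.na(ft$score), "", format(ft$score, digits = 8)),
                 flagged = ft$flagged),
      p, sep = ",", row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(result$evaluation)) {
    rows <- lapply(names(result$evaluation), function(nm) {
      ev <- result$evaluation[[nm]]
      data.frame(
        flag_set = nm,
        a = ev$agreement$a, b = ev$agreement$b,
        c = ev$agreement$c, d = ev$agreement$d,
        positive_overlap_pct = if (is.null(ev$overlap)) NA else ev$overlap$positive_overlap_pct,
        negative_overlap_pct = if (is.null(ev$overlap)) NA else ev$overlap$negative_overlap_pct,
        incremental_share_pct = if (is.null(ev$overlap)) NA else ev$overlap$incremental_share_pct,
        n_already_suspected = if (is.null(ev$validity)) NA else ev$validity$n_already_suspected,
        n_new_corroborated = if (is.null(ev$validity)) NA else ev$validity$n_new_corroborated,
        n_new_not_corroborated = if (is.null(ev$validity)) NA else ev$validity$n_new_not_corroborated,
        n_total_conspicuous = if (is.null(ev$validity)) NA else ev$validity$n_total_conspicuous,
        incremental_predictive_validity_pct =
          if (is.null(ev$validity)) NA else ev$validity$incremental_predictive_validity_pct)
    })
    p <- file.path(out_dir, "evaluation.csv")
    utils::write.table(do.call(rbind, rows), p, sep = ",", row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(result$positivity_fit)) {
    p <- file.path(out_dir, "positivity_model.json")
    jsonlite::write_json(positivity_model_report(result$positivity_fit), p,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths <- c(paths, p)
  }
  p <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(result$manifest, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(paths, p)
  invisible(paths)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("fraud-screening pipeline result\n")
  for (nm in names(x$flags)) {
    ft <- x$flags[[nm]]
    cat(sprintf("  %-14s %4d flagged / %4d eligible / %4d centres\n",
                nm, sum(ft$flagged), sum(ft$eligible), nrow(ft)))
  }
  if (x$degraded) cat("  [degraded: positivity model unavailable]\n")
  invisible(x)
}
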