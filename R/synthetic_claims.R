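FRAUD_BEHAVIOURS <- c("volume_inflation", "positivity_suppression",
                      "digit_rounding", "fabrication")

#' Configure the synthetic claims simulation
#'
#' Builds the configuration for a synthetic daily-claims dataset emulating
#' the billing data the detectors were designed for: three centre categories
#' (pharmacies, doctor's/dentist's offices, private test centres) at their
#' published cohort sizes, category-stratified daily volumes with medians
#' near 64 / 5 / 115 tests per day, an overall positivity near 2% varying
#' smoothly by calendar week, a 73-week study window with centres active on
#' subsets of days, and four injectable fraud behaviours.
#'
#' Daily volumes are discretised log-normal: a centre's base volume is drawn
#' from a category-level log-normal (log-median `volume_meanlog`, spread
#' `volume_sdlog_centre`), and each active day's count from a log-normal
#' around that base with day-level spread `day_sdlog`. The centre-level
#' spreads are calibrated so that the combined centre+day spread reproduces
#' the published mean/median ratios per category; the heavy right tail this
#' produces is what lets leading digits of honest centres approach Benford's
#' law when the day-level spread is wide.
#'
#' Positives are binomial with
#' `p = plogis(qlogis(weekly_curve[k]) + centre_offset)`, centre offsets
#' normal on the logit scale with sd `centre_pos_sd`, matching the
#' random-intercept structure of the positivity detector's model.
#'
#' Fraud behaviours transform a centre's honest generation: volume inflation
#' multiplies the expected daily volume; fabrication replaces the volume draw
#' by a uniform integer in `fabrication_band`; digit rounding rounds the
#' final volume to the nearest multiple of `rounding_base` (minimum one
#' base); positivity suppression multiplies the daily positive probability.
#' Inflation is applied before fabrication, and rounding last, so rounding
#' controls the last digit.
#'
#' Conventional suspicion and corroboration labels come from a two-coin
#' misclassification model (`p_suspect_fraud`, `p_suspect_honest`,
#' `p_corroborate_fraud`, `p_corroborate_honest`), so downstream agreement
#' tables are non-trivial.
#'
#' @param n_centres Named integer vector of centre counts per category
#'   (default `c(pharmacy = 60, practice = 390, private = 457)`).
#' @param window A [study_window()]; default 2021-04-08 .. 2022-08-28
#'   (73 weeks).
#' @param fraud_prevalence Named probabilities per behaviour.
#' @param volume_meanlog,volume_sdlog_centre Named per-category log-normal
#'   parameters for centre base volumes.
#' @param day_sdlog Day-level log-normal sd (natural log) of daily volumes
#'   around a centre's base.
#' @param weekly_positivity Length-`n_weeks` vector of weekly positive-rate
#'   probabilities; default a seasonal curve around 2%.
#' @param centre_pos_sd SD of centre positivity offsets on the logit scale.
#' @param inflation_factor,suppression_factor,rounding_base,fabrication_band
#'   Behaviour parameters.
#' @param activity_range Range of per-centre daily opening probabilities.
#' @param lifetime_median,lifetime_sdlog Log-normal parameters (median in
#'   days, sd on the log scale) of a centre's operating lifetime; uniform
#'   start within the window, truncated at the window end. Together with
#'   `activity_range` this spreads active-day counts widely, including a
#'   realistic share of centres billing on fewer than 30 days.
#' @param p_suspect_fraud,p_suspect_honest,p_corroborate_fraud,p_corroborate_honest
#'   Label-model probabilities.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(
    n_centres = c(pharmacy = 60L, practice = 390L, private = 457L),
    window = study_window("2021-04-08", "2022-08-28"),
    fraud_prevalence = c(volume_inflation = 0.05, positivity_suppression = 0.05,
                         digit_rounding = 0.05, fabrication = 0.05),
    volume_meanlog = c(pharmacy = log(64), practice = log(5), private = log(115)),
    volume_sdlog_centre = c(pharmacy = 0.6, practice = 1.5, private = 0.6),
    day_sdlog = 0.8,
    weekly_positivity = NULL,
    centre_pos_sd = 0.3,
    inflation_factor = 3,
    suppression_factor = 0.3,
    rounding_base = 5L,
    fabrication_band = c(480L, 520L),
    activity_range = c(0.4, 1),
    lifetime_median = 220,
    lifetime_sdlog = 1.2,
    p_suspect_fraud = 0.5,
    p_suspect_honest = 0.05,
    p_corroborate_fraud = 0.8,
    p_corroborate_honest = 0.1) {
  stopifnot(inherits(window, "study_window"))
  if (any(n_centres <= 0) || !all(names(n_centres) %in% CATEGORY_LEVELS))
    stop("n_centres must be positive counts named from ",
         paste(CATEGORY_LEVELS, collapse = ", "))
  cats_used <- intersect(CATEGORY_LEVELS, names(n_centres))
  if (is.null(weekly_positivity))
    weekly_positivity <- default_weekly_positivity(window$n_weeks)
  if (length(weekly_positivity) != window$n_weeks)
    stop("weekly_positivity must have length n_weeks = ", window$n_weeks)
  probs <- c(fraud_prevalence, weekly_positivity, p_suspect_fraud,
             p_suspect_honest, p_corroborate_fraud, p_corroborate_honest)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0, 1]")
  if (!rounding_base %in% c(5L, 10L)) stop("rounding_base must be 5 or 10")
  if (fabrication_band[1] > fabrication_band[2]) stop("fabrication_band low > high")
  if (inflation_factor < 1) stop("inflation_factor must be >= 1")
  if (suppression_factor <= 0 || suppression_factor > 1)
    stop("suppression_factor must be in (0, 1]")
  structure(list(
    n_centres = n_centres[cats_used], window = window,
    fraud_prevalence = fraud_prevalence[FRAUD_BEHAVIOURS],
    volume_meanlog = volume_meanlog[cats_used],
    volume_sdlog_centre = volume_sdlog_centre[cats_used],
    day_sdlog = day_sdlog, weekly_positivity = weekly_positivity,
    centre_pos_sd = centre_pos_sd, inflation_factor = inflation_factor,
    suppression_factor = suppression_factor, rounding_base = as.integer(rounding_base),
    fabrication_band = as.integer(fabrication_band),
    activity_range = activity_range,
    lifetime_median = lifetime_median, lifetime_sdlog = lifetime_sdlog,
    p_suspect_fraud = p_suspect_fraud, p_suspect_honest = p_suspect_honest,
    p_corroborate_fraud = p_corroborate_fraud,
    p_corroborate_honest = p_corroborate_honest),
    class = "simulation_config")
}

#' Seasonal weekly positivity curve around 2%
#'
#' Sinusoid on the logit scale around `qlogis(level)`, one full cycle per
#' 52 weeks, amplitude 0.5 logits (roughly 1.2% to 3.3% positivity).
#'
#' @param n_weeks Number of weeks.
#' @param level Central positivity.
#' @param amplitude Logit-scale amplitude.
#' @return Numeric vector of weekly probabilities.
#' @export
default_weekly_positivity <- function(n_weeks, level = 0.02, amplitude = 0.5) {
  stats::plogis(stats::qlogis(level) + amplitude * sin(2 * pi * (seq_len(n_weeks) - 1) / 52))
}

# Deterministic per-centre RNG substream: adding centres never shifts the
# draws of existing ones. Offsets keep the derived seed within 32-bit range.
centre_seed <- function(root_seed, i, stream = 0L) {
  as.integer((as.numeric(root_seed) + 7919 * i + 104729 * stream) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate centre specifications
#'
#' Draws one specification per centre: category, base daily volume, logit
#' positivity offset, activity pattern (start/end offsets within the window
#' and a daily opening probability), and an independently sampled set of
#' fraud behaviours at the configured prevalences. Deterministic given
#' `seed`; each centre uses its own derived RNG substream.
#'
#' @param config A [simulation_config()].
#' @param seed Integer root seed.
#' @return A `centre_spec` data frame, one row per centre; behaviours in the
#'   list-column `behaviours`.
#' @export
generate_centres <- function(config, seed = 1L) {
  stopifnot(inherits(config, "simulation_config"))
  cats <- rep(names(config$n_centres), times = config$n_centres)
  n <- length(cats)
  ids <- sprintf("C%04d", seq_len(n))
  rows <- lapply(seq_len(n), function(i) with_seed(centre_seed(seed, i), {
    cat_i <- cats[i]
    base <- stats::rlnorm(1, config$volume_meanlog[[cat_i]],
                          config$volume_sdlog_centre[[cat_i]])
    beh <- FRAUD_BEHAVIOURS[stats::runif(4) < config$fraud_prevalence]
    nd <- config$window$n_days
    # centre lifetime: uniform start, log-normal duration (median
    # `lifetime_median` days), truncated at the window end; combined with
    # the opening probability this yields a realistic spread of active-day
    # counts, including centres billing on fewer than 30 days
    start_off <- sample.int(nd, 1) - 1L
    dur <- max(1L, min(nd - start_off,
                       as.integer(round(stats::rlnorm(1, log(config$lifetime_median),
                                                      config$lifetime_sdlog)))))
    open_p <- stats::runif(1, config$activity_range[1], config$activity_range[2])
    list(base_volume = base, pos_offset = stats::rnorm(1, 0, config$centre_pos_sd),
         behaviours = beh, start_offset = start_off, duration = dur,
         open_prob = open_p)
  }))
  out <- data.frame(
    centre_id = ids, category = factor(cats, levels = CATEGORY_LEVELS),
    base_volume = vapply(rows, `[[`, 0, "base_volume"),
    pos_offset = vapply(rows, `[[`, 0, "pos_offset"),
    start_offset = vapply(rows, `[[`, 0L, "start_offset"),
    duration = vapply(rows, `[[`, 0L, "duration"),
    open_prob = vapply(rows, `[[`, 0, "open_prob"),
    stringsAsFactors = FALSE)
  out$behaviours <- I(lapply(rows, `[[`, "behaviours"))
  class(out) <- c("centre_spec", "data.frame")
  out
}

#' Generate daily claims and ground-truth labels
#'
#' For each centre and each day it is open, draws the honest daily volume
#' from the discretised log-normal (minimum 1) and positives binomially from
#' the weekly positivity curve plus the centre's logit offset, then applies
#' the centre's fraud behaviours: inflation scales the expected volume
#' before the draw, fabrication replaces the draw by a uniform integer in
#' the configured band, rounding snaps the final volume to the nearest
#' multiple of the rounding base, and suppression scales the daily positive
#' probability. The ground-truth table carries each centre's behaviours and
#' the simulated conventional-suspicion and corroboration labels.
#'
#' @param specs A `centre_spec` data frame from [generate_centres()].
#' @param config The same [simulation_config()].
#' @param seed Integer root seed (use the one given to [generate_centres()]).
#' @return List with elements `claims` (validated claims data frame) and
#'   `truth` (per-centre data frame: `centre_id`, `category`, `behaviours`
#'   list-column, `is_fraud`, `suspected_conventional`, `corroborated`).
#' @export
generate_claims <- function(specs, config, seed = 1L) {
  stopifnot(inherits(config, "simulation_config"))
  win <- config$window
  if (win$n_days == 0) {
    warning("degenerate study window: no days")
    return(list(claims = validate_claims(data.frame()), truth = NULL))
  }
  days <- seq(win$start_date, win$end_date, by = "day")
  wk <- week_index(days, win)
  claims_list <- vector("list", nrow(specs))
  truth_rows <- vector("list", nrow(specs))
  for (i in seq_len(nrow(specs))) {
    sp <- specs[i, ]
    beh <- specs$behaviours[[i]]
    res <- with_seed(centre_seed(seed, i, stream = 1L), {
      first <- 1L + sp$start_offset
      last <- min(win$n_days, sp$start_offset + sp$duration)
      idx <- seq(first, last)
      idx <- idx[stats::runif(length(idx)) < sp$open_prob]
      if (!length(idx)) idx <- first  # every centre bills at least one day
      nd <- length(idx)
      mu <- sp$base_volume
      if ("volume_inflation" %in% beh) mu <- mu * config$inflation_factor
      vol <- pmax(1L, as.integer(round(stats::rlnorm(nd, log(mu), config$day_sdlog))))
      if ("fabrication" %in% beh) {
        b <- config$fabrication_band
        vol <- as.integer(b[1] + floor(stats::runif(nd) * (b[2] - b[1] + 1L)))
      }
      if ("digit_rounding" %in% beh) {
        rb <- config$rounding_base
        vol <- pmax(rb, as.integer(round(vol / rb) * rb))
      }
      p <- stats::plogis(stats::qlogis(config$weekly_positivity[wk[idx]]) + sp$pos_offset)
      if ("positivity_suppression" %in% beh) p <- p * config$suppression_factor
      pos <- stats::rbinom(nd, vol, p)
      ## labels
      is_fraud <- length(beh) > 0
      p_susp <- if (is_fraud) config$p_suspect_fraud else config$p_suspect_honest
      suspected <- as.integer(stats::runif(1) < p_susp)
      p_corr <- if (is_fraud) config$p_corroborate_fraud else config$p_corroborate_honest
      corroborated <- as.integer(stats::runif(1) < p_corr)
      list(claims = data.frame(centre_id = sp$centre_id,
                               category = as.character(sp$category),
                               date = days[idx], n_tests = vol, n_positive = pos,
                               stringsAsFactors = FALSE),
           truth = list(is_fraud = is_fraud, suspected = suspected,
                        corroborated = corroborated))
    })
    claims_list[[i]] <- res$claims
    truth_rows[[i]] <- res$truth
  }
  claims <- do.call(rbind, claims_list)
  claims$date <- format(claims$date, "%Y-%m-%d")
  claims[] <- lapply(claims, as.character)
  claims <- validate_claims(claims)
  truth <- data.frame(
    centre_id = specs$centre_id, category = specs$category,
    is_fraud = vapply(truth_rows, `[[`, TRUE, "is_fraud"),
    suspected_conventional = vapply(truth_rows, `[[`, 0L, "suspected"),
    corroborated = vapply(truth_rows, `[[`, 0L, "corroborated"),
    stringsAsFactors = FALSE)
  truth$behaviours <- I(specs$behaviours)
  list(claims = claims, truth = truth)
}

#' Simulate a full synthetic claims dataset
#'
#' Convenience wrapper: [generate_centres()] then [generate_claims()].
#'
#' @inheritParams generate_claims
#' @param config A [simulation_config()].
#' @param seed Integer root seed.
#' @return As [generate_claims()], plus the `specs` element.
#' @export
simulate_claims <- function(config = simulation_config(), seed = 1L) {
  specs <- generate_centres(config, seed)
  out <- generate_claims(specs, config, seed)
  out$specs <- specs
  out
}
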