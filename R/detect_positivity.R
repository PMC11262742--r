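#' Fit the positivity model: Poisson regression with crossed random intercepts
#'
#' Models the daily number of positive tests per centre as Poisson with a
#' log link, an offset of log daily tests (so the linear predictor describes
#' the positive rate, not the raw count), crossed random intercepts for test
#' centre and calendar week, and centre category as a fixed effect:
#'
#' \deqn{\log \mu_{jk} = \log(\mathrm{tests}) + \beta_0 + \beta_{cat} + u_j + v_k,
#'       \quad u_j \sim N(0, \sigma_u^2), \; v_k \sim N(0, \sigma_v^2).}
#'
#' Each centre intercept \eqn{u_j} is that centre's deviation of log
#' positivity from the category mean; a significantly low conditional mode
#' is the fraud signal (a suppressed positive rate avoids the follow-up
#' obligations a positive test triggers). Estimation is by Laplace
#' approximation via [lme4::glmer()]; adaptive quadrature is unavailable for
#' crossed designs. Centre-days with zero tests are dropped (the offset is
#' undefined and such days carry no positivity information). The reference
#' category for the fixed effect is `practice`.
#'
#' @param claims Validated claims data frame.
#' @param window A [study_window()]; defaults to the claims' date range.
#'   Weeks are consecutive 7-day blocks from the window start.
#' @param include_week Include the calendar-week random intercept (default
#'   TRUE; FALSE gives the centre-only model, useful for small designs).
#' @return A `positivity_fit`: list with `model` (the `glmerMod`), `beta`
#'   (fixed effects), `sigma_u`, `sigma_v`, `ranef_centre` (data frame of
#'   conditional modes `u` and conditional sds `se_u` per centre),
#'   `ranef_week`, `n_rows`, `converged`, `boundary`.
#' @export
fit_positivity_model <- function(claims, window = NULL, include_week = TRUE) {
  d <- claims[claims$n_tests >= 1L, , drop = FALSE]
  if (length(unique(d$centre_id)) < 2) stop("need at least 2 centres with tests")
  if (is.null(window)) window <- study_window(min(d$date), max(d$date))
  d$week <- factor(week_index(d$date, window))
  if (include_week && nlevels(d$week) < 2) stop("need at least 2 weeks with data")
  d$centre <- factor(d$centre_id)
  d$category <- stats::relevel(factor(as.character(d$category),
                                      levels = intersect(CATEGORY_LEVELS,
                                                         unique(as.character(d$category)))),
                               ref = if ("practice" %in% d$category) "practice"
                                     else levels(factor(as.character(d$category)))[1])
  one_cat <- nlevels(d$category) < 2
  form <- if (include_week) {
    if (one_cat) n_positive ~ 1 + (1 | centre) + (1 | week) + offset(log(n_tests))
    else n_positive ~ category + (1 | centre) + (1 | week) + offset(log(n_tests))
  } else {
    if (one_cat) n_positive ~ 1 + (1 | centre) + offset(log(n_tests))
    else n_positive ~ category + (1 | centre) + offset(log(n_tests))
  }
  fit <- lme4::glmer(form, data = d, family = stats::poisson())
  vc <- as.data.frame(lme4::VarCorr(fit))
  sigma_u <- vc$sdcor[vc$grp == "centre"]
  sigma_v <- if (include_week) vc$sdcor[vc$grp == "week"] else 0
  msgs <- fit@optinfo$conv$lme4$messages
  converged <- is.null(msgs) || !any(grepl("failed to converge", msgs, ignore.case = TRUE))
  if (!converged)
    stop("positivity model failed to converge: ", paste(msgs, collapse = "; "))
  boundary <- isTRUE(sigma_u < 1e-6) || isTRUE(include_week && sigma_v < 1e-6)
  if (boundary)
    warning("variance component estimated at the boundary (sigma ~ 0)")
  re <- lme4::ranef(fit, condVar = TRUE)
  u <- re$centre[["(Intercept)"]]
  se_u <- sqrt(as.vector(attr(re$centre, "postVar")[1, 1, ]))
  ranef_centre <- data.frame(centre_id = rownames(re$centre), u = u, se_u = se_u,
                             stringsAsFactors = FALSE)
  ranef_week <- if (include_week)
    data.frame(week = as.integer(rownames(re$week)), v = re$week[["(Intercept)"]],
               stringsAsFactors = FALSE) else NULL
  structure(list(model = fit, beta = lme4::fixef(fit), sigma_u = sigma_u,
                 sigma_v = sigma_v, ranef_centre = ranef_centre,
                 ranef_week = ranef_week, n_rows = nrow(d),
                 converged = converged, boundary = boundary,
                 categories = {
                   tab <- tapply(as.character(d$category), d$centre_id, `[`, 1)
                   data.frame(centre_id = names(tab), category = unname(tab),
                              stringsAsFactors = FALSE)
                 }),
            class = "positivity_fit")
}

#' @export
print.positivity_fit <- function(x, ...) {
  cat(sprintf("Poisson positivity model: %d rows, %d centres\n",
              x$n_rows, nrow(x$ranef_centre)))
  cat(sprintf("  sigma_u (centre) = %.4f, sigma_v (week) = %.4f\n", x$sigma_u, x$sigma_v))
  cat("  fixed effects:\n")
  print(round(x$beta, 4))
  invisible(x)
}

#' Flag centres with significantly low positivity
#'
#' A centre is flagged when its empirical-Bayes conditional mode is
#' significantly below zero by a one-sided z-test:
#' `u_j / se(u_j) < qnorm(alpha)`. The score reported per centre is that z
#' ratio. All centres with at least one model row are eligible; a centre
#' with zero conditional sd is ineligible (degenerate).
#'
#' @param fit A `positivity_fit`.
#' @param alpha One-sided significance level, default 0.05.
#' @return A `method_flags` data frame (method `low_positivity`).
#' @export
flag_low_positivity <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "positivity_fit"), alpha > 0, alpha < 1)
  rc <- fit$ranef_centre
  eligible <- rc$se_u > 0
  if (any(!eligible)) warning("centres with zero conditional sd marked ineligible")
  z <- ifelse(eligible, rc$u / rc$se_u, NA_real_)
  flagged <- eligible & !is.na(z) & z < stats::qnorm(alpha)
  cats <- factor(fit$categories$category[match(rc$centre_id, fit$categories$centre_id)],
                 levels = CATEGORY_LEVELS)
  new_method_flags("low_positivity", rc$centre_id, cats, eligible, z, flagged)
}

#' Model report for the positivity fit
#'
#' Variance components, fixed effects and convergence information as a
#' plain list suitable for JSON serialisation.
#'
#' @param fit A `positivity_fit`.
#' @return Named list.
#' @export
positivity_model_report <- function(fit) {
  list(sigma_u = fit$sigma_u, sigma_v = fit$sigma_v,
       fixed_effects = as.list(fit$beta), n_rows = fit$n_rows,
       n_centres = nrow(fit$ranef_centre), converged = fit$converged,
       boundary = fit$boundary)
}
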