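test_that("homogeneous centres reduce to the pooled offset-Poisson intercept", {
  # every centre shares one 2% positivity (up to integer rounding of daily
  # counts): sigma_u collapses to the boundary, beta0 equals
  # log(sum positives / sum tests), nobody is flagged
  days <- lapply(1:6, function(i) rep(c(530, 970, 1410), 4))
  names(days) <- sprintf("H%02d", 1:6)
  rows <- do.call(rbind, lapply(names(days), function(id) {
    v <- days[[id]]
    data.frame(centre_id = id, category = "private",
               date = format(as.Date("2021-04-08") + seq_along(v) - 1),
               n_tests = as.character(v), n_positive = as.character(round(v * 0.02)),
               stringsAsFactors = FALSE)
  }))
  cl <- validate_claims(rows)
  fit <- suppressWarnings(fit_positivity_model(cl, include_week = FALSE))
  expect_lt(fit$sigma_u, 1e-4)
  expect_equal(unname(fit$beta[1]), log(sum(cl$n_positive) / sum(cl$n_tests)),
               tolerance = 1e-6)
  fl <- suppressWarnings(flag_low_positivity(fit, alpha = 0.05))
  expect_equal(sum(fl$flagged), 0L)
})

test_that("the flag rule is a one-sided z-test on the conditional mode", {
  fit <- fake_positivity_fit(u = c(0, -0.3, -0.6, 0.5, -0.1),
                             se_u = c(0.1, 0.1, 0.2, 0.1, 0))
  expect_warning(fl <- flag_low_positivity(fit, alpha = 0.05), "ineligible")
  # z = 0, -3, -3, 5, NA against qnorm(0.05) = -1.645
  expect_equal(fl$flagged, c(FALSE, TRUE, TRUE, FALSE, FALSE))
  expect_false(fl$eligible[5])
  expect_equal(fl$score[2], -3)
  # u = 0 everywhere -> nothing flagged
  fl0 <- flag_low_positivity(fake_positivity_fit(u = rep(0, 4), se_u = rep(0.1, 4)))
  expect_equal(sum(fl0$flagged), 0L)
})

test_that("doubling all tests and positives leaves rate estimates and flags unchanged", {
  sim <- simulate_claims(small_config(), seed = 17)
  fit1 <- suppressWarnings(fit_positivity_model(sim$claims))
  cl2 <- sim$claims
  cl2$n_tests <- cl2$n_tests * 2L
  cl2$n_positive <- cl2$n_positive * 2L
  fit2 <- suppressWarnings(fit_positivity_model(cl2))
  expect_equal(fit2$beta[-1], fit1$beta[-1], tolerance = 0.02)
  # the underlying rate deviations are unchanged; conditional modes of
  # sparsely observed centres move only through reduced shrinkage, so for
  # well-observed centres the modes agree closely, and the z scores sharpen
  # because doubling genuinely adds information — only centres already near
  # the significance threshold may change flag status
  s <- summarise_centres(sim$claims)
  tt <- s$total_tests[match(fit1$ranef_centre$centre_id, s$centre_id)]
  well <- tt >= 5000
  expect_gt(sum(well), 10)
  expect_lt(max(abs(fit1$ranef_centre$u - fit2$ranef_centre$u)[well]), 0.05)
  fl1 <- flag_low_positivity(fit1)
  fl2 <- flag_low_positivity(fit2)
  crit <- qnorm(0.05)
  clear <- abs(fl1$score - crit) > 0.5 & abs(fl2$score - crit) > 0.5
  expect_true(all(fl1$flagged[clear] == fl2$flagged[clear]))
})

test_that("lowering one centre's positives never raises its score", {
  # centres with genuinely different rates, so the variance is off the
  # boundary; dropping M01's positives must lower (never raise) its score
  rates <- 0.02 * (1 + 0.25 * (0:7))
  mk <- function(drop) {
    rows <- do.call(rbind, lapply(1:8, function(i) {
      v <- rep(c(400, 800), 6)
      p <- round(v * rates[i])
      if (i == 1) p <- pmax(0, p - drop)
      data.frame(centre_id = sprintf("M%02d", i), category = "private",
                 date = format(as.Date("2021-04-08") + seq_along(v) - 1),
                 n_tests = as.character(v), n_positive = as.character(p),
                 stringsAsFactors = FALSE)
    }))
    validate_claims(rows)
  }
  z_of <- function(claims) {
    fit <- suppressWarnings(fit_positivity_model(claims, include_week = FALSE))
    fl <- suppressWarnings(flag_low_positivity(fit))
    fl$score[fl$centre_id == "M01"]
  }
  expect_lt(z_of(mk(4L)), z_of(mk(0L)))
})

test_that("the Laplace fit matches a mode-centred Gauss-Hermite oracle", {
  # 5 centres x 4 weeks, week variance absent; the marginal likelihood is a
  # product of one-dimensional integrals that 50-node adaptive GH evaluates
  # near-exactly, giving an independent estimate of sigma_u.
  set.seed(7)
  u <- rnorm(5, 0, 0.4)
  d <- expand.grid(centre = 1:5, week = 1:4)
  d$tests <- pmax(50, round(rlnorm(nrow(d), log(400), 0.5)))
  d$pos <- rpois(nrow(d), d$tests * exp(log(0.02) + u[d$centre]))
  days <- split(d, d$centre)
  cl <- toy_claims(lapply(days, `[[`, "tests"), rate = 0)
  cl$n_positive <- unlist(lapply(days, `[[`, "pos"))
  fit <- fit_positivity_model(cl, include_week = FALSE)

  gh <- function(n) {  # Golub-Welsch nodes/weights for weight exp(-x^2)
    i <- 1:(n - 1); b <- sqrt(i / 2)
    J <- diag(0, n); J[cbind(i, i + 1)] <- b; J[cbind(i + 1, i)] <- b
    e <- eigen(J, symmetric = TRUE)
    list(x = e$values, w = sqrt(pi) * e$vectors[1, ]^2)
  }
  q <- gh(50)
  centre_ll <- function(y, off, b0, s) {
    f <- function(u) sum(dpois(y, exp(off + b0 + u), log = TRUE)) +
      dnorm(u, 0, s, log = TRUE)
    m <- optimize(function(u) -f(u), c(-5, 5))$minimum
    h <- sqrt(1 / (sum(y) + 1 / s^2))
    vals <- vapply(seq_along(q$x), function(k) {
      u <- m + sqrt(2) * h * q$x[k]
      exp(f(u) + q$x[k]^2) * q$w[k]
    }, 0)
    log(sum(vals) * sqrt(2) * h)
  }
  nll <- function(par) {
    -sum(vapply(unique(cl$centre_id), function(id) {
      rows <- cl$centre_id == id
      centre_ll(cl$n_positive[rows], log(cl$n_tests[rows]), par[1], exp(par[2]))
    }, 0))
  }
  opt <- optim(c(log(0.02), log(0.3)), nll, method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 5000))
  expect_equal(fit$sigma_u, exp(opt$par[2]), tolerance = 1e-3)
  expect_equal(unname(fit$beta[1]), opt$par[1], tolerance = 1e-3)
})

test_that("variance components are recovered from simulated data", {
  # moderate-size recovery run; the acceptance suite repeats this at the
  # full 300 x 50 design
  set.seed(23)
  nc <- 120; nw <- 30
  u <- rnorm(nc, 0, 0.5); v <- rnorm(nw, 0, 0.3)
  rows <- expand.grid(centre = seq_len(nc), week = seq_len(nw))
  rows$tests <- pmax(1, round(rlnorm(nrow(rows), log(80), 0.8)))
  p <- plogis(qlogis(0.02) + u[rows$centre] + v[rows$week])
  rows$pos <- rbinom(nrow(rows), rows$tests, p)
  start <- as.Date("2021-04-08")
  cl <- validate_claims(data.frame(
    centre_id = sprintf("R%03d", rows$centre), category = "private",
    date = format(start + (rows$week - 1) * 7, "%Y-%m-%d"),
    n_tests = as.character(rows$tests), n_positive = as.character(rows$pos),
    stringsAsFactors = FALSE))
  fit <- fit_positivity_model(cl)
  expect_equal(fit$sigma_u, 0.5, tolerance = 0.2)
  expect_equal(fit$sigma_v, 0.3, tolerance = 0.33)
})

test_that("degenerate inputs are rejected", {
  cl <- toy_claims(list(A = rep(10, 40)))
  expect_error(fit_positivity_model(cl), "at least 2 centres")
})
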