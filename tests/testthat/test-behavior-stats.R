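test_that("phi coefficients behave at the extremes and under independence", {
  # perfectly aligned flags: phi = 1
  f <- tibble::tibble(a = c(rep(1, 5), rep(0, 5)), b = c(rep(1, 5), rep(0, 5)),
                      c = rep(c(1, 0), 5))
  sc <- screen_collinearity(f, c("a", "b", "c"), threshold = 0.7)
  rep_ab <- dplyr::filter(sc$report, behavior_a == "a", behavior_b == "b")
  expect_equal(rep_ab$phi, 1)
  expect_true(rep_ab$flagged)
  # independent flags at n = 10,000: |phi| near zero
  set.seed(61)
  f2 <- tibble::tibble(x = rbinom(10000, 1, 0.3), y = rbinom(10000, 1, 0.25))
  sc2 <- screen_collinearity(f2, c("x", "y"))
  expect_lt(abs(sc2$report$phi), 0.05)
  expect_length(sc2$dropped, 0)
})

test_that("a contact variable built from grooming is dropped, grooming retained", {
  set.seed(62)
  n <- 300
  groom <- rbinom(n, 1, 0.3) * (rpois(n, 2) + 1)
  contact <- groom + rbinom(n, 1, 0.25) * (rpois(n, 1) + 1)
  f <- tibble::tibble(groom_by_female = groom, contact = contact,
                      approach_female = rbinom(n, 1, 0.3) * (rpois(n, 3) + 1))
  r <- cor(groom, contact)
  expect_gt(r, 0.7)  # construction puts the pair above threshold
  sc <- screen_collinearity(f, names(f))
  expect_true("contact" %in% sc$dropped)
  expect_true("groom_by_female" %in% sc$retained)
  expect_true("approach_female" %in% sc$retained)
})

test_that("zero-variance behaviors are excluded from the screen with a note", {
  f <- tibble::tibble(a = rbinom(50, 1, 0.5), b = rep(0, 50),
                      c = rbinom(50, 1, 0.5))
  expect_message(sc <- screen_collinearity(f, c("a", "b", "c")),
                 "no variation")
  expect_equal(sc$zero_variance, "b")
  expect_false("b" %in% sc$retained)
})

test_that("the truncated-NB count likelihood matches direct pmf summation", {
  set.seed(63)
  d <- tibble::tibble(
    female_id = rep(sprintf("F%02d", 1:5), each = 30),
    date = rep(seq(as.Date("2014-01-01"), by = "day", length.out = 30), 5),
    period = rep_len(c("PCP", "month1", "month2"), 150),
    age = rep(c(8, 9, 12, 15, 17), each = 30)
  )
  mu_true <- exp(1 + 0.5 * (d$period == "PCP"))
  d$y <- ifelse(runif(150) < 0.4, rztnb(150, mu_true, 2), 0L)
  fit <- suppressMessages(fit_hurdle(d, "y", random_effects = FALSE))
  cnt <- fit$count
  dfp <- d[d$y > 0, ]
  x <- stats::model.matrix(~ period + age,
                           data = transform(dfp, period = stats::relevel(
                             factor(period), "PCP")))
  mu_hat <- exp(as.numeric(x %*% glmmTMB::fixef(cnt)$cond))
  theta_hat <- stats::sigma(cnt)
  expect_equal(as.numeric(logLik(cnt)),
               oracle_ztnb_loglik(dfp$y, mu_hat, theta_hat),
               tolerance = 1e-6)
})

test_that("the hurdle log-likelihood decomposes exactly into its two parts", {
  set.seed(64)
  d <- sim_binary_study(focals_per_female = 60)
  d$y <- d$y * (rpois(nrow(d), 2) + 1)
  fit <- suppressMessages(fit_hurdle(d, "y"))
  ll <- pregsignal:::hurdle_loglik(fit)
  expect_equal(ll$total, as.numeric(logLik(fit$binary)) +
                 as.numeric(logLik(fit$count)))
  expect_equal(ll$df, attr(logLik(fit$binary), "df") +
                 attr(logLik(fit$count), "df"))
  # and the binary part is an honest Bernoulli likelihood: check against a
  # by-hand computation on a random-effect-free fit
  fit0 <- suppressMessages(fit_hurdle(d, "y", random_effects = FALSE))
  p_hat <- stats::predict(fit0$binary, type = "response")
  occ <- as.integer(d$y > 0)
  expect_equal(as.numeric(logLik(fit0$binary)),
               sum(occ * log(p_hat) + (1 - occ) * log(1 - p_hat)),
               tolerance = 1e-6)
})

test_that("degenerate and sparse responses are refused, not fit", {
  d <- sim_binary_study(focals_per_female = 30)
  d$zero <- 0L
  expect_message(fit <- fit_hurdle(d, "zero"), "degenerate")
  expect_true(fit$binary_degenerate)
  expect_null(fit$binary)
  expect_match(fit$count_refusal, "too few occurrences")
  d$rare <- c(rep(0L, nrow(d) - 3), c(2L, 1L, 4L))
  msgs <- capture_messages(fit2 <- fit_hurdle(d, "rare"))
  expect_match(paste(msgs, collapse = "\n"), "too few occurrences")
  expect_null(fit2$count)
  expect_false(is.null(fit2$binary))
})

test_that("the binary-part status estimate tracks the truth at large n", {
  set.seed(65)
  d <- sim_binary_study(n_females = 8, focals_per_female = 500,
                        sd_female = 0.2, sd_date = 0.2, n_dates = 100)
  fit <- suppressMessages(fit_hurdle(d, "y", min_positive = Inf))
  est <- glmmTMB::fixef(fit$binary)$cond[["periodmonth1"]]
  expect_equal(est, -1.5, tolerance = 0.25)
})

test_that("status-effect estimates de-bias as focals per female grow", {
  set.seed(66)
  bias <- sapply(c(50, 500), function(npf) {
    ests <- replicate(25, {
      d <- sim_binary_study(focals_per_female = npf)
      fit <- suppressMessages(fit_hurdle(d, "y", min_positive = Inf))
      glmmTMB::fixef(fit$binary)$cond[["periodmonth1"]]
    })
    mean(ests) - (-1.5)
  })
  expect_lt(abs(bias[2]), 0.12)
  expect_lt(abs(bias[2]), abs(bias[1]) + 0.1)
})

test_that("Gaussian fits are exact on noise-free data and exchangeable without REs", {
  d <- sim_null_gaussian()
  d$y <- 2 + 1 * (d$period == "month1") - 0.5 * (d$period == "month2")
  fit <- suppressMessages(fit_lme(d, "y"))
  expect_lt(stats::sigma(fit$fit), 1e-4)
  co <- tidy(fit)
  expect_equal(co$estimate[co$term == "periodmonth1"], 1, tolerance = 1e-6)

  # permuting female labels leaves a random-effect-free fit unchanged
  set.seed(67)
  d2 <- sim_null_gaussian()
  f1 <- suppressMessages(fit_lme(d2, "y", random_effects = FALSE))
  d3 <- d2
  d3$female_id <- sample(d3$female_id)
  f2 <- suppressMessages(fit_lme(d3, "y", random_effects = FALSE))
  expect_equal(coef(f1$fit), coef(f2$fit), tolerance = 1e-10)
})

test_that("confidence intervals cover a zero status effect at the nominal rate", {
  set.seed(68)
  cover <- replicate(200, {
    d <- sim_null_gaussian(n_per_female = 40)
    co <- tidy(suppressMessages(fit_lme(d, "y")))
    co <- co[co$term %in% c("periodmonth1", "periodmonth2"), ]
    all(abs(co$estimate) < 1.96 * co$std.error)
  })
  # joint coverage of both contrasts; ~0.95^? with correlated contrasts,
  # accept a generous band around the nominal rate
  expect_gt(mean(cover), 0.85)
  expect_lt(mean(cover), 0.99)
})

test_that("likelihood-ratio tests account for degrees of freedom by part", {
  set.seed(69)
  d <- sim_binary_study(focals_per_female = 80)
  d$y <- d$y * (rpois(nrow(d), 3) + 1)
  full <- suppressMessages(fit_hurdle(d, "y"))
  null <- update_null(full)
  combined <- lrt(full, null)
  expect_equal(combined$df, 4L)  # 2 per hurdle part for a 3-level factor
  expect_equal(lrt(full, null, part = "binary")$df, 2L)
  expect_equal(lrt(full, null, part = "count")$df, 2L)
  expect_equal(combined$statistic,
               lrt(full, null, "binary")$statistic +
                 lrt(full, null, "count")$statistic,
               tolerance = 1e-8)
  expect_gte(combined$statistic, 0)

  # identical models compare vacuously
  self <- lrt(full, full)
  expect_equal(self$statistic, 0)
  expect_equal(self$p_value, 1)

  # differing rows are refused
  d2 <- d[-(1:5), ]
  null2 <- suppressMessages(fit_hurdle(d2, "y", include_status = FALSE))
  expect_error(lrt(full, null2), "row counts")
  # a null with MORE structure than the full is non-nested
  expect_error(lrt(null, full), "not nested")
})

test_that("re-leveling the status factor is a pure reparameterization", {
  set.seed(70)
  d <- sim_null_gaussian()
  d$y <- d$y + 0.8 * (d$period == "month1")
  fit <- suppressMessages(fit_lme(d, "y"))
  rl <- relevel_contrasts(fit, "month1")
  expect_lt(attr(rl, "loglik_diff"), 1e-4)
  # PCP-vs-month1 equals the negated month1-vs-PCP coefficient
  orig <- tidy(fit)
  expect_equal(rl$estimate[rl$term == "periodPCP"],
               -orig$estimate[orig$term == "periodmonth1"],
               tolerance = 1e-4)
  # the LRT against the null is invariant to the baseline
  n0 <- update_null(fit)
  refit <- attr(rl, "fit")
  expect_equal(lrt(fit, n0)$statistic, lrt(refit, n0)$statistic,
               tolerance = 1e-6)
  expect_error(relevel_contrasts(fit, "lactation"), "unknown")
})

test_that("releveled contrasts agree with a direct pairwise refit", {
  set.seed(71)
  d <- sim_null_gaussian(n_per_female = 120)
  d$y <- d$y + 0.8 * (d$period == "month1") + 0.3 * (d$period == "month2")
  fit <- suppressMessages(fit_lme(d, "y", random_effects = FALSE))
  rl <- relevel_contrasts(fit, "month1")
  direct <- suppressMessages(
    fit_lme(d[d$period != "PCP", ], "y", baseline = "month1",
            random_effects = FALSE))
  dco <- tidy(direct)
  est_full <- rl$estimate[rl$term == "periodmonth2"]
  est_sub <- dco$estimate[dco$term == "periodmonth2"]
  se <- dco$std.error[dco$term == "periodmonth2"]
  expect_lt(abs(est_full - est_sub), 2 * se)
})

test_that("zero-inflation is detected only when structural zeros exist", {
  set.seed(72)
  mk <- function(n = 1000, zi = 0) {
    d <- tibble::tibble(
      female_id = sample(sprintf("F%02d", 1:5), n, TRUE),
      date = sample(seq(as.Date("2014-01-01"), by = "day", length.out = 40),
                    n, TRUE),
      period = sample(c("PCP", "month1", "month2"), n, TRUE),
      age = runif(n, 8, 17))
    eta <- 1 + 1.0 * (d$age - 12) - 1 * (d$period == "month1")
    struct <- runif(n) < zi
    d$y <- ifelse(struct, 0L, rbinom(n, 1, plogis(eta)))
    d
  }
  plain_sel <- replicate(100, attr(zero_inflation_check(mk(zi = 0), "y",
                                                        random_effects = FALSE),
                                   "chosen"))
  zi_sel <- replicate(100, attr(zero_inflation_check(mk(zi = 0.4), "y",
                                                     random_effects = FALSE),
                                "chosen"))
  expect_gte(mean(plain_sel == "binomial"), 0.9)
  expect_gte(mean(zi_sel == "zero-inflated binomial"), 0.9)

  # with no real inflation the two variants reach (near) equal likelihoods
  d <- mk(zi = 0)
  tab <- zero_inflation_check(d, "y", random_effects = FALSE)
  expect_lt(abs(diff(tab$logLik)), 2)
  expect_equal(attr(tab, "chosen"), "binomial")
})
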