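test_that("roster generation matches the study design and is reproducible", {
  cfg <- study_config()
  r1 <- simulate_roster(cfg, seed = 5)
  expect_equal(nrow(r1), 5)
  expect_equal(mean(r1$age), 11.6)
  expect_true(all(r1$age >= 8 & r1$age <= 17))
  expect_equal(r1$delivery_date, r1$conception_true + r1$gestation_days)
  expect_equal(r1$rise_true, r1$conception_true + 2)
  expect_identical(r1, simulate_roster(cfg, seed = 5))

  single <- study_config(n_females = 1, ages = 10,
                         focal_alloc = list(PCP = 5, month1 = 5, month2 = 5))
  expect_equal(nrow(simulate_roster(single, seed = 1)), 1)
  expect_error(study_config(n_females = 0, ages = numeric(),
                            focal_alloc = list(PCP = integer(),
                                               month1 = integer(),
                                               month2 = integer())),
               "n_females")
})

test_that("the timeline classifier recovers planted conceptions within 2 days", {
  # clean-sampling recovery: dense gap-free cadence and exact gestation
  # back-dating; the 2-SD scan can still fire on baseline noise, so recovery
  # relies on the nearest-window disambiguation against the delivery date
  cfg <- study_config()
  cfg$cycle_params$gap_prob <- 0
  cfg$cycle_params$cadence_days <- 2
  cfg$gestation_sd <- 0
  errors <- c()
  for (s in 1:20) {
    roster <- simulate_roster(cfg, seed = s)
    horm <- simulate_hormones(cfg, roster, seed = s + 100)
    tl <- reproductive_timeline(
      horm, deliveries = roster,
      study_start = cfg$study_start, study_end = cfg$study_end)
    merged <- dplyr::inner_join(tl$conceptions, roster, by = "female_id")
    errors <- c(errors,
                as.numeric(merged$conception_date - merged$conception_true))
  }
  expect_length(errors, 100)
  expect_true(all(abs(errors) <= 2))
})

test_that("every planted rise is found by the exhaustive 2-SD scan on clean series", {
  # with baseline noise switched off the first qualifying sample is exactly
  # the first sample on/after the planted rise, for package and oracle alike
  cfg <- study_config()
  cfg$cycle_params$gap_prob <- 0
  cfg$cycle_params$baseline_sd <- 0
  for (s in 1:5) {
    roster <- simulate_roster(cfg, seed = s)
    horm <- simulate_hormones(cfg, roster, seed = s + 100)
    rises <- detect_luteal_onset(horm)
    for (fid in roster$female_id) {
      sub <- dplyr::arrange(horm[horm$female_id == fid, ], date)
      planted <- roster$rise_true[roster$female_id == fid]
      expected <- min(sub$date[sub$date >= planted])
      expect_equal(oracle_rise_scan(sub$date, sub$pdg_ug_g), expected)
      expect_equal(rises$rise_date[rises$female_id == fid], expected)
    }
  }
})

test_that("noise-free strong rises are always detected", {
  cfg <- study_config()
  cfg$cycle_params$baseline_sd <- 0
  cfg$cycle_params$preg_log_sd <- 0
  cfg$cycle_params$month1_level <- 3 * cfg$cycle_params$baseline_mean
  cfg$cycle_params$gap_prob <- 0
  roster <- simulate_roster(cfg, seed = 3)
  horm <- simulate_hormones(cfg, roster, seed = 4)
  rises <- detect_luteal_onset(horm)
  expect_true(all(!is.na(rises$rise_date)))
})

test_that("an undetectably small rise magnitude triggers a warning", {
  cfg <- study_config()
  cfg$cycle_params$month1_level <-
    cfg$cycle_params$baseline_mean + 1 * cfg$cycle_params$baseline_sd
  roster <- simulate_roster(cfg, seed = 1)
  expect_warning(h <- simulate_hormones(cfg, roster, seed = 2),
                 "undetectable")
  expect_false(attr(h, "detectable"))
})

test_that("pregnancy PdG declines and the E1C/PdG ratio climbs, month1 to month2", {
  cfg <- study_config()
  m1_pdg <- c(); m2_pdg <- c(); m1_rat <- c(); m2_rat <- c()
  for (s in 1:200) {
    roster <- simulate_roster(cfg, seed = s)
    horm <- simulate_hormones(cfg, roster, seed = s + 10000)
    lab <- label_periods(
      dplyr::rename(roster, conception_date = "conception_true"),
      cfg$study_start, cfg$study_end)
    h <- dplyr::inner_join(horm, lab, by = c("female_id", "date"))
    m1 <- h[h$period == "month1", ]; m2 <- h[h$period == "month2", ]
    m1_pdg <- c(m1_pdg, mean(m1$pdg_ug_g)); m2_pdg <- c(m2_pdg, mean(m2$pdg_ug_g))
    m1_rat <- c(m1_rat, mean(m1$e1c_ng_g / m1$pdg_ug_g))
    m2_rat <- c(m2_rat, mean(m2$e1c_ng_g / m2$pdg_ug_g))
  }
  expect_lt(mean(m2_pdg), mean(m1_pdg))
  expect_gt(mean(m2_rat), mean(m1_rat))
})

test_that("the default design emits exactly 153 focals split 46/57/50", {
  st <- default_study()
  expect_equal(nrow(st$focals), 153)
  expect_equal(as.vector(table(st$focals$period)),
               c(PCP = 46, month1 = 57, month2 = 50), ignore_attr = TRUE)
  expect_true(all(st$focals$date >= st$config$study_start &
                    st$focals$date <= st$config$study_end))
})

test_that("zero-probability behaviors never occur", {
  st <- default_study()
  expect_true(all(st$focals$presentation_female == 0))
  expect_true(all(st$focals$inspection_male == 0))
  expect_true(all(st$focals$mount[st$focals$period != "PCP"] == 0))
})

test_that("with no random effects the occurrence fraction converges to the configured rate", {
  # law-of-large-numbers check at ~10,000 focals per period
  cfg <- study_config(
    focal_alloc = list(PCP = rep(2000, 5), month1 = rep(2000, 5),
                       month2 = rep(2000, 5)),
    re_params = list(occ_female_sd = 0, occ_date_sd = 0,
                     count_female_sd = 0, count_date_sd = 0)
  )
  roster <- simulate_roster(cfg, seed = 8)
  foc <- simulate_focals(cfg, roster, seed = 9)$focals
  rates <- cfg$rates
  for (b in c("approach_female", "estrus_call", "holding_male")) {
    for (p in c("PCP", "month1", "month2")) {
      target <- rates$p_occ[rates$behavior == b & rates$period == p]
      got <- mean(foc[[b]][foc$period == p] > 0)
      expect_equal(got, target, tolerance = 0.05 + 0.02 / max(target, 0.01))
    }
  }
})

test_that("focal counts embed the configured hurdle structure", {
  st <- default_study()
  f <- st$focals
  rates <- st$config$rates
  modeled <- unique(rates$behavior[rates$modeled])
  for (b in modeled) {
    # counts are >= 1 exactly where the behavior occurred
    expect_true(all(f[[b]] >= 0))
    expect_true(all(f[[b]] == floor(f[[b]])))
  }
  # durations positive iff bouts happened
  expect_true(all((f$groom_by_female_s > 0) == (f$groom_by_female > 0)))
  expect_true(all(f$contact >= f$groom_by_female + f$groom_by_male))
})

test_that("default photo counts are 28/35/25 and color effects point the configured way", {
  st <- default_study()
  expect_equal(as.vector(table(st$photos$period)),
               c(PCP = 28, month1 = 35, month2 = 25), ignore_attr = TRUE)

  cfg <- study_config()
  lumi_pcp <- c(); lumi_m1 <- c(); rg_m1 <- c(); rg_m2 <- c()
  for (s in 1:500) {
    roster <- simulate_roster(cfg, seed = s)
    col <- simulate_color(cfg, roster, seed = s + 20000)
    tr <- col$photos
    lum <- (tr$lw_true + tr$mw_true) / 2
    rg <- (tr$lw_true - tr$mw_true) / (tr$lw_true + tr$mw_true)
    lumi_pcp <- c(lumi_pcp, mean(lum[tr$period == "PCP"]))
    lumi_m1 <- c(lumi_m1, mean(lum[tr$period == "month1"]))
    rg_m1 <- c(rg_m1, mean(rg[tr$period == "month1"]))
    rg_m2 <- c(rg_m2, mean(rg[tr$period == "month2"]))
  }
  expect_lt(mean(lumi_m1), mean(lumi_pcp))
  expect_lt(mean(rg_m2), mean(rg_m1))
})

test_that("noise-free color generation reproduces the period means exactly", {
  cfg <- study_config()
  cfg$color_params$session_log_sd <- 0
  cfg$color_params$channel_log_sd <- 0
  cfg$color_params$rgb_noise_sd <- 0
  cfg$color_params$chart_noise_sd <- 0
  cfg$color_params$female_log_sd <- 0
  roster <- simulate_roster(cfg, seed = 2)
  col <- simulate_color(cfg, roster, seed = 3)
  means <- cfg$color_params$means
  for (p in means$period) {
    tr <- col$photos[col$photos$period == p, ]
    mm <- means[means$period == p, ]
    expect_equal(unique(round(tr$lw_true, 12)), mm$LW)
    rg_expected <- (mm$LW - mm$MW) / (mm$LW + mm$MW)
    rg_true <- (tr$lw_true - tr$mw_true) / (tr$lw_true + tr$mw_true)
    expect_equal(unique(round(rg_true, 12)), round(rg_expected, 12))
  }
})

test_that("hierarchy steepness controls interaction outcomes as configured", {
  cfg <- study_config()
  cfg$hierarchy$steepness <- 1e6
  roster <- simulate_roster(cfg, seed = 4)
  ints <- simulate_interactions(cfg, roster, seed = 5)
  rk <- stats::setNames(roster$rank_true, roster$female_id)
  expect_true(all(rk[ints$winner_id] < rk[ints$loser_id]))

  cfg$hierarchy$steepness <- 0
  cfg$hierarchy$n_interactions <- 4000
  ints0 <- simulate_interactions(cfg, roster, seed = 6)
  d <- dyadic_dominance(interaction_matrix(ints0, roster$female_id))
  off_diag <- d[upper.tri(d) | lower.tri(d)]
  expect_equal(mean(off_diag), 0.5, tolerance = 0.03)
})

test_that("NDS recovers the planted hierarchy at moderate steepness", {
  cfg <- study_config()  # steepness 5
  cfg$hierarchy$n_interactions <- 200
  ok <- 0
  for (s in 1:200) {
    roster <- simulate_roster(cfg, seed = s)
    ints <- simulate_interactions(cfg, roster, seed = s + 30000)
    scores <- rank_females(ints, roster)
    planted <- roster$rank_true[match(scores$id, roster$female_id)]
    if (all(scores$rank == planted)) ok <- ok + 1
  }
  expect_gte(ok / 200, 0.95)
})

test_that("a fixed seed reproduces the whole study bit-identically", {
  s1 <- simulate_study(study_config(), seed = 77)
  s2 <- simulate_study(study_config(), seed = 77)
  for (part in c("roster", "hormones", "focals", "photos", "charts",
                 "interactions")) {
    expect_identical(s1[[part]], s2[[part]])
  }
  expect_identical(s1$truth$roster, s2$truth$roster)
})

test_that("ground truth is emitted alongside the data", {
  st <- default_study()
  expect_true(all(c("roster", "coefficients", "color_means", "photos_true") %in%
                    names(st$truth)))
  expect_true(all(c("b_occ", "log_mu", "p_occ") %in%
                    names(st$truth$coefficients)))
  expect_equal(nrow(st$truth$roster), 5)
})
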