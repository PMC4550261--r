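#' Per-period focal-sample totals of the reference study design
#'
#' Event totals of female and male socio-sexual behaviors and calls per
#' reproductive period (pre-conceptive period `PCP`, first and second month of
#' pregnancy) in the reference field study of Koshima Japanese macaques,
#' together with the behaviors' direction and whether they are estimable in
#' the default statistical models. Grooming bouts were recorded but their
#' per-period totals were not tabulated in the source study; the grooming and
#' contact rows here are package defaults chosen to reproduce the reported
#' qualitative pattern (grooming decreasing after conception, contact strongly
#' correlated with grooming).
#'
#' @return A tibble with columns `behavior`, `direction`
#'   (`"female_to_male"` or `"male_to_female"`), `modeled` (enters the default
#'   hurdle models), `tabulated` (totals taken from the reference study rather
#'   than package defaults), and per-period event totals `PCP`, `month1`,
#'   `month2`.
#' @export
behavior_totals <- function() {
  tibble::tribble(
    ~behavior,             ~direction,       ~modeled, ~tabulated, ~PCP, ~month1, ~month2,
    "approach_female",     "female_to_male", TRUE,     TRUE,        130,      21,      82,
    "presentation_female", "female_to_male", FALSE,    TRUE,          0,       0,       0,
    "holding_female",      "female_to_male", FALSE,    TRUE,          0,       0,      27,
    "estrus_call",         "female_to_male", TRUE,     TRUE,       1809,     804,    3065,
    "copulation_call",     "female_to_male", FALSE,    TRUE,         57,       0,       0,
    "approach_male",       "male_to_female", FALSE,    TRUE,        137,       6,      27,
    "holding_male",        "male_to_female", TRUE,     TRUE,        163,       0,      45,
    "mount",               "male_to_female", FALSE,    TRUE,        138,       0,       0,
    "inspection_male",     "male_to_female", FALSE,    TRUE,          0,       0,       0,
    "groom_by_female",     "female_to_male", TRUE,     FALSE,        40,      17,      15,
    "groom_by_male",       "male_to_female", TRUE,     FALSE,        25,      12,      14
  )
}

# periods of the three-period contrast, in baseline-first order
period_levels <- function() c("PCP", "month1", "month2")

#' Build behavior occurrence/count rates from per-period event totals
#'
#' Converts per-period event totals into the two-part rates the synthetic
#' generator uses: an occurrence probability per focal (`p_occ`) and the
#' per-focal expected event count (`events_per_focal`). Calibration is in
#' expectation: `p_occ * E[positive count] = total / n_focals`. Occurrence
#' probabilities are capped at `p_max` so that the per-behavior fraction of
#' zero-count focals stays at or above `1 - p_max`; for sparse behaviors
#' `p_occ` is reduced further (to two-thirds of the per-focal rate) so the
#' zero-truncated positive-count mean stays above its lower bound of 1.
#'
#' @param totals A tibble as returned by [behavior_totals()].
#' @param n_focals Named integer vector of focal counts per period.
#' @param p_max Maximum per-focal occurrence probability (default 0.25,
#'   keeping at least 75% zero focals per behavior).
#' @param dispersion Negative-binomial size parameter of the positive-count
#'   part.
#' @return A tibble with one row per behavior x period: `behavior`,
#'   `direction`, `modeled`, `period`, `n_focals`, `total`,
#'   `events_per_focal`, `p_occ`, `dispersion`.
#' @export
behavior_rates <- function(totals = behavior_totals(),
                           n_focals = c(PCP = 46, month1 = 57, month2 = 50),
                           p_max = 0.25,
                           dispersion = 1.5) {
  stopifnot(all(period_levels() %in% names(n_focals)))
  totals |>
    tidyr::pivot_longer(dplyr::all_of(period_levels()),
                        names_to = "period", values_to = "total") |>
    dplyr::mutate(
      period = factor(.data$period, levels = period_levels()),
      n_focals = as.numeric(n_focals[as.character(.data$period)]),
      events_per_focal = .data$total / .data$n_focals,
      p_occ = ifelse(.data$total > 0,
                     pmin(p_max, (2 / 3) * .data$events_per_focal), 0),
      dispersion = dispersion
    )
}

#' Study configuration for the synthetic generator
#'
#' Assembles the full parameterization of a synthetic focal-sampling study.
#' Defaults reproduce the design of the reference study: 5 conceiving females
#' (mean age 11.6 +/- SD 3.8 years, range 8-17), a December-to-mid-March
#' study window, 46/57/50 focal observations across the pre-conceptive period
#' and the first two months of pregnancy, 28/35/25 facial photographs, fecal
#' sampling every ~3 days with weather dropouts, and behavior rates calibrated
#' in expectation to the tabulated per-period event totals.
#'
#' @param n_females Number of conceiving females.
#' @param ages Ages in years, one per female. The default set has mean 11.6
#'   and SD 3.8 within range 8-17.
#' @param study_start,study_end Study window (ISO-8601 or `Date`).
#' @param conception_earliest,conception_latest Window from which true
#'   conception dates are drawn, chosen so that the pre-conceptive month and
#'   both pregnancy months fall inside the study window.
#' @param focal_alloc Named list of per-female focal counts for `PCP`,
#'   `month1`, `month2`. Defaults sum to 46, 57 and 50.
#' @param rates Behavior rate table from [behavior_rates()].
#' @param cycle_params Hormone-profile parameters: baseline PdG mean/SD
#'   (ug/g dry feces), post-conception PdG levels for each pregnancy month
#'   (month2 below month1), lognormal noise SD of pregnancy PdG, E1C mean
#'   (ng/g) and lognormal SD, sampling cadence (days) and per-sample gap
#'   probability.
#' @param re_params Random-effect SDs: female and date intercepts on the
#'   occurrence logit scale and on the positive-count log-mean scale.
#' @param color_params Per-period long-wave (LW) and medium-wave (MW) receptor
#'   capture means, per-female photo allocation, and noise SDs (session
#'   exposure, per-channel biological noise, camera RGB measurement noise,
#'   chart patch noise).
#' @param hierarchy Dominance-hierarchy parameters: steepness of the dyadic
#'   win-probability curve and total number of agonistic interactions.
#' @param contact_extra_prob Probability that a focal records male-female body
#'   contact not attached to a grooming bout (contact is otherwise generated
#'   from the grooming bouts, which makes the two strongly correlated).
#' @param groom_duration Gamma parameters (shape, scale in seconds) of a
#'   single grooming/contact bout length.
#' @param gestation_mean,gestation_sd Gestation length in days: the species
#'   mean used for back-dating (176.3) and the between-female SD used when
#'   simulating true deliveries.
#' @return A `study_config` list, validated.
#' @export
study_config <- function(n_females = 5,
                         ages = c(8, 9, 10, 14, 17),
                         study_start = "2013-12-01",
                         study_end = "2014-03-15",
                         conception_earliest = "2013-12-31",
                         conception_latest = "2014-01-14",
                         focal_alloc = list(
                           PCP = c(3, 9, 10, 10, 14),
                           month1 = c(9, 10, 11, 12, 15),
                           month2 = c(9, 10, 10, 10, 11)
                         ),
                         rates = behavior_rates(),
                         cycle_params = list(
                           baseline_mean = 1.0, baseline_sd = 0.12,
                           month1_level = 3.0, month2_level = 2.0,
                           preg_log_sd = 0.15,
                           e1c_mean = 30, e1c_log_sd = 0.2,
                           cadence_days = 3, gap_prob = 0.1
                         ),
                         re_params = list(
                           occ_female_sd = 0.4, occ_date_sd = 0.3,
                           count_female_sd = 0.2, count_date_sd = 0.2
                         ),
                         color_params = list(
                           means = tibble::tribble(
                             ~period,  ~LW,   ~MW,
                             "PCP",    0.60,  0.45,
                             "month1", 0.52,  0.41,
                             "month2", 0.47,  0.385
                           ),
                           photo_alloc = list(
                             PCP = c(3, 5, 6, 6, 8),
                             month1 = c(6, 7, 7, 7, 8),
                             month2 = c(3, 4, 5, 6, 7)
                           ),
                           session_log_sd = 0.10,
                           channel_log_sd = 0.05,
                           rgb_noise_sd = 0.02,
                           chart_noise_sd = 0.01
                         ),
                         hierarchy = list(steepness = 5, n_interactions = 300),
                         contact_extra_prob = 0.05,
                         groom_duration = list(shape = 2, scale_s = 60),
                         gestation_mean = 176.3,
                         gestation_sd = 3) {
  if (n_females < 1) abort("n_females must be >= 1 (empty roster request)")
  # adapt per-female allocations to n_females: scalars are recycled; default
  # (or otherwise mismatched) vectors are redistributed near-evenly across
  # females, preserving the per-period totals
  recycle <- function(alloc) lapply(alloc, function(x) {
    if (length(x) == n_females) return(x)
    if (length(x) == 1) return(rep(x, n_females))
    total <- sum(x)
    out <- rep(total %/% n_females, n_females)
    extra <- total %% n_females
    if (extra > 0) out[seq_len(extra)] <- out[seq_len(extra)] + 1
    out
  })
  focal_alloc <- recycle(focal_alloc)
  color_params$photo_alloc <- recycle(color_params$photo_alloc)
  if (length(ages) == 1) ages <- rep(ages, n_females)
  cfg <- list(
    n_females = as.integer(n_females),
    female_ids = sprintf("F%02d", seq_len(n_females)),
    ages = ages,
    study_start = as_date_strict(study_start, "study_start"),
    study_end = as_date_strict(study_end, "study_end"),
    conception_earliest = as_date_strict(conception_earliest),
    conception_latest = as_date_strict(conception_latest),
    focal_alloc = focal_alloc,
    rates = rates,
    cycle_params = cycle_params,
    re_params = re_params,
    color_params = color_params,
    hierarchy = hierarchy,
    contact_extra_prob = contact_extra_prob,
    groom_duration = groom_duration,
    gestation_mean = gestation_mean,
    gestation_sd = gestation_sd
  )
  class(cfg) <- "study_config"
  validate_study_config(cfg)
}

#' Validate a study configuration
#'
#' Checks the invariants the generator relies on: at least one female, one
#' age and one focal allocation entry per female, occurrence probabilities in
#' \[0, 1\], positive dispersion, positive receptor-capture means, exactly the
#' three contrast periods, and a conception window that keeps all three
#' 30-day periods inside the study window.
#'
#' @param cfg A `study_config`.
#' @return `cfg`, invisibly returned on success; otherwise an error.
#' @export
validate_study_config <- function(cfg) {
  if (cfg$n_females < 1) abort("n_females must be >= 1 (empty roster request)")
  if (length(cfg$ages) != cfg$n_females) {
    abort("`ages` must have one entry per female")
  }
  for (p in period_levels()) {
    if (length(cfg$focal_alloc[[p]]) != cfg$n_females) {
      abort(sprintf("focal_alloc$%s must have one entry per female", p))
    }
    if (length(cfg$color_params$photo_alloc[[p]]) != cfg$n_females) {
      abort(sprintf("color_params$photo_alloc$%s must have one entry per female", p))
    }
  }
  if (!setequal(unique(as.character(cfg$rates$period)), period_levels())) {
    abort("rate table periods must be exactly {PCP, month1, month2}")
  }
  if (any(cfg$rates$p_occ < 0 | cfg$rates$p_occ > 1)) {
    abort("occurrence probabilities must lie in [0, 1]")
  }
  if (any(cfg$rates$dispersion <= 0)) abort("dispersion must be > 0")
  if (any(cfg$color_params$means$LW <= 0) || any(cfg$color_params$means$MW <= 0)) {
    abort("LW and MW period means must be > 0")
  }
  if (cfg$cycle_params$cadence_days > 7) {
    abort("sampling cadence must average at least one sample per 7 days")
  }
  if (cfg$conception_earliest - 30 < cfg$study_start ||
      cfg$conception_latest + 59 > cfg$study_end) {
    abort("conception window must keep PCP and both pregnancy months inside the study window")
  }
  invisible(cfg)
}

#' Read / write a study configuration as YAML
#'
#' Round-trips the subset of [study_config()] arguments that are plain values
#' or tables; unspecified fields take their defaults.
#'
#' @param path File path.
#' @param cfg A `study_config` (for writing).
#' @return `read_study_config()` returns a `study_config`;
#'   `write_study_config()` returns `path` invisibly.
#' @export
read_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- list()
  scalar_fields <- c("n_females", "ages", "study_start", "study_end",
                     "conception_earliest", "conception_latest",
                     "contact_extra_prob", "gestation_mean", "gestation_sd")
  for (f in scalar_fields) if (!is.null(raw[[f]])) args[[f]] <- raw[[f]]
  list_fields <- c("focal_alloc", "cycle_params", "re_params", "hierarchy",
                   "groom_duration")
  for (f in list_fields) {
    if (!is.null(raw[[f]])) {
      args[[f]] <- utils::modifyList(formals(study_config)[[f]] |> eval(), raw[[f]])
    }
  }
  if (!is.null(raw$color_params)) {
    cp <- eval(formals(study_config)$color_params)
    over <- raw$color_params
    if (!is.null(over$means)) over$means <- tibble::as_tibble(over$means)
    args$color_params <- utils::modifyList(cp, over)
  }
  do.call(study_config, args)
}

#' @rdname read_study_config
#' @export
write_study_config <- function(cfg, path) {
  out <- list(
    n_females = cfg$n_females,
    ages = cfg$ages,
    study_start = format(cfg$study_start),
    study_end = format(cfg$study_end),
    conception_earliest = format(cfg$conception_earliest),
    conception_latest = format(cfg$conception_latest),
    focal_alloc = cfg$focal_alloc,
    cycle_params = cfg$cycle_params,
    re_params = cfg$re_params,
    hierarchy = cfg$hierarchy,
    groom_duration = cfg$groom_duration,
    contact_extra_prob = cfg$contact_extra_prob,
    gestation_mean = cfg$gestation_mean,
    gestation_sd = cfg$gestation_sd,
    color_params = list(
      means = as.list(cfg$color_params$means),
      photo_alloc = cfg$color_params$photo_alloc,
      session_log_sd = cfg$color_params$session_log_sd,
      channel_log_sd = cfg$color_params$channel_log_sd,
      rgb_noise_sd = cfg$color_params$rgb_noise_sd,
      chart_noise_sd = cfg$color_params$chart_noise_sd
    )
  )
  yaml::write_yaml(out, path)
  invisible(path)
}
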