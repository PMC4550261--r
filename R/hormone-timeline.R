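# Reproductive-timeline classification from fecal hormone series.
#
# The luteal onset is the first sample whose PdG concentration exceeds the
# mean of the 3-4 immediately preceding baseline samples by at least k
# (default 2) sample standard deviations. Windows are then constructed in
# calendar days relative to that fecal rise: the 2-day peri-ovulatory window
# is {rise-3, rise-2} (the 2-3 day excretion lag is absorbed into these
# offsets) and the 5-day fertile window {rise-6 ... rise-2} adds the three
# preceding days for sperm survival. Conception is dated to the last fertile
# day and cross-checked against delivery minus the 176.3-day mean gestation.

#' Detect the luteal-phase PdG rise
#'
#' Scans each female's dated PdG series for the first sample at least
#' `k` sample standard deviations above the mean of the `baseline_n`
#' immediately preceding samples (SD with the n-1 denominator). A sample on
#' a flat baseline (SD = 0) qualifies only if it strictly exceeds the
#' baseline mean, so constant series yield no rise.
#'
#' @param hormones Tibble with `female_id`, `date`, `pdg_ug_g` (dates unique
#'   per female; PdG >= 0).
#' @param baseline_n `"auto"` (default; use 4 preceding samples when
#'   available, else 3, favoring baseline stability) or a fixed 3 or 4.
#' @param k SD multiplier (default 2).
#' @param candidates If `TRUE`, return every rise onset (a qualifying sample
#'   whose predecessor did not qualify), one row each, for disambiguation
#'   against a delivery date; otherwise only the earliest.
#' @return A tibble with `female_id`, `rise_date` (`NA` if no sample
#'   qualifies), `pdg_at_rise`, `threshold`, `baseline_mean`, `baseline_sd`,
#'   `baseline_n_used`.
#' @export
detect_luteal_onset <- function(hormones, baseline_n = "auto", k = 2,
                                candidates = FALSE) {
  assert_columns(hormones, c("female_id", "date", "pdg_ug_g"), "hormones")
  if (!identical(baseline_n, "auto") && !baseline_n %in% c(3, 4)) {
    abort("baseline_n must be \"auto\", 3 or 4")
  }
  if (any(hormones$pdg_ug_g < 0, na.rm = TRUE)) abort("PdG must be >= 0")
  dup <- hormones |> dplyr::count(.data$female_id, .data$date) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) abort("dates must be unique within female")

  one_series <- function(df) {
    df <- dplyr::arrange(df, .data$date)
    pdg <- df$pdg_ug_g
    n <- length(pdg)
    min_b <- if (identical(baseline_n, "auto")) 3 else baseline_n
    if (n < min_b + 1) {
      abort(sprintf("series for %s has %d samples; need at least baseline_n + 1",
                    df$female_id[1], n))
    }
    qualifies <- rep(FALSE, n)
    meta <- matrix(NA_real_, n, 4)
    for (i in seq(min_b + 1, n)) {
      b <- if (identical(baseline_n, "auto")) min(4, i - 1) else baseline_n
      if (i - 1 < b) next
      base <- pdg[(i - b):(i - 1)]
      m <- mean(base)
      s <- sd(base)
      qualifies[i] <- (pdg[i] - m >= k * s) && (pdg[i] > m)
      meta[i, ] <- c(m + k * s, m, s, b)
    }
    onset <- qualifies & !dplyr::lag(qualifies, default = FALSE)
    idx <- which(onset)
    if (!candidates) idx <- utils::head(idx, 1)
    if (length(idx) == 0) {
      return(tibble::tibble(
        female_id = df$female_id[1], rise_date = as.Date(NA),
        pdg_at_rise = NA_real_, threshold = NA_real_,
        baseline_mean = NA_real_, baseline_sd = NA_real_,
        baseline_n_used = NA_integer_
      ))
    }
    tibble::tibble(
      female_id = df$female_id[1],
      rise_date = df$date[idx],
      pdg_at_rise = pdg[idx],
      threshold = meta[idx, 1],
      baseline_mean = meta[idx, 2],
      baseline_sd = meta[idx, 3],
      baseline_n_used = as.integer(meta[idx, 4])
    )
  }
  hormones |>
    dplyr::group_by(.data$female_id) |>
    dplyr::group_split() |>
    purrr::map(one_series) |>
    dplyr::bind_rows()
}

#' Construct peri-ovulatory and fertile windows from a PdG rise
#'
#' The 2-day peri-ovulatory window is days -3 and -2 relative to the fecal
#' rise; the 5-day fertile window spans days -6 through -2 (the
#' peri-ovulatory days plus the three preceding days).
#'
#' @param rises Tibble with `female_id` and `rise_date` (e.g. from
#'   [detect_luteal_onset()]). Rows with `NA` rise dates get `NA` windows.
#' @return The input with `peri_start`, `peri_end`, `fertile_start`,
#'   `fertile_end`, and a `fertile_days` list-column of the 5 dates.
#' @export
build_windows <- function(rises) {
  assert_columns(rises, c("female_id", "rise_date"), "rises")
  rises |>
    dplyr::mutate(
      peri_start = .data$rise_date - 3,
      peri_end = .data$rise_date - 2,
      fertile_start = .data$rise_date - 6,
      fertile_end = .data$rise_date - 2,
      fertile_days = purrr::map2(.data$fertile_start, .data$fertile_end,
                                 function(a, b) {
                                   if (is.na(a)) as.Date(NA) else seq(a, b, by = "day")
                                 })
    )
}

#' Estimate conception dates
#'
#' Conception is dated to the last day of the fertile window (the latest
#' possible fertilization day). When a delivery date is available, a
#' back-dated estimate `delivery - round(gestation_days)` is computed as
#' well; if several candidate rises exist, the fertile window whose last day
#' lies nearest the back-dated estimate is chosen, and the discrepancy in
#' days is recorded. With no detectable rise the back-dated estimate is used
#' alone.
#'
#' @param windows Tibble from [build_windows()], possibly several candidate
#'   rows per female.
#' @param deliveries Optional tibble `female_id`, `delivery_date`.
#' @param gestation_days Mean gestation length in days (default 176.3; dates
#'   are back-calculated with the value rounded to a whole day, the
#'   fractional constant being retained for reporting).
#' @return One row per female: `female_id`, `conception_date`, `rise_date`,
#'   `method` (`"hormonal"`, `"backdated"` or `"combined"`),
#'   `backdated_date`, `discrepancy_days`, `n_candidates`.
#' @export
estimate_conception <- function(windows, deliveries = NULL,
                                gestation_days = 176.3) {
  assert_columns(windows, c("female_id", "fertile_end"), "windows")
  gest <- round(gestation_days)
  deliv <- if (is.null(deliveries)) {
    tibble::tibble(female_id = character(), delivery_date = as.Date(character()))
  } else {
    assert_columns(deliveries, c("female_id", "delivery_date"), "deliveries")
    deliveries
  }
  one_female <- function(df) {
    fid <- df$female_id[1]
    dd <- deliv$delivery_date[match(fid, deliv$female_id)]
    cand <- df |> dplyr::filter(!is.na(.data$fertile_end))
    backdated <- if (length(dd) == 1 && !is.na(dd)) dd - gest else as.Date(NA)
    if (nrow(cand) == 0 && is.na(backdated)) {
      abort(sprintf("female %s: no hormonal fertile window and no delivery date", fid))
    }
    if (nrow(cand) == 0) {
      return(tibble::tibble(female_id = fid, conception_date = backdated,
                            rise_date = as.Date(NA), method = "backdated",
                            backdated_date = backdated,
                            discrepancy_days = NA_real_, n_candidates = 0L))
    }
    if (is.na(backdated)) {
      pick <- cand[1, ]
      return(tibble::tibble(female_id = fid,
                            conception_date = pick$fertile_end,
                            rise_date = pick$rise_date, method = "hormonal",
                            backdated_date = backdated,
                            discrepancy_days = NA_real_,
                            n_candidates = nrow(cand)))
    }
    gap <- abs(as.numeric(cand$fertile_end - backdated))
    pick <- cand[which.min(gap), ]
    tibble::tibble(female_id = fid, conception_date = pick$fertile_end,
                   rise_date = pick$rise_date, method = "combined",
                   backdated_date = backdated,
                   discrepancy_days = as.numeric(pick$fertile_end - backdated),
                   n_candidates = nrow(cand))
  }
  windows |>
    dplyr::group_by(.data$female_id) |>
    dplyr::group_split() |>
    purrr::map(one_female) |>
    dplyr::bind_rows()
}

#' Label study days by reproductive period
#'
#' Pregnancy months are 30-day blocks anchored at conception: `month1` is
#' days 0-29 from conception, `month2` days 30-59, and the pre-conceptive
#' period (`PCP`) days -30 to -1. All remaining study days are `other`.
#'
#' @param conceptions Tibble with `female_id`, `conception_date`.
#' @param study_start,study_end Study window.
#' @return Long tibble `female_id`, `date`, `period` (factor `PCP`,
#'   `month1`, `month2`, `other`) partitioning the window per female.
#' @export
label_periods <- function(conceptions, study_start, study_end) {
  assert_columns(conceptions, c("female_id", "conception_date"), "conceptions")
  study_start <- as_date_strict(study_start, "study_start")
  study_end <- as_date_strict(study_end, "study_end")
  days <- seq(study_start, study_end, by = "day")
  tidyr::crossing(
    dplyr::select(conceptions, "female_id", "conception_date"),
    date = days
  ) |>
    dplyr::mutate(
      offset = as.numeric(.data$date - .data$conception_date),
      period = factor(dplyr::case_when(
        .data$offset >= -30 & .data$offset <= -1 ~ "PCP",
        .data$offset >= 0 & .data$offset <= 29 ~ "month1",
        .data$offset >= 30 & .data$offset <= 59 ~ "month2",
        TRUE ~ "other"
      ), levels = c(period_levels(), "other"))
    ) |>
    dplyr::select("female_id", "date", "period")
}

#' Per-sample hormone outcomes on the modeling scale
#'
#' Joins period labels onto the hormone series and natural-log transforms
#' PdG, E1C and their ratio (all lognormal-like). Rows with a zero hormone
#' value are excluded with a warning, since their logs are undefined.
#'
#' @param hormones Tibble `female_id`, `date`, `pdg_ug_g`, `e1c_ng_g`.
#' @param labels Period labels from [label_periods()], or `NULL` if
#'   `hormones` already carries a `period` column.
#' @return Tibble with `period`, `ratio_e1c_pdg`, `log_pdg`, `log_e1c`,
#'   `log_ratio` per retained sample.
#' @export
hormone_outcomes <- function(hormones, labels = NULL) {
  assert_columns(hormones, c("female_id", "date", "pdg_ug_g", "e1c_ng_g"),
                 "hormones")
  out <- hormones
  if (!is.null(labels)) {
    out <- dplyr::left_join(out,
                            dplyr::select(labels, "female_id", "date", "period"),
                            by = c("female_id", "date"))
  } else {
    assert_columns(out, "period", "hormones")
  }
  bad <- out$pdg_ug_g <= 0 | out$e1c_ng_g <= 0
  if (all(bad)) abort("all hormone values are non-positive; nothing to log-transform")
  if (any(bad)) {
    warn(sprintf("excluding %d sample(s) with non-positive PdG or E1C from log outcomes",
                 sum(bad)))
    out <- out[!bad, ]
  }
  out |>
    dplyr::mutate(
      ratio_e1c_pdg = .data$e1c_ng_g / .data$pdg_ug_g,
      log_pdg = log(.data$pdg_ug_g),
      log_e1c = log(.data$e1c_ng_g),
      log_ratio = log(.data$ratio_e1c_pdg)
    )
}

#' Full reproductive-timeline classification
#'
#' Convenience wrapper chaining [detect_luteal_onset()] (with candidate
#' rises), [build_windows()], [estimate_conception()] and [label_periods()].
#'
#' @param hormones Tibble `female_id`, `date`, `pdg_ug_g`, `e1c_ng_g`.
#' @param deliveries Optional tibble `female_id`, `delivery_date`.
#' @param study_start,study_end Study window; defaults to the hormone series
#'   range.
#' @inheritParams detect_luteal_onset
#' @inheritParams estimate_conception
#' @return A `reproductive_timeline` list: `rises` (all candidates),
#'   `conceptions` (one row per female) and `labels` (per female-day).
#' @export
reproductive_timeline <- function(hormones, deliveries = NULL,
                                  study_start = min(hormones$date),
                                  study_end = max(hormones$date),
                                  baseline_n = "auto", k = 2,
                                  gestation_days = 176.3) {
  rises <- detect_luteal_onset(hormones, baseline_n = baseline_n, k = k,
                               candidates = TRUE)
  windows <- build_windows(rises)
  conceptions <- estimate_conception(windows, deliveries,
                                     gestation_days = gestation_days)
  labels <- label_periods(conceptions, study_start, study_end)
  out <- list(rises = rises, conceptions = conceptions, labels = labels)
  class(out) <- "reproductive_timeline"
  out
}

#' @export
print.reproductive_timeline <- function(x, ...) {
  cat("<reproductive_timeline>", nrow(x$conceptions), "females\n")
  print(x$conceptions)
  invisible(x)
}
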