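# End-to-end pipeline: simulate -> timeline -> color -> rank -> fit -> report.
#
# Each stage reads the CSVs an earlier stage wrote (or that a user supplied
# in the same dialect), so partial runs resume from cached stage outputs.
# Every run writes a manifest (config snapshot, seed, package version, file
# digests) sufficient to reproduce it, plus a structured log of decisions
# (excluded rows, refused models, boundary fits).

pipeline_stages <- function() {
  c("simulate", "timeline", "color", "rank", "fit", "report")
}

read_stage_csv <- function(path, date_cols = character()) {
  if (!file.exists(path)) {
    abort(sprintf("required input file is missing: %s (run the producing stage or supply it)",
                  path))
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  for (col in intersect(date_cols, names(df))) {
    df[[col]] <- as_date_strict(df[[col]], col)
  }
  df
}

#' Run the analysis pipeline
#'
#' Executes the selected stages in dependency order inside `outdir`:
#' `simulate` writes a synthetic study; `timeline` classifies reproductive
#' periods from the hormone CSV; `color` calibrates each photo session
#' against its chart and computes receptor-space color outcomes; `rank`
#' computes Normalized David's Scores; `fit` runs the collinearity screen,
#' hurdle models, Gaussian mixed models and likelihood-ratio tests; `report`
#' writes summary tables and figures. Stages not selected are skipped and
#' their outputs, if needed downstream, are read from `outdir` (a schema
#' error naming the file is raised when they are absent).
#'
#' @param config A [study_config()] or path to a YAML config file.
#' @param seed Integer seed governing all randomness (recorded in the
#'   manifest).
#' @param outdir Output directory (created if needed).
#' @param stages Character vector of stages, or `"all"`.
#' @param log_level `"info"` (log to console and file) or `"quiet"` (file
#'   only).
#' @return Invisibly, a list with the stage outputs that were computed and
#'   the manifest.
#' @export
run_pipeline <- function(config = study_config(), seed = 1L,
                         outdir = "pregsignal-run", stages = "all",
                         log_level = c("info", "quiet")) {
  log_level <- match.arg(log_level)
  if (is.character(config)) config <- read_study_config(config)
  validate_study_config(config)
  if (identical(stages, "all")) stages <- pipeline_stages()
  bad <- setdiff(stages, pipeline_stages())
  if (length(bad) > 0) {
    abort(paste("unknown stage(s):", paste(bad, collapse = ", ")))
  }
  stages <- pipeline_stages()[pipeline_stages() %in% stages]
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  log_lines <- character()
  log_event <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    if (log_level == "info") inform(line)
    invisible(NULL)
  }
  out_path <- function(f) file.path(outdir, f)
  outputs <- list()

  if ("simulate" %in% stages) {
    study <- simulate_study(config, seed = seed)
    readr::write_csv(study$roster, out_path("roster.csv"))
    readr::write_csv(study$hormones, out_path("hormones.csv"))
    readr::write_csv(study$focals, out_path("focals.csv"))
    readr::write_csv(study$photos, out_path("photos.csv"))
    readr::write_csv(study$charts, out_path("charts.csv"))
    readr::write_csv(study$interactions, out_path("interactions.csv"))
    readr::write_csv(study$truth$roster, out_path("truth_roster.csv"))
    readr::write_csv(study$truth$coefficients, out_path("truth_coefficients.csv"))
    log_event("simulate: %d focals, %d fecal samples, %d photos (seed %d)",
              nrow(study$focals), nrow(study$hormones), nrow(study$photos),
              seed)
    outputs$study <- study
  }

  if ("timeline" %in% stages) {
    hormones <- read_stage_csv(out_path("hormones.csv"), "date")
    assert_columns(hormones, c("female_id", "date", "pdg_ug_g", "e1c_ng_g"),
                   "hormones.csv")
    roster <- read_stage_csv(out_path("roster.csv"), "delivery_date")
    timeline <- reproductive_timeline(
      hormones, deliveries = roster,
      study_start = config$study_start, study_end = config$study_end)
    readr::write_csv(timeline$conceptions, out_path("conceptions.csv"))
    readr::write_csv(timeline$labels, out_path("timeline_labels.csv"))
    readr::write_csv(
      hormone_outcomes(hormones, timeline$labels),
      out_path("hormone_outcomes.csv"))
    log_event("timeline: conception dated for %d females (methods: %s)",
              nrow(timeline$conceptions),
              paste(unique(timeline$conceptions$method), collapse = ", "))
    outputs$timeline <- timeline
  }

  if ("color" %in% stages) {
    photos <- read_stage_csv(out_path("photos.csv"), "date")
    charts <- read_stage_csv(out_path("charts.csv"))
    labels <- read_stage_csv(out_path("timeline_labels.csv"), "date")
    model <- synthetic_receptor_model()
    capt <- expected_captures(synthetic_chart_reflectance(), model)
    measured <- photos |>
      dplyr::group_by(.data$session_id) |>
      dplyr::group_split() |>
      purrr::map(function(ph) {
        chart <- dplyr::filter(charts, .data$session_id == ph$session_id[1])
        cal <- fit_calibration(chart, capt)
        measure_face(ph, cal)
      }) |>
      dplyr::bind_rows()
    col_out <- color_outcomes(
      dplyr::select(measured, -dplyr::any_of("period")), labels)
    readr::write_csv(col_out, out_path("color_measurements.csv"))
    log_event("color: %d photos measured across %d sessions",
              nrow(col_out), length(unique(photos$session_id)))
    outputs$color <- col_out
  }

  if ("rank" %in% stages) {
    interactions <- read_stage_csv(out_path("interactions.csv"), "date")
    roster <- read_stage_csv(out_path("roster.csv"))
    ranks <- rank_females(interactions, roster)
    readr::write_csv(ranks, out_path("rank.csv"))
    rc <- attr(ranks, "rank_age_cor")
    log_event("rank: NDS computed for %d females; rank-age correlation %.2f%s",
              nrow(ranks), rc,
              if (abs(rc) > 0.95) " (collinear with age; rank not used as a model covariate)" else "")
    outputs$ranks <- ranks
  }

  if ("fit" %in% stages) {
    focals <- read_stage_csv(out_path("focals.csv"), "date")
    labels <- read_stage_csv(out_path("timeline_labels.csv"), "date")
    roster <- read_stage_csv(out_path("roster.csv"))
    fit_out <- fit_stage(focals, labels, roster,
                         hormone_out = read_stage_csv(
                           out_path("hormone_outcomes.csv"), "date"),
                         color_out = read_stage_csv(
                           out_path("color_measurements.csv"), "date"),
                         rates = config$rates, log_event = log_event)
    readr::write_csv(fit_out$lrt_table, out_path("lrt_table.csv"))
    readr::write_csv(fit_out$coef_table, out_path("coef_table.csv"))
    readr::write_csv(fit_out$screen$report, out_path("collinearity_screen.csv"))
    outputs$fits <- fit_out
  }

  if ("report" %in% stages) {
    fits <- outputs$fits
    if (is.null(fits)) {
      lrt_path <- out_path("lrt_table.csv")
      fits <- list(lrt_table = read_stage_csv(lrt_path),
                   coef_table = read_stage_csv(out_path("coef_table.csv")))
    }
    report <- render_report(fits,
                            focals = read_stage_csv(out_path("focals.csv"), "date"),
                            labels = read_stage_csv(out_path("timeline_labels.csv"), "date"),
                            color_out = read_stage_csv(out_path("color_measurements.csv"), "date"))
    fig_dir <- out_path("figures")
    dir.create(fig_dir, showWarnings = FALSE)
    for (nm in names(report$plots)) {
      ggplot2::ggsave(file.path(fig_dir, paste0(nm, ".pdf")),
                      report$plots[[nm]], width = 5, height = 4)
    }
    readr::write_csv(report$period_means, out_path("report_period_means.csv"))
    log_event("report: %d figures, %d LRT rows",
              length(report$plots), nrow(fits$lrt_table))
    outputs$report <- report
  }

  writeLines(log_lines, out_path("log.txt"))
  data_files <- list.files(outdir, pattern = "\\.csv$", full.names = TRUE)
  manifest <- list(
    seed = seed,
    stages = stages,
    package_version = as.character(utils::packageVersion("pregsignal")),
    config_snapshot = out_path("config.yaml"),
    file_digests = as.list(tools::md5sum(data_files)),
    created = "run manifest; rerun run_pipeline() with this seed and config to reproduce"
  )
  write_study_config(config, out_path("config.yaml"))
  jsonlite::write_json(manifest, out_path("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  outputs$manifest <- manifest
  invisible(outputs)
}

# the statistical stage on assembled data
fit_stage <- function(focals, labels, roster, hormone_out, color_out,
                      rates = behavior_rates(), log_event = inform) {
  ages <- dplyr::select(roster, "female_id", "age")
  labs <- dplyr::select(labels, "female_id", "date", "period")
  behaviors <- unique(rates$behavior[rates$modeled])

  fdat <- focals |>
    dplyr::select(-dplyr::any_of("period")) |>
    dplyr::left_join(labs, by = c("female_id", "date")) |>
    dplyr::left_join(ages, by = "female_id")
  n_other <- sum(!fdat$period %in% period_levels())
  if (n_other > 0) {
    log_event("fit: excluding %d focal(s) whose recovered label falls outside the three contrast periods",
              n_other)
    fdat <- dplyr::filter(fdat, .data$period %in% period_levels())
  }

  screen <- suppressMessages(
    screen_collinearity(fdat, c(behaviors, "contact")))
  if (length(screen$dropped) > 0) {
    log_event("fit: collinearity screen dropped %s",
              paste(screen$dropped, collapse = ", "))
  }
  behaviors <- intersect(behaviors, screen$retained)

  lrt_rows <- list()
  coef_rows <- list()

  for (b in behaviors) {
    occ_by_period <- tapply(fdat[[b]] > 0, fdat$period, sum)
    keep_periods <- names(occ_by_period)[!is.na(occ_by_period) & occ_by_period > 0]
    if (length(keep_periods) < 2) {
      log_event("fit: `%s` observed in <2 periods; too few occurrences for the statistical models to be run", b)
      next
    }
    if (length(keep_periods) < 3) {
      log_event("fit: `%s` has no occurrences in %s; contrasting %s only",
                b, paste(setdiff(period_levels(), keep_periods), collapse = ", "),
                paste(keep_periods, collapse = " vs "))
    }
    sub <- dplyr::filter(fdat, .data$period %in% keep_periods)
    base <- if ("PCP" %in% keep_periods) "PCP" else keep_periods[1]
    full <- suppressMessages(fit_hurdle(sub, b, baseline = base))
    null <- update_null(full)
    if (!full$converged) log_event("fit: `%s` hurdle fit reported non-convergence", b)
    count_ok <- !is.null(full$count) && !is.null(null$count) &&
      is.finite(as.numeric(logLik(full$count))) &&
      is.finite(as.numeric(logLik(null$count)))
    if (!is.null(full$count) && !count_ok) {
      log_event("fit: `%s` truncated count part failed to yield a finite likelihood; testing the binary part only", b)
    }
    part <- if (count_ok) "combined" else "binary"
    lrt_rows[[b]] <- lrt(full, null, part = part)
    tt <- tidy(full) |> dplyr::mutate(response = b, baseline = base)
    coef_rows[[b]] <- tt
    if (all(c("month1", "month2") %in% keep_periods)) {
      rl <- suppressMessages(relevel_contrasts(full, "month1"))
      coef_rows[[paste0(b, "_relevel")]] <- rl |>
        dplyr::mutate(response = b, baseline = "month1")
    }
  }

  gaussian_outcomes <- list(
    luminance = list(data = color_out, col = "log_luminance"),
    rg_ratio = list(data = color_out, col = "rg_ratio"),
    pdg = list(data = hormone_out, col = "log_pdg"),
    e1c = list(data = hormone_out, col = "log_e1c"),
    e1c_pdg_ratio = list(data = hormone_out, col = "log_ratio")
  )
  for (nm in names(gaussian_outcomes)) {
    g <- gaussian_outcomes[[nm]]
    gdat <- g$data |>
      dplyr::filter(.data$period %in% period_levels()) |>
      dplyr::left_join(ages, by = "female_id")
    full <- suppressMessages(fit_lme(gdat, g$col))
    null <- update_null(full)
    if (full$singular) log_event("fit: `%s` LME variance at boundary (singular fit reported)", nm)
    lr <- lrt(full, null)
    lr$response <- nm
    lrt_rows[[nm]] <- lr
    coef_rows[[nm]] <- tidy(full) |>
      dplyr::mutate(response = nm, baseline = "PCP", part = "gaussian")
    rl <- suppressMessages(relevel_contrasts(full, "month1"))
    coef_rows[[paste0(nm, "_relevel")]] <- rl |>
      dplyr::mutate(response = nm, baseline = "month1", part = "gaussian")
  }

  lrt_table <- dplyr::bind_rows(lrt_rows)
  coef_table <- dplyr::bind_rows(coef_rows) |>
    dplyr::select("response", "baseline", dplyr::any_of("part"), "term",
                  "estimate", "std.error", "statistic", "p.value")
  log_event("fit: %d LRT rows, %d coefficient rows (no multiple-testing correction applied)",
            nrow(lrt_table), nrow(coef_table))
  list(lrt_table = lrt_table, coef_table = coef_table, screen = screen)
}

#' Assemble report tables and figures
#'
#' Per-period mean (+/- SEM) summaries and plots of behavior occurrence
#' probabilities and color outcomes, alongside the LRT and coefficient
#' tables of the fit stage. An empty fit set yields an empty report with a
#' warning.
#'
#' @param fits Output of the fit stage (needs `lrt_table`, `coef_table`).
#' @param focals Wide focal tibble.
#' @param labels Timeline labels (`female_id`, `date`, `period`).
#' @param color_out Color outcome tibble.
#' @return A list: `lrt_table`, `coef_table`, `period_means` (long tibble of
#'   plotted means, equal to the figure values), `plots` (named ggplots).
#' @export
render_report <- function(fits, focals, labels, color_out) {
  if (is.null(fits$lrt_table) || nrow(fits$lrt_table) == 0) {
    warn("no fitted results; rendering an empty report")
    return(list(lrt_table = tibble::tibble(), coef_table = tibble::tibble(),
                period_means = tibble::tibble(), plots = list()))
  }
  fdat <- focals |>
    dplyr::select(-dplyr::any_of("period")) |>
    dplyr::left_join(dplyr::select(labels, "female_id", "date", "period"),
                     by = c("female_id", "date")) |>
    dplyr::filter(.data$period %in% period_levels())
  behavior_rows <- intersect(unique(fits$lrt_table$response), names(fdat))
  plots <- list()
  means <- list()
  for (b in behavior_rows) {
    plots[[paste0("occurrence_", b)]] <- plot_occurrence_probability(fdat, b)
    means[[b]] <- fdat |>
      dplyr::mutate(.occ = as.numeric(.data[[b]] > 0)) |>
      period_summary(".occ") |>
      dplyr::mutate(outcome = paste0("P(", b, ")"))
  }
  for (cc in c("luminance", "rg_ratio")) {
    if (cc %in% names(color_out)) {
      plots[[cc]] <- plot_outcome_means(color_out, cc)
      means[[cc]] <- period_summary(color_out, cc) |>
        dplyr::mutate(outcome = cc)
    }
  }
  list(lrt_table = fits$lrt_table, coef_table = fits$coef_table,
       period_means = dplyr::bind_rows(means) |>
         dplyr::select("outcome", "period", "mean", "sem"),
       plots = plots)
}
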