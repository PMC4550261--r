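# Statistical stage: collinearity screening, two-part (hurdle) mixed models
# for behavior counts, Gaussian mixed models for log color/hormone outcomes,
# and full-vs-null likelihood-ratio tests.
#
# Every model has reproductive status (3 levels, pre-conceptive baseline) as
# the predictor of interest, age as a confounding covariate, and crossed
# random intercepts for female identity and observation date. Null models
# drop status but always retain age. All fits are by maximum likelihood so
# likelihood-ratio comparisons are valid.

# internal: standardized modeling frame
model_frame <- function(data, response, baseline = "PCP") {
  assert_columns(data, c(response, "period", "age", "female_id", "date"), "data")
  levels_present <- intersect(c(period_levels(), "other"),
                              unique(as.character(data$period)))
  df <- tibble::tibble(
    .y = data[[response]],
    period = stats::relevel(factor(as.character(data$period),
                                   levels = levels_present),
                            ref = baseline),
    age = data$age,
    female_id = factor(data$female_id),
    date_f = factor(as.character(data$date))
  )
  if (anyNA(df$.y)) abort(sprintf("response `%s` contains NA", response))
  df
}

fixed_rhs <- function(include_status, include_age) {
  terms <- c(if (include_status) "period", if (include_age) "age")
  if (length(terms) == 0) "1" else paste(terms, collapse = " + ")
}

glmm_converged <- function(fit) {
  isTRUE(fit$fit$convergence == 0) && isTRUE(fit$sdr$pdHess)
}

# fit the zero-truncated NB part, falling back through optimizer settings:
# the truncated likelihood occasionally defeats the default nlminb path on
# small positive-count sets, so retry from the package default and then with
# BFGS before accepting a failed fit
fit_truncated_count <- function(f_cnt, dfp, control) {
  attempts <- list(
    function() glmmTMB::glmmTMB(f_cnt, data = dfp,
                                family = glmmTMB::truncated_nbinom2(),
                                control = control),
    function() glmmTMB::glmmTMB(f_cnt, data = dfp,
                                family = glmmTMB::truncated_nbinom2()),
    function() glmmTMB::glmmTMB(f_cnt, data = dfp,
                                family = glmmTMB::truncated_nbinom2(),
                                control = glmmTMB::glmmTMBControl(
                                  optimizer = stats::optim,
                                  optArgs = list(method = "BFGS")))
  )
  best <- NULL
  for (att in attempts) {
    fit <- tryCatch(suppressWarnings(att()), error = function(e) NULL)
    if (is.null(fit)) next
    ll <- as.numeric(logLik(fit))
    if (is.finite(ll) && glmm_converged(fit)) return(fit)
    if (is.finite(ll) &&
        (is.null(best) || ll > as.numeric(logLik(best)))) best <- fit
  }
  best %||% attempts[[1]]()
}

#' Fit a two-part (hurdle) mixed model to a behavior
#'
#' Part one models presence/absence per focal with a binomial GLMM; part two
#' models the positive counts with a zero-truncated negative binomial GLMM.
#' Both parts have reproductive status plus age as fixed effects and crossed
#' random intercepts for female identity and date. The total log-likelihood
#' decomposes exactly as binary part plus truncated count part. The count
#' part is refused (with a message, mirroring field practice for rare
#' behaviors) when fewer than `min_positive` focals are positive; a response
#' with no variation makes the binary part degenerate and it is flagged
#' rather than fit. Non-convergence is reported via a warning and recorded,
#' never silently accepted.
#'
#' @param data Tibble with the response column plus `period`, `age`,
#'   `female_id`, `date`.
#' @param response Name of the count column to model.
#' @param baseline Reference status level (default `"PCP"`).
#' @param include_status Set `FALSE` to fit the null model (age retained).
#' @param min_positive Minimum positive focals for the count part (default 5).
#' @param random_effects Include the crossed female/date random intercepts
#'   (default `TRUE`; `FALSE` gives plain fixed-effect fits, useful for
#'   structural checks on data without grouping).
#' @param control Optimizer control, see [glmmTMB::glmmTMBControl()];
#'   defaults to relative tolerance 1e-8 and 500 iterations.
#' @return A `hurdle_fit` object with elements `binary`, `count` (glmmTMB
#'   fits or `NULL`), `binary_degenerate`, `count_refusal`, `converged`,
#'   `n`, `n_positive`, `response`, `baseline`, `include_status`, `data`.
#' @export
fit_hurdle <- function(data, response, baseline = "PCP",
                       include_status = TRUE, min_positive = 5,
                       random_effects = TRUE, control = NULL) {
  df <- model_frame(data, response, baseline)
  df$.occ <- as.integer(df$.y > 0)
  n_pos <- sum(df$.occ)
  include_age <- stats::var(df$age) > 0
  if (!include_age) inform("`age` has no variation and was dropped")
  control <- control %||% glmmTMB::glmmTMBControl(
    optCtrl = list(iter.max = 500, eval.max = 500, rel.tol = 1e-8))
  re_part <- if (random_effects) "+ (1 | female_id) + (1 | date_f)" else ""

  binary <- NULL
  binary_degenerate <- FALSE
  if (n_pos == 0 || n_pos == nrow(df)) {
    binary_degenerate <- TRUE
    inform(sprintf("`%s`: occurrence has no variation; binary part is degenerate and was not fit",
                   response))
  } else {
    f_bin <- as.formula(paste(".occ ~", fixed_rhs(include_status, include_age),
                              re_part))
    binary <- glmmTMB::glmmTMB(f_bin, data = df, family = stats::binomial(),
                               control = control)
  }

  count <- NULL
  count_refusal <- NULL
  if (n_pos < min_positive) {
    count_refusal <- sprintf(
      "too few occurrences (%s < %s) for the truncated count model to be run",
      n_pos, format(min_positive))
    inform(paste0("`", response, "`: ", count_refusal))
  } else {
    dfp <- df[df$.occ == 1, ]
    f_cnt <- as.formula(paste(".y ~", fixed_rhs(include_status, include_age),
                              re_part))
    count <- fit_truncated_count(f_cnt, dfp, control)
  }

  converged <- all(vapply(Filter(Negate(is.null), list(binary, count)),
                          function(f) glmm_converged(f) &&
                            is.finite(as.numeric(logLik(f))), logical(1)))
  if (!converged) {
    warn(sprintf("hurdle fit for `%s` did not fully converge; inspect before use",
                 response))
  }
  structure(list(
    binary = binary, count = count,
    binary_degenerate = binary_degenerate, count_refusal = count_refusal,
    converged = converged, n = nrow(df), n_positive = n_pos,
    response = response, baseline = baseline,
    include_status = include_status, min_positive = min_positive,
    random_effects = random_effects, data = data
  ), class = "hurdle_fit")
}

#' @export
print.hurdle_fit <- function(x, ...) {
  cat("<hurdle_fit>", x$response, "|", x$n, "focals,", x$n_positive,
      "positive\n")
  if (x$binary_degenerate) cat("  binary part: degenerate (no variation)\n")
  if (!is.null(x$count_refusal)) cat("  count part:", x$count_refusal, "\n")
  ll <- hurdle_loglik(x)
  cat(sprintf("  logLik: binary %.3f + count %.3f = %.3f (df %d)\n",
              ll$binary, ll$count, ll$total, ll$df))
  invisible(x)
}

# log-likelihood decomposition of a hurdle fit; a fitted part with a
# non-finite likelihood poisons the total (never silently dropped)
hurdle_loglik <- function(fit) {
  lb <- if (!is.null(fit$binary)) logLik(fit$binary) else NULL
  lc <- if (!is.null(fit$count)) logLik(fit$count) else NULL
  parts <- c(if (!is.null(lb)) as.numeric(lb), if (!is.null(lc)) as.numeric(lc))
  total <- if (length(parts) == 0) NA_real_ else sum(parts)
  df <- sum(c(if (!is.null(lb)) attr(lb, "df"), if (!is.null(lc)) attr(lc, "df")))
  list(binary = if (is.null(lb)) NA_real_ else as.numeric(lb),
       count = if (is.null(lc)) NA_real_ else as.numeric(lc),
       total = total, df = df)
}

#' Fit a Gaussian mixed model to a (log-transformed) continuous outcome
#'
#' Linear mixed-effects model by maximum likelihood with reproductive status
#' and age as fixed effects and crossed random intercepts for female and
#' date. Singular (boundary) random-effect fits are reported via a message
#' and recorded, not errored: with few females, variance estimates at zero
#' are expected.
#'
#' @param data Tibble with the response plus `period`, `age`, `female_id`,
#'   `date`.
#' @param response Name of the continuous outcome column (already on the
#'   modeling scale, e.g. `log_luminance`).
#' @inheritParams fit_hurdle
#' @return An `lme_fit` object: `fit` (lmerMod), `singular`, `response`,
#'   `baseline`, `include_status`, `data`.
#' @export
fit_lme <- function(data, response, baseline = "PCP", include_status = TRUE,
                    random_effects = TRUE) {
  df <- model_frame(data, response, baseline)
  include_age <- stats::var(df$age) > 0
  if (!include_age) inform("`age` has no variation and was dropped")
  if (random_effects) {
    f <- as.formula(paste(".y ~", fixed_rhs(include_status, include_age),
                          "+ (1 | female_id) + (1 | date_f)"))
    fit <- lme4::lmer(f, data = df, REML = FALSE,
                      control = lme4::lmerControl(check.conv.singular = "ignore"))
    singular <- lme4::isSingular(fit)
  } else {
    f <- as.formula(paste(".y ~", fixed_rhs(include_status, include_age)))
    fit <- stats::glm(f, data = df, family = stats::gaussian())
    singular <- FALSE
  }
  if (singular) {
    inform(sprintf("`%s`: random-effect variance estimated at the boundary (singular fit)",
                   response))
  }
  structure(list(fit = fit, singular = singular, response = response,
                 baseline = baseline, include_status = include_status,
                 random_effects = random_effects, data = data),
            class = "lme_fit")
}

#' @export
print.lme_fit <- function(x, ...) {
  cat("<lme_fit>", x$response, if (x$singular) "(singular RE fit)", "\n")
  print(summary(x$fit)$coefficients)
  invisible(x)
}

#' Refit a model without reproductive status (the null model)
#'
#' Drops the status term while retaining age and the random-effect
#' structure, on the same data rows, so the result is nested in the full
#' fit and suitable for [lrt()].
#'
#' @param fit A [fit_hurdle()] or [fit_lme()] object.
#' @return A fit of the same class with `include_status = FALSE`.
#' @export
update_null <- function(fit) {
  if (inherits(fit, "hurdle_fit")) {
    suppressMessages(fit_hurdle(fit$data, fit$response, baseline = fit$baseline,
                                include_status = FALSE,
                                min_positive = fit$min_positive,
                                random_effects = fit$random_effects))
  } else if (inherits(fit, "lme_fit")) {
    suppressMessages(fit_lme(fit$data, fit$response, baseline = fit$baseline,
                             include_status = FALSE,
                             random_effects = fit$random_effects))
  } else {
    abort("update_null() expects a hurdle_fit or lme_fit")
  }
}

#' Likelihood-ratio test of a full against a null model
#'
#' `X^2 = 2 (logLik_full - logLik_null)` clipped at zero, with the
#' parameter-count difference as degrees of freedom and an upper-tail
#' chi-square p-value. For hurdle fits, `part = "combined"` (default) sums
#' the binary and truncated-count log-likelihoods of each model before
#' comparing, so a 3-level status factor contributes 4 degrees of freedom
#' (2 per part); `"binary"` and `"count"` test each part alone (2 df).
#' Models must be fitted to the same rows and the null must be nested in
#' the full.
#'
#' @param full,null Fits of the same class ([fit_hurdle()], [fit_lme()]).
#' @param part For hurdle fits: `"combined"`, `"binary"` or `"count"`.
#' @return A one-row tibble: `response`, `part`, `statistic`, `df`,
#'   `p_value`, `loglik_full`, `loglik_null`.
#' @export
lrt <- function(full, null, part = c("combined", "binary", "count")) {
  part <- match.arg(part)
  if (!identical(class(full), class(null))) {
    abort("full and null fits must be of the same class")
  }
  if (inherits(full, "hurdle_fit")) {
    if (full$n != null$n) abort("full and null models use differing row counts")
    if (!full$include_status && null$include_status) {
      abort("null model is not nested in the full model (non-nested specs)")
    }
    pick <- function(fit) {
      lab <- switch(part,
                    combined = hurdle_loglik(fit)[c("total", "df")],
                    binary = {
                      if (is.null(fit$binary)) abort("binary part unavailable")
                      ll <- logLik(fit$binary)
                      list(total = as.numeric(ll), df = attr(ll, "df"))
                    },
                    count = {
                      if (is.null(fit$count)) {
                        abort(paste("count part unavailable:",
                                    fit$count_refusal %||% "not fit"))
                      }
                      ll <- logLik(fit$count)
                      list(total = as.numeric(ll), df = attr(ll, "df"))
                    })
      lab
    }
    lf <- pick(full)
    ln <- pick(null)
    if (!is.finite(lf$total) || !is.finite(ln$total)) {
      abort("non-finite log-likelihood in a hurdle part; refit before testing")
    }
    response <- full$response
  } else if (inherits(full, "lme_fit")) {
    if (stats::nobs(full$fit) != stats::nobs(null$fit)) {
      abort("full and null models use differing row counts")
    }
    if (!full$include_status && null$include_status) {
      abort("null model is not nested in the full model (non-nested specs)")
    }
    llf <- logLik(full$fit)
    lln <- logLik(null$fit)
    lf <- list(total = as.numeric(llf), df = attr(llf, "df"))
    ln <- list(total = as.numeric(lln), df = attr(lln, "df"))
    part <- "gaussian"
    response <- full$response
  } else {
    abort("lrt() expects hurdle_fit or lme_fit objects")
  }
  ddf <- lf$df - ln$df
  x2 <- max(0, 2 * (lf$total - ln$total))
  if (ddf < 1) {
    # two fits of equal dimension are comparable only if they are the same
    # model; then the test is vacuous (X^2 = 0, p = 1)
    if (abs(lf$total - ln$total) > 1e-8) {
      abort("null model is not nested in the full model (no df difference)")
    }
    return(tibble::tibble(response = response, part = part, statistic = 0,
                          df = 0L, p_value = 1,
                          loglik_full = lf$total, loglik_null = ln$total))
  }
  tibble::tibble(
    response = response, part = part, statistic = x2, df = ddf,
    p_value = stats::pchisq(x2, df = ddf, lower.tail = FALSE),
    loglik_full = lf$total, loglik_null = ln$total
  )
}

#' Re-level the status baseline and extract pregnancy-month contrasts
#'
#' Refits the model with a new reference level (typically `month1`, so the
#' month2-vs-month1 contrast appears directly) and verifies that the
#' log-likelihood is unchanged — re-leveling is a reparameterization and
#' must not move the fit.
#'
#' @param fit A [fit_hurdle()] or [fit_lme()] object.
#' @param baseline New reference level (must be an observed status level).
#' @param tol Tolerance for the log-likelihood invariance check.
#' @return The [tidy()] coefficient table of the releveled fit, with
#'   attributes `fit` (the releveled fit) and `loglik_diff`.
#' @export
relevel_contrasts <- function(fit, baseline = "month1", tol = 1e-4) {
  levels_present <- unique(as.character(fit$data$period))
  if (!baseline %in% levels_present) {
    abort(sprintf("unknown status level `%s`", baseline))
  }
  refit <- if (inherits(fit, "hurdle_fit")) {
    suppressMessages(fit_hurdle(fit$data, fit$response, baseline = baseline,
                                include_status = fit$include_status,
                                min_positive = fit$min_positive,
                                random_effects = fit$random_effects))
  } else if (inherits(fit, "lme_fit")) {
    suppressMessages(fit_lme(fit$data, fit$response, baseline = baseline,
                             include_status = fit$include_status,
                             random_effects = fit$random_effects))
  } else {
    abort("relevel_contrasts() expects a hurdle_fit or lme_fit")
  }
  ll_old <- if (inherits(fit, "hurdle_fit")) hurdle_loglik(fit)$total
            else as.numeric(logLik(fit$fit))
  ll_new <- if (inherits(refit, "hurdle_fit")) hurdle_loglik(refit)$total
            else as.numeric(logLik(refit$fit))
  diff <- abs(ll_new - ll_old)
  if (diff > tol) {
    warn(sprintf("log-likelihood moved by %.2g on re-leveling (optimizer noise above tol)",
                 diff))
  }
  out <- tidy(refit)
  attr(out, "fit") <- refit
  attr(out, "loglik_diff") <- diff
  out
}

#' Check whether the binary part needs a zero-inflation component
#'
#' Fits the occurrence model as a plain binomial GLMM and as a zero-inflated
#' binomial GLMM (constant structural-zero probability) and compares them by
#' an information criterion, BIC by default: the inflation probability sits
#' on the boundary of its parameter space under the simpler model, where
#' AIC's fixed 2-unit penalty is known to over-select the richer structure.
#' With hurdle-structured data the plain binomial should prevail; a genuine
#' excess of structural zeros favors the inflated variant.
#'
#' @param data Tibble with the response plus `period`, `age`, `female_id`,
#'   `date`.
#' @param response Count or 0/1 occurrence column.
#' @param baseline Reference status level.
#' @param random_effects Include the crossed random intercepts (default
#'   `TRUE`; turn off for quick structural checks).
#' @param ic Information criterion used for the choice: `"BIC"` (default)
#'   or `"AIC"`. Both are reported.
#' @return A two-row tibble (`model`, `df`, `logLik`, `AIC`, `BIC`,
#'   `chosen`), the chosen row flagged; attribute `chosen` gives the model
#'   name.
#' @export
zero_inflation_check <- function(data, response, baseline = "PCP",
                                 random_effects = TRUE,
                                 ic = c("BIC", "AIC")) {
  ic <- match.arg(ic)
  df <- model_frame(data, response, baseline)
  df$.occ <- as.integer(df$.y > 0)
  include_age <- stats::var(df$age) > 0
  re_part <- if (random_effects) "+ (1 | female_id) + (1 | date_f)" else ""
  f <- as.formula(paste(".occ ~", fixed_rhs(TRUE, include_age), re_part))
  plain <- glmmTMB::glmmTMB(f, data = df, family = stats::binomial())
  zi <- glmmTMB::glmmTMB(f, data = df, family = stats::binomial(),
                         ziformula = ~1)
  out <- tibble::tibble(
    model = c("binomial", "zero-inflated binomial"),
    df = c(attr(logLik(plain), "df"), attr(logLik(zi), "df")),
    logLik = c(as.numeric(logLik(plain)), as.numeric(logLik(zi))),
    AIC = c(AIC(plain), AIC(zi)),
    BIC = c(stats::BIC(plain), stats::BIC(zi))
  )
  crit <- out[[ic]]
  out$chosen <- crit == min(crit)
  attr(out, "chosen") <- out$model[which.min(crit)]
  out
}

#' Screen behaviors for collinearity
#'
#' Computes all pairwise phi coefficients on occurrence flags (a phi
#' coefficient is the Pearson correlation of two binary variables) and
#' Pearson correlations on counts. Pairs exceeding the threshold in absolute
#' value on either scale are collapsed to one representative: the member
#' with the *larger* total occurrence count is dropped, on the reasoning
#' that the more inclusive composite behavior (e.g. body contact, which
#' subsumes grooming) duplicates its sparser component. Behaviors with zero
#' variance are reported and excluded from the screen.
#'
#' @param focals Wide focal tibble with one count column per behavior.
#' @param behaviors Character vector of behavior columns to screen.
#' @param threshold Absolute correlation above which a pair collapses
#'   (default 0.7).
#' @return A `collinearity_screen` list: `report` (pairwise tibble with
#'   `phi`, `pearson`, `flagged`), `retained`, `dropped`, `zero_variance`.
#' @export
screen_collinearity <- function(focals, behaviors, threshold = 0.7) {
  assert_columns(focals, behaviors, "focals")
  if (length(behaviors) < 2) abort("need at least 2 behaviors to screen")
  if (nrow(focals) < 10) abort("need at least 10 focals to screen")
  counts <- as.matrix(focals[, behaviors])
  flags <- (counts > 0) * 1L
  zero_var <- behaviors[apply(counts, 2, stats::var) == 0]
  if (length(zero_var) > 0) {
    inform(paste("excluded from screen (no variation):",
                 paste(zero_var, collapse = ", ")))
  }
  keep <- setdiff(behaviors, zero_var)
  pairs <- utils::combn(keep, 2)
  report <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    tibble::tibble(
      behavior_a = a, behavior_b = b,
      phi = suppressWarnings(cor(flags[, a], flags[, b])),
      pearson = suppressWarnings(cor(counts[, a], counts[, b]))
    )
  }) |>
    dplyr::mutate(flagged = pmax(abs(.data$phi), abs(.data$pearson),
                                 na.rm = TRUE) > threshold)
  retained <- keep
  dropped <- character()
  flagged <- report |> dplyr::filter(.data$flagged) |>
    dplyr::arrange(-pmax(abs(.data$phi), abs(.data$pearson), na.rm = TRUE))
  occ_totals <- colSums(flags)
  for (i in seq_len(nrow(flagged))) {
    a <- flagged$behavior_a[i]; b <- flagged$behavior_b[i]
    if (a %in% retained && b %in% retained) {
      drop <- if (occ_totals[a] >= occ_totals[b]) a else b
      retained <- setdiff(retained, drop)
      dropped <- c(dropped, drop)
    }
  }
  structure(list(report = report, retained = retained, dropped = dropped,
                 zero_variance = zero_var, threshold = threshold),
            class = "collinearity_screen")
}

#' @export
print.collinearity_screen <- function(x, ...) {
  cat("<collinearity_screen> threshold", x$threshold, "\n")
  cat("  retained:", paste(x$retained, collapse = ", "), "\n")
  if (length(x$dropped) > 0) {
    cat("  dropped: ", paste(x$dropped, collapse = ", "), "\n")
  }
  if (length(x$zero_variance) > 0) {
    cat("  no variation:", paste(x$zero_variance, collapse = ", "), "\n")
  }
  print(dplyr::filter(x$report, .data$flagged))
  invisible(x)
}
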