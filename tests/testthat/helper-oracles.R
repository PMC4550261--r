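# Independent oracles and small data builders shared across tests.
# Each oracle is a deliberately naive re-implementation, kept separate from
# the package's code paths.

# exhaustive-scan oracle for the PdG rise rule: for every sample with enough
# preceding baseline values, recompute mean/SD by hand and return the date of
# the first sample of the first qualifying run
oracle_rise_scan <- function(dates, pdg, baseline_n = "auto", k = 2) {
  n <- length(pdg)
  min_b <- if (identical(baseline_n, "auto")) 3 else baseline_n
  qual <- rep(FALSE, n)
  for (i in seq_len(n)) {
    b <- if (identical(baseline_n, "auto")) min(4, i - 1) else baseline_n
    if (i <= min_b || i - 1 < b) next
    base <- pdg[(i - b):(i - 1)]
    m <- sum(base) / b
    s <- sqrt(sum((base - m)^2) / (b - 1))
    qual[i] <- (pdg[i] - m >= k * s) && (pdg[i] > m)
  }
  for (i in seq_len(n)) {
    if (qual[i] && (i == 1 || !qual[i - 1])) return(dates[i])
  }
  as.Date(NA)
}

# four-loop David's Score oracle
oracle_davids <- function(mat, corrected = TRUE) {
  n <- nrow(mat)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    nij <- mat[i, j] + mat[j, i]
    if (nij == 0) {
      d[i, j] <- 0.5
    } else {
      p <- mat[i, j] / nij
      d[i, j] <- if (corrected) p - (p - 0.5) / (nij + 1) else p
    }
  }
  ds <- numeric(n)
  w <- numeric(n); l <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      w[i] <- w[i] + d[i, j]
      l[i] <- l[i] + d[j, i]
    }
  }
  for (i in seq_len(n)) {
    w2 <- 0; l2 <- 0
    for (j in seq_len(n)) {
      w2 <- w2 + w[j] * d[i, j]
      l2 <- l2 + l[j] * d[j, i]
    }
    ds[i] <- w[i] + w2 - l[i] - l2
  }
  list(DS = ds, NDS = (ds + n * (n - 1) / 2) / n)
}

# direct zero-truncated negative binomial log-likelihood: sum of
# log( pmf(y) / (1 - pmf(0)) ) with the untruncated NB pmf
oracle_ztnb_loglik <- function(y, mu, size) {
  sum(log(dnbinom(y, mu = mu, size = size) /
            (1 - dnbinom(0, mu = mu, size = size))))
}

# pixel-by-pixel accumulation oracle for region means
oracle_region_mean <- function(image, mask) {
  acc <- c(0, 0, 0); n <- 0
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    if (mask[i, j]) {
      acc <- acc + image[i, j, ]
      n <- n + 1
    }
  }
  acc / n
}

# direct interval-membership oracle for period labels
oracle_period_label <- function(date, conception) {
  off <- as.numeric(date - conception)
  if (off >= -30 && off <= -1) "PCP"
  else if (off >= 0 && off <= 29) "month1"
  else if (off >= 30 && off <= 59) "month2"
  else "other"
}

# random hormone-like series for oracle-equivalence sweeps
random_pdg_series <- function(n = 12) {
  base <- runif(1, 0.5, 2)
  pdg <- abs(rnorm(n, base, base * runif(1, 0.05, 0.4)))
  if (runif(1) < 0.7) {
    at <- sample(5:n, 1)
    pdg[at:n] <- pdg[at:n] + base * runif(1, 0, 3)
  }
  tibble::tibble(
    female_id = "F01",
    date = as.Date("2014-01-01") + sort(sample(0:(3 * n), n)),
    pdg_ug_g = pdg, e1c_ng_g = abs(rnorm(n, 30, 5))
  )
}

# occurrence-only dataset from a known logistic model with crossed effects
sim_binary_study <- function(n_females = 5, focals_per_female = 150,
                             beta_month1 = -1.5, beta_month2 = -0.75,
                             b0 = -0.6, sd_female = 0.5, sd_date = 0.3,
                             n_dates = 75) {
  ids <- sprintf("F%02d", seq_len(n_females))
  ages <- runif(n_females, 8, 17)
  dates <- seq(as.Date("2014-01-01"), by = "day", length.out = n_dates)
  d <- tidyr::crossing(female_id = ids, idx = seq_len(focals_per_female))
  d$period <- rep_len(c("PCP", "month1", "month2"), nrow(d))
  d$date <- sample(dates, nrow(d), replace = TRUE)
  d$age <- ages[match(d$female_id, ids)]
  u <- stats::setNames(rnorm(n_females, 0, sd_female), ids)
  v <- stats::setNames(rnorm(n_dates, 0, sd_date), as.character(dates))
  eta <- b0 + ifelse(d$period == "month1", beta_month1,
                     ifelse(d$period == "month2", beta_month2, 0)) +
    u[d$female_id] + v[as.character(d$date)]
  d$y <- rbinom(nrow(d), 1, plogis(eta))
  d[, c("female_id", "date", "period", "age", "y")]
}

# Gaussian outcome with no status effect (for type-I error checks)
sim_null_gaussian <- function(n_per_female = 50, n_females = 5, n_dates = 30) {
  ids <- sprintf("F%02d", seq_len(n_females))
  ages <- runif(n_females, 8, 17)
  dates <- seq(as.Date("2014-01-01"), by = "day", length.out = n_dates)
  d <- tidyr::crossing(female_id = ids, idx = seq_len(n_per_female))
  d$period <- sample(c("PCP", "month1", "month2"), nrow(d), replace = TRUE)
  d$date <- sample(dates, nrow(d), replace = TRUE)
  d$age <- ages[match(d$female_id, ids)]
  u <- stats::setNames(rnorm(n_females, 0, 0.3), ids)
  v <- stats::setNames(rnorm(n_dates, 0, 0.2), as.character(dates))
  d$y <- 0.05 * d$age + u[d$female_id] + v[as.character(d$date)] +
    rnorm(nrow(d), 0, 0.5)
  d[, c("female_id", "date", "period", "age", "y")]
}

# compact default-config study cached per test file run
default_study <- local({
  cache <- NULL
  function(seed = 421) {
    if (is.null(cache)) cache <<- simulate_study(study_config(), seed = seed)
    cache
  }
})
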