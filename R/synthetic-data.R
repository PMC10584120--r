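#' Design of a crossed starvation-survival experiment
#'
#' Three embryo pH levels fully crossed with three larval pH levels, with
#' replicate inserts (mesh-bottomed chambers) per cell each holding a fixed
#' number of larvae, observed daily until a censoring horizon. The defaults
#' are the design scale of the study this package emulates: 5 inserts of 20
#' larvae per cell and a 49-day (7-week) horizon, i.e. 45 inserts and 900
#' larvae per experiment.
#'
#' @param embryo_levels,larval_levels Ordered treatment labels (3 each).
#' @param inserts_per_cell Replicate inserts per design cell (>= 1).
#' @param larvae_per_insert Larvae counted into each insert (>= 1).
#' @param max_day Censoring horizon in days (>= 1).
#' @param seed Integer seed driving all randomness of the generated dataset.
#' @return List of class \code{"oa_design"}.
#' @export
design_spec <- function(embryo_levels = treatment_levels(),
                        larval_levels = treatment_levels(),
                        inserts_per_cell = 5, larvae_per_insert = 20,
                        max_day = 49, seed = 1) {
  if (anyDuplicated(embryo_levels) || anyDuplicated(larval_levels)) {
    stop("treatment levels must be distinct", call. = FALSE)
  }
  if (inserts_per_cell < 1 || larvae_per_insert < 1 || max_day < 1) {
    stop("inserts_per_cell, larvae_per_insert and max_day must all be >= 1",
         call. = FALSE)
  }
  structure(list(embryo_levels = embryo_levels, larval_levels = larval_levels,
                 inserts_per_cell = as.integer(inserts_per_cell),
                 larvae_per_insert = as.integer(larvae_per_insert),
                 max_day = as.integer(max_day), seed = seed),
            class = "oa_design")
}

#' Simulate death days from the power-logistic survival curve
#'
#' Continuous death times are drawn from the log-logistic distribution with
#' CDF \eqn{F(t) = 1/(1+(t/t_{50})^s)} by inverse-CDF sampling and recorded as
#' the integer day interval \code{(d-1, d]} in which they fall, matching daily
#' monitoring. Times beyond \code{max_day} are censored alive.
#'
#' @param t50 Time to 50% mortality in days (> 0).
#' @param s Slope (< 0; a non-negative slope would give a non-increasing
#'   mortality curve and is rejected).
#' @param n Number of larvae (>= 0).
#' @param max_day Censoring horizon in days.
#' @param seed Integer seed.
#' @return Integer vector of length \code{n}: death day in
#'   \code{1..max_day}, or \code{NA} for larvae censored alive.
#' @export
gen_death_days <- function(t50, s, n, max_day = 49, seed = 1) {
  if (!is.finite(t50) || t50 <= 0) stop("'t50' must be > 0", call. = FALSE)
  if (!is.finite(s) || s >= 0) {
    stop("'s' must be negative (increasing mortality)", call. = FALSE)
  }
  if (n < 0) stop("'n' must be >= 0", call. = FALSE)
  if (n == 0) return(integer(0))
  with_seed(seed, {
    u <- stats::runif(n)
    t <- mortality_quantile(u, t50, s)
    day <- as.integer(ceiling(t))
    day[day < 1L] <- 1L
    day[t > max_day] <- NA_integer_
    day
  })
}

#' Simulate a full crossed starvation-survival experiment
#'
#' One record stream per insert: a row for every day from 1 to the horizon
#' with the count of new deaths that day. Per insert, daily deaths plus final
#' survivors always sum to \code{larvae_per_insert}.
#'
#' @param design A [design_spec()].
#' @param params Per-cell curve parameters: data frame with columns
#'   \code{embryo}, \code{larval}, \code{t50}, \code{s} covering every design
#'   cell (e.g. [survival_curve_params()]).
#' @param year Year label attached to every record.
#' @param insert_sd Optional SD of a log-normal insert-level random effect on
#'   \code{t50} (0 = larvae i.i.d. within cell, the default: the design's
#'   observation model has no stated inter-insert overdispersion).
#' @return A [mortality_data()] object.
#' @examples
#' dat <- gen_survival_experiment(design_spec(seed = 7), survival_curve_params(1))
#' length(unique(dat$insert_id))  # 45 inserts
#' @export
gen_survival_experiment <- function(design, params, year = 1, insert_sd = 0) {
  stopifnot(inherits(design, "oa_design"))
  key <- cell_key(params$embryo, params$larval)
  rows <- list()
  insert_no <- 0L
  with_seed(design$seed, {
    for (e in design$embryo_levels) {
      for (l in design$larval_levels) {
        i <- match(cell_key(e, l), key)
        if (is.na(i)) {
          stop(sprintf("missing parameters for cell %s", cell_key(e, l)),
               call. = FALSE)
        }
        for (r in seq_len(design$inserts_per_cell)) {
          insert_no <- insert_no + 1L
          t50_i <- params$t50[i] *
            if (insert_sd > 0) exp(stats::rnorm(1, 0, insert_sd)) else 1
          u <- stats::runif(design$larvae_per_insert)
          t <- mortality_quantile(u, t50_i, params$s[i])
          day <- pmax(as.integer(ceiling(t)), 1L)
          day[t > design$max_day] <- NA_integer_
          deaths <- tabulate(day, nbins = design$max_day)
          rows[[insert_no]] <- data.frame(
            insert_id = sprintf("I%03d", insert_no),
            year = year,
            embryo_ph = e, larval_ph = l,
            day = seq_len(design$max_day),
            new_deaths = deaths,
            initial_n = design$larvae_per_insert
          )
        }
      }
    }
  })
  mortality_data(do.call(rbind, rows), max_day = design$max_day)
}

#' Simulate a multivariate-normal morphometric table
#'
#' Group means with a shared covariance; draws with any negative measurement
#' are redrawn (truncation at zero by resampling keeps the means unbiased at
#' realistic noise levels, where truncation is rare).
#'
#' @param group_means Named list (or matrix with one row per group) of mean
#'   vectors, one value per measurement; names become group labels and, where
#'   available, measurement names.
#' @param covariance Symmetric positive semi-definite covariance matrix.
#' @param n_per_group Samples per group.
#' @param seed Integer seed.
#' @return Data frame: column \code{group} plus one numeric column per
#'   measurement.
#' @export
gen_morphometrics <- function(group_means, covariance, n_per_group = 15,
                              seed = 1) {
  if (is.matrix(group_means)) {
    group_means <- stats::setNames(
      lapply(seq_len(nrow(group_means)), function(i) group_means[i, ]),
      rownames(group_means))
  }
  p <- length(group_means[[1]])
  covariance <- as.matrix(covariance)
  if (!isTRUE(all.equal(covariance, t(covariance))) ||
      min(eigen(covariance, symmetric = TRUE, only.values = TRUE)$values) <
        -1e-8 * max(1, max(abs(covariance)))) {
    stop("'covariance' must be symmetric positive semi-definite", call. = FALSE)
  }
  vars <- names(group_means[[1]])
  if (is.null(vars)) vars <- paste0("V", seq_len(p))
  with_seed(seed, {
    out <- lapply(seq_along(group_means), function(g) {
      mu <- group_means[[g]]
      x <- MASS::mvrnorm(n_per_group, mu, covariance)
      x <- matrix(x, ncol = p)
      bad <- which(apply(x, 1, function(r) any(r < 0)))
      guard <- 0
      while (length(bad) > 0 && guard < 1000) {
        x[bad, ] <- matrix(MASS::mvrnorm(length(bad), mu, covariance), ncol = p)
        bad <- which(apply(x, 1, function(r) any(r < 0)))
        guard <- guard + 1
      }
      if (length(bad) > 0) {
        stop("could not draw non-negative morphometrics; check means/covariance",
             call. = FALSE)
      }
      colnames(x) <- vars
      data.frame(group = names(group_means)[g] %||% paste0("G", g), x,
                 check.names = FALSE)
    })
    do.call(rbind, out)
  })
}

#' Simulate per-female clutch outcomes
#'
#' Each female's total embryo count is drawn as Poisson around
#' \code{mean_fecundity / (1 - p_nonviable - p_unhatched)} (so that the
#' expected number of viable larvae is \code{mean_fecundity}), then split
#' multinomially into viable larvae, non-viable larvae, and unhatched eggs.
#'
#' @param mean_fecundity Expected viable larvae per female.
#' @param p_nonviable,p_unhatched Category probabilities; non-negative with
#'   \code{p_nonviable + p_unhatched < 1}.
#' @param n_females Number of females.
#' @param seed Integer seed.
#' @return Data frame: \code{female}, \code{viable}, \code{nonviable},
#'   \code{unhatched}.
#' @export
gen_clutch_outcomes <- function(mean_fecundity, p_nonviable = 0.01,
                                p_unhatched = 0.02, n_females = 15, seed = 1) {
  if (p_nonviable < 0 || p_unhatched < 0) {
    stop("proportions must be non-negative", call. = FALSE)
  }
  if (p_nonviable + p_unhatched >= 1) {
    stop("p_nonviable + p_unhatched must be < 1", call. = FALSE)
  }
  p_viable <- 1 - p_nonviable - p_unhatched
  with_seed(seed, {
    totals <- stats::rpois(n_females, mean_fecundity / p_viable)
    counts <- vapply(totals, function(tot) {
      drop(stats::rmultinom(1, tot, c(p_viable, p_nonviable, p_unhatched)))
    }, numeric(3))
    data.frame(female = sprintf("F%02d", seq_len(n_females)),
               viable = counts[1, ], nonviable = counts[2, ],
               unhatched = counts[3, ])
  })
}

#' Simulate a water-chemistry monitoring series
#'
#' Daily temperature/pH records and weekly DIC/TA records around a target
#' carbonate state. The weekly base (DIC, TA) pair is derived from the target
#' pH and DIC through the carbonate solver, so before noise every record is
#' internally consistent with the solver.
#'
#' @param target_ph Target pH on the free scale.
#' @param temperature Mean temperature, deg C.
#' @param salinity Salinity, PSU (constant across the series).
#' @param dic Mean dissolved inorganic carbon, mmol/kg.
#' @param n_days Length of the daily series (>= 1); weekly samples fall on
#'   days 1, 8, 15, ...
#' @param noise_sd Named list of Gaussian noise SDs: \code{ph},
#'   \code{temperature} (daily records), \code{dic}, \code{ta} (weekly
#'   records, mmol/kg).
#' @param seed Integer seed.
#' @return Data frame with columns \code{day}, \code{type} ("daily"/"weekly"),
#'   \code{temperature}, \code{salinity}, \code{ph_free}, \code{dic},
#'   \code{ta} (daily rows carry pH/temperature; weekly rows carry DIC/TA).
#' @export
gen_water_series <- function(target_ph, temperature, salinity = 32, dic = 2.1,
                             n_days = 49,
                             noise_sd = list(ph = 0.02, temperature = 0.3,
                                             dic = 0.02, ta = 0.02),
                             seed = 1) {
  if (n_days < 1) stop("'n_days' must be >= 1", call. = FALSE)
  base <- solve_from_ph_dic(ph_free = target_ph, dic = dic,
                            temperature = temperature, salinity = salinity)
  weekly_days <- seq(1, n_days, by = 7)
  with_seed(seed, {
    daily <- data.frame(
      day = seq_len(n_days), type = "daily",
      temperature = temperature + stats::rnorm(n_days, 0, noise_sd$temperature),
      salinity = salinity,
      ph_free = target_ph + stats::rnorm(n_days, 0, noise_sd$ph),
      dic = NA_real_, ta = NA_real_
    )
    weekly <- data.frame(
      day = weekly_days, type = "weekly",
      temperature = temperature, salinity = salinity, ph_free = NA_real_,
      dic = dic + stats::rnorm(length(weekly_days), 0, noise_sd$dic),
      ta = base$ta + stats::rnorm(length(weekly_days), 0, noise_sd$ta)
    )
    out <- rbind(daily, weekly)
    out[order(out$day, out$type), ]
  })
}
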