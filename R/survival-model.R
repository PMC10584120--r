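#' Power-logistic cumulative mortality curve
#'
#' Cumulative probability of mortality at time \code{t} under the
#' power formulation of the logistic regression,
#' \deqn{P_m(t) = \frac{1}{1 + (t/t_{50})^s},}
#' where \code{t50} is the time to 50% mortality (the LT50) and \code{s} is a
#' slope parameter. With \code{s < 0} this is the CDF of a log-logistic
#' death-time distribution: \code{Pm(0) = 0}, \code{Pm(t50) = 0.5} exactly,
#' and \code{Pm} is monotone non-decreasing in \code{t}.
#'
#' @param t Time in days, \code{t >= 0}. Vectorized.
#' @param t50 Time to 50% mortality in days, \code{> 0}.
#' @param s Slope parameter (negative for an increasing mortality curve).
#' @return Probability (or vector of probabilities) in \code{[0, 1]}.
#' @examples
#' mortality_prob(6.2, t50 = 6.2, s = -3.06)   # 0.5 exactly
#' mortality_prob(2 * 5, t50 = 5, s = -3)      # 8/9
#' @export
mortality_prob <- function(t, t50, s) {
  if (any(!is.finite(t50)) || any(t50 <= 0)) stop("'t50' must be > 0", call. = FALSE)
  if (any(t < 0)) stop("'t' must be >= 0", call. = FALSE)
  # 1/(1+(t/t50)^s) rewritten through plogis for numerical stability at the
  # tails; log(0) = -Inf gives the correct limit Pm(0) = 0 for s < 0.
  stats::plogis(s * (log(t50) - log(t)))
}

# Inverse CDF of the death-time distribution: F(t) = u  =>  t.
mortality_quantile <- function(u, t50, s) {
  t50 * ((1 - u) / u)^(1 / s)
}

# -- model specifications ----------------------------------------------------

STRUCTURES <- c("const", "E", "L", "E+L", "E#L")

#' Factor structure of a starvation-survival model
#'
#' A model specification says how the two curve parameters vary with the
#' crossed pH treatments: \code{"const"} (one shared value), \code{"E"}
#' (varies with embryo treatment), \code{"L"} (larval treatment),
#' \code{"E+L"} (additive), or \code{"E#L"} (one value per design cell,
#' i.e. the full interaction). \code{t50} is modelled on the log scale.
#'
#' @param t50_structure,s_structure One of \code{"const"}, \code{"E"},
#'   \code{"L"}, \code{"E+L"}, \code{"E#L"}.
#' @return An object of class \code{"oa_survival_spec"}.
#' @seealso [candidate_models()] for the 10-model candidate set,
#'   [count_params()] for the parameter count K.
#' @export
survival_spec <- function(t50_structure = "const", s_structure = "const") {
  t50_structure <- match.arg(t50_structure, STRUCTURES)
  s_structure <- match.arg(s_structure, STRUCTURES)
  structure(list(t50 = t50_structure, s = s_structure),
            class = "oa_survival_spec")
}

#' @export
print.oa_survival_spec <- function(x, ...) {
  cat(format_spec(x), "\n")
  invisible(x)
}

format_spec <- function(spec) {
  lab <- function(p, st) if (st == "const") p else sprintf("%s(%s)", p, st)
  sprintf("%s, %s", lab("t50", spec$t50), lab("s", spec$s))
}

#' Number of free parameters of a model specification
#'
#' Each structure contributes \code{const} = 1, \code{E} or \code{L} = 3,
#' \code{E+L} = 5, \code{E#L} = 9 parameters; K is the sum over the two curve
#' parameters. The candidate set spans K = 2 (both constant) to K = 18
#' (both fully crossed).
#'
#' @param spec An [survival_spec()] object.
#' @return Integer parameter count.
#' @export
count_params <- function(spec) {
  stopifnot(inherits(spec, "oa_survival_spec"))
  per <- c(const = 1L, E = 3L, L = 3L, `E+L` = 5L, `E#L` = 9L)
  unname(per[spec$t50] + per[spec$s])
}

#' The 10-model candidate set
#'
#' All five \code{t50} structures with constant \code{s}; constant \code{t50}
#' with the four non-trivial \code{s} structures; and the full-interaction
#' model with both parameters varying by design cell.
#'
#' @return List of [survival_spec()] objects, named by model formula.
#' @export
candidate_models <- function() {
  specs <- c(
    lapply(STRUCTURES, function(st) survival_spec(st, "const")),
    lapply(STRUCTURES[-1], function(st) survival_spec("const", st)),
    list(survival_spec("E#L", "E#L"))
  )
  names(specs) <- vapply(specs, format_spec, character(1))
  specs
}

# Design matrix (9 cells x k) for a structure; rows ordered as cells_grid().
structure_matrix <- function(structure, cells) {
  e <- cells$embryo
  l <- cells$larval
  switch(structure,
    const = matrix(1, nrow(cells), 1),
    E = stats::model.matrix(~e),
    L = stats::model.matrix(~l),
    `E+L` = stats::model.matrix(~ e + l),
    `E#L` = diag(nrow(cells)),
    stop("unknown structure: ", structure, call. = FALSE)
  )
}

cells_grid <- function() {
  g <- expand.grid(larval = TREATMENT_LEVELS, embryo = TREATMENT_LEVELS,
                   stringsAsFactors = FALSE)[, c("embryo", "larval")]
  g$embryo <- as_treatment(g$embryo, "embryo")
  g$larval <- as_treatment(g$larval, "larval")
  rownames(g) <- NULL
  g
}

# Expand a parameter vector into per-cell (t50, s) given a spec.
expand_params <- function(params, spec, cells = cells_grid()) {
  Xt <- structure_matrix(spec$t50, cells)
  Xs <- structure_matrix(spec$s, cells)
  kt <- ncol(Xt)
  if (length(params) != kt + ncol(Xs)) {
    stop(sprintf("parameter vector has length %d, expected %d",
                 length(params), kt + ncol(Xs)), call. = FALSE)
  }
  data.frame(cells,
             t50 = exp(drop(Xt %*% params[seq_len(kt)])),
             s = drop(Xs %*% params[-seq_len(kt)]))
}

# -- mortality data ----------------------------------------------------------

#' Validate a per-insert daily mortality table
#'
#' @param x Data frame with columns \code{insert_id}, \code{year},
#'   \code{embryo_ph}, \code{larval_ph}, \code{day}, \code{new_deaths},
#'   \code{initial_n}. One row per insert per observation day; days must be
#'   strictly increasing within an insert and deaths may not exceed the
#'   insert's starting count.
#' @param max_day Censoring horizon in days; larvae alive past this day are
#'   censored. Defaults to the largest observed day.
#' @return The validated data frame with class \code{"mortality_data"} and a
#'   \code{max_day} attribute.
#' @export
mortality_data <- function(x, max_day = NULL) {
  need <- c("insert_id", "year", "embryo_ph", "larval_ph", "day",
            "new_deaths", "initial_n")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  x <- as.data.frame(x)[, need]
  x$embryo_ph <- as_treatment(x$embryo_ph, "embryo_ph")
  x$larval_ph <- as_treatment(x$larval_ph, "larval_ph")
  if (nrow(x) > 0) {
    bad <- which(x$new_deaths < 0 | x$new_deaths != round_half_up(x$new_deaths))
    if (length(bad) > 0) {
      stop("negative or non-integer new_deaths at row ", bad[1], call. = FALSE)
    }
    for (id in unique(x$insert_id)) {
      rows <- x[x$insert_id == id, ]
      if (any(diff(rows$day) <= 0)) {
        stop("days not strictly increasing for insert ", id, call. = FALSE)
      }
      if (sum(rows$new_deaths) > rows$initial_n[1]) {
        stop(sprintf("insert %s: total deaths (%d) exceed initial_n (%d)",
                     id, sum(rows$new_deaths), rows$initial_n[1]),
             call. = FALSE)
      }
    }
  }
  if (is.null(max_day)) max_day <- if (nrow(x) > 0) max(x$day) else 0L
  structure(x, class = c("mortality_data", "data.frame"), max_day = max_day)
}

# Aggregate a mortality dataset to per-cell death-day counts plus censored
# totals; this is the sufficient statistic for the interval likelihood.
aggregate_cells <- function(data) {
  max_day <- attr(data, "max_day")
  cells <- cells_grid()
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    sub <- data[data$embryo_ph == cells$embryo[i] &
                  data$larval_ph == cells$larval[i], , drop = FALSE]
    deaths <- tapply(sub$new_deaths, sub$day, sum)
    deaths <- deaths[deaths > 0]
    n_total <- sum(tapply(sub$initial_n, sub$insert_id, function(v) v[1]))
    out[[i]] <- list(
      days = as.numeric(names(deaths)),
      deaths = as.numeric(deaths),
      censored = n_total - sum(sub$new_deaths),
      n = n_total
    )
  }
  list(cells = cells, counts = out, max_day = max_day,
       n_larvae = sum(vapply(out, `[[`, numeric(1), "n")))
}

# -- likelihood --------------------------------------------------------------

#' Log-likelihood of a factor-structured survival model
#'
#' Default mode \code{"interval"} is the interval-censored (multinomial)
#' likelihood: a larva dying on day \code{d} (i.e. in \code{(d-1, d]})
#' contributes \code{log(Pm(d) - Pm(d-1))}, and a larva alive at the horizon
#' contributes \code{log(1 - Pm(max_day))}. Mode \code{"daily-binomial"}
#' instead sums binomial log-masses of each day's cumulative dead out of the
#' insert's starting count; the daily terms are not independent, so this is a
#' pseudo-likelihood kept for comparability with analyses phrased that way.
#'
#' @param params Numeric parameter vector, \code{log(t50)} coefficients first
#'   then \code{s} coefficients, with length \code{count_params(spec)}.
#' @param data A [mortality_data()] object.
#' @param spec A [survival_spec()].
#' @param mode \code{"interval"} (default) or \code{"daily-binomial"}.
#' @param eps Floor for interval probabilities; values below it are floored
#'   with a warning (zero-probability intervals would otherwise give -Inf).
#' @return Log-likelihood (scalar).
#' @export
interval_loglik <- function(params, data, spec, mode = c("interval", "daily-binomial"),
                            eps = 1e-12) {
  mode <- match.arg(mode)
  if (any(!is.finite(params))) stop("non-finite parameters", call. = FALSE)
  agg <- if (inherits(data, "cell_counts")) data else
    structure(aggregate_cells(data), class = "cell_counts")
  loglik_from_counts(params, agg, spec, mode, eps, data_raw = data)
}

loglik_from_counts <- function(params, agg, spec, mode, eps, data_raw = NULL,
                               warn_floor = TRUE) {
  par_cells <- expand_params(params, spec, agg$cells)
  # extreme optimizer trial steps can under/overflow exp(log t50)
  if (any(!is.finite(par_cells$t50)) || any(par_cells$t50 <= 0) ||
      any(!is.finite(par_cells$s))) {
    return(-Inf)
  }
  if (mode == "interval") {
    ll <- 0
    floored <- FALSE
    for (i in seq_len(nrow(par_cells))) {
      cc <- agg$counts[[i]]
      if (cc$n == 0) next
      t50 <- par_cells$t50[i]; s <- par_cells$s[i]
      if (length(cc$days) > 0) {
        p <- mortality_prob(cc$days, t50, s) - mortality_prob(cc$days - 1, t50, s)
        if (any(p < eps)) { p <- pmax(p, eps); floored <- TRUE }
        ll <- ll + sum(cc$deaths * log(p))
      }
      if (cc$censored > 0) {
        psurv <- 1 - mortality_prob(agg$max_day, t50, s)
        if (psurv < eps) { psurv <- eps; floored <- TRUE }
        ll <- ll + cc$censored * log(psurv)
      }
    }
    if (floored && warn_floor) {
      warning("interval probabilities floored at eps = ", eps, call. = FALSE)
    }
    ll
  } else {
    if (is.null(data_raw) || !inherits(data_raw, "mortality_data")) {
      stop("'daily-binomial' mode needs the per-insert mortality_data",
           call. = FALSE)
    }
    key <- cell_key(data_raw$embryo_ph, data_raw$larval_ph)
    par_key <- cell_key(par_cells$embryo, par_cells$larval)
    ll <- 0
    for (id in unique(data_raw$insert_id)) {
      rows <- data_raw[data_raw$insert_id == id, , drop = FALSE]
      i <- match(key[data_raw$insert_id == id][1], par_key)
      cum_dead <- cumsum(rows$new_deaths)
      p <- mortality_prob(rows$day, par_cells$t50[i], par_cells$s[i])
      p <- pmin(pmax(p, eps), 1 - eps)
      ll <- ll + sum(stats::dbinom(cum_dead, rows$initial_n[1], p, log = TRUE))
    }
    ll
  }
}

# -- fitting -----------------------------------------------------------------

#' Fitting settings for the survival model
#'
#' @param mode Likelihood mode, see [interval_loglik()].
#' @param eps Interval-probability floor.
#' @param reltol Relative convergence tolerance on the log-likelihood.
#' @param n_restarts Jittered restarts attempted if the first quasi-Newton
#'   search does not converge.
#' @param seed Seed for the (deterministic) restart jitter.
#' @return List of settings.
#' @export
fit_settings <- function(mode = "interval", eps = 1e-12, reltol = 1e-10,
                         n_restarts = 5, seed = 1) {
  list(mode = mode, eps = eps, reltol = reltol,
       n_restarts = n_restarts, seed = seed)
}

#' Fit the starvation-survival model by maximum likelihood
#'
#' Maximizes [interval_loglik()] with a quasi-Newton (BFGS) search from a
#' deterministic start: the overall empirical median death day for
#' \code{t50} (optimized on the log scale) and \code{s = -3}. If the search
#' fails to converge, up to \code{n_restarts} jittered restarts are tried and
#' the result is flagged.
#'
#' @param data A [mortality_data()] object covering all design cells the
#'   specification references.
#' @param spec A [survival_spec()].
#' @param settings See [fit_settings()].
#' @return Object of class \code{"oa_survival_fit"}: per-cell \code{t50} and
#'   \code{s} for all 9 cells, raw coefficients, \code{logLik}, \code{K},
#'   effective \code{n}, \code{AICc}, and convergence diagnostics.
#' @examples
#' params <- survival_curve_params(1)
#' dat <- gen_survival_experiment(design_spec(seed = 42), params)
#' fit <- fit_survival_model(dat, survival_spec("E#L", "E#L"))
#' fit$cells
#' @export
fit_survival_model <- function(data, spec, settings = fit_settings()) {
  stopifnot(inherits(spec, "oa_survival_spec"))
  if (!inherits(data, "mortality_data")) data <- mortality_data(data)
  if (nrow(data) == 0) stop("empty mortality dataset", call. = FALSE)
  agg <- structure(aggregate_cells(data), class = "cell_counts")

  present <- vapply(agg$counts, function(cc) cc$n > 0, logical(1))
  no_deaths <- vapply(agg$counts, function(cc) cc$n > 0 && length(cc$days) == 0,
                      logical(1))
  if (any(no_deaths)) {
    i <- which(no_deaths)[1]
    stop(sprintf("cell %s is all-censored: t50 is unidentifiable",
                 cell_key(agg$cells$embryo[i], agg$cells$larval[i])),
         call. = FALSE)
  }
  # only cells the factor structure references must be present
  needs_all <- spec$t50 == "E#L" || spec$s == "E#L"
  if (needs_all && !all(present)) {
    i <- which(!present)[1]
    stop(sprintf("design cell %s has no data",
                 cell_key(agg$cells$embryo[i], agg$cells$larval[i])),
         call. = FALSE)
  }
  involves <- function(f) {
    any(c(spec$t50, spec$s) %in% if (f == "E") c("E", "E+L") else c("L", "E+L"))
  }
  if (involves("E") &&
      !all(TREATMENT_LEVELS %in% agg$cells$embryo[present])) {
    stop("data must cover every embryo treatment level for this model",
         call. = FALSE)
  }
  if (involves("L") &&
      !all(TREATMENT_LEVELS %in% agg$cells$larval[present])) {
    stop("data must cover every larval treatment level for this model",
         call. = FALSE)
  }

  # start values: overall median death day; s = -3
  all_days <- unlist(lapply(agg$counts, function(cc) rep(cc$days, cc$deaths)))
  med <- stats::median(all_days)
  kt <- ncol(structure_matrix(spec$t50, agg$cells))
  ks <- ncol(structure_matrix(spec$s, agg$cells))
  start_t <- if (spec$t50 == "E#L") rep(log(med), kt) else c(log(med), rep(0, kt - 1))
  start_s <- if (spec$s == "E#L") rep(-3, ks) else c(-3, rep(0, ks - 1))
  start <- c(start_t, start_s)

  nll <- function(p) {
    v <- -loglik_from_counts(p, agg, spec, settings$mode, settings$eps,
                             data_raw = data, warn_floor = FALSE)
    if (!is.finite(v)) 1e10 else v
  }
  run_optim <- function(p0) {
    stats::optim(p0, nll, method = "BFGS",
                 control = list(maxit = 1000, reltol = settings$reltol))
  }
  opt <- run_optim(start)
  restarts_used <- 0L
  if (opt$convergence != 0) {
    with_seed(settings$seed, {
      for (r in seq_len(settings$n_restarts)) {
        cand <- run_optim(opt$par + stats::rnorm(length(start), 0, 0.2))
        restarts_used <- restarts_used + 1L
        if (cand$value < opt$value) opt <- cand
        if (opt$convergence == 0) break
      }
    })
  }
  converged <- opt$convergence == 0
  if (!converged) {
    warning("survival model fit did not converge (", format_spec(spec), ")",
            call. = FALSE)
  }

  cells <- expand_params(opt$par, spec, agg$cells)
  if (any(cells$s >= 0)) {
    warning("estimated s >= 0 in at least one cell: mortality curve is ",
            "non-increasing there", call. = FALSE)
  }
  K <- count_params(spec)
  n_eff <- if (settings$mode == "interval") agg$n_larvae else
    length(unique(paste(data$insert_id, data$day)))
  structure(list(
    spec = spec,
    coefficients = opt$par,
    cells = cells,
    logLik = -opt$value,
    K = K,
    n = n_eff,
    n_definition = if (settings$mode == "interval") "larvae" else "insert-days",
    AICc = aicc(-opt$value, K, n_eff),
    converged = converged,
    restarts = restarts_used,
    settings = settings
  ), class = "oa_survival_fit")
}

#' @export
print.oa_survival_fit <- function(x, digits = 3, ...) {
  cat("Starvation-survival model fit:", format_spec(x$spec), "\n")
  cat(sprintf("  logLik = %.3f, K = %d, n = %d (%s), AICc = %.2f\n",
              x$logLik, x$K, x$n, x$n_definition, x$AICc))
  if (!x$converged) cat("  WARNING: optimizer did not converge\n")
  cells <- x$cells
  cells$t50 <- round(cells$t50, digits)
  cells$s <- round(cells$s, digits)
  print(cells, row.names = FALSE)
  invisible(x)
}

#' Akaike Information Criterion with small-sample correction
#'
#' \deqn{AICc = -2 \log L + 2K + 2K(K+1)/(n-K-1)}
#'
#' @param logLik Maximized log-likelihood.
#' @param K Number of free parameters.
#' @param n Effective sample size; must exceed \code{K + 1}.
#' @return AICc value.
#' @examples
#' aicc(-100, 2, 1000)  # 204.012...
#' @export
aicc <- function(logLik, K, n) {
  if (n <= K + 1) {
    stop("AICc undefined: n must exceed K + 1", call. = FALSE)
  }
  -2 * logLik + 2 * K + 2 * K * (K + 1) / (n - K - 1)
}

#' Fit and rank the candidate model set by AICc
#'
#' Fits every specification in the candidate set (by default the 10-model
#' set), then ranks by AICc: \eqn{\Delta AICc} relative to the minimum,
#' relative likelihood \eqn{\exp(-\Delta/2)}, and Akaike weights
#' (relative likelihoods normalized to sum to 1). Models with
#' \eqn{\Delta < 2} are flagged as the top set (models that close are
#' considered to have equal support). Non-converged fits are excluded with a
#' warning.
#'
#' @param data A [mortality_data()] object.
#' @param settings See [fit_settings()].
#' @param specs List of [survival_spec()] objects; default [candidate_models()].
#' @return Data frame of class \code{"oa_model_comparison"} with one row per
#'   model (columns \code{model}, \code{K}, \code{logLik}, \code{AICc},
#'   \code{dAICc}, \code{rel_lik}, \code{weight}, \code{top_set}), ordered by
#'   AICc; the fitted objects are attached as attribute \code{"fits"}.
#' @export
compare_models <- function(data, settings = fit_settings(),
                           specs = candidate_models()) {
  if (!inherits(data, "mortality_data")) data <- mortality_data(data)
  if (nrow(data) == 0) stop("empty mortality dataset", call. = FALSE)
  fits <- lapply(specs, function(sp) fit_survival_model(data, sp, settings))
  ok <- vapply(fits, `[[`, logical(1), "converged")
  if (!all(ok)) {
    warning("excluding non-converged model(s): ",
            paste(names(fits)[!ok], collapse = "; "), call. = FALSE)
  }
  fits_ok <- fits[ok]
  tab <- data.frame(
    model = vapply(fits_ok, function(f) format_spec(f$spec), character(1)),
    K = vapply(fits_ok, `[[`, numeric(1), "K"),
    logLik = vapply(fits_ok, `[[`, numeric(1), "logLik"),
    AICc = vapply(fits_ok, `[[`, numeric(1), "AICc"),
    row.names = NULL
  )
  tab$dAICc <- tab$AICc - min(tab$AICc)
  tab$rel_lik <- exp(-tab$dAICc / 2)
  tab$weight <- tab$rel_lik / sum(tab$rel_lik)
  tab$top_set <- tab$dAICc < 2
  tab <- tab[order(tab$AICc), ]
  rownames(tab) <- NULL
  structure(tab, class = c("oa_model_comparison", "data.frame"),
            fits = fits_ok)
}

#' @export
print.oa_model_comparison <- function(x, digits = 2, ...) {
  cat("Model comparison (AICc):\n")
  y <- as.data.frame(x)
  for (cl in c("logLik", "AICc", "dAICc", "rel_lik", "weight")) {
    y[[cl]] <- round(y[[cl]], digits)
  }
  print(y, row.names = FALSE)
  invisible(x)
}

#' Best-fit survival-curve parameters from the two-year study
#'
#' Per-cell \code{(t50, s)} estimates for the full-interaction model in each
#' study year of the crossed snow crab experiment that this package's
#' synthetic design emulates. Used as generator defaults for
#' design-scale simulation.
#'
#' @param year 1 (larvae from wild-extruded clutches) or 2 (oocytes developed
#'   under treatment).
#' @return Data frame with columns \code{embryo}, \code{larval}, \code{t50}
#'   (days), \code{s}.
#' @export
survival_curve_params <- function(year = 1) {
  cells <- cells_grid()
  if (year == 1) {
    t50 <- c(6.20, 6.75, 6.69, 4.02, 5.86, 5.15, 4.90, 6.49, 5.36)
    s <- c(-3.06, -2.92, -2.89, -2.92, -2.48, -3.21, -4.38, -3.69, -3.61)
  } else if (year == 2) {
    t50 <- c(7.75, 7.65, 7.81, 7.95, 9.27, 8.05, 7.82, 8.15, 9.03)
    s <- c(-3.32, -3.92, -3.78, -3.92, -4.85, -3.98, -3.21, -3.74, -3.27)
  } else {
    stop("'year' must be 1 or 2", call. = FALSE)
  }
  data.frame(cells, t50 = t50, s = s)
}
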