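#' One-way fixed-effects ANOVA
#'
#' Classical decomposition with \code{F = MS_between / MS_within}. When
#' \code{checks = TRUE}, residual normality (Anderson-Darling) and variance
#' homogeneity (Levene) are tested and the heteroscedasticity decision rule
#' (see [heteroscedastic_gate()]) is applied to the treatment term.
#'
#' @param values Numeric response.
#' @param groups Group labels; >= 2 groups with >= 2 observations each.
#' @param checks Run assumption checks and the significance gate.
#' @param alpha Nominal significance level for the gate.
#' @return Object of class \code{"oa_anova"}: term table (\code{term},
#'   \code{df}, \code{SS}, \code{MS}, \code{F}, \code{p}) with assumption
#'   p-values, adjusted alpha and decision flags as attributes.
#' @examples
#' one_way_anova(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
#' @export
one_way_anova <- function(values, groups, checks = TRUE, alpha = 0.05) {
  g <- droplevels(as.factor(groups))
  if (nlevels(g) < 2) stop("need >= 2 groups", call. = FALSE)
  if (min(table(g)) < 2) stop("every group needs >= 2 observations", call. = FALSE)
  if (stats::var(values) == 0) {
    stop("all values identical: F is undefined (0/0)", call. = FALSE)
  }
  fit <- stats::aov(values ~ g)
  tab <- summary(fit)[[1]]
  out <- data.frame(
    term = c("treatment", "Residual"),
    df = tab$Df, SS = tab$`Sum Sq`, MS = tab$`Mean Sq`,
    F = c(tab$`F value`[1], NA), p = c(tab$`Pr(>F)`[1], NA)
  )
  finish_anova(out, values, g, fit, checks, alpha)
}

finish_anova <- function(out, values, g, fit, checks, alpha) {
  ad_p <- lev_p <- NA_real_
  gate <- NULL
  if (checks) {
    res <- stats::residuals(fit)
    ad_p <- tryCatch(anderson_darling(res), error = function(e) NA_real_)
    lev_p <- tryCatch(levene_test(values, g)$p, error = function(e) NA_real_)
    if (!is.na(lev_p)) {
      gate <- lapply(which(!is.na(out$p)), function(i) {
        heteroscedastic_gate(out$p[i], lev_p, alpha)
      })
      names(gate) <- out$term[!is.na(out$p)]
    }
  }
  structure(out, class = c("oa_anova", "data.frame"),
            ad_p = ad_p, levene_p = lev_p, gate = gate, alpha = alpha)
}

#' @export
print.oa_anova <- function(x, digits = 4, ...) {
  y <- as.data.frame(x)
  for (cl in c("SS", "MS", "F")) y[[cl]] <- round(y[[cl]], digits)
  y$p <- signif(y$p, 3)
  print(y, row.names = FALSE)
  ad <- attr(x, "ad_p"); lev <- attr(x, "levene_p")
  if (!is.na(ad) || !is.na(lev)) {
    cat(sprintf("Assumptions: Anderson-Darling p = %.3g, Levene p = %.3g\n",
                ad, lev))
  }
  gate <- attr(x, "gate")
  if (!is.null(gate)) {
    for (nm in names(gate)) {
      cat(sprintf("  %s: %s (alpha used = %.3g)\n", nm,
                  if (gate[[nm]]$significant) "significant" else "not significant",
                  gate[[nm]]$alpha_used))
    }
  }
  invisible(x)
}

#' Fully crossed two-way fixed-effects ANOVA
#'
#' Main effects, interaction and residual with Type I (sequential) sums of
#' squares, which coincide with Type III on balanced designs; whether the
#' design is balanced is reported. A constant second factor collapses to the
#' one-way analysis of the first.
#'
#' @param values Numeric response.
#' @param factor_a,factor_b Crossed factors.
#' @inheritParams one_way_anova
#' @return An \code{"oa_anova"} object with a \code{balanced} attribute.
#' @export
two_way_anova <- function(values, factor_a, factor_b, checks = TRUE,
                          alpha = 0.05) {
  a <- droplevels(as.factor(factor_a))
  b <- droplevels(as.factor(factor_b))
  if (nlevels(b) < 2) return(one_way_anova(values, a, checks, alpha))
  if (nlevels(a) < 2) return(one_way_anova(values, b, checks, alpha))
  cell_n <- table(a, b)
  if (any(cell_n == 0)) {
    stop("empty design cell: interaction is not estimable", call. = FALSE)
  }
  interaction_ok <- all(cell_n >= 2)
  fml <- if (interaction_ok) values ~ a * b else values ~ a + b
  fit <- stats::aov(fml)
  tab <- summary(fit)[[1]]
  terms <- c("A", "B", if (interaction_ok) "A:B", "Residual")
  out <- data.frame(
    term = terms, df = tab$Df, SS = tab$`Sum Sq`, MS = tab$`Mean Sq`,
    F = tab$`F value`, p = tab$`Pr(>F)`
  )
  res <- finish_anova(out, values, interaction(a, b, drop = TRUE), fit,
                      checks, alpha)
  attr(res, "balanced") <- length(unique(as.vector(cell_n))) == 1
  res
}

#' ANOVA with a unit nested in treatment and an optional crossed factor
#'
#' For designs where each experimental unit (e.g. a female) appears in
#' exactly one treatment level while a second factor (e.g. month) is crossed
#' with treatment. The treatment F uses the mean square of
#' unit-within-treatment as its denominator (units are the replicates for
#' treatment); the crossed factor and the treatment x crossed interaction
#' are tested over the residual.
#'
#' @param values Numeric response.
#' @param treatment Treatment factor.
#' @param nested_unit Unit identifier nested within treatment.
#' @param crossed_factor Optional factor crossed with treatment.
#' @inheritParams one_way_anova
#' @return An \code{"oa_anova"} object; the treatment row's F and p use the
#'   nested-unit mean square.
#' @export
nested_anova <- function(values, treatment, nested_unit, crossed_factor = NULL,
                         checks = TRUE, alpha = 0.05) {
  tr <- droplevels(as.factor(treatment))
  un <- droplevels(as.factor(nested_unit))
  span <- tapply(tr, un, function(x) length(unique(x)))
  if (any(span > 1)) {
    stop("nested unit(s) appear in more than one treatment: ",
         paste(names(span)[span > 1], collapse = ", "), call. = FALSE)
  }
  df_unit <- nlevels(un) - nlevels(tr)
  if (df_unit < 1) {
    stop("need more than one unit per treatment (denominator df = 0)",
         call. = FALSE)
  }
  if (is.null(crossed_factor)) {
    fit <- stats::aov(values ~ tr + un)
    tab <- summary(fit)[[1]]
    terms <- c("treatment", "unit", "Residual")
  } else {
    mo <- droplevels(as.factor(crossed_factor))
    fit <- stats::aov(values ~ tr + un + mo + tr:mo)
    tab <- summary(fit)[[1]]
    terms <- c("treatment", "unit", "crossed", "treatment:crossed", "Residual")
  }
  out <- data.frame(term = terms, df = tab$Df, SS = tab$`Sum Sq`,
                    MS = tab$`Mean Sq`, F = tab$`F value`, p = tab$`Pr(>F)`)
  # re-test treatment over the unit-within-treatment mean square
  ms_unit <- out$MS[out$term == "unit"]
  out$F[1] <- out$MS[1] / ms_unit
  out$p[1] <- stats::pf(out$F[1], out$df[1], out$df[out$term == "unit"],
                        lower.tail = FALSE)
  out$F[out$term == "unit"] <- NA
  out$p[out$term == "unit"] <- NA
  finish_anova(out, values, tr, fit, checks, alpha)
}

#' Levene's test of variance homogeneity
#'
#' One-way ANOVA on absolute deviations from the group mean (classical
#' variant; \code{center = "median"} gives the Brown-Forsythe variant).
#'
#' @param values Numeric response.
#' @param groups Group labels, >= 3 observations per group.
#' @param center \code{"mean"} (default) or \code{"median"}.
#' @return List with \code{statistic}, \code{df}, and \code{p}.
#' @export
levene_test <- function(values, groups, center = c("mean", "median")) {
  center <- match.arg(center)
  g <- droplevels(as.factor(groups))
  if (min(table(g)) < 3) {
    stop("Levene's test needs >= 3 observations per group", call. = FALSE)
  }
  tab <- car::leveneTest(values ~ g,
                         center = if (center == "mean") mean else median)
  list(statistic = tab$`F value`[1], df = tab$Df, p = tab$`Pr(>F)`[1])
}

#' Anderson-Darling test of normality
#'
#' Case-3 composite test (mean and variance estimated from the sample).
#'
#' @param values Numeric sample, n >= 8.
#' @return p-value.
#' @export
anderson_darling <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 8) {
    stop("Anderson-Darling test needs n >= 8", call. = FALSE)
  }
  nortest::ad.test(values)$p.value
}

#' Significance decision under the heteroscedasticity rule
#'
#' When the homogeneity-of-variance test is non-significant the ANOVA term
#' is judged at the nominal alpha. When it is significant, the ANOVA is
#' rejected at an alpha lower than the homogeneity test's p-value: the term
#' is called significant only if its p-value is below the Levene p-value.
#'
#' @param p_anova ANOVA term p-value.
#' @param p_levene Levene test p-value.
#' @param alpha Nominal level (default 0.05).
#' @return List: \code{significant} (logical), \code{alpha_used}.
#' @examples
#' heteroscedastic_gate(1e-16, 1e-15)$significant  # TRUE
#' heteroscedastic_gate(0.03, 0.01)$significant    # FALSE
#' @export
heteroscedastic_gate <- function(p_anova, p_levene, alpha = 0.05) {
  stopifnot(p_anova >= 0, p_anova <= 1, p_levene >= 0, p_levene <= 1)
  if (p_levene >= alpha) {
    list(significant = p_anova < alpha, alpha_used = alpha)
  } else {
    list(significant = p_anova < p_levene, alpha_used = p_levene)
  }
}

#' Tukey HSD pairwise comparisons with compact letter display
#'
#' Studentized-range pairwise comparisons after a one-way fit, plus the
#' letter display used to annotate treatment plots: groups sharing a letter
#' are not significantly different.
#'
#' @param values Numeric response.
#' @param groups Group labels (>= 2 groups).
#' @param alpha Level for the letter display.
#' @return List of class \code{"oa_tukey"}: \code{pairs} (data frame with
#'   \code{diff}, \code{lwr}, \code{upr}, \code{p_adj}) and \code{letters}
#'   (named character vector, groups ordered by decreasing mean).
#' @export
tukey_hsd <- function(values, groups, alpha = 0.05) {
  g <- droplevels(as.factor(groups))
  if (nlevels(g) < 2) stop("need >= 2 groups", call. = FALSE)
  fit <- stats::aov(values ~ g)
  if (stats::df.residual(fit) < 1) stop("residual df < 1", call. = FALSE)
  hsd <- stats::TukeyHSD(fit)$g
  pairs <- data.frame(comparison = rownames(hsd), as.data.frame(hsd),
                      row.names = NULL)
  names(pairs) <- c("comparison", "diff", "lwr", "upr", "p_adj")
  # not-significantly-different graph -> maximal cliques -> letters
  lev <- names(sort(tapply(values, g, mean), decreasing = TRUE))
  k <- length(lev)
  nsd <- diag(TRUE, k); dimnames(nsd) <- list(lev, lev)
  for (i in seq_len(nrow(pairs))) {
    ab <- strsplit(pairs$comparison[i], "-", fixed = TRUE)[[1]]
    same <- pairs$p_adj[i] >= alpha
    nsd[ab[1], ab[2]] <- nsd[ab[2], ab[1]] <- same
  }
  cliques <- maximal_cliques(nsd)
  letters_out <- stats::setNames(rep("", k), lev)
  for (ci in seq_along(cliques)) {
    for (v in cliques[[ci]]) {
      letters_out[v] <- paste0(letters_out[v], letters[ci])
    }
  }
  structure(list(pairs = pairs, letters = letters_out, alpha = alpha),
            class = "oa_tukey")
}

# Maximal cliques of a small undirected graph given as a logical adjacency
# matrix (Bron-Kerbosch, no pivoting; fine for <= ~10 treatments).
maximal_cliques <- function(adj) {
  nodes <- rownames(adj)
  out <- list()
  bk <- function(R, P, X) {
    if (length(P) == 0 && length(X) == 0) {
      out[[length(out) + 1L]] <<- R
      return(invisible())
    }
    for (v in P) {
      nb <- setdiff(nodes[adj[v, ]], v)
      bk(c(R, v), intersect(P, nb), intersect(X, nb))
      P <- setdiff(P, v)
      X <- c(X, v)
    }
  }
  bk(character(0), nodes, character(0))
  # order cliques by the position of their best (first-listed) member
  out[order(vapply(out, function(cl) min(match(cl, nodes)), numeric(1)))]
}

#' @export
print.oa_tukey <- function(x, digits = 4, ...) {
  cat("Tukey HSD pairwise comparisons:\n")
  y <- x$pairs
  for (cl in c("diff", "lwr", "upr")) y[[cl]] <- round(y[[cl]], digits)
  y$p_adj <- signif(y$p_adj, 3)
  print(y, row.names = FALSE)
  cat("Letters (alpha =", x$alpha, "):\n")
  print(x$letters)
  invisible(x)
}
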