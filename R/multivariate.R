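#' Z-score normalization of a morphometric table
#'
#' Each numeric column is centred to mean 0 and scaled to SD 1 (denominator
#' n-1), the standard preprocessing before Euclidean-distance multivariate
#' analysis of measurements on different scales. Non-numeric columns (labels)
#' pass through unchanged.
#'
#' @param x Data frame or matrix of measurements.
#' @return Same shape as \code{x}, numeric columns standardized.
#' @export
zscore_normalize <- function(x) {
  is_df <- is.data.frame(x)
  m <- if (is_df) x else as.data.frame(x)
  num <- vapply(m, is.numeric, logical(1))
  for (j in which(num)) {
    sdj <- stats::sd(m[[j]])
    if (!is.finite(sdj) || sdj == 0) {
      stop(sprintf("column '%s' is constant: cannot z-score", names(m)[j]),
           call. = FALSE)
    }
    m[[j]] <- (m[[j]] - mean(m[[j]])) / sdj
  }
  if (is_df) m else as.matrix(m)
}

#' Euclidean distance matrix from a measurement table
#'
#' @param x Data frame or matrix; only numeric columns are used.
#' @return A \code{stats::dist} object.
#' @export
euclidean_distance <- function(x) {
  m <- as.matrix(as.data.frame(x)[vapply(as.data.frame(x), is.numeric,
                                         logical(1))])
  stats::dist(m, method = "euclidean")
}

# Gower-centred inner-product matrix G from a dist object:
# G = (I - 11'/n) (-D^2/2) (I - 11'/n).  tr(G) = total sum of squares.
gower_centre <- function(d) {
  D2 <- as.matrix(d)^2
  n <- nrow(D2)
  A <- -D2 / 2
  rm <- rowMeans(A)
  A - outer(rm, rep(1, n)) - outer(rep(1, n), rm) + mean(A)
}

# All permutations of a vector (small n), by recursion.
perms_of <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in perms_of(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  }
  out
}

# Generate permutation index sets: either sampled (respecting strata) or
# exhaustive for small n.
permutation_indices <- function(n, n_perm, seed, strata = NULL,
                                exhaustive = FALSE) {
  if (exhaustive) {
    if (n > 8) stop("exhaustive enumeration supported for n <= 8", call. = FALSE)
    return(list(perms = perms_of(seq_len(n)), exhaustive = TRUE))
  }
  perms <- with_seed(seed, {
    if (is.null(strata)) {
      lapply(seq_len(n_perm), function(i) sample.int(n))
    } else {
      strata <- as.factor(strata)
      lapply(seq_len(n_perm), function(i) {
        idx <- seq_len(n)
        for (lev in levels(strata)) {
          w <- which(strata == lev)
          idx[w] <- w[sample.int(length(w))]
        }
        idx
      })
    }
  })
  list(perms = perms, exhaustive = FALSE)
}

perm_pvalue <- function(obs, perm_stats, exhaustive) {
  if (exhaustive) {
    mean(perm_stats >= obs - 1e-12)
  } else {
    (sum(perm_stats >= obs - 1e-12) + 1) / (length(perm_stats) + 1)
  }
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Partitions the total sum of squared Euclidean distances among one or two
#' crossed factors (sequential sums of squares via projection onto the
#' Gower-centred matrix) and tests each term's pseudo-F by permuting sample
#' identities, optionally within strata (e.g. restricting permutations to
#' within a nesting unit).
#'
#' @param d A \code{dist} object (see [euclidean_distance()]).
#' @param factors A factor, or a list/data frame of one or two factors.
#' @param n_perm Number of permutations (add-one p-value convention).
#' @param seed Integer seed for the permutation stream.
#' @param strata Optional grouping; permutations are restricted to within
#'   its levels.
#' @param exhaustive If \code{TRUE} (n <= 8 only), enumerate all
#'   permutations and report the exact fraction.
#' @return Object of class \code{"oa_permanova"}: data frame with one row
#'   per term plus residual/total rows (columns \code{df}, \code{SS},
#'   \code{MS}, \code{pseudo_F}, \code{p}).
#' @export
permanova <- function(d, factors, n_perm = 9999, seed = 1, strata = NULL,
                      exhaustive = FALSE) {
  stopifnot(inherits(d, "dist"))
  if (is.factor(factors) || is.character(factors)) factors <- list(factors)
  factors <- lapply(factors, as.factor)
  if (length(factors) < 1 || length(factors) > 2) {
    stop("'factors' must contain one or two factors", call. = FALSE)
  }
  if (is.null(names(factors)) || any(names(factors) == "")) {
    names(factors) <- paste0("factor", seq_along(factors))[seq_along(factors)]
  }
  n <- attr(d, "Size")
  for (f in factors) {
    if (length(f) != n) stop("factor length must match sample count", call. = FALSE)
    if (nlevels(droplevels(f)) < 2) stop("factors need >= 2 levels", call. = FALSE)
    if (min(table(droplevels(f))) < 2) {
      stop("every factor level needs >= 2 samples", call. = FALSE)
    }
  }
  G <- gower_centre(d)
  ss_total <- sum(diag(G))
  if (ss_total < 1e-12) {
    stop("all samples identical: total sum of squares is zero", call. = FALSE)
  }

  # sequential projectors: intercept, +A, +B, +A:B
  dfr <- data.frame(factors)
  forms <- if (length(factors) == 1) {
    list(stats::as.formula(paste("~", names(dfr)[1])))
  } else {
    list(stats::as.formula(paste("~", names(dfr)[1])),
         stats::as.formula(paste("~", names(dfr)[1], "+", names(dfr)[2])),
         stats::as.formula(paste("~", names(dfr)[1], "*", names(dfr)[2])))
  }
  term_names <- if (length(factors) == 1) names(dfr)[1] else
    c(names(dfr)[1], names(dfr)[2], paste0(names(dfr)[1], ":", names(dfr)[2]))
  hats <- lapply(forms, function(fm) {
    X <- stats::model.matrix(fm, dfr)
    qr_x <- qr(X)
    Q <- qr.Q(qr_x)[, seq_len(qr_x$rank), drop = FALSE]
    tcrossprod(Q)
  })
  H0 <- matrix(1 / n, n, n)
  projs <- c(list(H0), hats)
  dfs <- vapply(seq_along(hats), function(i) {
    round(sum(diag(projs[[i + 1]])) - sum(diag(projs[[i]])))
  }, numeric(1))
  H_full <- hats[[length(hats)]]
  df_res <- n - round(sum(diag(H_full)))

  term_ss <- function(Gm) {
    fits <- vapply(projs, function(H) sum(H * Gm), numeric(1))
    diff(fits)
  }
  ss <- term_ss(G)
  ss_res <- ss_total - sum(ss)
  Fobs <- (ss / dfs) / (ss_res / df_res)

  pi <- permutation_indices(n, n_perm, seed, strata, exhaustive)
  perm_F <- matrix(NA_real_, length(pi$perms), length(ss))
  for (j in seq_along(pi$perms)) {
    p <- pi$perms[[j]]
    Gp <- G[p, p]
    ssp <- term_ss(Gp)
    ssp_res <- ss_total - sum(ssp)
    perm_F[j, ] <- (ssp / dfs) / (ssp_res / df_res)
  }
  pvals <- vapply(seq_along(ss), function(i) {
    perm_pvalue(Fobs[i], perm_F[, i], pi$exhaustive)
  }, numeric(1))

  tab <- data.frame(
    term = c(term_names, "Residual", "Total"),
    df = c(dfs, df_res, n - 1),
    SS = c(ss, ss_res, ss_total),
    MS = c(ss / dfs, ss_res / df_res, NA),
    pseudo_F = c(Fobs, NA, NA),
    p = c(pvals, NA, NA)
  )
  structure(tab, class = c("oa_permanova", "data.frame"),
            n_perm = if (pi$exhaustive) length(pi$perms) else n_perm,
            exhaustive = pi$exhaustive, seed = seed)
}

#' @export
print.oa_permanova <- function(x, digits = 4, ...) {
  cat(sprintf("PERMANOVA (%s, %d permutations)\n",
              if (attr(x, "exhaustive")) "exhaustive" else "sampled",
              attr(x, "n_perm")))
  y <- as.data.frame(x)
  y$SS <- round(y$SS, digits); y$MS <- round(y$MS, digits)
  y$pseudo_F <- round(y$pseudo_F, digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Permutation test of multivariate dispersion homogeneity (PERMDISP)
#'
#' Samples are embedded by principal coordinates of the distance matrix;
#' each sample's distance to its group centroid is computed (squared
#' contributions from negative-eigenvalue axes are subtracted), and a
#' one-way F statistic on those distances is tested by permuting the
#' least-squares residuals.
#'
#' @inheritParams permanova
#' @param groups Group labels (>= 2 groups, each with >= 2 samples).
#' @return Object of class \code{"oa_permtest"}: statistic (F), permutation
#'   p-value, group mean distances-to-centroid.
#' @export
permdisp <- function(d, groups, n_perm = 999, seed = 1, exhaustive = FALSE) {
  stopifnot(inherits(d, "dist"))
  g <- as.factor(groups)
  if (nlevels(g) < 2) stop("need >= 2 groups", call. = FALSE)
  if (min(table(g)) < 2) stop("every group needs >= 2 samples", call. = FALSE)
  n <- attr(d, "Size")

  G <- gower_centre(d)
  eig <- eigen(G, symmetric = TRUE)
  tol <- max(abs(eig$values)) * 1e-8
  pos <- eig$values > tol
  neg <- eig$values < -tol
  U_pos <- eig$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(eig$values[pos]), sum(pos))
  U_neg <- if (any(neg)) {
    eig$vectors[, neg, drop = FALSE] %*% diag(sqrt(-eig$values[neg]), sum(neg))
  } else matrix(0, n, 0)

  dist_to_centroid <- function(U_pos, U_neg, g) {
    z2 <- numeric(n)
    for (lev in levels(g)) {
      w <- which(g == lev)
      cp <- colMeans(U_pos[w, , drop = FALSE])
      dp <- sweep(U_pos[w, , drop = FALSE], 2, cp)
      z2[w] <- rowSums(dp^2)
      if (ncol(U_neg) > 0) {
        cn <- colMeans(U_neg[w, , drop = FALSE])
        dn <- sweep(U_neg[w, , drop = FALSE], 2, cn)
        z2[w] <- z2[w] - rowSums(dn^2)
      }
    }
    sqrt(pmax(z2, 0))
  }
  z <- dist_to_centroid(U_pos, U_neg, g)

  anova_F <- function(y, g) {
    gm <- tapply(y, g, mean)
    ssb <- sum(table(g) * (gm - mean(y))^2)
    ssw <- sum((y - gm[g])^2)
    dfb <- nlevels(g) - 1
    dfw <- length(y) - nlevels(g)
    if (ssw == 0) return(if (ssb == 0) 0 else Inf)
    (ssb / dfb) / (ssw / dfw)
  }
  Fobs <- anova_F(z, g)
  resid_z <- z - tapply(z, g, mean)[g]
  pi <- permutation_indices(n, n_perm, seed, strata = NULL, exhaustive)
  perm_F <- vapply(pi$perms, function(p) anova_F(resid_z[p], g), numeric(1))
  structure(list(statistic = Fobs,
                 p = perm_pvalue(Fobs, perm_F, pi$exhaustive),
                 group_means = tapply(z, g, mean),
                 n_perm = if (pi$exhaustive) length(pi$perms) else n_perm,
                 exhaustive = pi$exhaustive, seed = seed,
                 method = "PERMDISP"),
            class = "oa_permtest")
}

#' Analysis of similarities (ANOSIM)
#'
#' Ranks all pairwise distances (midranks for ties) and compares mean
#' between-group to mean within-group ranks:
#' \deqn{R = \frac{\bar r_B - \bar r_W}{M/2}, \quad M = n(n-1)/2,}
#' so \code{R} is 1 when all between-group distances exceed all within-group
#' distances and near 0 under random labelling. Significance by label
#' permutation.
#'
#' @inheritParams permdisp
#' @return Object of class \code{"oa_permtest"} with the R statistic.
#' @export
anosim <- function(d, groups, n_perm = 9999, seed = 1, exhaustive = FALSE) {
  stopifnot(inherits(d, "dist"))
  g <- as.factor(groups)
  if (nlevels(g) < 2) stop("need >= 2 groups", call. = FALSE)
  if (min(table(g)) < 2) stop("every group needs >= 2 samples", call. = FALSE)
  n <- attr(d, "Size")
  r <- rank(as.vector(d))  # midranks
  M <- n * (n - 1) / 2
  pair_i <- unlist(lapply(seq_len(n - 1), function(i) rep(i, n - i)))
  pair_j <- unlist(lapply(seq_len(n - 1), function(i) (i + 1):n))
  stat_R <- function(g) {
    within <- g[pair_i] == g[pair_j]
    (mean(r[!within]) - mean(r[within])) / (M / 2)
  }
  Robs <- stat_R(g)
  pi <- permutation_indices(n, n_perm, seed, strata = NULL, exhaustive)
  perm_R <- vapply(pi$perms, function(p) stat_R(g[p]), numeric(1))
  structure(list(statistic = Robs,
                 p = perm_pvalue(Robs, perm_R, pi$exhaustive),
                 n_perm = if (pi$exhaustive) length(pi$perms) else n_perm,
                 exhaustive = pi$exhaustive, seed = seed,
                 method = "ANOSIM"),
            class = "oa_permtest")
}

#' @export
print.oa_permtest <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4f, p = %.4g (%s, %d permutations)\n",
              x$method, x$statistic, x$p,
              if (x$exhaustive) "exhaustive" else "sampled", x$n_perm))
  invisible(x)
}

#' Similarity percentages (SIMPER) for two groups
#'
#' For every between-group pair of samples, variable k's contribution to the
#' squared Euclidean distance is its squared coordinate difference;
#' contributions are averaged over all between-group pairs and expressed as
#' percentages summing to 100, sorted descending. Run on the raw
#' (non-normalized) measurements so contributions are in measurement units.
#' Percent difference of the group means is reported per variable
#' (see [percent_difference()]).
#'
#' @param x Data frame of raw measurements (numeric columns used).
#' @param groups Group labels; exactly two groups.
#' @return Data frame of class \code{"oa_simper"}: \code{variable},
#'   \code{mean_a}, \code{mean_b}, \code{contribution_pct},
#'   \code{pct_difference}, ordered by contribution.
#' @export
simper <- function(x, groups) {
  g <- as.factor(groups)
  if (nlevels(g) != 2) stop("SIMPER needs exactly two groups", call. = FALSE)
  m <- as.matrix(as.data.frame(x)[vapply(as.data.frame(x), is.numeric,
                                         logical(1))])
  a <- m[g == levels(g)[1], , drop = FALSE]
  b <- m[g == levels(g)[2], , drop = FALSE]
  contrib <- colMeans(
    do.call(rbind, lapply(seq_len(nrow(a)), function(i) {
      sweep(b, 2, a[i, ])^2
    }))
  )
  total <- sum(contrib)
  if (total < 1e-15) stop("groups are identical: zero total dissimilarity",
                          call. = FALSE)
  out <- data.frame(
    variable = colnames(m),
    mean_a = colMeans(a),
    mean_b = colMeans(b),
    contribution_pct = 100 * contrib / total,
    row.names = NULL
  )
  out$pct_difference <- ifelse(
    out$mean_a == 0, NA_real_,
    100 * (out$mean_a - out$mean_b) / out$mean_a)
  out <- out[order(-out$contribution_pct), ]
  rownames(out) <- NULL
  structure(out, class = c("oa_simper", "data.frame"),
            groups = levels(g))
}

#' Average percent difference between two treatment means
#'
#' \code{100 * (mean_a - mean_b) / mean_a}; negative values indicate the
#' second treatment is larger.
#'
#' @param mean_a Reference (first) treatment mean; must be nonzero.
#' @param mean_b Second treatment mean.
#' @return Percent difference.
#' @examples
#' percent_difference(2.89, 2.73)  # 5.5 (carapace width example)
#' percent_difference(1.68, 1.83)  # -8.9
#' @export
percent_difference <- function(mean_a, mean_b) {
  if (any(mean_a == 0)) stop("reference mean must be nonzero", call. = FALSE)
  100 * (mean_a - mean_b) / mean_a
}
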