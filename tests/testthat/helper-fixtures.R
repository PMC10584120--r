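# Build a single-cell mortality dataset from a vector of death days
# (NA = censored alive), split into equal inserts.
mortality_from_days <- function(days, max_day = 49, embryo = "Ambient",
                                larval = "Ambient", n_inserts = 1,
                                id_prefix = "X") {
  n <- length(days)
  per <- ceiling(n / n_inserts)
  rows <- lapply(seq_len(n_inserts), function(i) {
    d <- days[((i - 1) * per + 1):min(i * per, n)]
    deaths <- tabulate(d[!is.na(d)], nbins = max_day)
    data.frame(insert_id = paste0(id_prefix, i), year = 1,
               embryo_ph = embryo, larval_ph = larval,
               day = seq_len(max_day), new_deaths = deaths,
               initial_n = length(d))
  })
  mortality_data(do.call(rbind, rows), max_day = max_day)
}

# Closed-form log-logistic CDF, written independently of the package.
llogis_cdf <- function(t, t50, s) 1 / (1 + (t / t50)^s)

# Direct one-factor PERMANOVA pseudo-F from a distance matrix and labels,
# via the group sums-of-squares identity (independent of the projection
# implementation).
direct_pseudo_F <- function(d, g) {
  D2 <- as.matrix(d)^2
  n <- nrow(D2)
  ss_total <- sum(D2[upper.tri(D2)]) / n
  ss_within <- 0
  for (lev in unique(g)) {
    w <- which(g == lev)
    sub <- D2[w, w, drop = FALSE]
    ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(w)
  }
  a <- length(unique(g))
  ((ss_total - ss_within) / (a - 1)) / (ss_within / (n - a))
}
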