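#' Percent area yolk
#'
#' \code{PAY = 100 * yolk_area / egg_area}, an index of embryonic yolk
#' consumption: 100 at extrusion, falling toward 0 as the embryo develops.
#'
#' @param yolk_area,egg_area Areas in mm^2; \code{0 <= yolk_area <= egg_area},
#'   \code{egg_area > 0}. Vectorized.
#' @return Percent in \code{[0, 100]}.
#' @export
percent_area_yolk <- function(yolk_area, egg_area) {
  if (any(egg_area <= 0)) stop("'egg_area' must be > 0", call. = FALSE)
  if (any(yolk_area < 0)) stop("'yolk_area' must be >= 0", call. = FALSE)
  if (any(yolk_area > egg_area)) {
    stop("'yolk_area' cannot exceed 'egg_area'", call. = FALSE)
  }
  100 * yolk_area / egg_area
}

#' Per-female clutch summary
#'
#' Fecundity is the number of viable larvae hatched; hatching success,
#' percent non-viable and percent unhatched are each category as a percent
#' of the total estimated embryo count (viable + non-viable + unhatched),
#' so the three percentages partition 100.
#'
#' @param viable Count of viable larvae, or a data frame with columns
#'   \code{viable}, \code{nonviable}, \code{unhatched} (e.g. from
#'   [gen_clutch_outcomes()]).
#' @param nonviable,unhatched Counts (ignored if \code{viable} is a data
#'   frame).
#' @return Data frame: \code{fecundity}, \code{hatching_success},
#'   \code{pct_nonviable}, \code{pct_unhatched}.
#' @examples
#' clutch_summary(95, 2, 3)
#' @export
clutch_summary <- function(viable, nonviable = NULL, unhatched = NULL) {
  if (is.data.frame(viable)) {
    df <- viable
    viable <- df$viable; nonviable <- df$nonviable; unhatched <- df$unhatched
  }
  if (any(viable < 0 | nonviable < 0 | unhatched < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  total <- viable + nonviable + unhatched
  if (any(total <= 0)) stop("total embryo count must be > 0", call. = FALSE)
  data.frame(
    fecundity = viable,
    hatching_success = 100 * viable / total,
    pct_nonviable = 100 * nonviable / total,
    pct_unhatched = 100 * unhatched / total
  )
}

#' Pooled mean larval dry mass from calibration batches
#'
#' Several counted batches (typically ~5 batches of 50 larvae per female)
#' are dried and weighed; the pooled per-larva mass is total mass over total
#' count.
#'
#' @param batch_masses Dry masses of the calibration batches, mg.
#' @param batch_counts Larvae per batch (recycled; default 50).
#' @return Mean per-larva dry mass, mg.
#' @export
mean_larval_mass <- function(batch_masses, batch_counts = 50) {
  if (length(batch_masses) < 1) stop("need >= 1 calibration batch", call. = FALSE)
  if (any(batch_masses <= 0) || any(batch_counts <= 0)) {
    stop("masses and counts must be positive", call. = FALSE)
  }
  batch_counts <- rep_len(batch_counts, length(batch_masses))
  sum(batch_masses) / sum(batch_counts)
}

#' Estimate larvae hatched from batch dry mass
#'
#' @param batch_dry_mass Dry mass of the day's collected larvae, mg (>= 0).
#' @param mean_mass Per-larva dry mass, mg (see [mean_larval_mass()]).
#' @return Estimated count (rounded half-up at this final step only).
#' @examples
#' estimate_count_by_mass(105, mean_larval_mass(c(10, 11), 50))  # 500
#' @export
estimate_count_by_mass <- function(batch_dry_mass, mean_mass) {
  if (any(mean_mass <= 0)) stop("'mean_mass' must be > 0", call. = FALSE)
  if (any(batch_dry_mass < 0)) stop("'batch_dry_mass' must be >= 0", call. = FALSE)
  as.integer(round_half_up(batch_dry_mass / mean_mass))
}

#' Estimate larvae hatched from volumetric subsamples
#'
#' Larvae that must stay alive are counted in 3-4 subsamples of known
#' volume; the mean concentration scales to the total volume.
#'
#' @param subsample_counts Larvae counted in each subsample (>= 1 subsample).
#' @param subsample_volume Volume of each subsample, mL (> 0).
#' @param total_volume Total volume, mL (> 0).
#' @return Estimated count (rounded half-up).
#' @examples
#' estimate_count_by_volume(c(9, 10, 11), 10, 1000)  # 1000
#' @export
estimate_count_by_volume <- function(subsample_counts, subsample_volume,
                                     total_volume) {
  if (length(subsample_counts) < 1) stop("need >= 1 subsample", call. = FALSE)
  if (subsample_volume <= 0 || total_volume <= 0) {
    stop("volumes must be > 0", call. = FALSE)
  }
  if (any(subsample_counts < 0)) stop("counts must be >= 0", call. = FALSE)
  as.integer(round_half_up(mean(subsample_counts) / subsample_volume *
                             total_volume))
}
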