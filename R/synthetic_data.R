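# Plate-reader-like synthetic datasets: replicate wells, OD600 variation,
# multiplicative lognormal noise, 15-min sampling cadence. Gives every
# pipeline stage realistic inputs without any download.

# multiplicative noise with unit mean: lognormal with meanlog = -sigma^2/2
rlnorm_unit <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sigma <- sqrt(log1p(cv^2))
  rlnorm(n, meanlog = -sigma^2 / 2, sdlog = sigma)
}

#' Generate a synthetic plate-reader dose-response dataset
#'
#' For each input level and replicate well, the raw luminescence is
#' `model(input) * noise * od600` where `noise` is multiplicative lognormal
#' with unit mean and coefficient of variation `noise_cv`, and `od600` is a
#' per-well culture density drawn uniformly within 10% of 0.4. Dividing by
#' `od600` (see [od_normalize()]) recovers the model value in expectation.
#'
#' @param model function mapping an input concentration to a signal (a.u.).
#' @param input_grid inducer concentrations.
#' @param noise_cv coefficient of variation of the multiplicative noise
#'   (>= 0; default 0.1).
#' @param seed integer seed; required for reproducibility (same seed, same
#'   dataset).
#' @param replicates wells per input level (default 3, the usual triplicate).
#' @param t_min endpoint read time recorded for every well (min).
#' @return A data frame with columns `well`, `condition`, `replicate`,
#'   `t_min`, `od600`, `lum`, `gfp` (gfp is `NA` unless `gfp_model` given).
#' @param gfp_model optional second model for the fluorescence channel.
#' @export
generate_dose_response <- function(model, input_grid, noise_cv = 0.1, seed,
                                   replicates = 3, t_min = 240,
                                   gfp_model = NULL) {
  if (!is.finite(noise_cv) || noise_cv < 0) stop("noise_cv must be >= 0")
  if (missing(seed)) stop("a seed is required")
  set.seed(as.integer(seed))
  grid <- expand.grid(replicate = seq_len(replicates),
                      condition = input_grid)
  nwell <- nrow(grid)
  od600 <- runif(nwell, 0.4 * 0.9, 0.4 * 1.1)
  lum <- model(grid$condition) * rlnorm_unit(nwell, noise_cv) * od600
  gfp <- if (is.null(gfp_model)) rep(NA_real_, nwell) else
    gfp_model(grid$condition) * rlnorm_unit(nwell, noise_cv) * od600
  data.frame(well = sprintf("W%03d", seq_len(nwell)),
             condition = grid$condition,
             replicate = grid$replicate,
             t_min = t_min, od600 = od600, lum = lum, gfp = gfp)
}

#' Generate a synthetic plate-reader time-course dataset
#'
#' Down-samples a model trace simulated on a fine grid to the plate reader's
#' 15-min cadence and applies per-sample multiplicative lognormal noise and
#' a per-well OD600 factor, as in [generate_dose_response()].
#'
#' @param tc a [time_course()] simulated on a fine (e.g. 1-min) grid.
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param seed integer seed.
#' @param replicates number of wells (default 3).
#' @param cadence sampling interval of the "measured" trace (min, default 15).
#' @return A data frame with columns `well`, `replicate`, `t_min`, `od600`,
#'   `lum`.
#' @export
generate_time_course <- function(tc, noise_cv = 0.1, seed, replicates = 3,
                                 cadence = 15) {
  if (!all(c("t_min", "I") %in% names(tc)))
    stop("tc must have columns t_min and I")
  if (!is.finite(noise_cv) || noise_cv < 0) stop("noise_cv must be >= 0")
  if (missing(seed)) stop("a seed is required")
  set.seed(as.integer(seed))
  keep <- tc$t_min %% cadence == 0
  t_s <- tc$t_min[keep]
  I_s <- tc$I[keep]
  rows <- lapply(seq_len(replicates), function(r) {
    od <- runif(1, 0.4 * 0.9, 0.4 * 1.1)
    data.frame(well = sprintf("W%03d", r), replicate = r, t_min = t_s,
               od600 = od,
               lum = I_s * rlnorm_unit(length(I_s), noise_cv) * od)
  })
  do.call(rbind, rows)
}

#' OD-normalize plate-reader signals
#'
#' Adds `lum_norm` (and `gfp_norm` where gfp is present): raw signal divided
#' by the well's OD600, the standard culture-density normalization.
#'
#' @param dat a data frame from [generate_dose_response()] or
#'   [generate_time_course()].
#' @return The data frame with normalized signal columns appended.
#' @export
od_normalize <- function(dat) {
  stopifnot(all(c("od600", "lum") %in% names(dat)))
  dat$lum_norm <- dat$lum / dat$od600
  if ("gfp" %in% names(dat)) dat$gfp_norm <- dat$gfp / dat$od600
  dat
}
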