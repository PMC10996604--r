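#' Simulate strain-frequency trajectories under the haploid chemostat model
#'
#' Under selection between two strains in a chemostat, the odds of the focal
#' strain follow a geometric series, `p_t/q_t = (p0/q0) * omega^t`, where
#' `omega` is the per-week ratio of the two strains' fitnesses. Equivalently
#' `p_t = r * omega^t / (1 + r * omega^t)` with `r = p0/(1 - p0)`. With
#' `sampling_depth = D`, the observed frequency at each time point is
#' `Binomial(D, p_t)/D`, emulating finite sequencing coverage.
#'
#' @param omega per-week selection coefficient (> 0) of the focal strain.
#' @param p0 initial frequency of the focal strain at week 0.
#' @param weeks integer horizon; time points are weeks `0..weeks`.
#' @param sampling_depth optional integer; when given, binomial sampling
#'   noise at this depth is applied to every time point.
#' @param replicates number of replicate series (independent noise draws).
#' @param seed integer RNG seed (used only when `sampling_depth` is set).
#' @return a `frequency_series`: a data frame with columns `week`,
#'   `replicate`, `p` (focal strain) and `q = 1 - p`.
#' @examples
#' simulate_trajectory(omega = 3, p0 = 0.5, weeks = 2)
#' @export
simulate_trajectory <- function(omega, p0, weeks, sampling_depth = NULL,
                                replicates = 1L, seed = 1L) {
  stopifnot(omega > 0, p0 >= 0, p0 <= 1, weeks >= 0, replicates >= 1)
  t <- 0:weeks
  if (p0 %in% c(0, 1) && is.null(sampling_depth)) {
    warning("p0 is ", p0, ": no dynamics possible, returning constant series")
    p <- rep(p0, length(t))
  } else if (p0 == 0) {
    p <- rep(0, length(t))
  } else if (p0 == 1) {
    p <- rep(1, length(t))
  } else {
    r <- p0 / (1 - p0)
    p <- r * omega^t / (1 + r * omega^t)
  }
  out <- do.call(rbind, lapply(seq_len(replicates), function(rep_i) {
    obs <- p
    if (!is.null(sampling_depth)) {
      stopifnot(sampling_depth >= 1)
      obs <- with_seed(
        derive_seed(seed, paste0("traj:", rep_i)),
        rbinom(length(p), size = as.integer(sampling_depth), prob = p) /
          sampling_depth
      )
    }
    data.frame(week = t, replicate = rep_i, p = obs, q = 1 - obs)
  }))
  class(out) <- c("frequency_series", "data.frame")
  out
}

#' Simulate a geometric titer series
#'
#' `titer_t = titer0 * (1 + weekly_fold)^t` for weeks `0..weeks`, optionally
#' with lognormal noise (sd on the log scale). The inverse problem — fitting
#' `weekly_fold` back from such a series — is [weekly_fold_change()].
#'
#' @param weekly_fold per-week fractional change (e.g. `0.17` for +17% per
#'   week, `-0.14` for a 14% weekly decline); must exceed -1.
#' @param weeks integer horizon (>= 2, so the downstream regression has at
#'   least three points).
#' @param titer0 starting titer.
#' @param noise_sd optional lognormal noise sd on the log scale.
#' @param replicates number of replicate series.
#' @param seed integer RNG seed.
#' @return a `titer_series`: data frame with `week`, `replicate`, `titer`.
#' @export
simulate_titer_series <- function(weekly_fold, weeks, titer0 = 1,
                                  noise_sd = NULL, replicates = 1L,
                                  seed = 1L) {
  stopifnot(weekly_fold > -1, titer0 > 0, replicates >= 1)
  if (weeks < 2) stop("weeks must be >= 2 for the downstream regression")
  t <- 0:weeks
  base <- titer0 * (1 + weekly_fold)^t
  out <- do.call(rbind, lapply(seq_len(replicates), function(rep_i) {
    v <- base
    if (!is.null(noise_sd) && noise_sd > 0) {
      v <- with_seed(
        derive_seed(seed, paste0("titer:", rep_i)),
        v * exp(rnorm(length(v), mean = 0, sd = noise_sd))
      )
    }
    data.frame(week = t, replicate = rep_i, titer = v)
  }))
  class(out) <- c("titer_series", "data.frame")
  out
}

#' Simulate cell counts under exponential growth
#'
#' `N_t = N0 * g^t` on a daily grid, with optional lognormal measurement
#' noise — the generative model inverted by [doubling_time()].
#'
#' @param g per-day geometric growth factor (`g = 2^(1/T_d)` for doubling
#'   time `T_d` in days).
#' @param days vector of sampling days (first is the seeding day).
#' @param n0 starting concentration (cells/mL).
#' @param noise_sd optional lognormal noise sd on the log scale.
#' @param replicates number of replicate series.
#' @param seed integer RNG seed.
#' @return a `cell_count_series`: data frame with `day`, `replicate`,
#'   `count`, `dilution` (all 1; see [doubling_time()] for how recorded
#'   passage dilutions are chained).
#' @export
simulate_cell_counts <- function(g, days = c(0, 7), n0 = 1e6,
                                 noise_sd = NULL, replicates = 1L,
                                 seed = 1L) {
  stopifnot(g > 0, n0 > 0, length(days) >= 2, all(diff(days) > 0))
  base <- n0 * g^(days - days[1])
  out <- do.call(rbind, lapply(seq_len(replicates), function(rep_i) {
    v <- base
    if (!is.null(noise_sd) && noise_sd > 0) {
      v <- with_seed(
        derive_seed(seed, paste0("cells:", rep_i)),
        v * exp(rnorm(length(v), mean = 0, sd = noise_sd))
      )
    }
    data.frame(day = days, replicate = rep_i, count = v, dilution = 1)
  }))
  class(out) <- c("cell_count_series", "data.frame")
  out
}

#' Write a simulated series to TSV
#'
#' Writes `week`/`day`, `replicate` and the value column of a simulated
#' series as a tab-separated file.
#'
#' @param series a `frequency_series`, `titer_series` or `cell_count_series`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_series_tsv <- function(series, path) {
  write.table(as.data.frame(series), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
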