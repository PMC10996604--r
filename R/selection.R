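# Shared log-linear regression core: OLS of log(y) on time. Both the
# selection coefficient (y = p/q) and the weekly titer fold change (y =
# titer) are exp(slope) of this fit.
log_linear_fit <- function(t, y) {
  stopifnot(length(t) == length(y))
  if (length(t) < 2) stop("need >= 2 usable points for the regression")
  if (length(unique(t)) < 2) stop("all time points identical: slope undefined")
  fit <- lm(log(y) ~ t)
  # noise-free geometric inputs fit perfectly; summary.lm's "essentially
  # perfect fit" warning is expected there, not a problem
  s <- suppressWarnings(summary(fit))
  list(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    se_slope = unname(s$coefficients[2, 2]),
    r_squared = s$r.squared,
    n = length(t)
  )
}

#' Strain frequencies from per-timepoint depth summaries
#'
#' The chemostat selection model is defined on the two symbionts only:
#' `p_t` is the focal strain's share of symbiont coverage,
#' `mean_depth(A) / (mean_depth(A) + mean_depth(B))`. (The host-inclusive
#' "proportion of total coverage" from [genomic_titer()] is the plotting
#' statistic, not the modelling one.) Optionally depths are first divided by
#' symbiont genome length — off by default since the strain genomes are
#' within a few percent of each other in length.
#'
#' @param depth_table data frame with columns `week`, `depth_A`, `depth_B`
#'   (mean mappable depth of the focal and the competing strain), and
#'   optionally `replicate`.
#' @param lengths optional numeric pair `c(len_A, len_B)` for
#'   length-normalisation of the two depths.
#' @return a `frequency_series` data frame (`week`, `replicate`, `p`, `q`).
#'   Time points where both depths are 0 are dropped with a warning.
#' @export
frequencies_from_depths <- function(depth_table, lengths = NULL) {
  stopifnot(all(c("week", "depth_A", "depth_B") %in% names(depth_table)))
  dA <- depth_table$depth_A
  dB <- depth_table$depth_B
  if (!is.null(lengths)) {
    stopifnot(length(lengths) == 2, all(lengths > 0))
    dA <- dA / lengths[1]
    dB <- dB / lengths[2]
  }
  both_zero <- (dA + dB) == 0
  if (any(both_zero)) {
    warning(sum(both_zero), " time point(s) with zero depth on both strains",
            " dropped")
  }
  out <- data.frame(
    week = depth_table$week,
    replicate = depth_table$replicate %||% 1L,
    p = dA / (dA + dB)
  )
  out <- out[!both_zero, , drop = FALSE]
  out$q <- 1 - out$p
  rownames(out) <- NULL
  class(out) <- c("frequency_series", "data.frame")
  out
}

#' Estimate the selection coefficient from a frequency time series
#'
#' Fits the haploid chemostat model: under constant selection the odds of the
#' focal strain satisfy `ln(p_t/q_t) = ln(p0/q0) + t * ln(omega)`, so an
#' ordinary least-squares fit of `ln(p_t/q_t)` on `t` estimates `ln(omega)`
#' as its slope. The per-week selection coefficient `omega = exp(slope)` is
#' the ratio of the two strains' fitnesses; `omega = 1` means no selection.
#' Time points with `p` exactly 0 or 1 carry no finite log-odds and are
#' excluded from the fit (for mixtures where the focal strain is initially
#' undetectable, fit from the first week it appears).
#'
#' @param series a `frequency_series` (columns `week`, `p`; `q` is derived
#'   if absent). Multiple replicates are fit independently.
#' @param window optional numeric pair `c(t_start, t_end)`: inclusive week
#'   window to fit over (default: all weeks).
#' @return a `selection_fit`: data frame with one row per replicate and
#'   columns `replicate`, `slope`, `se_slope`, `intercept`, `omega`,
#'   `r_squared`, `n`, `t_start`, `t_end`.
#' @examples
#' traj <- simulate_trajectory(omega = 3, p0 = 0.5, weeks = 3)
#' estimate_selection(traj)$omega # exactly 3
#' @export
estimate_selection <- function(series, window = NULL) {
  stopifnot(is.data.frame(series), all(c("week", "p") %in% names(series)))
  if (!"q" %in% names(series)) series$q <- 1 - series$p
  if (!"replicate" %in% names(series)) series$replicate <- 1L
  if (!is.null(window)) {
    stopifnot(length(window) == 2, window[1] <= window[2])
    series <- series[series$week >= window[1] & series$week <= window[2], ,
                     drop = FALSE]
  }
  fits <- do.call(rbind, lapply(split(series, series$replicate), function(d) {
    usable <- d$p > 0 & d$p < 1
    d <- d[usable, , drop = FALSE]
    f <- log_linear_fit(d$week, d$p / d$q)
    data.frame(
      replicate = d$replicate[1], slope = f$slope, se_slope = f$se_slope,
      intercept = f$intercept, omega = exp(f$slope),
      r_squared = f$r_squared, n = f$n,
      t_start = min(d$week), t_end = max(d$week)
    )
  }))
  rownames(fits) <- NULL
  class(fits) <- c("selection_fit", "data.frame")
  fits
}

#' Weekly titer fold change by log-linear regression
#'
#' OLS of `ln(titer)` on week; the per-week multiplicative fold is
#' `exp(slope)` and its percent form is `(fold - 1) * 100` (+17 means titer
#' grows 17% per week, -14 means it declines 14% per week). Zero titers are
#' excluded with a warning.
#'
#' @param series a `titer_series` (columns `week`, `titer`; optional
#'   `replicate`, fit independently).
#' @param window optional inclusive `c(t_start, t_end)` week window.
#' @return a `fold_change_fit`: data frame with `replicate`, `slope`,
#'   `se_slope`, `fold` (per week), `percent`, `r_squared`, `n`, `t_start`,
#'   `t_end`.
#' @examples
#' s <- simulate_titer_series(weekly_fold = 0.17, weeks = 2)
#' weekly_fold_change(s)$percent # exactly 17
#' @export
weekly_fold_change <- function(series, window = NULL) {
  stopifnot(is.data.frame(series), all(c("week", "titer") %in% names(series)))
  if (!"replicate" %in% names(series)) series$replicate <- 1L
  if (!is.null(window)) {
    stopifnot(length(window) == 2, window[1] <= window[2])
    series <- series[series$week >= window[1] & series$week <= window[2], ,
                     drop = FALSE]
  }
  fits <- do.call(rbind, lapply(split(series, series$replicate), function(d) {
    zero <- d$titer <= 0
    if (any(zero)) {
      warning(sum(zero), " nonpositive titer(s) excluded from log-linear fit")
      d <- d[!zero, , drop = FALSE]
    }
    f <- log_linear_fit(d$week, d$titer)
    data.frame(
      replicate = d$replicate[1], slope = f$slope, se_slope = f$se_slope,
      fold = exp(f$slope), percent = (exp(f$slope) - 1) * 100,
      r_squared = f$r_squared, n = f$n,
      t_start = min(d$week), t_end = max(d$week)
    )
  }))
  rownames(fits) <- NULL
  class(fits) <- c("fold_change_fit", "data.frame")
  fits
}
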