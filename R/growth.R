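#' Host-cell doubling time and per-day growth factor
#'
#' For two counts, `T_d = dt * ln(2) / ln(N_t/N_0)`; for more than two
#' points, `ln(count)` is regressed on day and `T_d = ln(2) / slope`. The
#' per-day geometric growth factor is `g = (N_t/N_0)^(1/dt)` (equivalently
#' `exp(slope)`), so `g = 2^(1/T_d)` whenever both are defined. Recorded
#' passage dilutions are chained multiplicatively: a count taken after a 1:2
#' split (dilution 2) is scaled by the cumulative product of dilution
#' factors, so splits do not bias the estimate.
#'
#' @param series a `cell_count_series`: data frame with `day`, `count`, and
#'   optionally `dilution` (factor by which the culture was diluted since
#'   the previous count; default 1) and `replicate` (fit independently).
#' @param window optional inclusive `c(day_start, day_end)` window.
#' @return a `growth_estimate`: data frame with `replicate`, `g` (per-day
#'   fold), `doubling_time` (days; `NA` with `g = 1`, negative values
#'   reported as `half_life` with `declining = TRUE`), `half_life`,
#'   `declining`, `n`, `t_start`, `t_end`.
#' @examples
#' s <- data.frame(day = c(0, 7), count = c(1e6, 4e6))
#' doubling_time(s)$doubling_time # 3.5
#' @export
doubling_time <- function(series, window = NULL) {
  stopifnot(is.data.frame(series), all(c("day", "count") %in% names(series)))
  if (!"replicate" %in% names(series)) series$replicate <- 1L
  if (!"dilution" %in% names(series)) series$dilution <- 1
  if (!is.null(window)) {
    stopifnot(length(window) == 2, window[1] <= window[2])
    series <- series[series$day >= window[1] & series$day <= window[2], ,
                     drop = FALSE]
  }
  fits <- do.call(rbind, lapply(split(series, series$replicate), function(d) {
    d <- d[order(d$day), , drop = FALSE]
    if (nrow(d) < 2) stop("need >= 2 counts")
    if (d$count[1] <= 0) stop("starting count must be > 0")
    adj <- d$count * cumprod(d$dilution)
    if (nrow(d) == 2) {
      slope <- log(adj[2] / adj[1]) / (d$day[2] - d$day[1])
    } else {
      slope <- log_linear_fit(d$day, adj)$slope
    }
    g <- exp(slope)
    td <- if (slope == 0) NA_real_ else log(2) / slope
    declining <- !is.na(td) && td < 0
    data.frame(
      replicate = d$replicate[1], g = g,
      doubling_time = if (declining || is.na(td)) NA_real_ else td,
      half_life = if (declining) -td else NA_real_,
      declining = declining, n = nrow(d),
      t_start = min(d$day), t_end = max(d$day)
    )
  }))
  rownames(fits) <- NULL
  class(fits) <- c("growth_estimate", "data.frame")
  fits
}

#' Hemocytometer count to cells/mL
#'
#' `cells / boxes * dilution * 10000` cells per mL.
#'
#' @param cells total cells counted.
#' @param boxes number of hemocytometer boxes counted.
#' @param dilution dilution factor of the counted sample (2 for a 1:2
#'   dilution).
#' @return concentration in cells/mL.
#' @export
cells_per_ml <- function(cells, boxes = 1, dilution = 1) {
  stopifnot(cells >= 0, boxes >= 1, dilution > 0)
  cells / boxes * dilution * 1e4
}

#' Plan culture volumes for mixing two infected lines at a target ratio
#'
#' Given two cultures with host-cell densities `x_a`, `x_b` (cells/mL) and
#' symbiont titers `y_a`, `y_b` (symbiont cells per host cell), the volume of
#' culture A needed so that the mixed flask holds symbiont cells of strains
#' A and B at ratio `ratio = A/B` in total volume `v_total` is
#' `V_A = v_total / ((x_a/x_b) * (y_a/y_b) * (1/ratio) + 1)` and
#' `V_B = v_total - V_A`. The returned volumes satisfy
#' `(V_A * x_a * y_a) / (V_B * x_b * y_b) = ratio` exactly.
#'
#' @param x_a,x_b host-cell densities (cells/mL) of cultures A and B.
#' @param y_a,y_b symbiont titers (symbiont cells per host cell).
#' @param ratio target symbiont-cell ratio A/B.
#' @param v_total total flask volume (mL, default 4).
#' @return a `mix_plan`: list with the inputs plus `v_a` and `v_b` (mL).
#' @examples
#' plan_mixture(x_a = 1e6, x_b = 1e6, y_a = 10, y_b = 1, ratio = 1)$v_a
#' @export
plan_mixture <- function(x_a, x_b, y_a, y_b, ratio, v_total = 4) {
  if (any(c(x_a, x_b, y_a, y_b, ratio, v_total) <= 0)) {
    stop("all densities, titers, the ratio and the volume must be > 0")
  }
  v_a <- v_total / ((x_a / x_b) * (y_a / y_b) * (1 / ratio) + 1)
  structure(list(x_a = x_a, x_b = x_b, y_a = y_a, y_b = y_b, ratio = ratio,
                 v_total = v_total, v_a = v_a, v_b = v_total - v_a),
            class = "mix_plan")
}

#' @export
print.mix_plan <- function(x, ...) {
  cat(sprintf(
    "mix_plan: V_A = %.4g mL, V_B = %.4g mL (total %.4g mL, target A/B = %g)\n",
    x$v_a, x$v_b, x$v_total, x$ratio
  ))
  invisible(x)
}
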