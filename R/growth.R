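# One-step growth curve analysis: latent period, burst time and burst
# size from PFU time series.

#' Construct a one-step growth curve
#'
#' @param times Sampling times in minutes, strictly increasing, starting
#'   at 0.
#' @param titers PFU per ml, positive, same length as `times` (>= 5
#'   points).
#' @param n0 Initial count of infected cells per ml; when `NULL` it is
#'   taken as the mean pre-rise titer during estimation.
#' @param moi Multiplicity of infection (metadata, default 0.01).
#' @return A `growth_curve` list.
#' @export
growth_curve <- function(times, titers, n0 = NULL, moi = 0.01) {
  if (length(times) != length(titers) || length(times) < 5L)
    stop("need >= 5 (time, titer) points of equal length", call. = FALSE)
  if (times[1L] != 0) stop("times must start at 0", call. = FALSE)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing",
                                  call. = FALSE)
  if (any(titers <= 0)) stop("titers must be positive", call. = FALSE)
  structure(list(times = as.numeric(times), titers = as.numeric(titers),
                 n0 = n0, moi = moi), class = "growth_curve")
}

#' Estimate one-step growth parameters
#'
#' Fits a three-phase model in log10 titer -- flat pre-rise level, a
#' log-linear rise, and a flat plateau -- by exhaustive grid search over
#' breakpoint pairs on the sampling grid, minimizing the residual sum of
#' squares. The latent period is the first breakpoint (last moment before
#' progeny release), burst time the second (plateau onset). Burst size is
#' computed by the classical ratio definition: mean plateau titer divided
#' by mean pre-rise titer (initial count of infected cells), not from the
#' fitted amplitude. The pre-rise mean excludes the sample at the first
#' breakpoint; the plateau mean includes every sample from the second
#' breakpoint on.
#'
#' @param curve A [growth_curve()].
#' @param grid_dt Breakpoint grid spacing; by default breakpoints are the
#'   observed time points themselves.
#' @return A `growth_params` list: latent_min, burst_time_min, burst_size,
#'   fit_rss (log10 space), pre_mean, plateau_mean.
#' @export
estimate_growth_params <- function(curve, grid_dt = NULL) {
  t <- curve$times; y <- curve$titers
  ly <- log10(y)
  if (max(y) <= 2 * mean(y[1:2]))
    stop("flat curve: titers never exceed twice the initial level",
         call. = FALSE)
  grid <- if (is.null(grid_dt)) t else
    t[t %in% seq(min(t), max(t), by = grid_dt)]
  n <- length(t)
  best <- NULL
  for (i in seq_along(grid)) {
    for (j in seq_along(grid)) {
      ti <- grid[i]; tj <- grid[j]
      if (tj <= ti) next
      pre <- which(t < ti)
      plat <- which(t >= tj)
      rise <- which(t >= ti & t < tj)
      if (length(pre) < 2L || length(plat) < 2L) next
      lpre <- mean(ly[pre]); lplat <- mean(ly[plat])
      model <- numeric(n)
      model[pre] <- lpre
      model[plat] <- lplat
      if (length(rise) > 0L)
        model[rise] <- lpre + (lplat - lpre) * (t[rise] - ti) / (tj - ti)
      rss <- sum((ly - model)^2)
      if (is.null(best) || rss < best$rss - 1e-12) {
        best <- list(ti = ti, tj = tj, rss = rss,
                     pre_mean = mean(y[pre]), plateau_mean = mean(y[plat]))
      }
    }
  }
  if (is.null(best))
    stop("degenerate fit: fewer than 2 points in a phase for every breakpoint pair",
         call. = FALSE)
  n0 <- curve$n0 %||% best$pre_mean
  structure(list(latent_min = best$ti, burst_time_min = best$tj,
                 burst_size = best$plateau_mean / n0,
                 fit_rss = best$rss, pre_mean = best$pre_mean,
                 plateau_mean = best$plateau_mean),
            class = "growth_params")
}

#' @export
print.growth_params <- function(x, ...) {
  cat(sprintf(
    "<growth_params> latent %.4g min, burst time %.4g min, burst size %.4g (RSS %.3g)\n",
    x$latent_min, x$burst_time_min, x$burst_size, x$fit_rss))
  invisible(x)
}

#' Summarize replicate growth-parameter estimates
#'
#' Arithmetic mean and sample standard deviation per parameter across
#' replicate determinations, with the conventional "mean +/- sd" display
#' used in one-step growth tables.
#'
#' @param params List of `growth_params` (>= 2 replicates).
#' @param digits Rounding for the formatted strings (default 0, matching
#'   whole-minute / whole-particle reporting).
#' @return Data frame: parameter, mean, sd, formatted.
#' @export
summarize_replicates <- function(params, digits = 0) {
  if (length(params) < 2L)
    stop("need at least 2 replicates to summarize", call. = FALSE)
  fields <- c("burst_size", "latent_min", "burst_time_min")
  rows <- lapply(fields, function(f) {
    v <- vapply(params, function(p) p[[f]], 0)
    data.frame(parameter = f, mean = mean(v), sd = stats::sd(v),
               formatted = sprintf("%.*f ± %.*f", digits, mean(v),
                                   digits, stats::sd(v)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read growth curves from a delimited file
#'
#' Expects columns `time_min`, `pfu_per_ml` and optionally `replicate`.
#'
#' @param path CSV file.
#' @return Named list of [growth_curve()]s, one per replicate.
#' @export
read_growth_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_min", "pfu_per_ml") %in% names(df)))
    stop("growth CSV needs columns time_min, pfu_per_ml", call. = FALSE)
  if (is.null(df$replicate)) df$replicate <- 1L
  lapply(split(df, df$replicate), function(d)
    growth_curve(d$time_min, d$pfu_per_ml))
}
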