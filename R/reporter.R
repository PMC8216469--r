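#' Promoter activity from plate-reader GFP/OD time courses
#'
#' Activity at time `t` is the per-interval fluorescence gain normalized by
#' culture density, `(GFP_t - GFP_{t-1}) / OD_t`, after subtracting the
#' time-matched background fluorescence of an isogenic non-GFP control, and
#' smoothed with a centered moving average (default 3 points; the window
#' shrinks at the series edges). Negative background-subtracted fluorescence
#' is floored at zero with a warning.
#'
#' @param times Measurement times (minutes), strictly increasing.
#' @param od600 Optical densities (> 0).
#' @param gfp GFP fluorescence (arbitrary units).
#' @param background_gfp Optional background fluorescence at matched times.
#' @param smooth_window Odd moving-average window size (default 3).
#' @return A `data.table` with `time` (from the second point on),
#'   `activity_raw` and `activity` (smoothed), in AU.
#' @export
promoter_activity <- function(times, od600, gfp, background_gfp = NULL,
                              smooth_window = 3L) {
  nlen <- length(times)
  if (nlen < 2L) stop("need at least 2 time points", call. = FALSE)
  if (length(od600) != nlen || length(gfp) != nlen)
    stop("times, od600 and gfp must have equal length", call. = FALSE)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  if (any(od600 <= 0)) stop("OD600 must be strictly positive", call. = FALSE)
  if (smooth_window < 1L || smooth_window %% 2L == 0L)
    stop("smooth_window must be a positive odd integer", call. = FALSE)
  g <- gfp
  if (!is.null(background_gfp)) {
    if (length(background_gfp) != nlen)
      stop("background_gfp must match the series length", call. = FALSE)
    g <- gfp - background_gfp
    if (any(g < 0)) {
      warning("negative background-subtracted GFP floored at 0", call. = FALSE)
      g <- pmax(g, 0)
    }
  }
  a <- diff(g) / od600[-1L]
  h <- (smooth_window - 1L) %/% 2L
  m <- length(a)
  sm <- vapply(seq_len(m), function(i)
    mean(a[max(1L, i - h):min(m, i + h)]), numeric(1))
  data.table(time = times[-1L], activity_raw = a, activity = sm)
}

#' Competition-assay fitness comparison
#'
#' Two strains are co-cultured from a (verified) 1:1 inoculum; after 24 h the
#' per-replicate CFU ratio `cfu_a / cfu_b`, normalized by the inoculum ratio,
#' measures relative fitness. Ratios of a test assay are compared to a
#' reference assay (e.g. marked WT vs WT) with Welch's unequal-variance
#' two-sided t-test (Satterthwaite degrees of freedom).
#'
#' @param assay,reference Lists or data.frames with `cfu_a`, `cfu_b`
#'   (per-replicate colony counts, `cfu_b > 0`, at least 2 replicates) and
#'   optionally `inoculum_ratio` (default 1).
#' @param log_ratios If `TRUE`, the Welch test is run on `log` ratios.
#' @return A `competition_fitness` list: `ratios_assay`, `ratios_reference`,
#'   `t`, `df`, `p_value` (two-sided).
#' @export
competition_fitness <- function(assay, reference, log_ratios = FALSE) {
  ratios <- function(x) {
    if (is.null(x$cfu_a) || is.null(x$cfu_b))
      stop("assay needs cfu_a and cfu_b", call. = FALSE)
    if (length(x$cfu_a) != length(x$cfu_b) || length(x$cfu_a) < 2L)
      stop("need >= 2 replicates per group", call. = FALSE)
    if (any(x$cfu_b <= 0)) stop("zero CFU denominator", call. = FALSE)
    if (any(x$cfu_a < 0)) stop("negative CFU count", call. = FALSE)
    ir <- if (is.null(x$inoculum_ratio)) 1 else x$inoculum_ratio
    (x$cfu_a / x$cfu_b) / ir
  }
  ra <- ratios(assay); rr <- ratios(reference)
  xa <- if (log_ratios) log(ra) else ra
  xr <- if (log_ratios) log(rr) else rr
  if (stats::sd(xa) == 0 && stats::sd(xr) == 0 && mean(xa) == mean(xr)) {
    # degenerate but well-defined: no difference whatsoever
    wt <- list(statistic = 0, parameter = NA_real_, p.value = 1)
  } else {
    wt <- t.test(xa, xr, var.equal = FALSE)
  }
  structure(list(ratios_assay = ra, ratios_reference = rr,
                 t = unname(wt$statistic), df = unname(wt$parameter),
                 p_value = wt$p.value, log_ratios = log_ratios),
            class = "competition_fitness")
}

#' @export
print.competition_fitness <- function(x, ...) {
  cat(sprintf("<competition_fitness> mean ratio %.3f vs %.3f%s: Welch t = %.3f (df %.2f), p = %.4g\n",
              mean(x$ratios_assay), mean(x$ratios_reference),
              if (x$log_ratios) " (log scale)" else "",
              x$t, x$df, x$p_value))
  invisible(x)
}
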