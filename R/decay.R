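#' Normalize a rifampicin-chase band time course
#'
#' Band intensities are divided by a loading control (an abundant stable RNA,
#' e.g. 16S or 5S rRNA, re-probed on the same blot) and expressed as percent
#' of the time-zero value:
#' `percent_remaining_t = 100 * (band_t / control_t) / (band_0 / control_0)`.
#' Any common rescaling of the intensities (exposure, probe activity) cancels.
#'
#' @param times Minutes after rifampicin addition; strictly increasing,
#'   starting at 0.
#' @param band Band intensities (arbitrary units, > 0).
#' @param control Loading-control intensities (> 0), same length.
#' @return A `decay_series`: `data.table` with `time`, `percent_remaining`.
#' @export
normalize_decay <- function(times, band, control) {
  if (length(times) != length(band) || length(band) != length(control))
    stop("times, band and control must have equal length", call. = FALSE)
  if (length(times) < 2L) stop("need at least two time points", call. = FALSE)
  if (times[1] != 0) stop("first time point must be 0 (rifampicin addition)", call. = FALSE)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  if (any(band <= 0) || any(control <= 0))
    stop("intensities must be strictly positive", call. = FALSE)
  ratio <- band / control
  out <- data.table(time = as.numeric(times),
                    percent_remaining = 100 * ratio / ratio[1])
  setattr(out, "class", c("decay_series", class(data.table())))
  out[]
}

#' Average replicate decay series
#'
#' Technical replicates are averaged on the percent-remaining scale, point by
#' point, before fitting (curves must share time points).
#'
#' @param series_list List of `decay_series`.
#' @return A single `decay_series`.
#' @export
average_decay <- function(series_list) {
  stopifnot(length(series_list) >= 1L)
  t0 <- series_list[[1L]]$time
  for (s in series_list[-1L]) {
    if (!isTRUE(all.equal(s$time, t0)))
      stop("replicate series must share time points", call. = FALSE)
  }
  pm <- rowMeans(vapply(series_list, `[[`, numeric(length(t0)), "percent_remaining"))
  out <- data.table(time = t0, percent_remaining = pm)
  setattr(out, "class", c("decay_series", class(data.table())))
  out[]
}

#' Fit an RNA half-life from a rifampicin chase
#'
#' Ordinary least squares on `log10(percent remaining)` versus time; the
#' half-life follows from the fitted slope as `t1/2 = -log10(2) / slope`
#' (log10 scale throughout — the formula only holds there). Some transcripts
#' decay biphasically (two co-existing populations); for those the reported
#' half-life comes from the *initial* slope. Model selection is reproducible
#' rather than visual: every interior breakpoint (at least 3 points per
#' segment, shared knot) is tried, the two-segment fit minimizing total SSE
#' is kept, and `auto` picks it only when it lowers the BIC (the breakpoint
#' counts as a parameter). A non-negative slope, or a fitted half-life beyond
#' `t_max`, is censored and reported as `> t_max` min.
#'
#' @param series A `decay_series` (see [normalize_decay()], [average_decay()]).
#' @param model `"auto"`, `"mono"` or `"biphasic"`.
#' @param t_max Censoring threshold in minutes; defaults to the last sampled
#'   time.
#' @return A `halflife_fit` list: `slope` (log10 percent / min), `intercept`,
#'   `t_half` (min; `NA` when censored), `censored`, `t_max`, `model`,
#'   `breakpoint` (biphasic only), `r_squared`, `segments`.
#' @export
fit_halflife <- function(series, model = c("auto", "mono", "biphasic"),
                         t_max = NULL) {
  model <- match.arg(model)
  tt <- series$time
  y <- log10(series$percent_remaining)
  n <- length(tt)
  if (n < 3L) stop("need at least 3 time points", call. = FALSE)
  if (is.null(t_max)) t_max <- max(tt)

  fit_line <- function(x, yy) {
    fl <- lm(yy ~ x)
    list(slope = unname(coef(fl)[2L]), intercept = unname(coef(fl)[1L]),
         sse = sum(fl$residuals^2))
  }
  mono <- fit_line(tt, y)
  sst <- sum((y - mean(y))^2)
  bic <- function(sse, p) n * log(max(sse, 1e-300) / n) + p * log(n)

  best_bi <- NULL
  if (n >= 6L) {
    # shared-knot candidates: >= 3 points on each side
    cand <- tt[seq(3L, n - 2L)]
    for (b in cand) {
      i1 <- tt <= b; i2 <- tt >= b
      if (sum(i1) < 3L || sum(i2) < 3L) next
      f1 <- fit_line(tt[i1], y[i1]); f2 <- fit_line(tt[i2], y[i2])
      sse <- f1$sse + f2$sse
      if (is.null(best_bi) || sse < best_bi$sse)
        best_bi <- list(breakpoint = b, first = f1, second = f2, sse = sse)
    }
  }
  if (model == "biphasic" && is.null(best_bi))
    stop("biphasic fit needs >= 6 points (>= 3 per segment)", call. = FALSE)

  # require a real SSE improvement before invoking the extra parameters,
  # so numerically-perfect fits (flat or exactly log-linear) stay monophasic
  eps <- 1e-10 * (sst + 1)
  use_bi <- switch(model,
    mono = FALSE,
    biphasic = TRUE,
    auto = !is.null(best_bi) && best_bi$sse < mono$sse - eps &&
      bic(best_bi$sse, 5L) < bic(mono$sse, 2L))

  if (use_bi) {
    slope <- best_bi$first$slope
    intercept <- best_bi$first$intercept
    sse <- best_bi$sse
    out_model <- "biphasic"
    breakpoint <- best_bi$breakpoint
    segments <- list(first = best_bi$first[c("slope", "intercept")],
                     second = best_bi$second[c("slope", "intercept")])
  } else {
    slope <- mono$slope; intercept <- mono$intercept; sse <- mono$sse
    out_model <- "monophasic"; breakpoint <- NA_real_
    segments <- list(first = mono[c("slope", "intercept")])
  }

  th <- if (slope < 0) -log10(2) / slope else Inf
  censored <- !is.finite(th) || th > t_max
  structure(list(slope = slope, intercept = intercept,
                 t_half = if (censored) NA_real_ else th,
                 censored = censored, t_max = t_max,
                 model = out_model, breakpoint = breakpoint,
                 r_squared = if (sst > 0) 1 - sse / sst else NA_real_,
                 segments = segments),
            class = "halflife_fit")
}

#' @export
print.halflife_fit <- function(x, ...) {
  th <- if (x$censored) sprintf("> %g min", x$t_max) else sprintf("%.2f min", x$t_half)
  cat(sprintf("<halflife_fit> %s, t1/2 = %s (slope %.5f log10%%/min, R^2 %.3f)%s\n",
              x$model, th, x$slope, x$r_squared,
              if (x$model == "biphasic")
                sprintf(", breakpoint %g min (initial slope reported)", x$breakpoint)
              else ""))
  invisible(x)
}

#' Gel ladder standard curve and size estimation
#'
#' `ladder_curve` fits `log10(size) ~ migration distance` by ordinary least
#' squares to ladder bands (the paper-and-pencil standard curve of any
#' denaturing gel); `estimate_size` evaluates the fit at a sample band's
#' migration distance, refusing to extrapolate beyond the ladder.
#'
#' @param distance Migration distances of the ladder bands (arbitrary units).
#' @param size_nt Ladder fragment sizes in nt.
#' @return `ladder_curve`: a `standard_curve` object.
#' @export
ladder_curve <- function(distance, size_nt) {
  stopifnot(length(distance) == length(size_nt), length(distance) >= 2L,
            all(size_nt > 0))
  fit <- lm(y ~ x, data = data.frame(x = distance, y = log10(size_nt)))
  structure(list(fit = fit, x = distance, y = log10(size_nt),
                 x_semantics = "migration_distance"),
            class = "standard_curve")
}

#' @rdname ladder_curve
#' @param ladder A `standard_curve` from [ladder_curve()].
#' @param migration_distance Query distance(s), within the ladder range.
#' @return `estimate_size`: estimated size(s) in nt.
#' @export
estimate_size <- function(ladder, migration_distance) {
  stopifnot(inherits(ladder, "standard_curve"),
            ladder$x_semantics == "migration_distance")
  rng <- range(ladder$x)
  if (any(migration_distance < rng[1] | migration_distance > rng[2]))
    stop("migration distance outside the ladder range: interpolation only",
         call. = FALSE)
  10^unname(predict(ladder$fit, data.frame(x = migration_distance)))
}

#' Absolute quantification against in vitro standards
#'
#' `quant_standards` fits band intensity against known amounts (fmol) of in
#' vitro transcript loaded alongside the samples; `quantify_by_standards`
#' inverse-regresses a sample band's intensity to fmol. Intensities outside
#' the standards' range are refused (the film/phosphor response is only
#' trusted where it was calibrated).
#'
#' @param fmol Known amounts of the standards.
#' @param intensity Measured band intensities of the standards.
#' @return `quant_standards`: a `standard_curve` object.
#' @export
quant_standards <- function(fmol, intensity) {
  stopifnot(length(fmol) == length(intensity), length(fmol) >= 2L)
  fit <- lm(y ~ x, data = data.frame(x = fmol, y = intensity))
  structure(list(fit = fit, x = fmol, y = intensity, x_semantics = "fmol"),
            class = "standard_curve")
}

#' @rdname quant_standards
#' @param standards A `standard_curve` from [quant_standards()].
#' @param sample_intensity Band intensity of the sample(s).
#' @return `quantify_by_standards`: estimated amount(s) in fmol.
#' @export
quantify_by_standards <- function(standards, sample_intensity) {
  stopifnot(inherits(standards, "standard_curve"),
            standards$x_semantics == "fmol")
  rng <- range(standards$y)
  if (any(sample_intensity < rng[1] | sample_intensity > rng[2]))
    stop("sample intensity outside the calibrated standard range", call. = FALSE)
  cf <- coef(standards$fit)
  if (cf[2L] == 0) stop("degenerate standards: zero slope", call. = FALSE)
  unname((sample_intensity - cf[1L]) / cf[2L])
}
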