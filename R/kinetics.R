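# Kinetic summaries: per-associated-vesicle normalized 1-s histograms,
# single-exponential decay fits with covariance-derived errors, per-second
# spontaneous probability, first-bin burst amplitude, triggered/spontaneous
# ratio, and replicate comparisons.

#' Per-associated-vesicle normalized fusion-event histogram
#'
#' Bins fusion events at `bin_width` (1 s by default) and normalizes counts
#' by the number of associated SV vesicles in the (possibly merged) table.
#' Triggered events are binned by latency from the Ca2+ arrival time of
#' their round; spontaneous events are binned by time from the start of the
#' spontaneous period. Bins are half-open `[t0 + k*bw, t0 + (k+1)*bw)`, so
#' an event exactly at the time origin falls in bin 0.
#'
#' @param table An `"sv_event_table"` with `n_associated > 0`.
#' @param which `"triggered"` or `"spontaneous"`.
#' @param bin_width Bin width in seconds.
#' @return An object of class `"fusion_histogram"`: list with `which`,
#'   `bin_width`, `left` (bin left edges relative to the time origin),
#'   `counts`, `normalized` (counts / n_associated), `n_associated`,
#'   `n_events`.
#' @export
fusion_histogram <- function(table, which = c("triggered", "spontaneous"),
                             bin_width = 1) {
  which <- match.arg(which)
  if (table$n_associated == 0L) stop("no associated vesicles (n_associated = 0)")
  s <- table$schedule
  if (which == "triggered") {
    lat <- table$records$latency[table$records$fate == "triggered"]
    period_len <- s$trig_end - s$trig_start
  } else {
    ft <- table$records$fusion_time[table$records$fate == "spontaneous"]
    lat <- ft - s$spont_start
    period_len <- s$spont_end - s$spont_start
  }
  n_bins <- floor(period_len / bin_width)
  if (length(lat) > 0 && (any(lat < 0) || any(lat >= n_bins * bin_width)))
    stop("fusion event outside its period (classification inconsistency)")
  idx <- floor(lat / bin_width) + 1L
  counts <- tabulate(idx, nbins = n_bins)
  structure(list(which = which, bin_width = bin_width,
                 left = (seq_len(n_bins) - 1L) * bin_width,
                 counts = counts,
                 normalized = counts / table$n_associated,
                 n_associated = table$n_associated,
                 n_events = length(lat)),
            class = "fusion_histogram")
}

#' @export
print.fusion_histogram <- function(x, ...) {
  cat(sprintf("%s fusion histogram: %d events / %d associated vesicles, %g-s bins\n",
              x$which, x$n_events, x$n_associated, x$bin_width))
  cat(sprintf("  first bin: %.4g per associated vesicle\n", x$normalized[1L]))
  invisible(x)
}

#' @export
plot.fusion_histogram <- function(x, fit = NULL, ...) {
  graphics::barplot(x$normalized, names.arg = x$left, space = 0,
                    xlab = "time from origin (s)",
                    ylab = "fusion probability per associated vesicle", ...)
  if (!is.null(fit)) {
    tt <- seq(0, max(x$left) + x$bin_width, length.out = 200)
    graphics::lines(tt / x$bin_width, predict(fit, newdata = tt),
                    col = "red", lwd = 2)
  }
  invisible(x)
}

#' Fit a single-exponential decay to a fusion histogram
#'
#' Fits `n_k = A * exp(-lambda * t_k)` to the normalized bin contents by
#' unweighted nonlinear least squares using a Levenberg-Marquardt
#' minimizer, with `t_k` the bin left edges (so `A` is interpreted as the
#' first-bin fusion probability per associated vesicle). Standard errors
#' come from the fit covariance matrix (scaled inverse of the approximate
#' normal-equations matrix at the optimum). Initial values are the first
#' (or maximum) bin for `A` and the reciprocal mean event time for
#' `lambda`.
#'
#' @param hist A [fusion_histogram()] with at least 3 non-zero bins.
#' @param abscissa `"left"` (default) to evaluate the model at bin left
#'   edges, `"center"` for bin centers.
#' @param weighted If `TRUE`, Poisson-weight the residuals by the inverse
#'   expected counts; default is the unweighted fit.
#' @return An object of class `"decay_fit"` with fields `A`, `lambda`,
#'   `se_A`, `se_lambda`, `rss`, `n_bins_used`, `cov`.
#' @examples
#' \dontrun{
#' fit <- fit_exponential_decay(fusion_histogram(tab, "triggered"))
#' coef(fit)
#' }
#' @export
fit_exponential_decay <- function(hist, abscissa = c("left", "center"),
                                  weighted = FALSE) {
  abscissa <- match.arg(abscissa)
  y <- hist$normalized
  t <- hist$left + if (abscissa == "center") hist$bin_width / 2 else 0
  if (sum(y > 0) < 3L) stop("insufficient events: fewer than 3 non-zero bins")

  A0 <- max(y[1L], max(y) / 2)
  mean_t <- sum(t * y) / sum(y) + hist$bin_width / 2
  l0 <- 1 / max(mean_t, hist$bin_width / 2)
  w <- if (weighted) 1 / pmax(y, min(y[y > 0])) else rep(1, length(y))

  fit <- minpack.lm::nlsLM(
    y ~ A * exp(-lambda * t),
    data = list(y = y, t = t),
    start = list(A = A0, lambda = l0),
    weights = w,
    lower = c(0, 1e-10),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                         ptol = 1e-15))
  if (!fit$convInfo$isConv && fit$convInfo$stopCode == 0)
    stop("exponential fit did not converge: ", fit$convInfo$stopMessage)
  cf <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  structure(list(A = unname(cf["A"]), lambda = unname(cf["lambda"]),
                 se_A = unname(se["A"]), se_lambda = unname(se["lambda"]),
                 rss = stats::deviance(fit), n_bins_used = length(y),
                 cov = stats::vcov(fit), abscissa = abscissa,
                 bin_width = hist$bin_width, which = hist$which,
                 data = data.frame(t = t, y = y)),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat("Single-exponential decay fit: y = A * exp(-lambda * t)\n")
  cat(sprintf("  A      = %.4g  (se %.3g)   [first-bin probability]\n",
              x$A, x$se_A))
  cat(sprintf("  lambda = %.4g  (se %.3g) 1/s   [decay rate]\n",
              x$lambda, x$se_lambda))
  cat(sprintf("  rss = %.3g over %d bins\n", x$rss, x$n_bins_used))
  invisible(x)
}

#' @export
coef.decay_fit <- function(object, ...) {
  c(A = object$A, lambda = object$lambda)
}

#' @export
vcov.decay_fit <- function(object, ...) object$cov

#' @export
summary.decay_fit <- function(object, ...) {
  z <- c(object$A / object$se_A, object$lambda / object$se_lambda)
  data.frame(estimate = c(object$A, object$lambda),
             std_error = c(object$se_A, object$se_lambda),
             row.names = c("A", "lambda"))
}

#' @export
predict.decay_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$t else newdata
  object$A * exp(-object$lambda * t)
}

#' @export
residuals.decay_fit <- function(object, ...) {
  object$data$y - predict(object)
}

#' @export
plot.decay_fit <- function(x, ...) {
  graphics::plot(x$data$t, x$data$y, pch = 16,
                 xlab = "time from origin (s)",
                 ylab = "fusion probability per associated vesicle", ...)
  tt <- seq(min(x$data$t), max(x$data$t), length.out = 200)
  graphics::lines(tt, predict(x, tt), col = "red", lwd = 2)
  invisible(x)
}

#' Spontaneous fusion probability per associated vesicle
#'
#' The per-second form is the number of spontaneous fusion events divided
#' by (number of associated vesicles x spontaneous-period duration); the
#' per-period (per-minute, for a 60-s period) form is events per associated
#' vesicle over the whole observation window. Both are returned to avoid
#' unit confusion.
#'
#' @param table An `"sv_event_table"` with `n_associated > 0`.
#' @return List with `per_second`, `percent_per_second`, `per_period`,
#'   `n_spontaneous`, `n_associated`, `duration_s`.
#' @examples
#' \dontrun{spontaneous_rate(tab)$percent_per_second}
#' @export
spontaneous_rate <- function(table) {
  if (table$n_associated == 0L) stop("no associated vesicles (n_associated = 0)")
  dur <- table$schedule$spont_end - table$schedule$spont_start
  ps <- table$n_spontaneous / (table$n_associated * dur)
  list(per_second = ps,
       percent_per_second = 100 * ps,
       per_period = table$n_spontaneous / table$n_associated,
       n_spontaneous = table$n_spontaneous,
       n_associated = table$n_associated,
       duration_s = dur)
}

#' First-bin amplitude of a fusion histogram
#'
#' Returns the normalized content of the first bin `[t0, t0 + bin_width)`
#' — the per-associated-vesicle fusion probability in the first second
#' after Ca2+ arrival — together with the per-fusion-event variant (first
#' bin divided by the total number of fusion events in the histogram).
#'
#' @param hist A [fusion_histogram()] with at least one event.
#' @return List with `per_associated` and `per_fusion_event`.
#' @export
first_bin_amplitude <- function(hist) {
  if (length(hist$counts) == 0L || sum(hist$counts) == 0L)
    stop("empty histogram: no fusion events")
  list(per_associated = hist$normalized[1L],
       per_fusion_event = hist$counts[1L] / sum(hist$counts))
}

#' Ratio of triggered to spontaneous fusion probability
#'
#' Compares the per-bin triggered fusion probability (first-bin amplitude)
#' with the per-second spontaneous probability scaled to the same bin
#' width.
#'
#' @param first_bin Triggered fusion probability in the first bin
#'   (dimensionless, per associated vesicle).
#' @param spont Spontaneous fusion probability per associated vesicle per
#'   second; must be positive.
#' @param bin_width Bin width in seconds (1 s makes the two comparable).
#' @return The dimensionless ratio `first_bin / (spont * bin_width)`.
#' @examples
#' triggered_to_spontaneous_ratio(0.017, 0.0002)   # 85
#' triggered_to_spontaneous_ratio(0.006, 0.001)    # 6
#' @export
triggered_to_spontaneous_ratio <- function(first_bin, spont, bin_width = 1) {
  if (spont <= 0) stop("undefined ratio: spontaneous probability is zero")
  first_bin / (spont * bin_width)
}

#' Compare replicate values between two conditions
#'
#' Two-sample Student's t test with pooled variance on per-replicate
#' values (per-round rates, decay rates, amplitudes), as used for the
#' condition bar-chart comparisons; significance is flagged at p < 0.01.
#'
#' @param a,b Numeric vectors of replicate values (>= 2 each).
#' @return An object of class `"sv_comparison"`: list with per-group
#'   `mean`, `sd` (n-1 denominator), `n`, plus `t`, `df`, `p_value`,
#'   `significant`.
#' @export
compare_conditions <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("at least 2 replicates per group are required")
  df <- length(a) + length(b) - 2L
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    # degenerate pooled variance: equal constants compare as no difference,
    # distinct constants as a perfectly separated difference
    tstat <- if (mean(a) == mean(b)) 0 else sign(mean(a) - mean(b)) * Inf
    pval <- if (mean(a) == mean(b)) 1 else 0
  } else {
    tt <- stats::t.test(a, b, var.equal = TRUE)
    tstat <- unname(tt$statistic)
    pval <- tt$p.value
  }
  structure(list(mean_a = mean(a), mean_b = mean(b),
                 sd_a = stats::sd(a), sd_b = stats::sd(b),
                 n_a = length(a), n_b = length(b),
                 t = tstat, df = df,
                 p_value = pval,
                 significant = pval < 0.01),
            class = "sv_comparison")
}

#' @export
print.sv_comparison <- function(x, ...) {
  cat(sprintf("Group A: mean %.4g (sd %.3g, n %d); Group B: mean %.4g (sd %.3g, n %d)\n",
              x$mean_a, x$sd_a, x$n_a, x$mean_b, x$sd_b, x$n_b))
  cat(sprintf("Student's t = %.3f, df = %g, p = %.4g%s\n",
              x$t, x$df, x$p_value,
              if (x$significant) "  ** (p < 0.01)" else ""))
  invisible(x)
}
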