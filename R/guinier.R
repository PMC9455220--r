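#' @importFrom stats coef median sd var
NULL

new_guinier_result <- function(Rg, sigma_Rg, I0, sigma_I0, window,
                               qmin_Rg, qmax_Rg, quality, aggregated,
                               method, r_squared = NA_real_, valid = TRUE) {
  structure(list(Rg = Rg, sigma_Rg = sigma_Rg, I0 = I0, sigma_I0 = sigma_I0,
                 window = as.integer(window), qmin_Rg = qmin_Rg,
                 qmax_Rg = qmax_Rg, quality = quality,
                 aggregated = aggregated, method = method,
                 r_squared = r_squared, valid = valid),
            class = "guinier_result")
}

#' @export
print.guinier_result <- function(x, ...) {
  if (!isTRUE(x$valid)) {
    cat(sprintf("<guinier:%s> invalid fit (aggregated/upturned data?)\n", x$method))
    return(invisible(x))
  }
  cat(sprintf(
    "<guinier:%s> Rg = %.4g +/- %.2g nm, I0 = %.4g +/- %.2g; window [%d, %d), qRg in [%.3f, %.3f], quality %.2f\n",
    x$method, x$Rg, x$sigma_Rg, x$I0, x$sigma_I0, x$window[1], x$window[2],
    x$qmin_Rg, x$qmax_Rg, x$quality))
  invisible(x)
}

# Weighted linear fit of ln I on q^2 with delta-method weights (I/sigma)^2.
# Returns NULL if fewer than 3 usable points.
guinier_wls <- function(q, I, sigma) {
  ok <- is.finite(I) & I > 0
  if (!is.null(sigma)) ok <- ok & is.finite(sigma)
  q <- q[ok]; I <- I[ok]
  if (length(q) < 3) return(NULL)
  x <- q^2
  y <- log(I)
  w <- if (is.null(sigma)) rep(1, length(q)) else (I / pmax(sigma[ok], .Machine$double.xmin))^2
  sw <- sum(w); sx <- sum(w * x); sy <- sum(w * y)
  sxx <- sum(w * x^2); sxy <- sum(w * x * y)
  delta <- sw * sxx - sx^2
  if (delta <= 0) return(NULL)
  slope <- (sw * sxy - sx * sy) / delta
  intercept <- (sxx * sy - sx * sxy) / delta
  yhat <- intercept + slope * x
  rss <- sum(w * (y - yhat)^2)
  ybar <- sy / sw
  tss <- sum(w * (y - ybar)^2)
  r2 <- if (tss > 0) 1 - rss / tss else 1
  if (is.null(sigma)) {
    s2 <- rss / max(length(q) - 2, 1)
    var_slope <- s2 * sw / delta
    var_int <- s2 * sxx / delta
  } else {
    var_slope <- sw / delta
    var_int <- sxx / delta
  }
  list(slope = slope, intercept = intercept, var_slope = var_slope,
       var_intercept = var_int, r_squared = max(0, min(1, r2)),
       n = length(q), qmin = q[1], qmax = q[length(q)])
}

#' Guinier fit on a fixed window
#'
#' Weighted least-squares fit of `ln I = ln I0 - (q Rg)^2 / 3` on a chosen
#' index window, with weights `(I/sigma)^2` (the delta-method variance of
#' `ln I`). Points with `I <= 0` are excluded; fewer than 3 remaining points
#' is an error. A non-negative slope (intensity rising with q, the signature
#' of aggregation) yields a flagged, invalid result rather than a silent NaN.
#'
#' @param curve A [sas_curve()].
#' @param window Integer length-2 `(start, end)`, half-open 1-based index
#'   range into the curve.
#' @return A `guinier_result`.
#' @export
fit_guinier_window <- function(curve, window) {
  stopifnot(inherits(curve, "sas_curve"))
  i <- window[1]; j <- window[2]
  if (i < 1 || j > nrow(curve) + 1 || j - i < 3) {
    stop("window must contain at least 3 points inside the curve", call. = FALSE)
  }
  idx <- i:(j - 1)
  sigma <- if (has_sigma(curve)) curve$sigma[idx] else NULL
  fit <- guinier_wls(curve$q[idx], curve$I[idx], sigma)
  if (is.null(fit)) stop("fewer than 3 positive-intensity points in window", call. = FALSE)
  if (fit$slope >= 0) {
    return(new_guinier_result(NA_real_, NA_real_, exp(fit$intercept), NA_real_,
                              window, NA_real_, NA_real_, 0,
                              aggregated = TRUE, method = "window",
                              r_squared = fit$r_squared, valid = FALSE))
  }
  Rg <- sqrt(-3 * fit$slope)
  sigma_Rg <- 3 / (2 * Rg) * sqrt(fit$var_slope)
  I0 <- exp(fit$intercept)
  sigma_I0 <- I0 * sqrt(fit$var_intercept)
  new_guinier_result(Rg, sigma_Rg, I0, sigma_I0, window,
                     qmin_Rg = fit$qmin * Rg, qmax_Rg = fit$qmax * Rg,
                     quality = fit$r_squared, aggregated = FALSE,
                     method = "window", r_squared = fit$r_squared)
}

# Enumerate admissible Guinier windows on the low-q part of a curve.
# Returns a data.frame of window fits (O(1) per window via prefix sums).
guinier_scan <- function(curve, min_window = 10, qmax_rg_limit = 1.3,
                         qmin_rg_limit = 1.0) {
  n <- nrow(curve)
  q <- curve$q; I <- curve$I
  sigma <- if (has_sigma(curve)) curve$sigma else NULL
  valid <- is.finite(I) & I > 0
  if (!is.null(sigma)) valid <- valid & is.finite(sigma) & sigma > 0
  if (sum(valid[seq_len(min(n, 3 * min_window))]) < min(n, 2 * min_window)) {
    # low-q region largely unusable; still try but bail out on too few points
  }
  # cap the scan: rough Rg from an expanding head fit
  cap <- n
  head_fit <- NULL
  for (j in unique(pmin(n, c(min_window, 2 * min_window, 4 * min_window, 8 * min_window)))) {
    f <- guinier_wls(q[1:j], I[1:j], sigma[1:j])
    if (!is.null(f) && f$slope < 0) { head_fit <- f; break }
  }
  if (!is.null(head_fit)) {
    rg0 <- sqrt(-3 * head_fit$slope)
    cap <- min(n, max(min_window + 2L, sum(q <= 2.0 * qmax_rg_limit / rg0)))
  } else {
    cap <- min(n, 250L)
  }
  x <- q^2
  y <- ifelse(valid, log(pmax(I, .Machine$double.xmin)), 0)
  w <- if (is.null(sigma)) as.double(valid) else ifelse(valid, (I / sigma)^2, 0)
  w[!is.finite(w)] <- 0
  cs <- function(z) cumsum(c(0, z))
  Pw <- cs(w[1:cap]); Px <- cs(w[1:cap] * x[1:cap]); Py <- cs(w[1:cap] * y[1:cap])
  Pxx <- cs(w[1:cap] * x[1:cap]^2); Pxy <- cs(w[1:cap] * x[1:cap] * y[1:cap])
  Pyy <- cs(w[1:cap] * y[1:cap]^2); Pn <- cs(as.double(valid[1:cap]))
  # all (i, j) with j - i >= min_window, 1 <= i, j <= cap + 1 (half-open)
  ii <- integer(0); jj <- integer(0)
  for (i in 1:(cap - min_window + 1L)) {
    js <- (i + min_window):(cap + 1L)
    ii <- c(ii, rep.int(i, length(js))); jj <- c(jj, js)
  }
  sw <- Pw[jj] - Pw[ii]; sx <- Px[jj] - Px[ii]; sy <- Py[jj] - Py[ii]
  sxx <- Pxx[jj] - Pxx[ii]; sxy <- Pxy[jj] - Pxy[ii]; syy <- Pyy[jj] - Pyy[ii]
  nv <- Pn[jj] - Pn[ii]
  delta <- sw * sxx - sx^2
  slope <- (sw * sxy - sx * sy) / delta
  Rg <- sqrt(pmax(-3 * slope, 0))
  qmin_w <- q[ii]; qmax_w <- q[jj - 1L]
  rss <- syy - (sy^2 / sw) - slope^2 * (sxx - sx^2 / sw)
  tss <- syy - sy^2 / sw
  r2 <- ifelse(tss > 0, 1 - rss / tss, 1)
  ok <- is.finite(slope) & slope < 0 & nv >= 3 & delta > 0 &
    (qmax_w * Rg) <= qmax_rg_limit & (qmin_w * Rg) < qmin_rg_limit
  data.frame(i = ii, j = jj, slope = slope, Rg = Rg,
             var_slope = if (is.null(sigma)) rep(NA_real_, length(sw)) else sw / delta,
             qmin_Rg = qmin_w * Rg, qmax_Rg = qmax_w * Rg,
             r_squared = pmax(0, pmin(1, r2)), n_valid = nv,
             admissible = ok)[ok, , drop = FALSE]
}

#' Automatic Guinier-region search
#'
#' Exhaustively scans candidate low-q windows of at least `min_window`
#' points whose fitted `q Rg` products satisfy `qmax Rg <= 1.3` (the
#' Guinier validity bound) and `qmin Rg < 1` (guarding against the
#' beam-stop shadow), re-estimating Rg self-consistently inside each
#' window. The returned window maximizes a composite score of fit R-squared
#' (weight 0.6), window-length fraction (0.3) and a low-qmin bonus (0.1).
#'
#' @param curve A [sas_curve()] with at least 20 usable low-q points.
#' @param min_window Minimum window length in points (default 10).
#' @return A `guinier_result` with `quality` set to the composite score.
#' @export
auto_guinier <- function(curve, min_window = 10) {
  stopifnot(inherits(curve, "sas_curve"))
  if (sum(curve$I > 0, na.rm = TRUE) < 20) {
    stop("need at least 20 valid low-q points", call. = FALSE)
  }
  sc <- guinier_scan(curve, min_window = min_window)
  if (!nrow(sc)) stop("no Guinier region found", call. = FALSE)
  len <- sc$j - sc$i
  score <- 0.6 * sc$r_squared + 0.3 * len / max(len) +
    0.1 * (1 - pmin(sc$qmin_Rg, 1))
  best <- which.max(score)
  res <- fit_guinier_window(curve, c(sc$i[best], sc$j[best]))
  res$quality <- score[best]
  res$method <- "auto"
  res
}

#' Consensus Guinier fit
#'
#' Rather than picking the single best window, fits *all* admissible
#' windows, finds the largest mutually consistent cluster of Rg estimates
#' (the biggest set within 2% relative tolerance of a central value), and
#' returns the inverse-variance-weighted mean of that cluster together with
#' the union of its windows. This consensus is robust to contaminated
#' low-q points (e.g. an aggregation upturn), which only ever enter a
#' minority of windows and disagree with each other. `quality` is the
#' cluster mass fraction (1 when every admissible window agrees).
#'
#' @inheritParams auto_guinier
#' @param rel_tol Relative Rg tolerance for single-linkage clustering.
#' @return A `guinier_result` with method `"consensus"`.
#' @export
auto_rg_consensus <- function(curve, min_window = 10, rel_tol = 0.02) {
  stopifnot(inherits(curve, "sas_curve"))
  if (sum(curve$I > 0, na.rm = TRUE) < 20) {
    stop("need at least 20 valid low-q points", call. = FALSE)
  }
  sc <- guinier_scan(curve, min_window = min_window)
  if (!nrow(sc)) stop("no Guinier region found", call. = FALSE)
  # largest mutually consistent cluster: the biggest set of window fits
  # lying within +/- rel_tol of one central estimate (a mode-seeking ball;
  # a contaminated low-q region produces a thin continuum of outlying fits
  # that cannot chain its way into the consensus)
  rg <- sc$Rg
  srt <- sort(rg)
  lo <- findInterval(srt * (1 - rel_tol), srt)
  hi <- findInterval(srt * (1 + rel_tol), srt)
  counts <- hi - lo
  center <- srt[which.max(counts)]
  members <- which(rg >= center * (1 - rel_tol) & rg <= center * (1 + rel_tol))
  fits <- lapply(members, function(k) fit_guinier_window(curve, c(sc$i[k], sc$j[k])))
  rgv <- vapply(fits, `[[`, numeric(1), "Rg")
  i0v <- vapply(fits, `[[`, numeric(1), "I0")
  srg <- vapply(fits, `[[`, numeric(1), "sigma_Rg")
  si0 <- vapply(fits, `[[`, numeric(1), "sigma_I0")
  w <- 1 / (srg^2 + (1e-12 * rgv)^2)
  w <- w / sum(w)
  Rg <- sum(w * rgv)
  I0 <- sum(w * i0v)
  window <- c(min(sc$i[members]), max(sc$j[members]))
  q <- curve$q
  new_guinier_result(
    Rg = Rg, sigma_Rg = sqrt(sum(w^2 * srg^2)),
    I0 = I0, sigma_I0 = sqrt(sum(w^2 * si0^2)),
    window = window,
    qmin_Rg = q[window[1]] * Rg, qmax_Rg = q[window[2] - 1L] * Rg,
    quality = length(members) / nrow(sc), aggregated = FALSE,
    method = "consensus",
    r_squared = stats::weighted.mean(vapply(fits, `[[`, numeric(1), "r_squared"), w))
}

#' Guinier-peak analysis (GPA)
#'
#' Fast Rg/I0 assessment from the peak of `q I(q)`: for Guinier-law data the
#' peak sits exactly at `q Rg = sqrt(3/2)`. A nonlinear fit of
#' `q I0 exp(-q^2 Rg^2 / 3)` is performed on the contiguous window around
#' the empirical peak where `q I` stays above half its maximum. Less robust
#' than the window searches, but cheap — the fast path when many curves must
#' be analysed, as in chromatography mode.
#'
#' @param curve A [sas_curve()] whose q range brackets the peak of `q I(q)`.
#' @param peak_fraction Initial window boundary as a fraction of the peak
#'   height.
#' @param qrg_max After an initial fit, the window's upper edge is pulled in
#'   to `q Rg <= qrg_max` and the fit repeated (the peak-height window alone
#'   reaches far beyond the Guinier regime and biases Rg on globular
#'   particles). Default 1.5.
#' @return A `guinier_result` with method `"gpa"`.
#' @export
auto_gpa <- function(curve, peak_fraction = 0.5, qrg_max = 1.5) {
  stopifnot(inherits(curve, "sas_curve"))
  ok <- is.finite(curve$I) & curve$I > 0
  y <- ifelse(ok, curve$q * curve$I, -Inf)
  m <- which.max(y)
  if (m == 1L || m == nrow(curve)) stop("GPA peak not bracketed", call. = FALSE)
  thr <- peak_fraction * y[m]
  lo <- m; while (lo > 1 && y[lo - 1] >= thr) lo <- lo - 1
  hi <- m; while (hi < length(y) && y[hi + 1] >= thr) hi <- hi + 1
  if (hi - lo + 1 < 5) { lo <- max(1, m - 3); hi <- min(length(y), m + 3) }
  for (pass in 1:3) {
    res <- gpa_fit(curve, lo, hi)
    hi_new <- max(which(curve$q <= qrg_max / res$Rg), lo + 4L)
    hi_new <- min(hi_new, nrow(curve))
    if (hi_new >= hi || hi_new <= m) break
    hi <- hi_new
  }
  res
}

gpa_fit <- function(curve, lo, hi) {
  idx <- lo:hi
  q <- curve$q[idx]; Iq <- curve$I[idx]
  sigma <- if (has_sigma(curve)) curve$sigma[idx] else NULL
  lin <- guinier_wls(q, Iq, sigma)
  if (is.null(lin) || lin$slope >= 0) stop("GPA peak not fittable", call. = FALSE)
  start <- list(Rg = sqrt(-3 * lin$slope), I0 = exp(lin$intercept))
  df <- data.frame(q = q, y = q * Iq)
  wts <- if (is.null(sigma)) rep(1, length(q)) else 1 / pmax(q * sigma, .Machine$double.xmin)^2
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ q * I0 * exp(-q^2 * Rg^2 / 3), data = df,
                      start = start, weights = wts,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # fall back to the linearized estimate
    Rg <- start$Rg; I0 <- start$I0
    sigma_Rg <- 3 / (2 * Rg) * sqrt(lin$var_slope)
    sigma_I0 <- I0 * sqrt(lin$var_intercept)
    r2 <- lin$r_squared
  } else {
    cf <- coef(fit)
    Rg <- abs(cf[["Rg"]]); I0 <- cf[["I0"]]
    se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) c(Rg = NA, I0 = NA))
    sigma_Rg <- unname(se["Rg"]); sigma_I0 <- unname(se["I0"])
    r2 <- 1 - sum(stats::resid(fit)^2 * wts) / max(sum(wts * (df$y - mean(df$y))^2), .Machine$double.xmin)
  }
  new_guinier_result(Rg, sigma_Rg, I0, sigma_I0, window = c(lo, hi + 1L),
                     qmin_Rg = curve$q[lo] * Rg, qmax_Rg = curve$q[hi] * Rg,
                     quality = max(0, min(1, r2)), aggregated = FALSE,
                     method = "gpa", r_squared = max(0, min(1, r2)))
}
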