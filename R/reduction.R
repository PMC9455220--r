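#' Diode-weighted pixel-wise frame average
#'
#' Averages the selected frames of a stack pixel-wise, weighted by the
#' beam-stop diode (monitor) reading: `values = sum_k F_k / sum_k d_k` — a
#' ratio of sums, *not* the mean of per-frame ratios, which is what makes
#' time-averaging commute with azimuthal integration. Under Poisson
#' statistics `Var[F] = E[F]`, so `variance = sum_k F_k / (sum_k d_k)^2`.
#'
#' @param stack A [frame_stack()].
#' @param accepted_ids Frame ids (matching `stack$frame_ids`) to include;
#'   default all.
#' @return An object of class `averaged_frame`: `values`, `variance`,
#'   `total_monitor`, `n_frames_used`, `accepted_ids`, `geometry`.
#' @export
average_frames <- function(stack, accepted_ids = stack$frame_ids) {
  stopifnot(inherits(stack, "frame_stack"))
  sel <- match(accepted_ids, stack$frame_ids)
  if (!length(sel) || anyNA(sel)) stop("accepted_ids must be non-empty and present", call. = FALSE)
  d <- stack$monitor[sel]
  if (any(d <= 0)) stop("monitor must be > 0", call. = FALSE)
  total <- sum(d)
  counts <- apply(stack$frames[sel, , , drop = FALSE], c(2, 3), sum)
  structure(list(values = counts / total, variance = counts / total^2,
                 total_monitor = total, n_frames_used = length(sel),
                 accepted_ids = as.integer(accepted_ids),
                 geometry = stack$geometry),
            class = "averaged_frame")
}

#' Pixel-wise frame subtraction
#'
#' Subtracts a buffer average from a sample average on the 2D frames
#' (before integration): values subtract, variances add.
#'
#' @param sample_avg,buffer_avg `averaged_frame`s of identical shape.
#' @return An `averaged_frame` of the difference; `n_frames_used` and
#'   `total_monitor` carry the sample's bookkeeping, with the buffer's kept
#'   in `buffer_n_frames` / `buffer_total_monitor`.
#' @export
subtract_frames <- function(sample_avg, buffer_avg) {
  stopifnot(inherits(sample_avg, "averaged_frame"),
            inherits(buffer_avg, "averaged_frame"))
  if (!identical(dim(sample_avg$values), dim(buffer_avg$values))) {
    stop("frame shapes do not match", call. = FALSE)
  }
  out <- sample_avg
  out$values <- sample_avg$values - buffer_avg$values
  out$variance <- sample_avg$variance + buffer_avg$variance
  out$buffer_n_frames <- buffer_avg$n_frames_used
  out$buffer_total_monitor <- buffer_avg$total_monitor
  out
}

#' Azimuthal integration of a detector frame
#'
#' Radially bins a (possibly averaged) frame into equal-width q bins from 0
#' up to the corner q of the detector. Per bin the statistic is the
#' arithmetic mean of unmasked pixel values, with
#' `sigma = sqrt(sum variance) / N_pixels`. Empty bins are dropped (not
#' NaN-filled) so the output q grid is always valid for the CorMap test's
#' exact-grid requirement. When the bin's propagated variance is exactly
#' zero on counting data, a one-count variance floor avoids sigma = 0
#' artifacts.
#'
#' @param frame An `averaged_frame`, or a numeric matrix of pixel values.
#' @param variance Pixel variance matrix (when `frame` is a matrix).
#' @param geometry A [sas_geometry()] (when `frame` is a matrix).
#' @param n_bins Number of q bins (default 200).
#' @return A [sas_curve()] of bin-centre q, mean intensity and sigma.
#' @export
azimuthal_integrate <- function(frame, variance = NULL, geometry = NULL,
                                n_bins = 200) {
  if (inherits(frame, "averaged_frame")) {
    geometry <- frame$geometry
    variance <- frame$variance
    floor_var <- 1 / frame$total_monitor^2
    frame <- frame$values
  } else {
    floor_var <- 0
  }
  stopifnot(is.matrix(frame), inherits(geometry, "sas_geometry"))
  if (is.null(variance)) variance <- matrix(0, nrow(frame), ncol(frame))
  qm <- q_map(geometry)
  keep <- !geometry$mask
  if (!any(keep)) stop("all pixels masked", call. = FALSE)
  qv <- qm[keep]; fv <- frame[keep]; vv <- variance[keep]
  q_corner <- max(qm)
  edges <- seq(0, q_corner, length.out = n_bins + 1)
  bin <- pmin(pmax(findInterval(qv, edges, rightmost.closed = TRUE), 1L), n_bins)
  n_px <- tabulate(bin, n_bins)
  # rowsum only returns occupied bins; rebuild dense vectors
  occ <- sort(unique(bin))
  dense <- function(x) { out <- numeric(n_bins); out[occ] <- x; out }
  sum_I <- dense(as.vector(rowsum(fv, bin)))
  sum_var <- dense(as.vector(rowsum(vv, bin)))
  nonempty <- n_px > 0
  centers <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  I <- sum_I[nonempty] / n_px[nonempty]
  sv <- pmax(sum_var[nonempty], floor_var)
  sigma <- sqrt(sv) / n_px[nonempty]
  sas_curve(centers[nonempty], I, sigma)
}

#' Monitor-weighted average of 1D curves
#'
#' Averages already-integrated curves with beam-stop diode weights:
#' `I = sum_k d_k I_k / sum_k d_k`, `sigma^2 = sum_k d_k^2 sigma_k^2 /
#' (sum_k d_k)^2`. With these weights the 1D average equals the
#' integrate-after-2D-average route exactly; a plain mean of normalized
#' curves does not once the monitors differ.
#'
#' @param curves List of [sas_curve()]s on one common q grid.
#' @param monitors Per-curve monitor values, all > 0.
#' @return A [sas_curve()].
#' @export
weighted_average_curves <- function(curves, monitors) {
  stopifnot(length(curves) >= 1, length(monitors) == length(curves))
  if (any(monitors <= 0)) stop("monitors must be > 0", call. = FALSE)
  q <- curves[[1]]$q
  for (cv in curves) {
    if (!isTRUE(all.equal(cv$q, q))) stop("q grids do not match", call. = FALSE)
  }
  d <- monitors; td <- sum(d)
  I <- Reduce(`+`, Map(function(cv, dk) dk * cv$I, curves, d)) / td
  if (all(vapply(curves, has_sigma, logical(1)))) {
    v <- Reduce(`+`, Map(function(cv, dk) dk^2 * cv$sigma^2, curves, d)) / td^2
    sas_curve(q, I, sqrt(v))
  } else {
    sas_curve(q, I)
  }
}

#' Inverse-variance weighted average of 1D curves
#'
#' Per-bin sigma-weighted mean, the 1D averaging used by the SEC-SAXS
#' pipeline where uncertainties come from azimuthal integration (this is
#' the route the 2D-exact monitor weighting of
#' [weighted_average_curves()] corrects; both are provided).
#'
#' @param curves List of [sas_curve()]s with `sigma`, one common q grid.
#' @return A [sas_curve()].
#' @export
sigma_weighted_average <- function(curves) {
  stopifnot(length(curves) >= 1)
  q <- curves[[1]]$q
  for (cv in curves) {
    if (!isTRUE(all.equal(cv$q, q))) stop("q grids do not match", call. = FALSE)
    if (!has_sigma(cv)) stop("curves must carry sigma", call. = FALSE)
  }
  W <- Reduce(`+`, lapply(curves, function(cv) 1 / cv$sigma^2))
  I <- Reduce(`+`, lapply(curves, function(cv) cv$I / cv$sigma^2)) / W
  sas_curve(q, I, sqrt(1 / W))
}

#' 1D curve subtraction with uncertainty propagation
#'
#' @param sample,buffer [sas_curve()]s on one common q grid.
#' @return A [sas_curve()] of `sample - buffer`; sigmas add in quadrature.
#' @export
subtract_curves <- function(sample, buffer) {
  if (!isTRUE(all.equal(sample$q, buffer$q))) stop("q grids do not match", call. = FALSE)
  if (has_sigma(sample) && has_sigma(buffer)) {
    sas_curve(sample$q, sample$I - buffer$I,
              sqrt(sample$sigma^2 + buffer$sigma^2),
              metadata = curve_metadata(sample))
  } else {
    sas_curve(sample$q, sample$I - buffer$I, metadata = curve_metadata(sample))
  }
}
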