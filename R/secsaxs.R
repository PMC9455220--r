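#' Assemble a chromatogram from partial frame blocks
#'
#' Concatenates the partial chromatograms produced per acquisition file into
#' the full frames-by-q intensity matrix. Rows are placed by frame id, so
#' missing blocks (lost files) leave masked rows rather than shortening the
#' run: the chromatogram always has the nominal length.
#'
#' @param partials List of blocks, each a list of [sas_curve()]s carrying a
#'   0-based `frame_id` in their metadata (as produced by [make_sec_run()]
#'   or the multi-frame pipeline).
#' @param n_frames Nominal run length; default `max(frame_id) + 1`.
#' @return An object of class `chromatogram`: intensity matrix `M`
#'   (frames x q), sigma matrix `S`, `q`, and logical `present` (FALSE =
#'   missing block).
#' @export
assemble_chromatogram <- function(partials, n_frames = NULL) {
  if (!length(partials)) stop("need at least one partial block", call. = FALSE)
  curves <- unlist(partials, recursive = FALSE)
  q <- curves[[1]]$q
  ids <- vapply(curves, function(cv) as.integer(curve_metadata(cv)$frame_id),
                integer(1))
  for (cv in curves) {
    if (!isTRUE(all.equal(cv$q, q))) stop("inconsistent q grids across partials", call. = FALSE)
  }
  if (is.null(n_frames)) n_frames <- max(ids) + 1L
  M <- matrix(NA_real_, n_frames, length(q))
  S <- matrix(NA_real_, n_frames, length(q))
  present <- rep(FALSE, n_frames)
  for (k in seq_along(curves)) {
    i <- ids[k] + 1L
    M[i, ] <- curves[[k]]$I
    S[i, ] <- if (has_sigma(curves[[k]])) curves[[k]]$sigma else NA_real_
    present[i] <- TRUE
  }
  structure(list(M = M, S = S, q = q, present = present,
                 frame_ids = seq_len(n_frames) - 1L),
            class = "chromatogram")
}

#' @export
print.chromatogram <- function(x, ...) {
  cat(sprintf("<chromatogram> %d frames (%d present) x %d q channels\n",
              nrow(x$M), sum(x$present), length(x$q)))
  invisible(x)
}

chromatogram_row <- function(chrom, i) {
  sas_curve(chrom$q, chrom$M[i, ], chrom$S[i, ],
            metadata = list(frame_id = chrom$frame_ids[i]))
}

# optimal singular-value threshold omega(beta) for noise truncation
# (Gavish-Donoho hard-threshold approximation, aspect ratio beta <= 1)
gavish_donoho_omega <- function(beta) {
  0.56 * beta^3 - 0.95 * beta^2 + 1.82 * beta + 1.43
}

#' SVD of a chromatogram with noise-rank selection
#'
#' Singular value decomposition of the unmasked rows; singular values above
#' the optimal hard threshold `omega(beta) * median(singular values)`
#' (aspect ratio `beta <= 1`) are retained, giving the number of
#' signal-carrying components (background + eluting species). The first
#' right singular vector — dominated by buffer scattering — is returned
#' with its sign fixed so its mean is positive.
#'
#' @param chromatogram A `chromatogram`.
#' @return List with `k` (retained rank), `singular_values`,
#'   `first_singular_vector` (q profile), `threshold`, `u`, `v`.
#' @export
svd_rank <- function(chromatogram) {
  M <- chromatogram$M[chromatogram$present, , drop = FALSE]
  if (nrow(M) < 2) stop("need at least 2 unmasked frames", call. = FALSE)
  if (all(M == 0)) stop("degenerate all-zero chromatogram", call. = FALSE)
  sv <- svd(M)
  beta <- min(dim(M)) / max(dim(M))
  tau <- gavish_donoho_omega(beta) * median(sv$d)
  k <- sum(sv$d > tau)
  v1 <- sv$v[, 1]
  if (mean(v1) < 0) v1 <- -v1
  list(k = k, singular_values = sv$d, first_singular_vector = v1,
       threshold = tau, u = sv$u, v = sv$v)
}

# deterministic NNDSVDa initialization (SVD-based, zeros filled with the
# matrix mean) for non-negative matrix factorization
nndsvda_init <- function(V, k) {
  sv <- svd(V, nu = k, nv = k)
  n <- nrow(V); m <- ncol(V)
  W <- matrix(0, n, k); H <- matrix(0, k, m)
  W[, 1] <- sqrt(sv$d[1]) * abs(sv$u[, 1])
  H[1, ] <- sqrt(sv$d[1]) * abs(sv$v[, 1])
  if (k > 1) for (j in 2:k) {
    u <- sv$u[, j]; v <- sv$v[, j]
    up <- pmax(u, 0); un <- pmax(-u, 0)
    vp <- pmax(v, 0); vn <- pmax(-v, 0)
    npos <- sqrt(sum(up^2)) * sqrt(sum(vp^2))
    nneg <- sqrt(sum(un^2)) * sqrt(sum(vn^2))
    if (npos >= nneg && npos > 0) {
      W[, j] <- sqrt(sv$d[j] * npos) * up / sqrt(sum(up^2))
      H[j, ] <- sqrt(sv$d[j] * npos) * vp / sqrt(sum(vp^2))
    } else if (nneg > 0) {
      W[, j] <- sqrt(sv$d[j] * nneg) * un / sqrt(sum(un^2))
      H[j, ] <- sqrt(sv$d[j] * nneg) * vn / sqrt(sum(vn^2))
    }
  }
  avg <- mean(V)
  W[W <= 0] <- avg; H[H <= 0] <- avg
  list(W = W, H = H)
}

#' Non-negative matrix factorization of a chromatogram
#'
#' Factorizes the (negative-clipped) unmasked chromatogram into
#' non-negative elution profiles `W` (frames x k) and component spectra `H`
#' (k x q) minimizing the Frobenius reconstruction error, by Lee-Seung
#' multiplicative updates from a deterministic NNDSVD-based initialization
#' with a fixed iteration cap — so repeated runs are bit-identical (NMF is
#' not unique; determinism is imposed by the initialization). Spectra are
#' normalized to unit maximum with the scale absorbed into `W`.
#'
#' @param chromatogram A `chromatogram`.
#' @param k Number of components (>= 1).
#' @param max_iter Iteration cap (default 500).
#' @param tol Relative reconstruction-error change for early stop.
#' @return List with `W` (full run length, masked rows NA), `H`,
#'   `rel_error` (final relative Frobenius error), `n_clipped` (negative
#'   entries clipped to 0), `iterations`.
#' @export
nmf_components <- function(chromatogram, k, max_iter = 500, tol = 1e-9) {
  present <- chromatogram$present
  V <- chromatogram$M[present, , drop = FALSE]
  if (k < 1 || k > min(dim(V))) stop("k out of range for this matrix", call. = FALSE)
  n_clipped <- sum(V < 0)
  V <- pmax(V, 0)
  init <- nndsvda_init(V, k)
  W <- init$W; H <- init$H
  eps <- .Machine$double.eps
  vnorm <- sqrt(sum(V^2))
  err_prev <- Inf
  it <- 0L
  for (it in seq_len(max_iter)) {
    H <- H * (crossprod(W, V) + eps) / (crossprod(W) %*% H + eps)
    W <- W * (V %*% t(H) + eps) / (W %*% tcrossprod(H) + eps)
    if (it %% 10 == 0) {
      err <- sqrt(sum((V - W %*% H)^2)) / vnorm
      if (is.finite(err_prev) && abs(err_prev - err) < tol * max(err, eps)) break
      err_prev <- err
    }
  }
  rel_error <- sqrt(sum((V - W %*% H)^2)) / vnorm
  scale <- apply(H, 1, max)
  scale[scale <= 0] <- 1
  H <- H / scale
  W <- sweep(W, 2, scale, `*`)
  W_full <- matrix(NA_real_, length(present), k)
  W_full[present, ] <- W
  list(W = W_full, H = H, rel_error = rel_error,
       n_clipped = n_clipped, iterations = it)
}

#' Identify and average the buffer frames of a run
#'
#' Ranks every unmasked frame by how well it matches the (least-squares
#' scaled) first singular vector under the CorMap test — from most likely
#' pure buffer to least likely — and averages the top `fraction` of frames
#' with inverse-variance (1D) uncertainty propagation. Ranking key:
#' p-value descending, ties broken by smaller longest-run C, then by frame
#' id.
#'
#' @param chromatogram A `chromatogram`.
#' @param first_singular_vector q profile from [svd_rank()].
#' @param fraction Fraction of unmasked frames to treat as buffer
#'   (default 0.30).
#' @return List with `buffer_curve` ([sas_curve()]), `selected_ids`
#'   (0-based frame ids), `ranking` (tibble of frame id, p, C).
#' @export
select_buffer <- function(chromatogram, first_singular_vector,
                          fraction = 0.30) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)", call. = FALSE)
  rows <- which(chromatogram$present)
  v <- first_singular_vector
  vv <- sum(v^2)
  stats_list <- lapply(rows, function(i) {
    m <- chromatogram$M[i, ]
    s <- sum(m * v) / vv
    out <- tryCatch(cormap_values(m, s * v),
                    error = function(e) list(p_value = 1, C = 0L))
    c(p = out$p_value, C = out$C)
  })
  st <- do.call(rbind, stats_list)
  ord <- order(-st[, "p"], st[, "C"], rows)
  n_sel <- floor(fraction * length(rows))
  if (n_sel < 2) stop("fewer than 2 selectable buffer frames", call. = FALSE)
  sel_rows <- rows[ord[seq_len(n_sel)]]
  curves <- lapply(sel_rows, function(i) chromatogram_row(chromatogram, i))
  list(buffer_curve = sigma_weighted_average(curves),
       selected_ids = sort(chromatogram$frame_ids[sel_rows]),
       ranking = tibble::tibble(frame_id = chromatogram$frame_ids[rows][ord],
                                p_value = st[ord, "p"], C = st[ord, "C"]))
}

# Ricker (Mexican-hat) wavelet, unit-energy normalization
ricker <- function(n, width) {
  t <- seq_len(n) - (n + 1) / 2
  a <- 2 / (sqrt(3 * width) * pi^0.25)
  a * (1 - (t / width)^2) * exp(-t^2 / (2 * width^2))
}

cwt_row <- function(x, width) {
  n <- min(10 * width, length(x))
  w <- ricker(n, width)
  as.vector(stats::filter(x, rev(w), sides = 2, circular = FALSE))
}

local_maxima <- function(x, order = 1) {
  n <- length(x)
  out <- logical(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - order); hi <- min(n, i + order)
    if (!is.na(x[i]) && x[i] == max(x[lo:hi], na.rm = TRUE) && x[i] > 0) out[i] <- TRUE
  }
  which(out)
}

#' Peak-picking on a subtracted chromatogram
#'
#' Finds elution fractions on the total-scattering trace (per-frame sum
#' over q of the buffer-subtracted intensities): the trace is smoothed by
#' median filtering (window 5), peaks are detected by a continuous wavelet
#' transform over a 5-50 frame width range (Ricker wavelet, ridge-line
#' linking, SNR filter), and each peak is expanded to the surrounding
#' region where the smoothed signal stays at or above 10% of the peak
#' height. Overlapping regions are split at the minimum between peaks.
#'
#' @param chromatogram_subtracted A `chromatogram` whose rows are
#'   buffer-subtracted, or a numeric vector already summed over q.
#' @param widths CWT width grid in frames.
#' @param min_snr Minimum ridge signal-to-noise (default 5).
#' @param boundary_fraction Fraction of peak height bounding a fraction.
#' @return List of half-open 1-based row ranges `c(start, end)`; empty
#'   list when no peak is found.
#' @export
find_fractions <- function(chromatogram_subtracted,
                           widths = c(5, 7, 10, 14, 20, 28, 38, 50),
                           min_snr = 5, boundary_fraction = 0.10) {
  if (inherits(chromatogram_subtracted, "chromatogram")) {
    total <- rowSums(chromatogram_subtracted$M)
    total[!chromatogram_subtracted$present] <- NA
  } else {
    total <- as.numeric(chromatogram_subtracted)
  }
  n <- length(total)
  # masked rows: linear interpolation so the convolutions stay defined
  if (anyNA(total)) {
    ok <- which(!is.na(total))
    if (length(ok) < 2) return(list())
    total <- stats::approx(ok, total[ok], xout = seq_len(n), rule = 2)$y
  }
  sm <- stats::runmed(total, 5)
  cwtm <- vapply(widths, function(w) cwt_row(sm, w), numeric(n))
  cwtm[is.na(cwtm)] <- 0
  noise <- stats::quantile(abs(cwtm[, 1]), 0.5) + 1e-12
  # ridge linking: walk from the largest width down, following maxima
  maxima <- lapply(seq_along(widths), function(j) {
    local_maxima(cwtm[, j], order = max(1L, floor(widths[j] / 2)))
  })
  ridges <- list()
  for (m in maxima[[length(widths)]]) {
    pos <- m; length_r <- 1L; best_snr <- cwtm[m, length(widths)] / noise
    for (j in rev(seq_len(length(widths) - 1L))) {
      cand <- maxima[[j]]
      if (!length(cand)) break
      d <- abs(cand - pos)
      if (min(d) > max(2, widths[j])) break
      pos <- cand[which.min(d)]
      length_r <- length_r + 1L
      best_snr <- max(best_snr, cwtm[pos, j] / noise)
    }
    if (length_r >= ceiling(length(widths) / 2) && best_snr >= min_snr) {
      ridges[[length(ridges) + 1L]] <- pos
    }
  }
  peaks <- sort(unique(unlist(ridges)))
  if (!length(peaks)) return(list())
  # merge peaks closer than the smallest width
  if (length(peaks) > 1) {
    keep <- c(TRUE, diff(peaks) > min(widths))
    peaks <- peaks[keep]
  }
  # expand each peak to its 10%-of-height region
  regions <- lapply(peaks, function(p) {
    thr <- boundary_fraction * sm[p]
    lo <- p; while (lo > 1 && sm[lo - 1] >= thr) lo <- lo - 1
    hi <- p; while (hi < n && sm[hi + 1] >= thr) hi <- hi + 1
    c(lo, hi + 1L)  # half-open
  })
  # split overlapping regions at the minimum between adjacent peaks
  if (length(regions) > 1) {
    for (j in seq_len(length(regions) - 1L)) {
      if (regions[[j]][2] > regions[[j + 1]][1]) {
        between <- peaks[j]:peaks[j + 1]
        cut <- between[which.min(sm[between])]
        regions[[j]][2] <- cut
        regions[[j + 1]][1] <- cut
      }
    }
  }
  regions
}

#' SAS analysis of one chromatographic fraction
#'
#' Averages the buffer-subtracted curves of a frame range
#' (inverse-variance weighting), then runs the chromatography-mode
#' analysis chain: Guinier-peak analysis first (the fast path, with the
#' window-search algorithm as fallback), dimensionless Kratky, Porod and
#' Rambo-Tainer invariants, and BIFT. A Guinier failure yields a partial
#' result with a failure status instead of an error.
#'
#' @param chromatogram A `chromatogram` (unsubtracted).
#' @param frame_range Half-open 1-based row range `c(start, end)`.
#' @param buffer_average Buffer [sas_curve()] from [select_buffer()].
#' @param do_bift Run BIFT (default TRUE; the slowest stage).
#' @return An object of class `fraction_result`.
#' @export
analyze_fraction <- function(chromatogram, frame_range, buffer_average,
                             do_bift = TRUE) {
  rows <- seq(frame_range[1], frame_range[2] - 1L)
  rows <- rows[rows >= 1 & rows <= nrow(chromatogram$M)]
  rows <- rows[chromatogram$present[rows]]
  if (!length(rows)) stop("frame range contains no usable frames", call. = FALSE)
  curves <- lapply(rows, function(i) {
    subtract_curves(chromatogram_row(chromatogram, i), buffer_average)
  })
  avg <- sigma_weighted_average(curves)
  guinier <- tryCatch(auto_gpa(avg), error = function(e) {
    tryCatch(auto_guinier(avg), error = function(e2) NULL)
  })
  # a fit whose Rg is statistically insignificant (pure-buffer fraction)
  # counts as a failure, not a result
  insignificant <- !is.null(guinier) &&
    (!is.finite(guinier$Rg) || !is.finite(guinier$sigma_Rg) ||
       guinier$sigma_Rg >= 0.3 * guinier$Rg)
  if (is.null(guinier) || !isTRUE(guinier$valid) || insignificant) {
    return(structure(list(frame_range = frame_range, curve = avg,
                          guinier = guinier, kratky = NULL,
                          invariants = NULL, pddf = NULL,
                          status = "guinier_failed"),
                     class = "fraction_result"))
  }
  kratky <- kratky_dimensionless(avg, guinier)
  invs <- tryCatch(sas_invariants(avg, guinier), error = function(e) NULL)
  pddf <- if (do_bift) tryCatch(bift_auto(avg), error = function(e) NULL) else NULL
  structure(list(frame_range = frame_range, curve = avg, guinier = guinier,
                 kratky = kratky, invariants = invs, pddf = pddf,
                 status = "ok"),
            class = "fraction_result")
}

#' @export
print.fraction_result <- function(x, ...) {
  cat(sprintf("<fraction> frames [%d, %d): %s", x$frame_range[1],
              x$frame_range[2], x$status))
  if (identical(x$status, "ok")) cat(sprintf(", Rg = %.3g nm", x$guinier$Rg))
  cat("\n")
  invisible(x)
}
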