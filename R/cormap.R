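#' Longest run of same-sign differences
#'
#' Core statistic of the correlation-map (CorMap) equivalence test: the
#' length of the longest contiguous block of channels where `a - b` keeps a
#' constant sign. Channels where `a == b` exactly are dropped (a
#' zero-probability event under continuous noise, but it must be
#' deterministic on integer-valued synthetic data).
#'
#' @param values_a,values_b Equal-length numeric vectors.
#' @return A list with `n` (usable channels) and `C` (longest run).
#' @export
longest_run <- function(values_a, values_b) {
  if (length(values_a) != length(values_b)) {
    stop("inputs must have equal length", call. = FALSE)
  }
  s <- sign(values_a - values_b)
  s <- s[s != 0]
  n <- length(s)
  if (n == 0) stop("zero usable channels (all values identical)", call. = FALSE)
  r <- rle(s)
  list(n = n, C = max(r$lengths))
}

#' Exact null distribution of the longest run
#'
#' Probability that the longest run of identical outcomes among `n` fair
#' Bernoulli trials is at least `c` (Schilling's longest-run distribution).
#' Computed by an absorbing-state dynamic programme over the current run
#' length: O(n c) time, additions of positive terms only, so it is exact in
#' double precision for small `n` (dyadic rationals) and free of overflow up
#' to n = 1e4 and beyond. For `c == n` the closed form `2^(1-n)` is used in
#' log space so that the log-probability survives double underflow.
#'
#' @param n Number of trials (>= 1).
#' @param c Run length threshold, `1 <= c <= n`.
#' @param log_p If `TRUE` return the natural log of the probability.
#' @return Probability (or its log), a bare scalar.
#' @export
prob_longest_run_ge <- function(n, c, log_p = FALSE) {
  n <- as.integer(n); c <- as.integer(c)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (c < 1 || c > n) stop("require 1 <= c <= n", call. = FALSE)
  if (c == 1L) return(if (log_p) 0 else 1)
  if (c == n) {
    # 2^(1-n), exactly representable down to the double denormals; the log
    # form keeps the value reportable beyond underflow
    if (log_p) return((1 - n) * log(2))
    return(if (n <= 1070) 2^(1 - n) else 0)
  }
  if (n <= 50L) {
    # integer-count DP: sequence counts stay below 2^50, so every double is
    # an exact integer and p is the exact dyadic rational
    v <- numeric(c - 1L); v[1] <- 2
    absorbed <- 0
    for (i in seq_len(n - 1L)) {
      absorbed <- 2 * absorbed + v[c - 1L]
      v <- c(sum(v), v[seq_len(c - 2L)])
    }
    p <- absorbed / 2^n
  } else {
    # probability-space DP: positive additions only, no overflow at any n
    v <- numeric(c - 1L); v[1] <- 1
    absorbed <- 0
    for (i in seq_len(n - 1L)) {
      grow <- v / 2             # next flip equal: run length j -> j + 1
      restart <- sum(v) / 2     # next flip different: run length -> 1
      absorbed <- absorbed + grow[c - 1L]
      v <- c(restart, grow[seq_len(c - 2L)])
    }
    p <- min(absorbed, 1)
  }
  if (log_p) log(p) else p
}

#' CorMap equivalence test between two curves
#'
#' Non-parametric test of whether two scattering curves are statistically
#' identical: under the null the sign of each channel difference is a fair
#' coin, so the observed longest run of same-sign differences `C` is
#' compared against its exact null distribution. A small p-value means the
#' curves differ systematically (e.g. radiation damage between frames).
#'
#' @param curve_a,curve_b [sas_curve()]s on the *same* q grid (exact match;
#'   no interpolation is attempted).
#' @param q_range Optional numeric length-2, restrict the test to
#'   `q_range[1] <= q <= q_range[2]`.
#' @param threshold Equivalence threshold on the p-value.
#' @return An object of class `cormap_outcome`: list with `n`, `C`,
#'   `p_value`, `log_p`, `equivalent`.
#' @export
cormap_test <- function(curve_a, curve_b, q_range = NULL, threshold = 0.01) {
  stopifnot(inherits(curve_a, "sas_curve"), inherits(curve_b, "sas_curve"))
  if (nrow(curve_a) != nrow(curve_b) || !isTRUE(all.equal(curve_a$q, curve_b$q))) {
    stop("q grids do not match exactly; CorMap does not interpolate", call. = FALSE)
  }
  keep <- rep(TRUE, nrow(curve_a))
  if (!is.null(q_range)) keep <- curve_a$q >= q_range[1] & curve_a$q <= q_range[2]
  if (!any(keep)) stop("q_range excludes all points", call. = FALSE)
  cormap_values(curve_a$I[keep], curve_b$I[keep], threshold)
}

# vector-level CorMap (used on chromatogram rows where no sas_curve exists)
cormap_values <- function(a, b, threshold = 0.01) {
  lr <- longest_run(a, b)
  p <- prob_longest_run_ge(lr$n, lr$C)
  lp <- prob_longest_run_ge(lr$n, lr$C, log_p = TRUE)
  structure(list(n = lr$n, C = lr$C, p_value = p, log_p = lp,
                 equivalent = p >= threshold),
            class = "cormap_outcome")
}

#' @export
print.cormap_outcome <- function(x, ...) {
  cat(sprintf("<cormap> n = %d, C = %d, p = %.4g (%s)\n", x$n, x$C, x$p_value,
              if (x$equivalent) "equivalent" else "different"))
  invisible(x)
}

#' Select the equivalent prefix of a frame series
#'
#' Applies the CorMap test pairwise over curves in acquisition order and
#' accepts frames while (i) each adjacent pair stays above
#' `threshold_adjacent` and (ii) each frame stays above `threshold_any`
#' against the first accepted frame. Acceptance is a contiguous prefix in
#' time: radiation damage accumulates, so once a frame fails, it and all
#' later frames are discarded.
#'
#' @param curves List of [sas_curve()]s on a common q grid, acquisition order.
#' @param threshold_adjacent p-value threshold for adjacent pairs (default
#'   0.01).
#' @param threshold_any p-value threshold against the first frame (default
#'   0.001).
#' @return List with `accepted` (integer indices, 1-based, always starting
#'   at 1) and `p_matrix` (full symmetric matrix of pairwise p-values).
#' @export
pairwise_equivalence <- function(curves, threshold_adjacent = 0.01,
                                 threshold_any = 0.001) {
  k <- length(curves)
  if (k < 1) stop("need at least one curve", call. = FALSE)
  pm <- matrix(1, k, k)
  if (k > 1) {
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      p <- tryCatch(cormap_test(curves[[i]], curves[[j]])$p_value,
                    error = function(e) 1)  # identical curves: no evidence of difference
      pm[i, j] <- pm[j, i] <- p
    }
  }
  accepted <- 1L
  if (k > 1) {
    for (j in 2:k) {
      ok <- pm[j - 1, j] >= threshold_adjacent && pm[1, j] >= threshold_any
      if (!ok) break
      accepted <- c(accepted, j)
    }
  }
  list(accepted = accepted, p_matrix = pm)
}
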