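#' Rambo-Tainer mass-calibration constants
#'
#' Versioned table of the empirical constants relating `Q_R = V_c^2 / Rg`
#' to molecular mass, per molecule class, in the angstrom-based units of
#' the original calibration. Exposed as data rather than hard-coded so the
#' provenance (reference and version) travels with every mass estimate.
#'
#' @return A tibble with columns `class`, `c`, `k`, `units`, `reference`,
#'   `version`.
#' @export
rambo_tainer_constants <- function() {
  tibble::tibble(
    class = c("protein", "rna"),
    c = c(0.1231, 0.00934),
    k = c(1.0, 0.808),
    units = "Q_R in A^3; mass in Da",
    reference = "Rambo & Tainer (2013) volume-of-correlation calibration",
    version = "2013.1"
  )
}

# Closed-form Guinier head integrals on [0, qmin]:
#   int q^2 I0 exp(-a q^2) dq  and  int q I0 exp(-a q^2) dq, a = Rg^2/3
guinier_head_q2 <- function(qmin, Rg, I0) {
  a <- Rg^2 / 3
  erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
  I0 * (sqrt(pi) / (4 * a^1.5) * erf(qmin * sqrt(a)) -
          qmin / (2 * a) * exp(-a * qmin^2))
}
guinier_head_q1 <- function(qmin, Rg, I0) {
  a <- Rg^2 / 3
  I0 * (1 - exp(-a * qmin^2)) / (2 * a)
}

#' Dimensionless Kratky representation
#'
#' `x = q Rg`, `y = (q Rg)^2 I / I0`: a scale-free flexibility diagnostic.
#' Globular particles peak at `(sqrt(3), 3/e)`; ideal flexible chains
#' plateau at 2.
#'
#' @param curve A [sas_curve()].
#' @param guinier A `guinier_result` providing Rg and I0.
#' @return A tibble with columns `x` and `y`.
#' @export
kratky_dimensionless <- function(curve, guinier) {
  stopifnot(inherits(curve, "sas_curve"))
  if (!isTRUE(guinier$I0 > 0)) stop("I0 must be > 0", call. = FALSE)
  x <- curve$q * guinier$Rg
  tibble::tibble(x = x, y = x^2 * curve$I / guinier$I0)
}

#' Porod invariant and Porod volume
#'
#' `Q_p = integral q^2 I dq` over `[0, Inf)`, assembled from three pieces:
#' the closed-form Guinier extrapolation on `[0, qmin]`, trapezoid
#' quadrature over the measured range, and a `K/q^4` Porod tail fitted on
#' the last decade of the curve and extended to infinity. The Porod volume
#' follows as `V_p = 2 pi^2 I0 / Q_p` — for a homogeneous particle it is
#' the particle volume, independent of intensity scale.
#'
#' @param curve A background-subtracted [sas_curve()].
#' @param guinier A `guinier_result` for the same curve.
#' @param tail_decades Width (in decades of q) of the Porod tail-fit range.
#' @return List with `Q_p`, `V_p`, `porod_constant`, `flagged` (TRUE when
#'   the tail fit came out non-positive and the tail was dropped).
#' @export
porod <- function(curve, guinier, tail_decades = 1) {
  stopifnot(inherits(curve, "sas_curve"))
  q <- curve$q; I <- curve$I
  head <- guinier_head_q2(q[1], guinier$Rg, guinier$I0)
  body <- pracma::trapz(q, q^2 * I)
  tail_idx <- which(q >= max(q) / 10^tail_decades)
  # Porod-plateau estimate: mean of I q^4 over the last decade, weighted
  # uniformly in log q (equal weight per resolution interval) so the
  # high-q form-factor oscillations do not dominate the average
  qt <- q[tail_idx]; yt <- (I * q^4)[tail_idx]
  K <- if (length(qt) > 2) {
    pracma::trapz(log(qt), yt) / (log(max(qt)) - log(min(qt)))
  } else mean(yt)
  flagged <- !is.finite(K) || K <= 0
  tail <- if (flagged) 0 else K / max(q)
  Q_p <- head + body + tail
  list(Q_p = Q_p, V_p = 2 * pi^2 * guinier$I0 / Q_p,
       porod_constant = K, flagged = flagged)
}

#' Rambo-Tainer invariants and mass estimate
#'
#' Volume of correlation `V_c = I0 / integral q I dq` over `[0, q_cut]`
#' (Guinier closed form on the unmeasured head), `Q_R = V_c^2 / Rg`, and
#' the empirical molecular-mass estimate `(Q_R / c)^k` using the constants
#' of [rambo_tainer_constants()] for the requested molecule class. `V_c`
#' and `Q_R` are intensity-scale invariant.
#'
#' @param curve A background-subtracted [sas_curve()].
#' @param guinier A `guinier_result` for the same curve.
#' @param molecule_class `"protein"` or `"rna"`.
#' @param q_cut Integration cutoff, nm^-1; default `8 / Rg` capped at the
#'   curve maximum.
#' @return List with `V_c` (nm^2), `Q_R` (nm^3), `mass_kda`, `mass_method`
#'   (constants provenance), `q_cut`, `flagged` (TRUE when the curve ends
#'   before `q_cut` and the available range was used).
#' @export
rambo_tainer <- function(curve, guinier, molecule_class = c("protein", "rna"),
                         q_cut = NULL) {
  stopifnot(inherits(curve, "sas_curve"))
  molecule_class <- match.arg(molecule_class)
  q <- curve$q; I <- curve$I
  want <- if (is.null(q_cut)) 8 / guinier$Rg else q_cut
  flagged <- want > max(q)
  cut <- min(want, max(q))
  keep <- q <= cut
  integral <- guinier_head_q1(q[1], guinier$Rg, guinier$I0) +
    pracma::trapz(q[keep], (q * I)[keep])
  V_c <- guinier$I0 / integral
  Q_R <- V_c^2 / guinier$Rg
  const <- rambo_tainer_constants()
  row <- const[const$class == molecule_class, ]
  # constants are angstrom-based: V_c nm^2 -> A^2 (x100), Rg nm -> A (x10)
  Q_R_A3 <- (V_c * 100)^2 / (guinier$Rg * 10)
  mass_da <- (Q_R_A3 / row$c)^row$k
  list(V_c = V_c, Q_R = Q_R, mass_kda = mass_da / 1000,
       mass_method = paste0("rambo-tainer:", molecule_class, ":", row$version),
       q_cut = cut, flagged = flagged)
}

#' All size/mass invariants of a subtracted curve
#'
#' Convenience wrapper bundling the dimensionless Kratky arrays, the Porod
#' invariant/volume and the Rambo-Tainer invariants into one result.
#'
#' @inheritParams rambo_tainer
#' @return An object of class `sas_invariants`.
#' @export
sas_invariants <- function(curve, guinier, molecule_class = "protein") {
  kr <- kratky_dimensionless(curve, guinier)
  po <- porod(curve, guinier)
  rt <- rambo_tainer(curve, guinier, molecule_class)
  structure(list(kratky = kr, Q_p = po$Q_p, V_p = po$V_p,
                 porod_flagged = po$flagged,
                 V_c = rt$V_c, Q_R = rt$Q_R, mass_kda = rt$mass_kda,
                 mass_method = rt$mass_method, q_cut = rt$q_cut,
                 rt_flagged = rt$flagged, Rg = guinier$Rg, I0 = guinier$I0),
            class = "sas_invariants")
}

#' @export
print.sas_invariants <- function(x, ...) {
  cat(sprintf(
    "<invariants> V_p = %.4g nm^3, Q_p = %.4g, V_c = %.4g nm^2, Q_R = %.4g nm^3, mass ~ %.3g kDa (%s)\n",
    x$V_p, x$Q_p, x$V_c, x$Q_R, x$mass_kda, x$mass_method))
  invisible(x)
}
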