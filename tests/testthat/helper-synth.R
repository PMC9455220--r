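# shared synthetic fixtures (built in code, never stored)

SPHERE_R <- 3
SPHERE_RG <- sqrt(3 / 5) * SPHERE_R   # 2.3238 nm
SPHERE_I0 <- 100

sphere_curve <- function(n = 1000, qmax = 5, R = SPHERE_R, I0 = SPHERE_I0,
                         background = 0) {
  q <- seq(0.05, qmax, length.out = n)
  sas_curve(q, sphere_intensity(q, R, I0) + background)
}

noisy_sphere <- function(seed, exposure = 1e5, n = 1000, qmax = 5) {
  add_noise(sphere_curve(n = n, qmax = qmax), exposure, seed = seed)
}

guinier_curve <- function(Rg = 2, I0 = 100, n = 500, qmax = 3) {
  q <- seq(0.01, qmax, length.out = n)
  sas_curve(q, guinier_intensity(q, Rg, I0))
}

# brute-force longest-run null distribution: enumerate all 2^n fair-coin
# sequences via bit arithmetic and tabulate the maximum run length
brute_longest_run_tail <- function(n) {
  ints <- 0:(2^n - 1)
  cur <- rep(1L, length(ints))
  mx <- rep(1L, length(ints))
  prev <- ints %% 2L
  x <- ints %/% 2L
  for (b in seq_len(n - 1)) {
    bit <- x %% 2L
    same <- bit == prev
    cur <- ifelse(same, cur + 1L, 1L)
    mx <- pmax(mx, cur)
    prev <- bit
    x <- x %/% 2L
  }
  counts <- tabulate(mx, n)
  # tail probability P(max run >= c) for c = 1..n
  rev(cumsum(rev(counts))) / 2^n
}
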