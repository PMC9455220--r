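test_that("diode-weighted averaging is a ratio of sums", {
  geo <- sas_geometry(0.1, 1000, c(1, 1), 0.5, c(1, 1))
  stack <- frame_stack(array(c(10, 30), dim = c(2, 1, 1)), c(1, 3), geo)
  avg <- average_frames(stack)
  expect_equal(as.vector(avg$values), 10)       # 40 / 4
  expect_equal(as.vector(avg$variance), 2.5)    # 40 / 16
  expect_equal(avg$total_monitor, 4)
  expect_equal(avg$n_frames_used, 2)

  # identical frames, equal monitors: values = F / d exactly
  stack2 <- frame_stack(array(rep(12, 3), dim = c(3, 1, 1)), rep(2, 3), geo)
  expect_equal(as.vector(average_frames(stack2)$values), 6)

  expect_error(frame_stack(array(1, dim = c(1, 1, 1)), 0, geo), "monitor")
  expect_error(average_frames(stack, accepted_ids = 99L), "present")
})

test_that("averaging is permutation invariant and unbiased", {
  geo <- default_geometry(c(32, 32))
  st <- make_frames(function(q) rep(20, length(q)), geo, 4,
                    monitor_values = c(1, 2, 3, 4), seed = 1)
  a <- average_frames(st, accepted_ids = c(0, 1, 2, 3))
  b <- average_frames(st, accepted_ids = c(3, 1, 0, 2))
  expect_equal(a$values, b$values)

  # E[average] unbiased over replicate stacks (binned to keep it cheap)
  means <- vapply(1:300, function(s) {
    stk <- make_frames(function(q) rep(5, length(q)), geo, 2,
                       monitor_values = c(1, 3), seed = s)
    mean(average_frames(stk)$values)
  }, numeric(1))
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - 5), 3 * se)
})

test_that("uniform frames integrate to a flat curve with zero variance", {
  geo <- default_geometry(c(64, 64))
  v <- matrix(7, 64, 64)
  cv <- azimuthal_integrate(v, matrix(0, 64, 64), geo, n_bins = 30)
  expect_true(all(abs(cv$I - 7) < 1e-12))
  expect_true(all(cv$sigma == 0))
})

test_that("bin count controls resolution without breaking recovery", {
  geo <- default_geometry()
  model <- function(q) sphere_intensity(q, 3, 100) + 50
  st <- make_frames(model, geo, 1, noise = FALSE)
  avg <- average_frames(st)
  c200 <- azimuthal_integrate(avg, n_bins = 200)
  c400 <- azimuthal_integrate(avg, n_bins = 400)
  expect_lt(max(abs(c200$I - model(c200$q)) / model(c200$q)), 0.01)
  expect_lt(max(abs(c400$I - model(c400$q)) / model(c400$q)), 0.02)
})

test_that("2D subtraction cancels matched signal and adds variance", {
  geo <- default_geometry(c(64, 64))
  st <- make_frames(function(q) rep(9, length(q)), geo, 2, noise = FALSE)
  avg <- average_frames(st)
  diff <- subtract_frames(avg, avg)
  expect_true(all(diff$values == 0))
  expect_equal(diff$variance, 2 * avg$variance)

  small <- sas_geometry(0.1, 1000, c(1, 1), 0.5, c(2, 2))
  other <- average_frames(frame_stack(array(1, c(1, 2, 2)), 1, small))
  expect_error(subtract_frames(avg, other), "shape")
})

test_that("sample-minus-buffer recovers the particle within counting noise", {
  geo <- default_geometry()
  sample_model <- function(q) sphere_intensity(q, 3, 100) + 50
  buffer_model <- function(q) rep(50, length(q))
  st_s <- make_frames(sample_model, geo, 5, seed = 1)
  st_b <- make_frames(buffer_model, geo, 5, seed = 2)
  sub <- subtract_frames(average_frames(st_s), average_frames(st_b))
  cv <- azimuthal_integrate(sub, n_bins = 150)
  truth <- sphere_intensity(cv$q, 3, 100)
  chi2_red <- mean(((cv$I - truth) / cv$sigma)^2)
  expect_lte(chi2_red, 1.5)
})

test_that("monitor-weighted 1D averaging equals the 2D route exactly", {
  geo <- default_geometry(c(64, 64))
  model <- function(q) sphere_intensity(q, 3, 100) + 50
  st <- make_frames(model, geo, 3, monitor_values = c(1, 10, 4),
                    noise = FALSE)
  route_2d <- azimuthal_integrate(average_frames(st), n_bins = 100)
  per_frame <- lapply(1:3, function(k) {
    azimuthal_integrate(st$frames[k, , ] / st$monitor[k],
                        st$frames[k, , ] / st$monitor[k]^2,
                        geo, n_bins = 100)
  })
  route_1d <- weighted_average_curves(per_frame, st$monitor)
  expect_lt(max(abs(route_1d$I - route_2d$I) / pmax(route_2d$I, 1e-12)), 1e-10)

  # equal monitors: the weighted average is the plain mean
  eq <- weighted_average_curves(per_frame, rep(2, 3))
  plain <- Reduce(`+`, lapply(per_frame, `[[`, "I")) / 3
  expect_equal(eq$I, plain)
})

test_that("a plain mean of normalized curves differs once monitors differ", {
  geo <- default_geometry(c(64, 64))
  model <- function(q) sphere_intensity(q, 3, 100) + 50
  # monitors (1, 10) with strongly differing count levels, Poisson noise
  st <- make_frames(model, geo, 2, monitor_values = c(1, 10), seed = 8)
  route_2d <- azimuthal_integrate(average_frames(st), n_bins = 100)
  per_frame <- lapply(1:2, function(k) {
    azimuthal_integrate(st$frames[k, , ] / st$monitor[k],
                        st$frames[k, , ] / st$monitor[k]^2,
                        geo, n_bins = 100)
  })
  plain <- Reduce(`+`, lapply(per_frame, `[[`, "I")) / 2
  expect_gt(max(abs(plain - route_2d$I) / pmax(route_2d$I, 1e-12)), 1e-3)
})

test_that("sigma shrinks with total monitor on identical-model frames", {
  geo <- default_geometry(c(64, 64))
  model <- function(q) rep(30, length(q))
  s1 <- azimuthal_integrate(average_frames(
    make_frames(model, geo, 1, seed = 1)), n_bins = 50)
  s16 <- azimuthal_integrate(average_frames(
    make_frames(model, geo, 16, seed = 1)), n_bins = 50)
  expect_equal(median(s16$sigma / s1$sigma), 1 / 4, tolerance = 0.1)
})

test_that("subtract_curves and sigma weighting propagate uncertainties", {
  a <- noisy_sphere(1, n = 100)
  b <- noisy_sphere(2, n = 100)
  d <- subtract_curves(a, b)
  expect_equal(d$sigma, sqrt(a$sigma^2 + b$sigma^2))
  w <- sigma_weighted_average(list(a, b))
  expect_true(all(w$sigma < pmax(a$sigma, b$sigma)))
  expect_error(subtract_curves(a, noisy_sphere(1, n = 90)), "q grids")
})
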