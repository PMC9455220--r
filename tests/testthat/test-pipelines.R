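mf_spec <- function(..., n_frames = 10, seed = 42) {
  utils::modifyList(
    list(kind = "simulate", model = "sphere", R = 3, I0 = 100,
         buffer_level = 50, n_frames = n_frames, seed = seed,
         shape = c(96, 96)),
    list(...))
}

mf_job <- function(frames, output = NULL, params = list(n_bins = 120)) {
  list(schema_version = "1", job_id = "t", pipeline = "multiframe",
       inputs = list(frames = frames), params = params, output = output)
}

test_that("identical noiseless frames all pass and average to themselves", {
  job <- mf_job(mf_spec(noise = FALSE))
  res <- run_multiframe(job)
  expect_equal(res$status, "success")
  eq <- res$bundle$stages$equivalence$outputs
  expect_equal(eq$n_accepted, 10)
  per_frame_I <- res$bundle$stages$integration$outputs$I[1, ]
  expect_equal(res$curve$I, per_frame_I, tolerance = 1e-12)
})

test_that("a perturbed tenth frame is discarded, nine are kept", {
  job <- mf_job(mf_spec(frame_scale = c(rep(1, 9), 1.2)))
  res <- run_multiframe(job)
  eq <- res$bundle$stages$equivalence$outputs
  expect_equal(eq$n_accepted, 9)
  expect_equal(sort(eq$accepted_ids), 0:8)
  expect_equal(res$bundle$stages$average$outputs$n_frames_used, 9)
})

test_that("saved jobs replay to bit-identical curves", {
  dir <- withr::local_tempdir()
  jp <- file.path(dir, "job.json")
  write_job(mf_job(mf_spec(), output = file.path(dir, "out.h5")), jp)
  r1 <- replay_job(jp)
  c1 <- read_result_curve(file.path(dir, "out.h5"),
                          "entry/4_integrate_average/outputs/curve")
  r2 <- replay_job(jp)
  c2 <- read_result_curve(file.path(dir, "out.h5"),
                          "entry/4_integrate_average/outputs/curve")
  expect_identical(c1$I, c2$I)
  expect_identical(c1$sigma, c2$sigma)
  expect_equal(r1$status, "success")
})

test_that("the subtraction pipeline recovers Rg end to end", {
  job <- list(schema_version = "1", job_id = "s", pipeline = "subtract",
              inputs = list(
                sample = mf_spec(seed = 11),
                buffers = list(mf_spec(model = "buffer", seed = 12),
                               mf_spec(model = "buffer", seed = 13))),
              params = list(n_bins = 120, do_bift = FALSE))
  res <- run_subtract(job)
  expect_equal(res$bundle$stages$buffer_comparison$outputs$used, c(1, 2))
  expect_lt(abs(res$guinier$Rg - sqrt(3 / 5) * 3) / (sqrt(3 / 5) * 3), 0.03)
})

test_that("an inconsistent buffer is dropped with a recorded warning", {
  job <- list(schema_version = "1", job_id = "s2", pipeline = "subtract",
              inputs = list(
                sample = mf_spec(seed = 11),
                buffers = list(mf_spec(model = "buffer", seed = 12),
                               mf_spec(model = "buffer", seed = 13,
                                       buffer_level = 65))),
              params = list(n_bins = 120, do_bift = FALSE))
  res <- run_subtract(job)
  st1 <- res$bundle$stages$buffer_comparison$outputs
  expect_equal(st1$used, 1)
  expect_match(st1$warning, "subset")
})

test_that("sample identical to buffer degrades to a partial result", {
  job <- list(schema_version = "1", job_id = "s3", pipeline = "subtract",
              inputs = list(
                sample = mf_spec(model = "buffer", seed = 21),
                buffers = list(mf_spec(model = "buffer", seed = 22))),
              params = list(n_bins = 120, do_bift = FALSE))
  res <- run_subtract(job)
  expect_equal(res$status, "partial")
  tab <- res$stages
  expect_equal(tab$status[tab$name == "guinier"], "failed")
  expect_equal(tab$status[tab$name == "kratky"], "skipped")
  # subtracted signal consistent with zero
  cv <- res$bundle$stages$integration$outputs$curve
  expect_lt(median(abs(cv$I) / cv$sigma), 2)
})

test_that("the HPLC pipeline handles gaps and single files", {
  job <- list(schema_version = "1", job_id = "h", pipeline = "hplc",
              inputs = list(sec = list(kind = "default_sim", seed = 7,
                                       missing_blocks = 0)),
              params = list(do_bift = FALSE))
  res <- run_hplc(job)
  expect_equal(res$status, "success")
  expect_false(any(res$bundle$stages$chromatogram$outputs$present[1:100]))
  expect_equal(res$bundle$stages$fractions$outputs$n_fractions, 2)
  for (f in res$fractions) {
    expect_equal(f$status, "ok")
  }
})

test_that("job schema violations are reported by field", {
  expect_error(validate_job(list(pipeline = "multiframe", inputs = list())),
               "schema_version")
  expect_error(validate_job(list(schema_version = "99",
                                 pipeline = "multiframe", inputs = list())),
               "99.*1|1.*99")
  expect_error(validate_job(list(schema_version = "1", pipeline = "bogus",
                                 inputs = list())),
               "pipeline")
  expect_error(validate_job(list(schema_version = "1",
                                 pipeline = "multiframe")),
               "inputs")
})

test_that("batches replay sequentially in input order", {
  dir <- withr::local_tempdir()
  paths <- vapply(1:3, function(k) {
    p <- file.path(dir, sprintf("j%d.json", k))
    write_job(mf_job(mf_spec(seed = k, n_frames = 3)), p)
    p
  }, character(1))
  res <- replay_job(paths)
  expect_length(res, 3)
  expect_true(all(vapply(res, function(r) r$status == "success", logical(1))))
})

test_that("every output bundle embeds the job that produced it", {
  dir <- withr::local_tempdir()
  out <- file.path(dir, "mf.h5")
  job <- mf_job(mf_spec(n_frames = 3), output = out)
  run_multiframe(job)
  raw <- rhdf5::h5read(out, "entry/provenance/job_json")
  back <- jsonlite::fromJSON(as.character(raw))
  expect_equal(back$pipeline, "multiframe")
  expect_equal(back$inputs$frames$seed, 42)
})
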