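test_that("three-column files parse into curves and roundtrip losslessly", {
  f <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("# sample: demo", "0.1 10 1", "0.2 5 1", "0.3 2 1"), f)
  cv <- read_dat(f)
  expect_s3_class(cv, "sas_curve")
  expect_equal(nrow(cv), 3)
  expect_equal(cv$q, c(0.1, 0.2, 0.3))
  expect_true("sigma" %in% names(cv))

  # roundtrip at full double precision
  cv2 <- sas_curve(seq(0.013, 2, length.out = 57),
                   exp(stats::runif(57)), sqrt(stats::runif(57)))
  g <- withr::local_tempfile(fileext = ".dat")
  write_dat(cv2, g)
  back <- read_dat(g)
  expect_identical(back$q, cv2$q)
  expect_identical(back$I, cv2$I)
  expect_identical(back$sigma, cv2$sigma)
  # header + payload structure
  lines <- readLines(g)
  expect_equal(sum(!grepl("^#", lines)), 57)
  expect_true(any(grepl("q_unit", lines)))
})

test_that("two-column files yield sigma-free curves", {
  f <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("0.1 10", "0.2 5"), f)
  cv <- read_dat(f)
  expect_false("sigma" %in% names(cv))
})

test_that("reader reports malformed input with line numbers", {
  f <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("0.1 10 1", "0.2 5 -1", "0.3 2 1"), f)
  expect_error(read_dat(f), "line 2")

  g <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("0.2 5 1", "0.1 10 1"), g)
  expect_error(read_dat(g), "increasing")

  expect_error(read_dat(withr::local_tempfile(fileext = ".dat")), "not found")
})

test_that("angstrom q units are converted to inverse nanometres on load", {
  f <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("# q_unit: angstrom^-1", "0.01 10 1", "0.02 5 1"), f)
  cv <- read_dat(f)
  expect_equal(cv$q, c(0.1, 0.2))
  g <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("0.01 10 1", "0.02 5 1"), g)
  expect_equal(read_dat(g, q_unit = "angstrom^-1")$q, c(0.1, 0.2))
})

test_that("empty curves write header-only files without error", {
  f <- withr::local_tempfile(fileext = ".dat")
  write_dat(sas_curve(numeric(0), numeric(0), numeric(0)), f)
  lines <- readLines(f)
  expect_true(all(grepl("^#", lines)))
  expect_equal(nrow(read_dat(f)), 0)
})

test_that("curve constructor enforces its invariants", {
  expect_error(sas_curve(c(0.2, 0.1), c(1, 2)), "increasing")
  expect_error(sas_curve(c(-0.1, 0.1), c(1, 2)), "non-negative")
  expect_error(sas_curve(c(NA, 0.1), c(1, 2)), "NaN")
  expect_error(sas_curve(c(0.1, 0.2), c(1, 2), c(1, -1)), "negative sigma")
  expect_error(sas_curve(c(0.1), c(1, 2)), "length")
})

test_that("HDF5 bundles hold one group per stage with configs and errors", {
  path <- withr::local_tempfile(fileext = ".h5")
  cv <- sphere_curve(n = 50)
  bundle <- list(
    pipeline = "subtract",
    stages = list(
      buffer_comparison = list(config = list(threshold = 0.01),
                               outputs = list(p_matrix = diag(2))),
      subtraction = list(config = list(), outputs = list(values = matrix(1, 2, 2))),
      integration = list(config = list(n_bins = 50), outputs = list(curve = cv)),
      guinier = list(config = list(), outputs = NULL, error = "no Guinier region"),
      kratky = list(config = list(), outputs = NULL, error = "skipped"),
      invariants = list(config = list(), outputs = NULL, error = "skipped"),
      bift = list(config = list(), outputs = NULL, error = "skipped")),
    default_plot = "entry/3_integration/outputs/curve",
    inputs = c("/data/raw_001.h5"),
    job = list(pipeline = "subtract", schema_version = "1"))
  write_result_h5(bundle, path)
  ls <- rhdf5::h5ls(path)
  groups <- ls$name[ls$group == "/entry"]
  expect_true(all(sprintf("%d_%s", 1:7, names(bundle$stages)) %in% groups))
  # every stage group carries a machine-readable configuration
  for (k in 1:7) {
    cfg <- rhdf5::h5read(path, sprintf("entry/%d_%s/configuration",
                                       k, names(bundle$stages)[k]))
    expect_type(as.character(cfg), "character")
  }
  expect_equal(as.character(rhdf5::h5read(path, "entry/4_guinier/error")),
               "no Guinier region")
  # curve payload roundtrips
  back <- read_result_curve(path, "entry/3_integration/outputs/curve")
  expect_equal(back$q, cv$q)
  expect_equal(back$I, cv$I)
})

test_that("re-writing a bundle yields identical payload datasets", {
  cv <- noisy_sphere(seed = 3, n = 120)
  bundle <- list(pipeline = "multiframe",
                 stages = list(integrate = list(config = list(n_bins = 120),
                                                outputs = list(curve = cv))),
                 inputs = character(0))
  p1 <- withr::local_tempfile(fileext = ".h5")
  p2 <- withr::local_tempfile(fileext = ".h5")
  write_result_h5(bundle, p1)
  write_result_h5(bundle, p2)
  a <- read_result_curve(p1, "entry/1_integrate/outputs/curve")
  b <- read_result_curve(p2, "entry/1_integrate/outputs/curve")
  expect_identical(a$I, b$I)
  expect_identical(a$sigma, b$sigma)
})

test_that("empty bundles still produce a valid file with provenance", {
  path <- withr::local_tempfile(fileext = ".h5")
  write_result_h5(list(pipeline = "multiframe", stages = list(),
                       inputs = "/nowhere/x.h5"), path)
  ls <- rhdf5::h5ls(path)
  expect_true("provenance" %in% ls$name)
})

test_that("extract_ascii exports every stored curve as .dat", {
  path <- withr::local_tempfile(fileext = ".h5")
  cv <- sphere_curve(n = 40)
  write_result_h5(list(pipeline = "multiframe",
                       stages = list(integrate = list(config = list(),
                                                      outputs = list(curve = cv)))),
                  path)
  dir <- withr::local_tempdir()
  files <- extract_ascii(path, dir)
  expect_length(files, 1)
  expect_equal(read_dat(files[1])$I, cv$I)
})
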