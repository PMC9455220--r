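#' @importFrom jsonlite toJSON fromJSON read_json write_json
NULL

JOB_SCHEMA_VERSION <- "1"

#' Write a job description to JSON
#'
#' Jobs are plain lists with fields `schema_version`, `job_id`, `pipeline`
#' (`"multiframe"`, `"subtract"` or `"hplc"`), `inputs`, `params` and
#' optionally `output` (an HDF5 path). A saved job replays
#' bit-reproducibly: all randomness is seeded from the job itself.
#'
#' @param job Job description list.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_job <- function(job, path) {
  if (is.null(job$schema_version)) job$schema_version <- JOB_SCHEMA_VERSION
  jsonlite::write_json(job, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read and validate a job description
#'
#' @param path JSON path.
#' @return The job list.
#' @export
read_job <- function(path) {
  job <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_job(job)
  job
}

validate_job <- function(job) {
  if (is.null(job$schema_version)) {
    stop("job is missing field `schema_version`", call. = FALSE)
  }
  if (!identical(as.character(job$schema_version), JOB_SCHEMA_VERSION)) {
    stop(sprintf("job schema_version %s not supported (this package speaks %s)",
                 job$schema_version, JOB_SCHEMA_VERSION), call. = FALSE)
  }
  if (is.null(job$pipeline) ||
      !job$pipeline %in% c("multiframe", "subtract", "hplc")) {
    stop("job field `pipeline` must be one of multiframe/subtract/hplc",
         call. = FALSE)
  }
  if (is.null(job$inputs)) stop("job is missing field `inputs`", call. = FALSE)
  invisible(job)
}

# Build a frame stack from a declarative spec (the simulate kind keeps job
# replay self-contained; the rds kind points at a stack saved on disk).
simulate_stack <- function(spec) {
  kind <- if (is.null(spec$kind)) "simulate" else spec$kind
  if (kind == "rds") return(readRDS(spec$path))
  shape <- if (is.null(spec$shape)) c(128, 128) else unlist(spec$shape)
  geo <- default_geometry(shape)
  model <- if (is.null(spec$model)) "sphere" else spec$model
  R <- if (is.null(spec$R)) 3 else spec$R
  I0 <- if (is.null(spec$I0)) 100 else spec$I0
  bg <- if (is.null(spec$buffer_level)) 50 else spec$buffer_level
  fn <- switch(model,
    sphere = function(q) sphere_intensity(q, R, I0) + bg,
    gaussian_chain = function(q) gaussian_chain_intensity(q, R, I0) + bg,
    buffer = function(q) rep(bg, length(q)),
    stop("unknown frame model: ", model, call. = FALSE))
  n <- if (is.null(spec$n_frames)) 10L else as.integer(spec$n_frames)
  monitors <- if (is.null(spec$monitors)) rep(1, n) else unlist(spec$monitors)
  make_frames(fn, geo, n, monitor_values = monitors,
              seed = if (is.null(spec$seed)) 0L else spec$seed,
              noise = !isFALSE(spec$noise),
              frame_scale = if (is.null(spec$frame_scale)) rep(1, n)
                            else unlist(spec$frame_scale))
}

new_job_result <- function(job, status, stages, bundle, output = NULL,
                           walltime = NA_real_) {
  structure(list(job_id = if (is.null(job$job_id)) NA_character_ else job$job_id,
                 pipeline = job$pipeline, status = status,
                 stages = stages, bundle = bundle, output = output,
                 walltime = walltime),
            class = "job_result")
}

#' @export
print.job_result <- function(x, ...) {
  cat(sprintf("<job:%s> %s (%s)\n", x$pipeline,
              if (is.na(x$job_id)) "" else x$job_id, x$status))
  for (i in seq_len(nrow(x$stages))) {
    cat(sprintf("  %d %-18s %s\n", i, x$stages$name[i], x$stages$status[i]))
  }
  invisible(x)
}

# sequential stage runner: each stage gets the shared state environment;
# a failure records the error and skips the remaining stages
run_stage_chain <- function(stage_fns, state) {
  stages <- list()
  failed <- FALSE
  for (nm in names(stage_fns)) {
    if (failed) {
      stages[[nm]] <- list(config = list(), outputs = NULL, error = "skipped")
      next
    }
    res <- tryCatch(stage_fns[[nm]](state), error = function(e) e)
    if (inherits(res, "error")) {
      stages[[nm]] <- list(config = list(), outputs = NULL,
                           error = conditionMessage(res))
      failed <- TRUE
    } else {
      stages[[nm]] <- res
    }
  }
  stages
}

stage_status_table <- function(stages) {
  tibble::tibble(
    name = names(stages),
    status = vapply(stages, function(s) {
      if (is.null(s$error)) "ok" else if (identical(s$error, "skipped")) "skipped" else "failed"
    }, character(1), USE.NAMES = FALSE),
    error = vapply(stages, function(s) {
      if (is.null(s$error)) NA_character_ else s$error
    }, character(1), USE.NAMES = FALSE))
}

finish_job <- function(job, stages, default_plot, t0, inputs = character(0)) {
  tab <- stage_status_table(stages)
  status <- if (all(tab$status == "ok")) "success"
            else if (any(tab$status == "ok")) "partial" else "failed"
  bundle <- list(pipeline = job$pipeline, stages = stages,
                 default_plot = default_plot, inputs = inputs, job = job)
  out <- NULL
  if (!is.null(job$output)) {
    out <- tryCatch(write_result_h5(bundle, job$output), error = function(e) NULL)
  }
  new_job_result(job, status, tab, bundle, output = out,
                 walltime = as.numeric(difftime(Sys.time(), t0, units = "secs")))
}

#' Multi-frame integration pipeline
#'
#' The common reduction pipeline: (1) azimuthal integration of every frame,
#' (2) CorMap comparison of the 1D curves to find the equivalent
#' (radiation-damage-free) prefix, (3) diode-weighted pixel-wise averaging
#' of the accepted frames (restarting from the 2D data — averaging and
#' integration do not commute for the unequal-monitor case), (4) azimuthal
#' integration of the averaged frame with propagated uncertainties. The
#' averaged curve is the bundle's default plot.
#'
#' @param job Job list (see [write_job()]) with `inputs$frames` a frame
#'   spec; `params`: `n_bins`, `threshold_adjacent`, `threshold_any`.
#' @return A `job_result`.
#' @export
run_multiframe <- function(job) {
  validate_job(job)
  t0 <- Sys.time()
  p <- job$params
  n_bins <- if (is.null(p$n_bins)) 200L else as.integer(p$n_bins)
  thr_adj <- if (is.null(p$threshold_adjacent)) 0.01 else p$threshold_adjacent
  thr_any <- if (is.null(p$threshold_any)) 0.001 else p$threshold_any
  state <- new.env(parent = emptyenv())
  state$stack <- simulate_stack(job$inputs$frames)
  stages <- run_stage_chain(list(
    integration = function(s) {
      st <- s$stack
      s$curves <- lapply(seq_along(st$frame_ids), function(k) {
        azimuthal_integrate(st$frames[k, , ] / st$monitor[k],
                            st$frames[k, , ] / st$monitor[k]^2,
                            st$geometry, n_bins = n_bins)
      })
      list(config = list(n_bins = n_bins),
           outputs = list(q = s$curves[[1]]$q,
                          I = t(vapply(s$curves, function(cv) cv$I,
                                       numeric(nrow(s$curves[[1]])))),
                          monitor = st$monitor))
    },
    equivalence = function(s) {
      eq <- pairwise_equivalence(s$curves, thr_adj, thr_any)
      s$accepted <- eq$accepted
      list(config = list(threshold_adjacent = thr_adj, threshold_any = thr_any),
           outputs = list(p_matrix = eq$p_matrix,
                          accepted_ids = s$stack$frame_ids[eq$accepted],
                          n_accepted = length(eq$accepted)))
    },
    average = function(s) {
      s$avg <- average_frames(s$stack, s$stack$frame_ids[s$accepted])
      list(config = list(weighting = "beam-stop diode"),
           outputs = list(values = s$avg$values, variance = s$avg$variance,
                          total_monitor = s$avg$total_monitor,
                          n_frames_used = s$avg$n_frames_used))
    },
    integrate_average = function(s) {
      s$curve <- azimuthal_integrate(s$avg, n_bins = n_bins)
      list(config = list(n_bins = n_bins),
           outputs = list(curve = s$curve))
    }), state)
  res <- finish_job(job, stages, "entry/4_integrate_average/outputs/curve", t0)
  res$curve <- state$curve
  res$averaged_frame <- state$avg
  res
}

#' Sample-changer subtraction and SAS-analysis pipeline
#'
#' (1) CorMap comparison of the buffer curves (incompatible buffers: the
#' largest consistent subset in acquisition order is used and recorded);
#' (2) diode-weighted buffer averaging and 2D subtraction from the sample
#' average; (3) azimuthal integration; (4) Guinier analysis (default
#' plot); (5) dimensionless Kratky; (6) Porod and Rambo-Tainer invariants;
#' (7) BIFT pair-distance distribution.
#'
#' @param job Job with `inputs$sample` and `inputs$buffers` (list of frame
#'   specs); `params`: `n_bins`, `molecule_class`, `do_bift`.
#' @return A `job_result`.
#' @export
run_subtract <- function(job) {
  validate_job(job)
  t0 <- Sys.time()
  p <- job$params
  n_bins <- if (is.null(p$n_bins)) 200L else as.integer(p$n_bins)
  do_bift <- !isFALSE(p$do_bift)
  state <- new.env(parent = emptyenv())
  state$sample <- run_multiframe(list(schema_version = JOB_SCHEMA_VERSION,
                                      pipeline = "multiframe",
                                      inputs = list(frames = job$inputs$sample),
                                      params = list(n_bins = n_bins)))
  buf_specs <- job$inputs$buffers
  if (is.data.frame(buf_specs)) buf_specs <- split(buf_specs, seq_len(nrow(buf_specs)))
  state$buffers <- lapply(buf_specs, function(spec) {
    run_multiframe(list(schema_version = JOB_SCHEMA_VERSION,
                        pipeline = "multiframe",
                        inputs = list(frames = spec),
                        params = list(n_bins = n_bins)))
  })
  stages <- run_stage_chain(list(
    buffer_comparison = function(s) {
      curves <- lapply(s$buffers, `[[`, "curve")
      nb <- length(curves)
      pm <- matrix(1, nb, nb)
      if (nb > 1) for (i in 1:(nb - 1)) for (j in (i + 1):nb) {
        pm[i, j] <- pm[j, i] <- tryCatch(
          cormap_test(curves[[i]], curves[[j]])$p_value, error = function(e) 1)
      }
      # greedy largest consistent subset in acquisition order
      use <- 1L
      if (nb > 1) for (j in 2:nb) {
        if (all(pm[use, j] >= 0.01)) use <- c(use, j)
      }
      s$buffer_use <- use
      list(config = list(threshold = 0.01),
           outputs = list(p_matrix = pm, used = use,
                          warning = if (length(use) < nb)
                            "inconsistent buffers: subset used" else NULL))
    },
    subtraction = function(s) {
      bufs <- s$buffers[s$buffer_use]
      counts <- Reduce(`+`, lapply(bufs, function(b) {
        b$averaged_frame$values * b$averaged_frame$total_monitor
      }))
      total <- sum(vapply(bufs, function(b) b$averaged_frame$total_monitor, numeric(1)))
      buf_avg <- bufs[[1]]$averaged_frame
      buf_avg$values <- counts / total
      buf_avg$variance <- counts / total^2
      buf_avg$total_monitor <- total
      s$sub <- subtract_frames(s$sample$averaged_frame, buf_avg)
      list(config = list(buffers_used = s$buffer_use),
           outputs = list(values = s$sub$values, variance = s$sub$variance))
    },
    integration = function(s) {
      s$curve <- azimuthal_integrate(s$sub, n_bins = n_bins)
      list(config = list(n_bins = n_bins), outputs = list(curve = s$curve))
    },
    guinier = function(s) {
      s$guinier <- auto_guinier(s$curve)
      list(config = list(algorithm = "auto"), outputs = s$guinier)
    },
    kratky = function(s) {
      list(config = list(), outputs = kratky_dimensionless(s$curve, s$guinier))
    },
    invariants = function(s) {
      inv <- sas_invariants(s$curve, s$guinier,
                            if (is.null(p$molecule_class)) "protein" else p$molecule_class)
      list(config = list(molecule_class = inv$mass_method), outputs = inv)
    },
    bift = function(s) {
      if (!do_bift) return(list(config = list(skipped = TRUE), outputs = NULL))
      pd <- bift_auto(s$curve)
      list(config = list(n_r = 100), outputs = pd)
    }), state)
  res <- finish_job(job, stages, "entry/4_guinier", t0)
  res$curve <- state$curve
  res$guinier <- state$guinier
  res
}

#' SEC-SAXS (HPLC) analysis pipeline
#'
#' (1) chromatogram assembly from partial blocks (missing blocks stay
#' masked), (2) SVD with noise-rank selection, (3) NMF component
#' extraction, (4) CorMap-ranked buffer identification and averaging,
#' (5) peak picking on the subtracted total-scattering trace, (6) per
#' fraction: Guinier (GPA fast path), Kratky, invariants, BIFT. The
#' default plot is the total intensity as a function of frame number.
#'
#' @param job Job with `inputs$sec` either `list(kind = "default_sim",
#'   seed, exposure, missing_blocks)` or `list(kind = "rds", path)` (a
#'   saved [make_sec_run()] output); `params`: `fraction`, `do_bift`,
#'   `nmf_k`.
#' @return A `job_result`.
#' @export
run_hplc <- function(job) {
  validate_job(job)
  t0 <- Sys.time()
  p <- job$params
  fraction <- if (is.null(p$fraction)) 0.30 else p$fraction
  do_bift <- !isFALSE(p$do_bift)
  spec <- job$inputs$sec
  run <- switch(if (is.null(spec$kind)) "default_sim" else spec$kind,
    default_sim = default_sec_run(
      seed = if (is.null(spec$seed)) 7L else as.integer(spec$seed),
      exposure = if (is.null(spec$exposure)) 20 else spec$exposure,
      missing_blocks = if (is.null(spec$missing_blocks)) integer(0)
                       else unlist(spec$missing_blocks)),
    rds = readRDS(spec$path),
    stop("unknown sec input kind", call. = FALSE))
  if (!length(run$files)) stop("all input blocks missing", call. = FALSE)
  state <- new.env(parent = emptyenv())
  state$run <- run
  stages <- run_stage_chain(list(
    chromatogram = function(s) {
      s$chrom <- assemble_chromatogram(s$run$files, n_frames = s$run$n_frames)
      total <- rowSums(s$chrom$M)
      total[!s$chrom$present] <- NA
      list(config = list(n_frames = s$run$n_frames),
           outputs = list(total_intensity = total, q = s$chrom$q,
                          present = s$chrom$present))
    },
    svd = function(s) {
      s$svd <- svd_rank(s$chrom)
      list(config = list(threshold_rule = "omega(beta) * median"),
           outputs = list(k = s$svd$k, singular_values = s$svd$singular_values,
                          first_singular_vector = s$svd$first_singular_vector,
                          threshold = s$svd$threshold))
    },
    nmf = function(s) {
      k <- if (is.null(p$nmf_k)) max(s$svd$k, 1L) else as.integer(p$nmf_k)
      s$nmf <- nmf_components(s$chrom, k)
      list(config = list(k = k, init = "nndsvda", max_iter = 500),
           outputs = list(W = s$nmf$W, H = s$nmf$H,
                          rel_error = s$nmf$rel_error,
                          n_clipped = s$nmf$n_clipped))
    },
    buffer = function(s) {
      s$buf <- select_buffer(s$chrom, s$svd$first_singular_vector, fraction)
      list(config = list(fraction = fraction),
           outputs = list(buffer_curve = s$buf$buffer_curve,
                          selected_ids = s$buf$selected_ids))
    },
    fractions = function(s) {
      sub <- s$chrom
      sub$M <- sweep(sub$M, 2, s$buf$buffer_curve$I)
      s$ranges <- find_fractions(sub)
      list(config = list(widths = "5-50", median_window = 5,
                         boundary_fraction = 0.10),
           outputs = list(n_fractions = length(s$ranges),
                          ranges = if (length(s$ranges))
                            do.call(rbind, s$ranges) else NULL))
    },
    analysis = function(s) {
      s$fractions <- lapply(s$ranges, function(r) {
        analyze_fraction(s$chrom, r, s$buf$buffer_curve, do_bift = do_bift)
      })
      names(s$fractions) <- sprintf("fraction_%03d", seq_along(s$fractions) - 1L)
      list(config = list(guinier = "gpa-first", do_bift = do_bift),
           outputs = s$fractions)
    }), state)
  res <- finish_job(job, stages, "entry/1_chromatogram/outputs/total_intensity", t0)
  res$chromatogram <- state$chrom
  res$fractions <- state$fractions
  res$buffer <- state$buf
  res$svd <- state$svd
  res
}

#' Execute a job description
#'
#' Dispatches to the pipeline named in the job. Identical inputs produce
#' identical outputs: every source of randomness is seeded from the job.
#'
#' @param job Job list or path to a job JSON file.
#' @return A `job_result`.
#' @export
run_job <- function(job) {
  if (is.character(job)) job <- read_job(job)
  validate_job(job)
  switch(job$pipeline,
         multiframe = run_multiframe(job),
         subtract = run_subtract(job),
         hplc = run_hplc(job))
}

#' Replay saved job descriptions
#'
#' Re-executes one or several saved jobs from their JSON description files,
#' sequentially, returning results in input order — offline reprocessing of
#' exactly what ran before.
#'
#' @param json_paths Character vector of job JSON paths.
#' @return List of `job_result`s (a single result if one path given).
#' @export
replay_job <- function(json_paths) {
  out <- lapply(json_paths, run_job)
  if (length(out) == 1L) out[[1]] else out
}
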