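#' @importFrom rhdf5 h5createFile h5createGroup h5write h5read h5ls H5Fopen H5Fclose H5close
NULL

# serialize an arbitrary analysis value into the HDF5 tree rooted at `path`
h5_write_any <- function(file, path, value) {
  if (is.null(value)) return(invisible())
  if (inherits(value, "sas_curve")) {
    rhdf5::h5createGroup(file, path)
    rhdf5::h5write(value$q, file, paste0(path, "/q"))
    rhdf5::h5write(value$I, file, paste0(path, "/I"))
    if (has_sigma(value)) rhdf5::h5write(value$sigma, file, paste0(path, "/sigma"))
    return(invisible())
  }
  if (is.data.frame(value)) {
    rhdf5::h5createGroup(file, path)
    for (nm in names(value)) {
      h5_write_any(file, paste0(path, "/", nm), value[[nm]])
    }
    return(invisible())
  }
  if (is.list(value)) {
    value <- unclass(value)
    value <- value[!vapply(value, is.function, logical(1))]
    rhdf5::h5createGroup(file, path)
    for (nm in names(value)) {
      if (nzchar(nm)) h5_write_any(file, paste0(path, "/", nm), value[[nm]])
    }
    return(invisible())
  }
  if (is.logical(value)) value <- as.integer(value)
  if (is.factor(value)) value <- as.character(value)
  rhdf5::h5write(value, file, path)
  invisible()
}

#' Write a pipeline result bundle to HDF5
#'
#' All results of one pipeline run go into a single HDF5 file: one group
#' per pipeline stage (NeXus-flavoured naming, `entry/<k>_<stage>`), each
#' holding a machine-readable copy of the configuration that produced it
#' (JSON, dataset `configuration`) plus its outputs — the reprocessability
#' contract. Failed stages are still written, with the error message in the
#' `error` dataset. A `default_plot` dataset at the entry level names the
#' dataset a viewer should display, and input provenance is recorded as
#' stored path strings.
#'
#' @param bundle A result bundle: list with `pipeline`, `stages` (named
#'   list of `list(config, outputs, error)`), optional `default_plot`,
#'   `inputs` (character paths), `job` (the job description list).
#' @param path Output `.h5` path (overwritten).
#' @return `path`, invisibly.
#' @export
write_result_h5 <- function(bundle, path) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "entry")
  rhdf5::h5write(if (is.null(bundle$pipeline)) "unknown" else bundle$pipeline,
                 path, "entry/pipeline")
  if (!is.null(bundle$default_plot)) {
    rhdf5::h5write(bundle$default_plot, path, "entry/default_plot")
  }
  rhdf5::h5createGroup(path, "entry/provenance")
  if (length(bundle$inputs)) {
    rhdf5::h5write(as.character(bundle$inputs), path, "entry/provenance/input_paths")
  }
  if (!is.null(bundle$job)) {
    rhdf5::h5write(as.character(jsonlite::toJSON(bundle$job, auto_unbox = TRUE,
                                                 digits = NA, null = "null")),
                   path, "entry/provenance/job_json")
  }
  stages <- bundle$stages
  for (k in seq_along(stages)) {
    nm <- names(stages)[k]
    g <- sprintf("entry/%d_%s", k, nm)
    rhdf5::h5createGroup(path, g)
    st <- stages[[k]]
    rhdf5::h5write(as.character(jsonlite::toJSON(
      if (is.null(st$config)) list() else st$config,
      auto_unbox = TRUE, digits = NA, null = "null")),
      path, paste0(g, "/configuration"))
    if (!is.null(st$error)) {
      rhdf5::h5write(as.character(st$error), path, paste0(g, "/error"))
    }
    if (!is.null(st$outputs)) h5_write_any(path, paste0(g, "/outputs"), st$outputs)
  }
  rhdf5::H5close()
  invisible(path)
}

#' Read a scattering curve back from a result bundle
#'
#' @param path HDF5 file written by [write_result_h5()].
#' @param name Group path of the curve (e.g.
#'   `"entry/4_integrate_average/outputs/curve"`).
#' @return A [sas_curve()].
#' @export
read_result_curve <- function(path, name) {
  q <- as.vector(rhdf5::h5read(path, paste0(name, "/q")))
  I <- as.vector(rhdf5::h5read(path, paste0(name, "/I")))
  sigma <- tryCatch(as.vector(rhdf5::h5read(path, paste0(name, "/sigma"))),
                    error = function(e) NULL)
  sas_curve(q, I, sigma)
}

#' Export every curve of a result bundle as three-column ASCII
#'
#' Walks the HDF5 tree of a pipeline result and writes each stored
#' scattering curve as a `.dat` file (headers included) for third-party
#' tools.
#'
#' @param h5_path HDF5 result file.
#' @param out_dir Output directory (created if missing).
#' @return Character vector of files written.
#' @export
extract_ascii <- function(h5_path, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  ls <- rhdf5::h5ls(h5_path)
  grp <- paste(ls$group, ls$name, sep = "/")
  q_sets <- grp[ls$name == "q"]
  written <- character(0)
  for (qs in q_sets) {
    parent <- sub("/q$", "", qs)
    if (!any(grp == paste0(parent, "/I"))) next
    cv <- tryCatch(read_result_curve(h5_path, sub("^/", "", parent)),
                   error = function(e) NULL)  # e.g. a per-frame I matrix
    if (is.null(cv)) next
    fn <- file.path(out_dir, paste0(gsub("/", "_", sub("^/entry/", "", parent)), ".dat"))
    write_dat(cv, fn)
    written <- c(written, fn)
  }
  written
}
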