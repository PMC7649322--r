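# Persistence: traces are stored as versioned RDS containers (lossless
# round-trip of every field including the delay buffer); 1-D sweeps go to
# CSV, scalars and manifests to JSON, frames to plain-text PGM.

#' Save a simulation trace
#'
#' Lossless, resume-capable container (RDS with a format version).
#'
#' @param trace a `simulation_trace`.
#' @param path output file path.
#' @return `path` invisibly.
#' @export
save_trace <- function(trace, path) {
  stopifnot(inherits(trace, "simulation_trace"))
  saveRDS(trace, path)
  invisible(path)
}

#' Load a simulation trace
#'
#' @param path file written by [save_trace()].
#' @return the `simulation_trace`.
#' @export
load_trace <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e)
    stop("trace format error: ", conditionMessage(e), call. = FALSE))
  if (!inherits(obj, "simulation_trace"))
    stop("trace format error: not a simulation_trace container",
         call. = FALSE)
  if (is.null(obj$format_version) || obj$format_version != 1L)
    stop("trace format error: unsupported format version", call. = FALSE)
  obj
}

#' Export frames as plain-text PGM images
#'
#' One ASCII (P2) PGM per frame, for eyeballing stimuli outside R.
#'
#' @param frames a `frame_sequence`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @param maxval PGM grey levels.
#' @return character vector of file paths, invisibly.
#' @export
export_frames_pgm <- function(frames, dir, prefix = "frame", maxval = 255L) {
  stopifnot(inherits(frames, "frame_sequence"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fs <- frames$frames
  T <- dim(fs)[3]
  paths <- character(T)
  for (t in seq_len(T)) {
    m <- round(fs[, , t] * maxval)
    path <- file.path(dir, sprintf("%s_%04d.pgm", prefix, t))
    con <- file(path, "w")
    writeLines(c("P2", paste(ncol(m), nrow(m)), as.character(maxval)), con)
    write(t(m), con, ncolumns = ncol(m))
    close(con)
    paths[t] <- path
  }
  invisible(paths)
}

#' Export ground-truth masks
#'
#' Masks as run-length-free JSON index lists (per frame, 1-based matrix
#' indices) plus a CSV summary of mask sizes per frame.
#'
#' @param gt ground truth from a stimulus generator.
#' @param dir output directory.
#' @return paths of the files written, invisibly.
#' @export
export_ground_truth <- function(gt, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mask_names <- names(gt)[vapply(gt, is.array, logical(1))]
  js <- lapply(mask_names, function(nm) {
    a <- gt[[nm]]
    lapply(seq_len(dim(a)[3]), function(t) which(a[, , t]))
  })
  names(js) <- mask_names
  js$true_dir <- gt$true_dir
  jpath <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(js, jpath, auto_unbox = FALSE)
  sizes <- do.call(cbind, lapply(mask_names, function(nm)
    apply(gt[[nm]], 3, sum)))
  colnames(sizes) <- mask_names
  cpath <- file.path(dir, "mask_sizes.csv")
  utils::write.csv(data.frame(frame = seq_len(nrow(sizes)), sizes),
                   cpath, row.names = FALSE)
  invisible(c(jpath, cpath))
}

#' Write a run manifest
#'
#' JSON record tying a trace to the stimulus spec, parameter hash, mode and
#' output files.
#'
#' @param path manifest path.
#' @param spec the `stimulus_spec` used.
#' @param p the `mt_params` used.
#' @param mode simulation mode.
#' @param outputs named character vector of output files.
#' @return `path` invisibly.
#' @export
write_manifest <- function(path, spec, p, mode, outputs) {
  man <- list(stimulus = unclass(spec), params_hash = params_hash(p),
              mode = mode, outputs = as.list(outputs),
              created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
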