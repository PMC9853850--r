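#' Write / read a traceset as a two-file plain-text bundle
#'
#' A traceset on disk is a directory holding `meta.yaml` (frame count,
#' frame time, class list, normalization flag, provenance) and
#' `traces.csv` (header `trace_id,label,replicate_id,v0,...,v{n-1}`, one
#' trace per row, values written with full precision). The round trip
#' preserves labels exactly and values to better than 1e-6 relative.
#'
#' @param ts A [traceset()].
#' @param dir Directory path for the bundle (created if needed).
#' @return `write_traceset()` returns `dir` invisibly; `read_traceset()`
#'   returns a [traceset()].
#' @export
write_traceset <- function(ts, dir) {
  stopifnot(inherits(ts, "traceset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(n_frames = ts$n_frames, frame_time = ts$frame_time,
               classes = as.list(ts$classes), normalized = ts$normalized,
               n_traces = n_traces(ts),
               provenance = ts$provenance[
                 !vapply(ts$provenance, is.null, logical(1L))])
  yaml::write_yaml(meta, file.path(dir, "meta.yaml"))
  dt <- data.table::data.table(ts$meta)
  vals <- data.table::as.data.table(ts$values)
  data.table::setnames(vals, sprintf("v%d", seq_len(ts$n_frames) - 1L))
  data.table::fwrite(cbind(dt, vals), file.path(dir, "traces.csv"))
  invisible(dir)
}

#' @rdname write_traceset
#' @export
read_traceset <- function(dir) {
  meta_path <- file.path(dir, "meta.yaml")
  csv_path <- file.path(dir, "traces.csv")
  if (!file.exists(meta_path)) {
    stop("traceset metadata file not found; expected ", meta_path,
         call. = FALSE)
  }
  if (!file.exists(csv_path)) {
    stop("traceset data file not found; expected ", csv_path,
         call. = FALSE)
  }
  meta <- yaml::read_yaml(meta_path)
  dt <- data.table::fread(csv_path, header = TRUE)
  need <- c("trace_id", "label", "replicate_id")
  if (!all(need %in% names(dt))) {
    stop("traceset format error in ", csv_path,
         ": missing metadata columns ",
         paste(setdiff(need, names(dt)), collapse = ", "), call. = FALSE)
  }
  vcols <- setdiff(names(dt), need)
  if (length(vcols) != meta$n_frames) {
    stop(sprintf(
      "traceset format error: metadata declares n_frames = %d but %s has %d value columns",
      meta$n_frames, csv_path, length(vcols)), call. = FALSE)
  }
  values <- as.matrix(dt[, vcols, with = FALSE])
  if (!is.numeric(values) || anyNA(values)) {
    bad <- which(apply(values, 1L, function(r) anyNA(suppressWarnings(
      as.numeric(r)))))[1L]
    stop("traceset format error: non-numeric or missing value near line ",
         bad + 1L, " of ", csv_path, call. = FALSE)
  }
  traceset(values, labels = dt$label, replicate_ids = dt$replicate_id,
           trace_ids = dt$trace_id, frame_time = meta$frame_time,
           normalized = isTRUE(meta$normalized),
           provenance = meta$provenance %||% list(source = "file"))
}

#' Write a prediction table
#'
#' Comma-separated text with columns `trace_id`, `predicted_class`, the
#' per-class mean probabilities, `uncertainty` and `accepted`.
#'
#' @param preds A [mc_predict()] data.frame (or any data.frame).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(preds, path) {
  data.table::fwrite(as.data.frame(preds), path)
  invisible(path)
}

#' Write a run manifest
#'
#' Records, as YAML, everything needed to reproduce a pipeline run: the
#' configuration used, the seed, package and R versions, and MD5 hashes
#' of the input files.
#'
#' @param out_dir Output directory (created if needed).
#' @param config Named list echoed verbatim.
#' @param seed Integer seed of the run.
#' @param inputs Character vector of input file paths to hash.
#' @return Path of the manifest file, invisibly.
#' @export
write_run_manifest <- function(out_dir, config = list(), seed = NA,
                               inputs = character(0)) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hashes <- if (length(inputs)) {
    as.list(tools::md5sum(inputs[file.exists(inputs)]))
  } else {
    list()
  }
  manifest <- list(
    package = "blinkid",
    package_version = as.character(utils::packageVersion("blinkid")),
    r_version = as.character(getRversion()),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config,
    input_md5 = hashes)
  path <- file.path(out_dir, "run_manifest.yaml")
  yaml::write_yaml(manifest, path)
  invisible(path)
}
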