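#' Construct a continuous multichannel recording
#'
#' The core data container: a channels-by-samples matrix of microvolt
#' values, its sampling rate, channel geometry and the block annotations
#' that describe the experiment's run/set structure.
#'
#' @param data numeric matrix, channels x samples (microvolts).
#' @param fs sampling rate in Hz.
#' @param channels character vector of channel names (must exist in
#'   [ten_twenty_positions()]).
#' @param annotations data.frame of block annotations, see
#'   [block_annotations()].
#' @param subject_id subject identifier string.
#' @param reference name of the reference channel, or `"average"`.
#' @return an object of class `ncv_recording`.
#' @export
new_recording <- function(data, fs, channels, annotations,
                          subject_id = "S01", reference = "average") {
  data <- as.matrix(data)
  rownames(data) <- channels
  rec <- structure(
    list(data = data, fs = fs, channels = channels,
         positions = channel_positions(channels),
         annotations = as_block_annotations(annotations),
         subject_id = subject_id, reference = reference),
    class = "ncv_recording")
  validate_recording(rec)
}

#' Build a block-annotation table
#'
#' Each row annotates one run: a contiguous stretch of a single condition.
#' Spans are half-open `[onset, onset + duration)` in seconds;
#' `chrono_index` gives the true recording order; `block_id` identifies the
#' unit over which block-specific confounds are shared (a run, or a grouped
#' repetition of one condition).
#'
#' @param onset,duration numeric vectors (seconds).
#' @param condition character vector of class labels.
#' @param run_id,set_id,day_id,chrono_index,block_id integer vectors.
#' @return data.frame of class annotations.
#' @export
block_annotations <- function(onset, duration, condition, run_id, set_id,
                              day_id = 1L, chrono_index = seq_along(onset),
                              block_id = run_id) {
  data.frame(onset = as.numeric(onset), duration = as.numeric(duration),
             condition = as.character(condition),
             run_id = as.integer(run_id), set_id = as.integer(set_id),
             day_id = as.integer(rep_len(day_id, length(onset))),
             chrono_index = as.integer(chrono_index),
             block_id = as.integer(block_id),
             stringsAsFactors = FALSE)
}

as_block_annotations <- function(ann) {
  need <- c("onset", "duration", "condition", "run_id", "set_id")
  missing <- setdiff(need, names(ann))
  if (length(missing)) {
    stop("annotation table lacks column(s): ", paste(missing, collapse = ", "))
  }
  block_annotations(ann$onset, ann$duration, ann$condition, ann$run_id,
                    ann$set_id,
                    day_id = ann$day_id %||% 1L,
                    chrono_index = ann$chrono_index %||% seq_len(nrow(ann)),
                    block_id = ann$block_id %||% ann$run_id)
}

#' Validate recording invariants
#'
#' Checks that annotation spans lie within the recorded interval and do not
#' overlap, that channel names are unique and known, and that
#' `chrono_index` is a strict total order consistent with onsets.
#'
#' @param rec an `ncv_recording`.
#' @return `rec`, invisibly unchanged, or an error.
#' @export
validate_recording <- function(rec) {
  stopifnot(inherits(rec, "ncv_recording"))
  if (nrow(rec$data) != length(rec$channels)) {
    stop("shape mismatch: ", length(rec$channels), " channels declared over a ",
         nrow(rec$data), "-row data matrix")
  }
  if (anyDuplicated(rec$channels)) stop("channel names must be unique")
  channel_positions(rec$channels) # unknown names error here
  ann <- rec$annotations
  t_max <- ncol(rec$data) / rec$fs
  if (any(ann$onset < -1e-9) || any(ann$onset + ann$duration > t_max + 1e-9)) {
    stop("annotation span outside the recorded interval [0, ", t_max, "]")
  }
  o <- order(ann$onset)
  ends <- ann$onset[o] + ann$duration[o]
  if (any(ann$onset[o][-1] < ends[-length(ends)] - 1e-9)) {
    stop("overlapping annotations")
  }
  if (anyDuplicated(ann$chrono_index) ||
      any(diff(ann$chrono_index[o]) <= 0)) {
    stop("chrono_index must be a strict total order consistent with onsets")
  }
  invisible(rec)
}

#' @export
print.ncv_recording <- function(x, ...) {
  cat(sprintf("<ncv_recording> %s: %d ch x %d samples @ %g Hz (%.1f s), ref %s\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$fs,
              ncol(x$data) / x$fs, x$reference))
  cat(sprintf("  %d annotated runs, %d sets, conditions: %s\n",
              nrow(x$annotations), length(unique(x$annotations$set_id)),
              paste(sort(unique(x$annotations$condition)), collapse = ", ")))
  invisible(x)
}

#' Write a recording to the native container
#'
#' The native container is a gzip-compressed stream of little-endian 32-bit
#' floats in channel-major (column-major channels x samples) order, plus a
#' JSON sidecar declaring sampling rate, channel names, reference, subject
#' and the block annotations (serialized in `chrono_index` order).
#'
#' @param rec an `ncv_recording`.
#' @param path_data path for the gzipped float32 payload.
#' @param path_sidecar path for the JSON sidecar.
#' @return invisibly, the sidecar path.
#' @export
write_recording <- function(rec, path_data, path_sidecar) {
  validate_recording(rec)
  con <- gzfile(path_data, "wb")
  on.exit(close(con))
  writeBin(as.vector(rec$data), con, size = 4L, endian = "little")
  ann <- rec$annotations[order(rec$annotations$chrono_index), , drop = FALSE]
  sidecar <- list(
    format = "neurocv-float32-v1",
    fs = rec$fs,
    n_channels = nrow(rec$data),
    n_samples = ncol(rec$data),
    channels = rec$channels,
    subject_id = rec$subject_id,
    reference = rec$reference,
    annotations = ann)
  jsonlite::write_json(sidecar, path_sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path_sidecar)
}

#' Load a recording from the native container
#'
#' @param path_data path to the gzipped float32 payload written by
#'   [write_recording()].
#' @param path_sidecar path to the JSON sidecar.
#' @return an `ncv_recording` with validated invariants.
#' @export
load_recording <- function(path_data, path_sidecar) {
  sc <- jsonlite::read_json(path_sidecar, simplifyVector = TRUE)
  if (!identical(sc$format, "neurocv-float32-v1")) {
    stop("unrecognized sidecar format: ", sc$format %||% "<missing>")
  }
  con <- gzfile(path_data, "rb")
  on.exit(close(con))
  n <- sc$n_channels * sc$n_samples
  vals <- readBin(con, what = "numeric", n = n + 1L, size = 4L,
                  endian = "little")
  if (length(vals) != n) {
    stop("shape mismatch: sidecar declares ", sc$n_channels, " x ",
         sc$n_samples, " but payload holds ", length(vals), " values")
  }
  new_recording(matrix(vals, nrow = sc$n_channels), fs = sc$fs,
                channels = sc$channels, annotations = sc$annotations,
                subject_id = sc$subject_id, reference = sc$reference)
}

results_columns <- c("subject", "dataset_layout", "contrast", "pipeline",
                     "cv_scheme", "fold", "accuracy", "n_test")

#' Construct/validate a long-format results table
#'
#' One row per (subject, layout, contrast, pipeline, scheme, fold) with the
#' fold accuracy and test-set size.
#'
#' @param df data.frame with the columns
#'   `subject, dataset_layout, contrast, pipeline, cv_scheme, fold,
#'   accuracy, n_test`.
#' @return validated data.frame of class `ncv_results`.
#' @export
results_table <- function(df = NULL) {
  if (is.null(df)) {
    df <- data.frame(subject = character(), dataset_layout = character(),
                     contrast = character(), pipeline = character(),
                     cv_scheme = character(), fold = integer(),
                     accuracy = numeric(), n_test = integer(),
                     stringsAsFactors = FALSE)
  }
  missing <- setdiff(results_columns, names(df))
  if (length(missing)) {
    stop("results table lacks column(s): ", paste(missing, collapse = ", "))
  }
  df <- df[, results_columns, drop = FALSE]
  if (nrow(df)) {
    stopifnot(all(df$accuracy >= 0 & df$accuracy <= 1), all(df$n_test > 0))
  }
  class(df) <- c("ncv_results", "data.frame")
  df
}

#' Export / import result tables as CSV
#'
#' @param table a results table (see [results_table()]).
#' @param path CSV path.
#' @return `import_results` returns the validated table;
#'   `export_results` returns the path invisibly.
#' @export
export_results <- function(table, path) {
  table <- results_table(as.data.frame(table))
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname export_results
#' @export
import_results <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(subject = "character",
                                dataset_layout = "character",
                                contrast = "character",
                                pipeline = "character",
                                cv_scheme = "character",
                                fold = "integer",
                                accuracy = "numeric",
                                n_test = "integer"))
  results_table(df)
}
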