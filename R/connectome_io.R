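# Tabular I/O for atlases, time series, matrices and subject tables, plus the
# motion-QC displacement metrics. The canonical dialect is TSV with '.'
# decimals and no index column; readers also accept comma-separated files.
# Readers validate and reject rather than silently coerce.

detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

#' Read an ROI atlas table
#'
#' Expects a header with `roi_id` and coordinate columns `x`, `y`, `z` (mm);
#' an optional `label` column is carried through. Row order defines the node
#' index used by every downstream matrix.
#'
#' @param path TSV or CSV file.
#' @return Atlas `data.frame` (roi_id, x, y, z, label).
#' @export
read_atlas <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = detect_sep(path),
                          stringsAsFactors = FALSE, colClasses = NA)
  needed <- c("roi_id", "x", "y", "z")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0L) {
    stop("atlas file ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (cc in c("x", "y", "z")) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df[[cc]]))))
    if (length(bad) > 0L) {
      stop("non-numeric coordinate in atlas column '", cc, "' at line ",
           bad[1L] + 1L, call. = FALSE)
    }
    df[[cc]] <- as.numeric(df[[cc]])
  }
  dup <- which(duplicated(df$roi_id))
  if (length(dup) > 0L) {
    stop("duplicated roi_id '", df$roi_id[dup[1L]], "' at line ",
         dup[1L] + 1L, call. = FALSE)
  }
  if (nrow(df) < 3L) stop("atlas needs at least 3 regions", call. = FALSE)
  if (!"label" %in% names(df)) df$label <- as.character(df$roi_id)
  df[, c("roi_id", "x", "y", "z", "label")]
}

#' Write an ROI atlas table
#' @param atlas Atlas `data.frame`.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_atlas <- function(atlas, path) {
  utils::write.table(atlas, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a subject time-series matrix
#'
#' Accepts either a header whose column names match the atlas roi ids
#' (optionally prefixed `roi_`), in any order -- columns are then reordered to
#' atlas order -- or a headerless/positional numeric table whose column count
#' equals the atlas size.
#'
#' @param path TSV or CSV file, rows = time points.
#' @param atlas Atlas `data.frame` the columns must align to.
#' @return Numeric T x N matrix in atlas column order.
#' @export
read_timeseries <- function(path, atlas) {
  df <- utils::read.table(path, header = TRUE, sep = detect_sep(path),
                          stringsAsFactors = FALSE, check.names = FALSE)
  n <- nrow(atlas)
  ids <- as.character(atlas$roi_id)
  nm <- sub("^roi_", "", names(df))
  if (all(ids %in% nm)) {
    if (ncol(df) != n) {
      stop("time-series file ", path, " has ", ncol(df),
           " columns, atlas has ", n, call. = FALSE)
    }
    df <- df[, match(ids, nm), drop = FALSE]
  } else if (ncol(df) != n) {
    stop("time-series file ", path, " has ", ncol(df),
         " columns, atlas has ", n, call. = FALSE)
  }
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("non-numeric values in ", path, call. = FALSE)
  bad <- which(!is.finite(m), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("missing/non-finite cells in ", path, ": ",
         paste(sprintf("(%d,%d)", bad[, 1L], bad[, 2L])[seq_len(min(5L, nrow(bad)))],
               collapse = " "),
         call. = FALSE)
  }
  if (nrow(m) < 10L) {
    stop("time series in ", path, " has fewer than 10 time points",
         call. = FALSE)
  }
  colnames(m) <- paste0("roi_", ids)
  m
}

#' Write a time-series matrix
#' @param ts Numeric T x N matrix (column names kept as header).
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_timeseries <- function(ts, path) {
  utils::write.table(ts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a square symmetric matrix as TSV
#'
#' Values are written with 17 significant digits so a write/read round trip
#' reproduces the matrix to better than 12 significant digits.
#'
#' @param m Square symmetric numeric matrix.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_matrix <- function(m, path) {
  check_square_symmetric(m, name = "matrix")
  lines <- apply(m, 1L, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a square matrix written by [write_matrix()]
#' @param path TSV path.
#' @return Numeric matrix.
#' @export
read_matrix <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE, sep = "\t"))
  dimnames(m) <- NULL
  m
}

#' Round-trip a matrix through disk
#'
#' Writes `m` to `path` and reads it back; used as an I/O self-check.
#'
#' @param m Square symmetric numeric matrix.
#' @param path File path to use.
#' @return The re-read matrix.
#' @export
matrix_roundtrip <- function(m, path) {
  write_matrix(m, path)
  read_matrix(path)
}

#' Read a subject table
#' @param path TSV/CSV with at least `subject_id` and `group` columns.
#' @return `data.frame` of subjects.
#' @export
read_subjects <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = detect_sep(path),
                          stringsAsFactors = FALSE)
  needed <- c("subject_id", "group")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0L) {
    stop("subject table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df$subject_id)) {
    stop("duplicated subject_id in ", path, call. = FALSE)
  }
  df
}

#' Head-motion displacement summaries from translation parameters
#'
#' From the per-volume rigid-body translation parameters (x, y, z in mm),
#' computes the mean absolute displacement (mean over volumes of the
#' Euclidean norm of the translation vector) and the mean scan-to-scan
#' displacement (mean over successive volume pairs of the Euclidean norm of
#' the difference). Only translations enter; rotations are out of scope.
#'
#' @param trace Numeric matrix or data.frame with >= 2 rows and columns
#'   x, y, z (or exactly three columns taken in that order).
#' @return Named list: `mean_absolute`, `mean_scan_to_scan` (both mm).
#' @export
#' @examples
#' compute_displacement(rbind(c(0, 0, 0), c(3, 4, 0), c(3, 4, 0)))
compute_displacement <- function(trace) {
  m <- as.matrix(trace)
  if (all(c("x", "y", "z") %in% colnames(m))) {
    m <- m[, c("x", "y", "z"), drop = FALSE]
  }
  if (ncol(m) != 3L) {
    stop("motion trace must have three translation columns (x, y, z)",
         call. = FALSE)
  }
  if (nrow(m) < 2L) stop("motion trace needs at least 2 volumes", call. = FALSE)
  if (any(!is.finite(m))) stop("non-finite motion parameters", call. = FALSE)
  norms <- sqrt(rowSums(m^2))
  diffs <- sqrt(rowSums(diff(m)^2))
  list(mean_absolute = mean(norms), mean_scan_to_scan = mean(diffs))
}
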