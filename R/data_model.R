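#' Regional BOLD time series for one subject
#'
#' Container for one subject's ROI-by-frame BOLD matrix. Rows are regions of
#' interest (ROIs), columns are fMRI frames acquired every `tr_seconds`
#' seconds. After [normalize_subject()] every non-constant ROI row has mean 0
#' and standard deviation 1 across time.
#'
#' @param subject_id character scalar identifying the subject.
#' @param matrix numeric matrix, `n_rois x n_frames`; all entries finite.
#' @param tr_seconds positive scalar, repetition time in seconds.
#' @param roi_labels character vector of ROI names, one per row. Defaults to
#'   `ROI1..ROIn`.
#'
#' @return An object of class `regional_time_series` with fields
#'   `subject_id`, `matrix`, `tr_seconds`, `roi_labels`.
#' @export
regional_time_series <- function(subject_id, matrix, tr_seconds,
                                 roi_labels = NULL) {
  stopifnot(is.character(subject_id), length(subject_id) == 1L)
  matrix <- as.matrix(matrix)
  if (!is.numeric(matrix)) {
    stop("BOLD matrix for subject '", subject_id, "' is not numeric")
  }
  bad <- which(!is.finite(matrix), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("non-finite BOLD value for subject '", subject_id,
         "' at ROI row ", bad[1L, 1L], ", frame ", bad[1L, 2L])
  }
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1L || tr_seconds <= 0) {
    stop("tr_seconds must be a positive scalar")
  }
  if (is.null(roi_labels)) roi_labels <- paste0("ROI", seq_len(nrow(matrix)))
  if (length(roi_labels) != nrow(matrix)) {
    stop("roi_labels length (", length(roi_labels),
         ") does not match ROI count (", nrow(matrix), ")")
  }
  rownames(matrix) <- roi_labels
  structure(
    list(subject_id = subject_id, matrix = matrix,
         tr_seconds = as.numeric(tr_seconds),
         roi_labels = as.character(roi_labels)),
    class = "regional_time_series")
}

#' @export
print.regional_time_series <- function(x, ...) {
  cat("<regional_time_series> subject", x$subject_id, "-",
      nrow(x$matrix), "ROIs x", ncol(x$matrix), "frames, TR",
      x$tr_seconds, "s\n")
  invisible(x)
}

#' Z-score each ROI time series across time
#'
#' Normalizes every ROI row of a subject's BOLD matrix to mean 0 and standard
#' deviation 1 across frames. The population convention (denominator `T`, not
#' `T - 1`) is used; correlation distance between frames is invariant to this
#' choice. Constant rows cannot be z-scored and are mapped to all zeros with a
#' warning, so a flat-lined synthetic or real ROI does not abort a cohort run.
#'
#' @param ts a [regional_time_series()].
#' @return A `regional_time_series` with normalized matrix. Idempotent.
#' @export
normalize_subject <- function(ts) {
  stopifnot(inherits(ts, "regional_time_series"))
  x <- ts$matrix
  if (ncol(x) < 2L) stop("need at least 2 frames to normalize")
  mu <- rowMeans(x)
  xc <- x - mu
  sdv <- sqrt(rowMeans(xc^2))
  const <- sdv <= .Machine$double.eps * 100 * pmax(abs(mu), 1)
  if (any(const)) {
    warning("subject '", ts$subject_id, "': constant ROI row(s) ",
            paste(which(const), collapse = ", "), " set to zero")
    xc[const, ] <- 0
    sdv[const] <- 1
  }
  ts$matrix <- xc / sdv
  rownames(ts$matrix) <- ts$roi_labels
  ts
}

#' Concatenate subjects' BOLD matrices along the temporal axis
#'
#' Stacks per-subject ROI-by-frame matrices column-wise into a single
#' `N x T_total` point cloud for clustering, keeping an exact frame-to-subject
#' map so no downstream statistic ever crosses a subject boundary.
#'
#' @param ts_list list of [regional_time_series()] with identical ROI labels
#'   in identical order.
#' @return Object of class `concatenated_dataset` with fields `matrix`
#'   (`N x T_total`), `frame_subject_index` (length `T_total` character),
#'   `subject_boundaries` (cumulative frame offsets, one per subject),
#'   `roi_labels`, `tr_seconds`.
#' @export
concatenate_cohort <- function(ts_list) {
  stopifnot(is.list(ts_list), length(ts_list) >= 1L)
  lab0 <- ts_list[[1L]]$roi_labels
  for (ts in ts_list) {
    stopifnot(inherits(ts, "regional_time_series"))
    if (!identical(ts$roi_labels, lab0)) {
      stop("ROI label order mismatch for subject '", ts$subject_id,
           "' relative to '", ts_list[[1L]]$subject_id, "'")
    }
  }
  frames <- vapply(ts_list, function(t) ncol(t$matrix), integer(1L))
  ids <- vapply(ts_list, function(t) t$subject_id, character(1L))
  structure(
    list(matrix = do.call(cbind, lapply(ts_list, `[[`, "matrix")),
         frame_subject_index = rep(ids, frames),
         subject_boundaries = cumsum(frames),
         roi_labels = lab0,
         tr_seconds = ts_list[[1L]]$tr_seconds),
    class = "concatenated_dataset")
}

#' @export
print.concatenated_dataset <- function(x, ...) {
  cat("<concatenated_dataset>", nrow(x$matrix), "ROIs x", ncol(x$matrix),
      "frames from", length(x$subject_boundaries), "subjects\n")
  invisible(x)
}

#' Weighted structural connectome for one subject
#'
#' Symmetric nonnegative matrix of white-matter streamline strengths between
#' parcellated gray-matter regions, with an exactly zero diagonal. ROI order
#' must match the time-series order; the match is validated by label equality.
#'
#' @param subject_id character scalar.
#' @param weights numeric `N x N` matrix; symmetric within `1e-9`,
#'   nonnegative, zero diagonal.
#' @param roi_labels character vector of ROI names.
#' @return Object of class `connectome`.
#' @export
connectome <- function(subject_id, weights, roi_labels = NULL) {
  weights <- as.matrix(weights)
  n <- nrow(weights)
  if (n != ncol(weights)) stop("connectome must be square")
  if (any(!is.finite(weights))) stop("non-finite connectome weight")
  asym <- abs(weights - t(weights))
  if (max(asym) > 1e-9) {
    ij <- which(asym == max(asym), arr.ind = TRUE)[1L, ]
    stop("connectome for '", subject_id, "' asymmetric at [",
         ij[1L], ",", ij[2L], "]: |A - t(A)| = ", max(asym))
  }
  if (any(weights < 0)) stop("negative connectome weight")
  if (any(diag(weights) != 0)) stop("connectome diagonal must be exactly zero")
  weights <- (weights + t(weights)) / 2
  diag(weights) <- 0
  if (is.null(roi_labels)) roi_labels <- paste0("ROI", seq_len(n))
  if (length(roi_labels) != n) stop("roi_labels length mismatch")
  dimnames(weights) <- list(roi_labels, roi_labels)
  structure(list(subject_id = subject_id, weights = weights,
                 roi_labels = as.character(roi_labels)),
            class = "connectome")
}

#' ROI-to-network parcellation table
#'
#' Maps each ROI to one of the eight resting-state networks used throughout:
#' the seven canonical cortical systems plus a subcortical grouping.
#'
#' @param roi_label character vector of ROI names.
#' @param network character vector of network labels, one per ROI, each one of
#'   VIS, SOM, DAT, VAT, LIM, FPN, DMN, SUB.
#' @return A `data.frame` of class `parcellation_table` with columns
#'   `roi_label`, `network`.
#' @export
parcellation_table <- function(roi_label, network) {
  stopifnot(length(roi_label) == length(network))
  if (anyDuplicated(roi_label)) stop("duplicated ROI label")
  bad <- setdiff(unique(network), rsn_networks())
  if (length(bad) > 0L) {
    stop("unknown network label(s): ", paste(bad, collapse = ", "))
  }
  structure(data.frame(roi_label = as.character(roi_label),
                       network = as.character(network),
                       stringsAsFactors = FALSE),
            class = c("parcellation_table", "data.frame"))
}

#' Canonical resting-state network labels
#'
#' @return Character vector: VIS, SOM, DAT, VAT, LIM, FPN, DMN, SUB.
#' @export
rsn_networks <- function() {
  c("VIS", "SOM", "DAT", "VAT", "LIM", "FPN", "DMN", "SUB")
}

#' Validate a clinical/covariate table
#'
#' Checks the per-subject clinical table consumed by the group-inference
#' stage: group labels present and in `{HC, MDD}`, covariates and symptom
#' scores finite where present.
#'
#' @param df data.frame with columns `subject`, `group`, `age`, `sex`,
#'   `medication` and score columns (`QIDS`, `MASQ_AD`, `MASQ_AA`, `MASQ_GD`,
#'   `RRS_DEP`, `RRS_BRO`, `RRS_REF`).
#' @return The validated data.frame, invisibly classed `clinical_table`.
#' @export
clinical_table <- function(df) {
  need <- c("subject", "group", "age", "sex", "medication")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("clinical table missing column(s): ", paste(miss, collapse = ", "))
  }
  if (anyNA(df$group)) stop("missing group label")
  bad <- setdiff(unique(as.character(df$group)), c("HC", "MDD"))
  if (length(bad) > 0L) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  scr <- setdiff(names(df), c("subject", "group"))
  for (s in scr) {
    v <- df[[s]]
    if (is.numeric(v) && any(!is.na(v) & !is.finite(v))) {
      stop("non-finite value in clinical column '", s, "'")
    }
  }
  class(df) <- unique(c("clinical_table", class(df)))
  invisible(df)
}

#' Read and write delimited numeric matrices
#'
#' Tab-delimited text is the on-disk convention for both BOLD matrices (ROIs
#' as rows, frames as columns) and square connectome matrices. Values
#' round-trip within `1e-12`. `kind = "connectome"` additionally validates
#' symmetry, nonnegativity and a zero diagonal; `kind = "bold"` validates
#' finiteness.
#'
#' @param path file path.
#' @param kind one of `"bold"`, `"connectome"`, `"plain"`.
#' @param transpose logical; if `TRUE` the file stores frames as rows and is
#'   transposed on read/write.
#' @return `read_matrix` returns a numeric matrix (validated per `kind`);
#'   `write_matrix` returns `path` invisibly.
#' @export
read_matrix <- function(path, kind = c("plain", "bold", "connectome"),
                        transpose = FALSE) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  rows <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(rows)
  if (length(unique(ncols)) != 1L) {
    stop("ragged rows in ", path, ": row ", which(ncols != ncols[1L])[1L],
         " has ", ncols[which(ncols != ncols[1L])[1L]],
         " fields, expected ", ncols[1L])
  }
  vals <- suppressWarnings(as.numeric(unlist(rows)))
  if (anyNA(vals)) {
    flat <- which(is.na(vals))[1L]
    stop("non-numeric cell in ", path, " at row ",
         (flat - 1L) %/% ncols[1L] + 1L, ", column ",
         (flat - 1L) %% ncols[1L] + 1L)
  }
  m <- matrix(vals, nrow = length(rows), byrow = TRUE)
  if (transpose) m <- t(m)
  if (kind == "bold" && any(!is.finite(m))) stop("non-finite BOLD value in ", path)
  if (kind == "connectome") {
    if (nrow(m) != ncol(m)) stop("connectome file not square: ", path)
    asym <- abs(m - t(m))
    if (max(asym) > 1e-9) {
      ij <- which(asym == max(asym), arr.ind = TRUE)[1L, ]
      stop("asymmetric connectome in ", path, " at [", ij[1L], ",", ij[2L], "]")
    }
    if (any(diag(m) != 0)) stop("nonzero connectome diagonal in ", path)
    if (any(m < 0)) stop("negative connectome weight in ", path)
  }
  m
}

#' @rdname read_matrix
#' @param m numeric matrix to write.
#' @export
write_matrix <- function(m, path, transpose = FALSE) {
  m <- as.matrix(m)
  if (transpose) m <- t(m)
  utils::write.table(format(m, digits = 17, scientific = TRUE, trim = TRUE),
                     path, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
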