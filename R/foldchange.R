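#' Per-patient paired log2 fold changes between pre- and on-treatment biopsies
#'
#' For every on-treatment (OT) sample whose patient has at least one
#' pre-treatment (PT) sample, computes
#' `log2FC(gene, OT) = value(gene, OT) - mean over the patient's PT samples`.
#' Each retained OT sample contributes one fold-change column; the column
#' inherits the OT sample's therapy and response labels. OT samples without a
#' PT partner, or with unknown response, are skipped with a warning.
#'
#' @param matrix A `normalized_matrix` of log2-CPM values.
#' @param data The [annotated_counts] object the matrix was derived from
#'   (source of the patient/timepoint/response annotation). Defaults to the
#'   annotation carried by `matrix`.
#'
#' @return An object of class `fold_change_table`: list with `log2fc`
#'   (genes x pairs matrix, columns named by OT sample) and `pairs`
#'   (data frame with `patient_id`, `ot_sample_id`, `therapy`, `response`).
#' @export
paired_log2fc <- function(matrix, data = NULL) {
  vals <- normalized_values(matrix)
  ann <- if (!is.null(data)) {
    stopifnot(inherits(data, "annotated_counts"))
    data$annotation
  } else if (inherits(matrix, "normalized_matrix")) {
    matrix$annotation
  }
  if (is.null(ann)) abort("no sample annotation available")
  if (!all(colnames(vals) %in% ann$sample_id)) {
    abort("matrix contains samples absent from the annotation")
  }
  ann <- ann[match(colnames(vals), ann$sample_id), , drop = FALSE]
  ot_idx <- which(ann$timepoint == "OT")
  cols <- list()
  pairs <- list()
  for (i in ot_idx) {
    pt <- which(ann$patient_id == ann$patient_id[i] & ann$timepoint == "PT")
    if (!length(pt)) {
      warnf("OT sample %s skipped: patient %s has no PT sample",
            ann$sample_id[i], ann$patient_id[i])
      next
    }
    if (!ann$response[i] %in% c("R", "NR")) {
      warnf("OT sample %s skipped: response is '%s'",
            ann$sample_id[i], ann$response[i])
      next
    }
    cols[[ann$sample_id[i]]] <- vals[, i] - rowMeans(vals[, pt, drop = FALSE])
    pairs[[ann$sample_id[i]]] <- data.frame(
      patient_id = ann$patient_id[i], ot_sample_id = ann$sample_id[i],
      therapy = ann$therapy[i], response = ann$response[i],
      stringsAsFactors = FALSE)
  }
  if (!length(cols)) abort("no usable (PT, OT) pairs found")
  fc <- do.call(cbind, cols)
  rownames(fc) <- rownames(vals)
  pair_df <- do.call(rbind, pairs)
  rownames(pair_df) <- NULL
  structure(list(log2fc = fc, pairs = pair_df), class = "fold_change_table")
}

#' @export
print.fold_change_table <- function(x, ...) {
  cat(sprintf("fold_change_table: %d genes x %d (PT,OT) pairs\n",
              nrow(x$log2fc), ncol(x$log2fc)))
  print(table(therapy = x$pairs$therapy, response = x$pairs$response))
  invisible(x)
}
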