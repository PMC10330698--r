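#' Construct an annotated count matrix
#'
#' Bundles a gene x sample matrix of sequencing counts with the per-sample
#' clinical annotation used throughout the paired-biopsy analysis:
#' patient identity, therapy arm, biopsy timepoint (pre- vs on-treatment),
#' clinical response, and processing batch.
#'
#' @param counts Numeric matrix of non-negative counts, genes in rows and
#'   samples in columns. Row and column names are required and must be unique.
#' @param annotation Data frame with one row per sample and columns
#'   `sample_id`, `patient_id`, `therapy`, `timepoint` (`"PT"` or `"OT"`),
#'   `response` (`"R"`, `"NR"` or `"unknown"`) and `batch`.
#'
#' @return An object of class `annotated_counts`: a list with elements
#'   `counts` (matrix) and `annotation` (data frame, rows ordered to match
#'   the matrix columns).
#' @export
annotated_counts <- function(counts, annotation) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("`counts` must have gene row names and sample column names")
  }
  dup_g <- unique(rownames(counts)[duplicated(rownames(counts))])
  if (length(dup_g)) {
    abort("duplicate gene IDs: %s", paste(dup_g, collapse = ", "))
  }
  dup_s <- unique(colnames(counts)[duplicated(colnames(counts))])
  if (length(dup_s)) {
    abort("duplicate sample IDs: %s", paste(dup_s, collapse = ", "))
  }
  if (!is.numeric(counts)) {
    abort("counts must be numeric")
  }
  bad <- which(!is.finite(counts) | counts < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    abort("negative or non-finite counts, e.g. gene %s in sample %s",
          rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]])
  }
  annotation <- as.data.frame(annotation, stringsAsFactors = FALSE)
  req <- c("sample_id", "patient_id", "therapy", "timepoint", "response", "batch")
  miss_col <- setdiff(req, names(annotation))
  if (length(miss_col)) {
    abort("annotation lacks columns: %s", paste(miss_col, collapse = ", "))
  }
  if (anyDuplicated(annotation$sample_id)) {
    abort("duplicate sample IDs in annotation: %s",
          paste(unique(annotation$sample_id[duplicated(annotation$sample_id)]),
                collapse = ", "))
  }
  missing_ann <- setdiff(colnames(counts), annotation$sample_id)
  if (length(missing_ann)) {
    abort("samples missing annotation: %s", paste(missing_ann, collapse = ", "))
  }
  annotation <- annotation[match(colnames(counts), annotation$sample_id), , drop = FALSE]
  rownames(annotation) <- NULL
  bad_tp <- setdiff(unique(annotation$timepoint), c("PT", "OT"))
  if (length(bad_tp)) {
    abort("timepoint must be 'PT' or 'OT'; found: %s", paste(bad_tp, collapse = ", "))
  }
  bad_resp <- setdiff(unique(annotation$response), c("R", "NR", "unknown"))
  if (length(bad_resp)) {
    abort("response must be 'R', 'NR' or 'unknown'; found: %s",
          paste(bad_resp, collapse = ", "))
  }
  structure(list(counts = counts, annotation = annotation),
            class = "annotated_counts")
}

#' Read a count matrix and its sample annotation from TSV files
#'
#' The counts file carries gene IDs in the first column and one column per
#' sample; the annotation file is keyed by `sample_id` and must cover every
#' sample in the counts file.
#'
#' @param counts_path Path to the tab-delimited counts file.
#' @param annotation_path Path to the tab-delimited annotation file with
#'   header `sample_id, patient_id, therapy, timepoint, response, batch`.
#'
#' @return An [annotated_counts] object; sample order follows the counts file.
#' @export
read_counts <- function(counts_path, annotation_path) {
  raw <- utils::read.delim(counts_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2) abort("counts file must have a gene column plus samples")
  genes <- as.character(raw[[1]])
  mat <- raw[, -1, drop = FALSE]
  non_num <- names(mat)[!vapply(mat, is.numeric, logical(1))]
  if (length(non_num)) {
    abort("non-numeric counts in sample(s): %s", paste(non_num, collapse = ", "))
  }
  mat <- as.matrix(mat)
  rownames(mat) <- genes
  ann <- utils::read.delim(annotation_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  annotated_counts(mat, ann)
}

#' Write an annotated count matrix to TSV files
#'
#' @param data An [annotated_counts] object.
#' @param counts_path,annotation_path Output paths.
#' @return Invisibly, `data`.
#' @export
write_counts <- function(data, counts_path, annotation_path) {
  stopifnot(inherits(data, "annotated_counts"))
  write_matrix_tsv(data$counts, counts_path, id_col = "gene_id")
  utils::write.table(data$annotation, annotation_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(data)
}

# genes-as-rows TSV writer used by several modules
write_matrix_tsv <- function(mat, path, id_col = "gene_id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.annotated_counts <- function(x, ...) {
  cat(sprintf("annotated_counts: %d genes x %d samples (%d patients, therapies: %s)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$annotation$patient_id)),
              paste(sort(unique(x$annotation$therapy)), collapse = ", ")))
  invisible(x)
}
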