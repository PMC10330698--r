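#' TMM normalization and log2 counts-per-million
#'
#' Computes trimmed-mean-of-M-values scaling factors against a reference
#' sample (the sample whose upper-quartile count fraction is closest to the
#' cohort mean), re-centers the factors to geometric mean 1, and converts
#' counts to `log2(1e6 * count / (lib_size * factor) + prior)`.
#'
#' @param data An [annotated_counts] object, or a non-negative count matrix
#'   with gene row names and sample column names.
#' @param trim_m Two-sided trim fraction applied to the M-values (log ratios).
#' @param trim_a Two-sided trim fraction applied to the A-values
#'   (average log abundances).
#' @param prior Pseudo-count added on the CPM scale before taking log2.
#'
#' @return An object of class `normalized_matrix`: list with `values`
#'   (log2-CPM matrix), `tmm_factors`, `effective_lib_sizes`, and the sample
#'   `annotation` when the input carried one.
#' @export
tmm_normalize <- function(data, trim_m = 0.30, trim_a = 0.05, prior = 1) {
  annotation <- NULL
  if (inherits(data, "annotated_counts")) {
    annotation <- data$annotation
    counts <- data$counts
  } else {
    counts <- as.matrix(data)
  }
  if (ncol(counts) < 2) abort("TMM normalization needs at least 2 samples")
  lib <- colSums(counts)
  zero <- colnames(counts)[lib == 0]
  if (length(zero)) abort("all-zero sample(s): %s", paste(zero, collapse = ", "))
  assert_scalar_number(trim_m, "trim_m", 0, 0.5)
  assert_scalar_number(trim_a, "trim_a", 0, 0.5)
  assert_scalar_number(prior, "prior", 0)
  f <- edgeR::calcNormFactors(counts, method = "TMM",
                              logratioTrim = trim_m, sumTrim = trim_a)
  names(f) <- colnames(counts)
  eff <- lib * f
  values <- log2(sweep(counts, 2, eff, "/") * 1e6 + prior)
  structure(list(values = values, tmm_factors = f,
                 effective_lib_sizes = eff, annotation = annotation),
            class = "normalized_matrix")
}

#' Remove an additive batch component from a normalized matrix
#'
#' Per gene, fits least squares of expression on the preserved-group design
#' plus sum-to-zero-coded batch indicators and subtracts only the fitted
#' batch component, so group means are untouched and the overall expression
#' level per gene is preserved.
#'
#' @param matrix A `normalized_matrix` (from [tmm_normalize()]) or a plain
#'   numeric matrix of log-scale values.
#' @param batch Per-sample batch labels.
#' @param preserve Optional per-sample biological group labels whose mean
#'   differences must survive the correction (e.g. therapy x timepoint x
#'   response).
#'
#' @return The input with `values` replaced by the batch-centered matrix.
#' @export
remove_batch <- function(matrix, batch, preserve = NULL) {
  vals <- normalized_values(matrix)
  batch <- as.factor(batch)
  if (length(batch) != ncol(vals)) {
    abort("`batch` must have one label per sample")
  }
  if (nlevels(droplevels(batch)) < 2) {
    return(replace_values(matrix, vals))   # single batch: nothing to remove
  }
  design <- NULL
  if (!is.null(preserve)) {
    preserve <- as.factor(preserve)
    if (length(preserve) != ncol(vals)) {
      abort("`preserve` must have one label per sample")
    }
    design <- stats::model.matrix(~preserve)
    # sum-to-zero batch contrasts, as used for the removal itself
    cb <- stats::contr.sum(nlevels(droplevels(batch)))
    bmat <- cb[as.integer(droplevels(batch)), , drop = FALSE]
    full <- cbind(design, bmat)
    if (qr(full)$rank < ncol(full)) {
      abort(paste("batch is confounded with the preserved groups:",
                  "the joint design is rank deficient, so batch and group",
                  "effects cannot be separated"))
    }
  }
  corrected <- limma::removeBatchEffect(vals, batch = batch, design = design)
  replace_values(matrix, corrected)
}

normalized_values <- function(x) {
  if (inherits(x, "normalized_matrix")) x$values else as.matrix(x)
}

replace_values <- function(x, vals) {
  if (inherits(x, "normalized_matrix")) {
    x$values <- vals
    x
  } else {
    vals
  }
}

#' Write a normalized matrix to TSV (genes x samples)
#'
#' @param matrix A `normalized_matrix` or numeric matrix.
#' @param path Output path.
#' @export
write_normalized <- function(matrix, path) {
  write_matrix_tsv(normalized_values(matrix), path, id_col = "gene_id")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("normalized_matrix: %d genes x %d samples; TMM factor range [%.3f, %.3f]\n",
              nrow(x$values), ncol(x$values),
              min(x$tmm_factors), max(x$tmm_factors)))
  invisible(x)
}
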