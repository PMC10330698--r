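#' Read gene sets from a GMT file
#'
#' GMT dialect: one set per line, `name TAB description TAB gene TAB gene ...`.
#'
#' @param path Path to the GMT file.
#' @return A named list of `gene_set` objects, each a list with `name`,
#'   `source` (the description field) and `genes` (unique character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  sets <- lapply(keep, function(i) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      abort("GMT line %d has %d field(s); need name, description and >= 1 gene",
            i, length(fields))
    }
    gene_set(fields[1], unique(fields[-(1:2)]), source = fields[2])
  })
  names(sets) <- vapply(sets, `[[`, character(1), "name")
  sets
}

#' Construct a gene set
#'
#' @param name Non-empty set name.
#' @param genes Non-empty character vector of gene IDs (made unique).
#' @param source Free-text provenance.
#' @return A `gene_set` object.
#' @export
gene_set <- function(name, genes, source = "") {
  if (!nzchar(name)) abort("gene set name must be non-empty")
  genes <- unique(as.character(genes))
  genes <- genes[nzchar(genes)]
  if (!length(genes)) abort("gene set '%s' has no genes", name)
  structure(list(name = name, source = source, genes = genes),
            class = "gene_set")
}

#' Write gene sets to a GMT file
#'
#' @param sets A list of `gene_set` objects.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    paste(c(s$name, s$source, s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Single-sample gene-set enrichment score
#'
#' Scores one gene set in every sample of a log-expression matrix. The
#' default `"ssgsea"` method is a rank-based weighted Kolmogorov-Smirnov
#' statistic: within each sample, genes are ranked by expression (ties get
#' the average rank); walking down the ranking, member genes advance an
#' in-set running sum in proportion to `rank^alpha` and non-members advance
#' the complement; the score is the sum of the running-sum differences.
#' `"mean_z"` averages the per-gene z-scores (standardized across samples)
#' of the member genes. Scores are comparable across samples within a set,
#' not across sets.
#'
#' @param matrix A `normalized_matrix` or numeric matrix (genes x samples).
#' @param set A `gene_set`.
#' @param method `"ssgsea"` or `"mean_z"`.
#' @param alpha Rank-weight exponent of the ssgsea statistic.
#' @param min_overlap Minimum number of set genes present in the matrix;
#'   below it the set is skipped (returns `NULL` with a warning).
#' @return Named numeric vector of per-sample scores, or `NULL`.
#' @export
single_sample_score <- function(matrix, set, method = c("ssgsea", "mean_z"),
                                alpha = 0.25, min_overlap = 3) {
  method <- match.arg(method)
  vals <- normalized_values(matrix)
  members <- intersect(set$genes, rownames(vals))
  if (length(members) < min_overlap) {
    warnf("gene set '%s' skipped: only %d of %d genes present (min_overlap = %d)",
          set$name, length(members), length(set$genes), min_overlap)
    return(NULL)
  }
  if (method == "mean_z") {
    mu <- rowMeans(vals)
    sdv <- apply(vals, 1, stats::sd)
    sdv[sdv == 0] <- Inf          # flat genes contribute z = 0
    z <- (vals - mu) / sdv
    return(colMeans(z[members, , drop = FALSE]))
  }
  is_member <- rownames(vals) %in% members
  apply(vals, 2, ssgsea_sample_score, is_member = is_member, alpha = alpha)
}

# weighted-KS running-sum score for one sample
ssgsea_sample_score <- function(v, is_member, alpha) {
  r <- rank(v)                          # ties -> average rank
  ord <- order(r, decreasing = TRUE)
  memb <- is_member[ord]
  w <- r[ord]^alpha * memb
  p_in <- cumsum(w) / sum(w)
  p_out <- cumsum(!memb) / sum(!memb)
  sum(p_in - p_out)
}

#' Score a collection of gene sets across samples
#'
#' @inheritParams single_sample_score
#' @param sets List of `gene_set` objects.
#' @return A set x sample score matrix with attribute `method`; sets falling
#'   below `min_overlap` are dropped with a warning.
#' @export
score_gene_sets <- function(matrix, sets, method = c("ssgsea", "mean_z"),
                            alpha = 0.25, min_overlap = 3) {
  method <- match.arg(method)
  rows <- lapply(sets, single_sample_score, matrix = matrix, method = method,
                 alpha = alpha, min_overlap = min_overlap)
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) abort("no gene set passed the minimum-overlap filter")
  out <- do.call(rbind, rows)
  structure(out, method = method)
}

#' Marker-mean cell-population abundance
#'
#' Estimates the abundance of each population as the arithmetic mean of the
#' log2-CPM values of its marker genes present in the matrix, the
#' marker-mean estimator used by transcriptome-based immune-population
#' counters.
#'
#' @param matrix A `normalized_matrix` or numeric matrix (genes x samples).
#' @param populations List of `gene_set` objects, one per population.
#' @return Population x sample matrix; populations without any present
#'   marker are dropped with a warning.
#' @export
marker_abundance <- function(matrix, populations) {
  vals <- normalized_values(matrix)
  rows <- lapply(populations, function(p) {
    present <- intersect(p$genes, rownames(vals))
    if (!length(present)) {
      warnf("population '%s' dropped: no marker genes present", p$name)
      return(NULL)
    }
    colMeans(vals[present, , drop = FALSE])
  })
  names(rows) <- vapply(populations, `[[`, character(1), "name")
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) abort("no population has marker genes in the matrix")
  do.call(rbind, rows)
}

#' Overlap-based gene-set enrichment (one-sided Fisher exact test)
#'
#' For each collection set (intersected with the universe), tests whether the
#' query over-represents the set using the one-sided Fisher exact test on the
#' 2x2 membership table over the universe, with Benjamini-Hochberg
#' adjustment across the collection.
#'
#' @param query Character vector of gene IDs, a subset of `universe`.
#' @param collection List of `gene_set` objects.
#' @param universe Character vector defining the background gene universe.
#' @return Data frame with columns `set`, `set_size`, `overlap`,
#'   `odds_ratio`, `p`, `q`.
#' @export
overlap_enrichment <- function(query, collection, universe) {
  universe <- unique(as.character(universe))
  query <- unique(as.character(query))
  if (!length(universe)) abort("empty universe")
  if (!length(query)) abort("empty query")
  outside <- setdiff(query, universe)
  if (length(outside)) {
    abort("query genes outside the universe: %s",
          paste(utils::head(outside, 5), collapse = ", "))
  }
  n_u <- length(universe)
  n_q <- length(query)
  rows <- lapply(collection, function(s) {
    genes <- intersect(s$genes, universe)
    a <- length(intersect(query, genes))
    b <- n_q - a
    c_ <- length(genes) - a
    d <- n_u - n_q - c_
    tab <- matrix(c(a, c_, b, d), nrow = 2)
    p <- stats::fisher.test(tab, alternative = "greater")$p.value
    data.frame(set = s$name, set_size = length(genes), overlap = a,
               odds_ratio = (a * d) / (b * c_), p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$q <- bh_adjust(out$p)
  out
}
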