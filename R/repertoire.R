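#' Read a clonotype table (AIRR-style TSV)
#'
#' Required columns: `sample_id`, `chain` (one of IGH, IGK, IGL, TRA, TRB,
#' TRD, TRG), `cdr3_nt`, `cdr3_aa`, `v_gene`, `j_gene`, `count`,
#' `productive` (logical).
#'
#' @param path Path to the tab-delimited clonotype file.
#' @return A validated clonotype data frame.
#' @export
read_clonotypes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_clonotypes(df)
}

#' Write a clonotype table to TSV
#' @param records Clonotype data frame.
#' @param path Output path.
#' @export
write_clonotypes <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Validate a clonotype data frame
#'
#' Checks the required columns, chain vocabulary, positive counts, non-empty
#' nucleotide junctions, and amino-acid/nucleotide length consistency
#' (`3 * nchar(cdr3_aa) == nchar(cdr3_nt)` where both are present).
#'
#' @param records Data frame of clonotype records.
#' @return The data frame, invisibly validated (logical `productive` coerced).
#' @export
validate_clonotypes <- function(records) {
  req <- c("sample_id", "chain", "cdr3_nt", "cdr3_aa", "v_gene", "j_gene",
           "count", "productive")
  miss <- setdiff(req, names(records))
  if (length(miss)) abort("clonotype table lacks columns: %s",
                          paste(miss, collapse = ", "))
  chains <- c("IGH", "IGK", "IGL", "TRA", "TRB", "TRD", "TRG")
  bad <- setdiff(unique(records$chain), chains)
  if (length(bad)) abort("unknown chain(s): %s", paste(bad, collapse = ", "))
  if (any(!nzchar(records$cdr3_nt))) abort("empty cdr3_nt in row(s): %s",
      paste(utils::head(which(!nzchar(records$cdr3_nt)), 5), collapse = ", "))
  if (any(!is.finite(records$count) | records$count < 1)) {
    abort("counts must be >= 1")
  }
  records$productive <- as.logical(records$productive)
  both <- nzchar(records$cdr3_aa) & nzchar(records$cdr3_nt)
  inconsistent <- which(both &
                        nchar(records$cdr3_nt) != 3L * nchar(records$cdr3_aa))
  if (length(inconsistent)) {
    abort("cdr3_nt length is not 3 x cdr3_aa length in row(s): %s",
          paste(utils::head(inconsistent, 5), collapse = ", "))
  }
  records
}

#' Keep only productive clonotype records
#'
#' Drops records not flagged productive and records whose amino-acid
#' junction contains a stop (`*`) or frameshift (`_`) symbol.
#'
#' @param records Clonotype data frame.
#' @return The productive subset.
#' @export
filter_productive <- function(records) {
  keep <- records$productive & !grepl("[*_]", records$cdr3_aa)
  records[keep, , drop = FALSE]
}

#' Merge convergent clonotypes
#'
#' Clonotypes with identical amino-acid junctions but different nucleotide
#' sequences (within one sample and chain) are merged: counts are summed and
#' the representative nucleotide sequence is the highest-count member
#' (ties broken by lexicographic order).
#'
#' @param records Clonotype data frame.
#' @return Merged clonotype data frame, one row per
#'   (sample, chain, cdr3_aa).
#' @export
merge_convergent <- function(records) {
  if (!nrow(records)) return(records)
  key <- paste(records$sample_id, records$chain, records$cdr3_aa, sep = "\r")
  ord <- order(key, -records$count, records$cdr3_nt)
  records <- records[ord, , drop = FALSE]
  key <- key[ord]
  first <- !duplicated(key)
  out <- records[first, , drop = FALSE]
  out$count <- as.vector(tapply(records$count, key, sum)[key[first]])
  rownames(out) <- NULL
  out
}

#' Richness, Shannon diversity and clonality of a clone-size distribution
#'
#' With clone frequencies `p_i = count_i / sum(count)`, Shannon entropy is
#' `H = -sum(p_i log p_i)` in nats; normalized diversity (Pielou evenness)
#' is `H / log(richness)` for more than one clone; clonality is
#' `1 - normalized diversity`. A monoclonal repertoire has, by convention,
#' normalized diversity 0 and clonality 1.
#'
#' @param counts Positive clone counts, or a clonotype data frame (its
#'   `count` column is used).
#' @param weighted If `FALSE`, every clone gets weight 1 instead of its
#'   count (clone-weighted metrics).
#' @return List with `richness`, `shannon`, `normalized_diversity`,
#'   `clonality`.
#' @export
diversity_metrics <- function(counts, weighted = TRUE) {
  if (is.data.frame(counts)) counts <- counts$count
  if (!length(counts)) abort("empty repertoire")
  if (any(!is.finite(counts) | counts <= 0)) abort("counts must be positive")
  if (!weighted) counts <- rep(1, length(counts))
  p <- counts / sum(counts)
  h <- -sum(p * log(p))
  richness <- length(counts)
  if (richness > 1) {
    nd <- h / log(richness)
    clonality <- 1 - nd
  } else {
    nd <- 0
    clonality <- 1
  }
  list(richness = richness, shannon = h, normalized_diversity = nd,
       clonality = clonality)
}

# normalized Hamming distance matrix for equal-length sequences
hamming_matrix <- function(seqs) {
  n <- length(seqs)
  m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    mism <- colMeans(t(m[(i + 1):n, , drop = FALSE]) != m[i, ])
    d[i, (i + 1):n] <- mism
    d[(i + 1):n, i] <- mism
  }
  d
}

# per-sequence nearest-neighbor normalized Hamming distances within
# (v_gene, j_gene, junction length) partitions
nearest_neighbor_distances <- function(records) {
  key <- paste(records$v_gene, records$j_gene, nchar(records$cdr3_nt),
               sep = "\r")
  unlist(lapply(split(records$cdr3_nt, key), function(seqs) {
    seqs <- unique(seqs)
    if (length(seqs) < 2) return(numeric(0))
    d <- hamming_matrix(seqs)
    diag(d) <- Inf
    apply(d, 1, min)
  }), use.names = FALSE)
}

#' Valley of a bimodal distance distribution
#'
#' Fits a Gaussian kernel density (Silverman's rule-of-thumb bandwidth) to
#' the supplied distances, finds its local maxima, and returns the position
#' of the density minimum between the two highest maxima. Returns the 0.1
#' fallback (with attribute `branch = "unimodal"`) when the density has
#' fewer than two local maxima.
#'
#' @param distances Numeric vector of distances in `[0, 1]`.
#' @param fallback Threshold returned when no valley exists.
#' @return The threshold, with attribute `branch` (`"bimodal"` or
#'   `"unimodal"`).
#' @export
detect_bimodal_threshold <- function(distances, fallback = 0.1) {
  dens <- stats::density(distances, bw = "nrd0")
  y <- dens$y
  n <- length(y)
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n],
              FALSE)
  # ignore negligible bumps (sampling noise) in the density tails
  peaks <- which(is_max & y >= 0.05 * max(y))
  if (length(peaks) < 2) {
    return(structure(fallback, branch = "unimodal"))
  }
  top2 <- peaks[order(y[peaks], decreasing = TRUE)][1:2]
  lo <- min(top2); hi <- max(top2)
  valley <- lo + which.min(y[lo:hi]) - 1L
  if (y[valley] >= 0.99 * min(y[top2])) {
    # no real dip between the two highest peaks: treat as unimodal
    return(structure(fallback, branch = "unimodal"))
  }
  structure(dens$x[valley], branch = "bimodal")
}

#' Automatic clustering threshold from nearest-neighbor junction distances
#'
#' Pools every sequence's nearest-neighbor normalized Hamming distance
#' within its (V gene, J gene, junction length) partition and places the
#' threshold at the density valley between the two modes of the resulting
#' bimodal distribution (somatic variants near zero, unrelated clones far
#' away). Falls back to 0.1 when fewer than 20 distances are available or
#' the distribution is unimodal.
#'
#' @param records Clonotype data frame (heavy-chain records).
#' @param fallback Threshold used by the fallback branches.
#' @return The threshold, with attribute `branch` naming the branch that
#'   fired (`"bimodal"`, `"unimodal"` or `"data_poor"`).
#' @export
find_threshold <- function(records, fallback = 0.1) {
  d <- nearest_neighbor_distances(records)
  if (length(d) < 20) {
    message(sprintf("threshold fallback %.3g: only %d nearest-neighbor distances",
                    fallback, length(d)))
    return(structure(fallback, branch = "data_poor"))
  }
  thr <- detect_bimodal_threshold(d, fallback = fallback)
  if (attr(thr, "branch") == "unimodal") {
    message(sprintf("threshold fallback %.3g: distance distribution is unimodal",
                    fallback))
  }
  thr
}

#' Infer germline clone lineages from heavy-chain junctions
#'
#' Partitions records by (V gene, J gene, junction length) and, within each
#' partition, single-linkage clusters the distinct nucleotide junctions
#' under normalized Hamming distance, cutting the dendrogram at the
#' threshold. Each cluster is one inferred germline clone; its distinct
#' nucleotide sequences are the mature (somatic-hypermutation-derived)
#' clones.
#'
#' @param records Productive, convergence-merged IGH clonotype records.
#' @param threshold Normalized Hamming distance cut in `(0, 1)`, or
#'   `"auto"` to estimate it with [find_threshold()].
#' @return A list of `clone_lineage` objects (fields `germline_clone_id`,
#'   `v_gene`, `j_gene`, `junction_length`, `mature_clones`, `total_count`),
#'   with attributes `assignments` (per input record, its lineage ID) and
#'   `threshold`.
#' @export
infer_lineages <- function(records, threshold = "auto") {
  if (!nrow(records)) abort("no records to cluster")
  non_igh <- records$chain != "IGH"
  if (all(non_igh)) abort("lineage inference needs IGH records")
  if (any(non_igh)) {
    warnf("%d non-IGH record(s) ignored", sum(non_igh))
    records <- records[!non_igh, , drop = FALSE]
  }
  if (identical(threshold, "auto")) {
    threshold <- find_threshold(records)
  }
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) {
    abort("threshold must lie in (0, 1)")
  }
  key <- paste(records$v_gene, records$j_gene, nchar(records$cdr3_nt),
               sep = "|")
  assignment <- character(nrow(records))
  lineages <- list()
  for (k in unique(key)) {
    idx <- which(key == k)
    seqs <- unique(records$cdr3_nt[idx])
    if (length(seqs) == 1) {
      cl <- stats::setNames(1L, seqs)
    } else {
      d <- stats::as.dist(hamming_matrix(seqs))
      hc <- stats::hclust(d, method = "single")
      cl <- stats::setNames(stats::cutree(hc, h = threshold), seqs)
    }
    for (g in sort(unique(cl))) {
      members <- names(cl)[cl == g]
      member_rows <- idx[records$cdr3_nt[idx] %in% members]
      id <- sprintf("%s_%02d", gsub("|", "_", k, fixed = TRUE), g)
      assignment[member_rows] <- id
      lineages[[id]] <- structure(
        list(germline_clone_id = id,
             v_gene = records$v_gene[idx[1]],
             j_gene = records$j_gene[idx[1]],
             junction_length = nchar(records$cdr3_nt[idx[1]]),
             mature_clones = members,
             total_count = sum(records$count[member_rows])),
        class = "clone_lineage")
    }
  }
  structure(unname(lineages), assignments = assignment,
            threshold = as.numeric(threshold))
}

#' Somatic-hypermutation occurrence frequency
#'
#' The number of germline clones associated with more than one mature clone,
#' divided by the total number of germline clones.
#'
#' @param lineages List of `clone_lineage` objects from [infer_lineages()].
#' @return A fraction in `[0, 1]`.
#' @export
shm_frequency <- function(lineages) {
  if (!length(lineages)) abort("empty lineage list")
  mean(vapply(lineages, function(l) length(l$mature_clones) >= 2, logical(1)))
}

#' Fraction of on-treatment clones absent before treatment
#'
#' Clone identity is the amino-acid junction; the fraction is taken over the
#' distinct on-treatment clones.
#'
#' @param pre,post Clonotype data frames for the pre- and on-treatment
#'   repertoires of one patient and chain.
#' @return A fraction in `[0, 1]` (1 = complete clonal replacement).
#' @export
novel_clone_fraction <- function(pre, post) {
  if (!nrow(post)) abort("empty on-treatment repertoire")
  if (!nrow(pre)) abort("empty pre-treatment repertoire")
  post_aa <- unique(post$cdr3_aa)
  mean(!(post_aa %in% unique(pre$cdr3_aa)))
}

#' Per-sample, per-chain repertoire metrics table
#'
#' Applies [diversity_metrics()] to every (sample, chain) repertoire and,
#' for IGH repertoires, adds the somatic-hypermutation frequency computed
#' from inferred lineages.
#'
#' @param records Productive, convergence-merged clonotype records.
#' @param threshold Lineage clustering threshold, or `"auto"` (per sample).
#' @param weighted Count-weighted (default) or clone-weighted diversity.
#' @return Data frame with columns `sample_id`, `chain`, `richness`,
#'   `shannon`, `normalized_diversity`, `clonality`, `shm_frequency`
#'   (NA for non-IGH chains).
#' @export
repertoire_metrics <- function(records, threshold = "auto", weighted = TRUE) {
  if (!nrow(records)) abort("empty clonotype table")
  groups <- split(records, paste(records$sample_id, records$chain, sep = "\r"))
  rows <- lapply(groups, function(g) {
    m <- diversity_metrics(g$count, weighted = weighted)
    shm <- NA_real_
    if (g$chain[1] == "IGH") {
      shm <- shm_frequency(infer_lineages(g, threshold = threshold))
    }
    data.frame(sample_id = g$sample_id[1], chain = g$chain[1],
               richness = m$richness, shannon = m$shannon,
               normalized_diversity = m$normalized_diversity,
               clonality = m$clonality, shm_frequency = shm,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$sample_id, out$chain), , drop = FALSE]
}

#' @export
print.clone_lineage <- function(x, ...) {
  cat(sprintf("clone_lineage %s: %s/%s, junction %d nt, %d mature clone(s), total count %d\n",
              x$germline_clone_id, x$v_gene, x$j_gene, x$junction_length,
              length(x$mature_clones), x$total_count))
  invisible(x)
}
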