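#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Thin validated wrapper around the step-up procedure:
#' `q_(i) = min over j >= i of (m * p_(j) / j)`, capped at 1 and mapped back
#' to the input order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values)) abort("p-values must be numeric")
  if (any(!is.finite(p_values) | p_values < 0 | p_values > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Responder contrast on paired fold changes within one therapy
#'
#' The per-gene statistic is the difference between the arithmetic mean of
#' the paired log2 fold changes in responder pairs and in non-responder
#' pairs, `delta_fc = mean(FC_R) - mean(FC_NR)`, tested with a two-sided
#' two-sample t-test (Welch by default) and Benjamini-Hochberg adjusted
#' across all tested genes. Up-regulated differential genes satisfy
#' `delta_fc >= fc_threshold` and `q < q_threshold`; down-regulated genes
#' satisfy the mirrored rule.
#'
#' @param fc A `fold_change_table` from [paired_log2fc()].
#' @param therapy The therapy label whose pairs are contrasted.
#' @param fc_threshold Minimum `|delta_fc|` in log2 units (1 = two-fold).
#' @param q_threshold FDR cutoff on the adjusted p-value.
#' @param var_equal Use the pooled-variance (Student) t-test instead of
#'   Welch's unequal-variance test.
#'
#' @return An object of class `delta_fc_result`: list with `table`
#'   (per-gene data frame: `gene`, `mean_fc_R`, `mean_fc_NR`, `delta_fc`,
#'   `t`, `p`, `q`, `n_R`, `n_NR`, `direction`), the `up` and `down` gene
#'   vectors, `therapy`, and `dropped` (genes with too few finite values).
#' @export
delta_fc_test <- function(fc, therapy, fc_threshold = 1, q_threshold = 0.05,
                          var_equal = FALSE) {
  stopifnot(inherits(fc, "fold_change_table"))
  sel <- fc$pairs$therapy == therapy
  if (!any(sel)) abort("no pairs found for therapy '%s'", therapy)
  r_cols <- which(sel & fc$pairs$response == "R")
  nr_cols <- which(sel & fc$pairs$response == "NR")
  if (length(r_cols) < 2 || length(nr_cols) < 2) {
    abort("therapy '%s' needs >= 2 responder and >= 2 non-responder pairs (got %d R, %d NR)",
          therapy, length(r_cols), length(nr_cols))
  }
  xr <- fc$log2fc[, r_cols, drop = FALSE]
  xnr <- fc$log2fc[, nr_cols, drop = FALSE]
  genes <- rownames(fc$log2fc)

  n_r <- rowSums(is.finite(xr))
  n_nr <- rowSums(is.finite(xnr))
  testable <- n_r >= 2 & n_nr >= 2
  dropped <- genes[!testable]
  if (length(dropped)) {
    warnf("%d gene(s) dropped: fewer than 2 finite fold changes in a group",
          length(dropped))
  }
  xr <- xr[testable, , drop = FALSE]
  xnr <- xnr[testable, , drop = FALSE]
  genes <- genes[testable]

  mr <- rowMeans(xr, na.rm = TRUE)
  mnr <- rowMeans(xnr, na.rm = TRUE)
  tt <- vapply(seq_along(genes), function(i) {
    a <- xr[i, ][is.finite(xr[i, ])]
    b <- xnr[i, ][is.finite(xnr[i, ])]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      # no within-group variation: the t statistic is undefined. Identical
      # constants are non-evidence (p = 1); distinct constants are perfect
      # separation (p = 0).
      return(c(NA_real_, as.numeric(mean(a) == mean(b))))
    }
    res <- stats::t.test(a, b, var.equal = var_equal)
    c(unname(res$statistic), res$p.value)
  }, numeric(2))
  flat <- sum(is.na(tt[1, ]))
  if (flat) {
    message(sprintf("%d gene(s) had zero variance in both groups; p set to 1", flat))
  }
  p <- tt[2, ]
  q <- bh_adjust(p)
  delta <- mr - mnr
  direction <- rep("none", length(genes))
  direction[delta >= fc_threshold & q < q_threshold] <- "up"
  direction[delta <= -fc_threshold & q < q_threshold] <- "down"
  table <- data.frame(gene = genes, mean_fc_R = mr, mean_fc_NR = mnr,
                      delta_fc = delta, t = tt[1, ], p = p, q = q,
                      n_R = n_r[testable], n_NR = n_nr[testable],
                      direction = direction, row.names = NULL,
                      stringsAsFactors = FALSE)
  structure(list(table = table,
                 up = genes[direction == "up"],
                 down = genes[direction == "down"],
                 therapy = therapy, dropped = dropped,
                 fc_threshold = fc_threshold, q_threshold = q_threshold),
            class = "delta_fc_result")
}

#' Cross-therapy contrast of responder fold-change statistics
#'
#' Selects genes whose responder contrast is specific to one therapy:
#' a gene is assigned to therapy A when
#' `delta_fc_A - delta_fc_B >= ddfc_threshold` and
#' `delta_fc_A >= within_threshold`; assignment to therapy B follows the
#' symmetric rule; all other genes are `"neither"`. Computed over the
#' intersection of the two tested gene universes.
#'
#' @param result_a,result_b `delta_fc_result` objects for the two therapies.
#' @param ddfc_threshold Minimum cross-therapy difference of the two
#'   responder contrasts (log2 units).
#' @param within_threshold Minimum within-therapy responder contrast
#'   (log2 units) for the therapy the gene is assigned to.
#'
#' @return An object of class `cross_therapy_result`: data frame with
#'   columns `gene`, `delta_fc_<A>`, `delta_fc_<B>`, `ddfc`, `selected_for`.
#' @export
cross_therapy_contrast <- function(result_a, result_b, ddfc_threshold = 1,
                                   within_threshold = 1) {
  stopifnot(inherits(result_a, "delta_fc_result"),
            inherits(result_b, "delta_fc_result"))
  genes <- intersect(result_a$table$gene, result_b$table$gene)
  if (!length(genes)) abort("the two results share no genes")
  da <- result_a$table$delta_fc[match(genes, result_a$table$gene)]
  db <- result_b$table$delta_fc[match(genes, result_b$table$gene)]
  ddfc <- da - db
  selected <- rep("neither", length(genes))
  selected[ddfc >= ddfc_threshold & da >= within_threshold] <- result_a$therapy
  selected[-ddfc >= ddfc_threshold & db >= within_threshold] <- result_b$therapy
  out <- data.frame(gene = genes, delta_fc_a = da, delta_fc_b = db,
                    ddfc = ddfc, selected_for = selected,
                    stringsAsFactors = FALSE)
  names(out)[2:3] <- paste0("delta_fc_", c(result_a$therapy, result_b$therapy))
  structure(out, class = c("cross_therapy_result", "data.frame"),
            therapies = c(result_a$therapy, result_b$therapy))
}

#' Partition two DEG lists into therapy-specific and shared sets
#'
#' @param degs_a,degs_b Character vectors of gene IDs.
#' @param labels Length-2 character vector naming the two lists.
#' @return A list with elements `<A>_specific`, `<B>_specific` and `shared`;
#'   pairwise disjoint, union equals the union of the inputs.
#' @export
classify_degs <- function(degs_a, degs_b, labels = c("A", "B")) {
  degs_a <- unique(as.character(degs_a))
  degs_b <- unique(as.character(degs_b))
  out <- list(setdiff(degs_a, degs_b), setdiff(degs_b, degs_a),
              intersect(degs_a, degs_b))
  names(out) <- c(paste0(labels[1], "_specific"),
                  paste0(labels[2], "_specific"), "shared")
  structure(out, class = "deg_classification")
}

#' Two-group comparison by the Wilcoxon rank-sum test
#'
#' Uses exact enumeration of all group assignments (valid with ties) when
#' either group has fewer than 8 observations and the enumeration is
#' tractable, otherwise the normal approximation with tie correction and
#' continuity correction.
#'
#' @param values Numeric vector of observations.
#' @param groups Vector of two group labels, parallel to `values`.
#' @return List with `statistic` (Mann-Whitney U for the first group),
#'   `p_value` (two-sided) and `method`.
#' @export
group_compare <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) != 2) abort("exactly two groups required")
  groups <- droplevels(groups)
  x <- values[groups == levels(groups)[1]]
  y <- values[groups == levels(groups)[2]]
  if (!length(x) || !length(y)) abort("each group needs >= 1 observation")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)])
  u_obs <- w_obs - n1 * (n1 + 1) / 2
  if (min(n1, n2) < 8 && choose(n1 + n2, n1) <= 2e5) {
    # exact two-sided p by enumerating all assignments of the pooled ranks
    mu <- n1 * (n1 + 1 + n2) / 2
    combs <- utils::combn(n1 + n2, n1)
    w_all <- colSums(matrix(r[combs], nrow = n1))
    p <- mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
    method <- "exact enumeration"
  } else {
    res <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
    p <- res$p.value
    method <- "normal approximation"
  }
  list(statistic = u_obs, p_value = p, method = method)
}

#' Write a responder-contrast result table to TSV
#'
#' @param result A `delta_fc_result`.
#' @param path Output path.
#' @export
write_deg_table <- function(result, path) {
  stopifnot(inherits(result, "delta_fc_result"))
  utils::write.table(result$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
print.delta_fc_result <- function(x, ...) {
  cat(sprintf("delta_fc_result [%s]: %d genes tested; %d up, %d down (|delta|>=%.2g, q<%.2g)\n",
              x$therapy, nrow(x$table), length(x$up), length(x$down),
              x$fc_threshold, x$q_threshold))
  invisible(x)
}
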