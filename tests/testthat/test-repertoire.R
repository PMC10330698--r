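mk_records <- function(cdr3_nt, count = 1, cdr3_aa = NULL, v = "IGHV1",
                       j = "IGHJ1", chain = "IGH", productive = TRUE,
                       sample = "S1") {
  if (is.null(cdr3_aa)) {
    cdr3_aa <- vapply(cdr3_nt, function(x) {
      paste(rep("A", nchar(x) / 3), collapse = "")
    }, character(1))
  }
  data.frame(sample_id = sample, chain = chain, cdr3_nt = cdr3_nt,
             cdr3_aa = cdr3_aa, v_gene = v, j_gene = j,
             count = count, productive = productive,
             stringsAsFactors = FALSE)
}

test_that("productive filtering removes stop/frameshift and unproductive records", {
  rec <- rbind(
    mk_records("TGTGCA", cdr3_aa = "CA"),
    mk_records("TGTGCA", cdr3_aa = "C*", productive = TRUE),
    mk_records("TGTGCA", cdr3_aa = "C_", productive = TRUE),
    mk_records("TGTGCA", cdr3_aa = "CA", productive = FALSE))
  out <- filter_productive(rec)
  expect_equal(nrow(out), 1L)
  expect_identical(out$cdr3_aa, "CA")

  all_ok <- mk_records(c("TGTGCA", "TGTGGA"), cdr3_aa = c("CA", "CG"))
  expect_identical(filter_productive(all_ok), all_ok)
})

test_that("convergent clonotypes merge by amino-acid identity with summed counts", {
  rec <- mk_records(c("TGTGCA", "TGCGCA"), count = c(3, 2), cdr3_aa = "CA")
  out <- merge_convergent(rec)
  expect_equal(nrow(out), 1L)
  expect_equal(out$count, 5)
  expect_identical(out$cdr3_nt, "TGTGCA")  # highest-count representative

  # tie on count: lexicographically smallest nucleotide sequence wins
  tie <- mk_records(c("TGTGCA", "TGCGCA"), count = c(2, 2), cdr3_aa = "CA")
  expect_identical(merge_convergent(tie)$cdr3_nt, "TGCGCA")

  # all-distinct amino acids: identity up to ordering
  dist <- mk_records(c("TGTGCA", "TGTGGA"), cdr3_aa = c("CA", "CG"))
  expect_equal(nrow(merge_convergent(dist)), 2L)
})

test_that("merging conserves total count and never increases richness", {
  set.seed(70)
  for (i in 1:5) {
    n <- 30
    aa <- sample(c("CAR", "CAS", "CAT", "CAW"), n, replace = TRUE)
    nt <- vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), 9, replace = TRUE), collapse = "")
    }, character(1))
    rec <- mk_records(nt, count = sample(1:10, n, replace = TRUE), cdr3_aa = aa)
    out <- merge_convergent(rec)
    expect_equal(sum(out$count), sum(rec$count))
    expect_lte(nrow(out), nrow(rec))
    # group-by-sum oracle
    oracle <- tapply(rec$count, rec$cdr3_aa, sum)
    expect_equal(out$count[match(names(oracle), out$cdr3_aa)],
                 unname(as.vector(oracle)))
  }
})

test_that("diversity metrics reproduce the Shannon/clonality formulas", {
  uniform <- diversity_metrics(c(5, 5, 5, 5))
  expect_equal(uniform$shannon, log(4), tolerance = 1e-12)
  expect_equal(uniform$normalized_diversity, 1, tolerance = 1e-12)
  expect_equal(uniform$clonality, 0, tolerance = 1e-12)

  mono <- diversity_metrics(7)
  expect_equal(mono$shannon, 0)
  expect_equal(mono$clonality, 1)
  expect_equal(mono$normalized_diversity, 0)

  skew <- diversity_metrics(c(8, 1, 1))
  h_hand <- -(0.8 * log(0.8) + 2 * 0.1 * log(0.1))
  expect_equal(skew$shannon, h_hand, tolerance = 1e-9)
  expect_equal(skew$clonality, 1 - h_hand / log(3), tolerance = 1e-9)

  expect_error(diversity_metrics(numeric(0)), "empty")
})

test_that("diversity is invariant to clone order and count scaling", {
  set.seed(71)
  counts <- sample(1:50, 12)
  a <- diversity_metrics(counts)
  b <- diversity_metrics(rev(counts))
  c3 <- diversity_metrics(counts * 7)
  expect_equal(a, b, tolerance = 1e-12)
  expect_equal(a, c3, tolerance = 1e-12)
  # clone-weighted variant ignores counts entirely
  cw <- diversity_metrics(counts, weighted = FALSE)
  expect_equal(cw$clonality, 0, tolerance = 1e-12)
})

test_that("lineage inference clusters near sequences and respects V/J partitions", {
  base <- paste(rep("TGC", 10), collapse = "")   # 30 nt
  variant <- sub("^TGC", "AGC", base)            # 1 mismatch, d ~ 0.033
  rec <- mk_records(c(base, variant), cdr3_aa = c("CCCCCCCCCC", "SCCCCCCCCC"))
  lin <- infer_lineages(rec, threshold = 0.1)
  expect_length(lin, 1L)
  expect_setequal(lin[[1]]$mature_clones, c(base, variant))

  # different V genes are never co-clustered
  rec2 <- rbind(mk_records(base, v = "IGHV1", cdr3_aa = "CCCCCCCCCC"),
                mk_records(base, v = "IGHV2", cdr3_aa = "CCCCCCCCCC"))
  lin2 <- infer_lineages(rec2, threshold = 0.99)
  expect_length(lin2, 2L)

  expect_error(infer_lineages(rec, threshold = 1.5), "\\(0, 1\\)")
  expect_error(infer_lineages(mk_records("TGTGCA", chain = "TRB",
                                         cdr3_aa = "CA")), "IGH")
})

test_that("lineage output partitions the records and shrinks with threshold", {
  sim <- simulate_repertoire(n_germline_clones = 40, seed = 72)
  rec <- merge_convergent(filter_productive(sim$records))
  lin_lo <- infer_lineages(rec, threshold = 0.05)
  lin_hi <- infer_lineages(rec, threshold = 0.45)
  # partition: every record assigned exactly once
  expect_true(all(nzchar(attr(lin_lo, "assignments"))))
  expect_equal(sum(vapply(lin_lo, function(l) length(l$mature_clones),
                          integer(1))), length(unique(rec$cdr3_nt)))
  # lineage count is non-increasing in the threshold
  expect_gte(length(lin_lo), length(lin_hi))
  # total counts conserved
  expect_equal(sum(vapply(lin_lo, `[[`, numeric(1), "total_count")),
               sum(rec$count))
})

test_that("somatic-hypermutation frequency follows its defining ratio", {
  mk_lineage <- function(n_mature) {
    structure(list(germline_clone_id = "x", v_gene = "v", j_gene = "j",
                   junction_length = 30,
                   mature_clones = paste0("s", seq_len(n_mature)),
                   total_count = n_mature), class = "clone_lineage")
  }
  expect_equal(shm_frequency(lapply(c(2, 1, 1), mk_lineage)), 1 / 3)
  expect_equal(shm_frequency(lapply(c(1, 1), mk_lineage)), 0)
  expect_equal(shm_frequency(lapply(c(3, 2), mk_lineage)), 1)
  expect_error(shm_frequency(list()), "empty")
})

test_that("automatic threshold detection separates bimodal distances and falls back", {
  set.seed(73)
  d <- c(pmax(rnorm(300, 0.02, 0.005), 0), pmin(rnorm(300, 0.30, 0.03), 1))
  thr <- detect_bimodal_threshold(d)
  expect_identical(attr(thr, "branch"), "bimodal")
  expect_gt(thr, 0.05); expect_lt(thr, 0.25)

  uni <- rnorm(200, 0.3, 0.01)
  thr_u <- detect_bimodal_threshold(uni)
  expect_identical(attr(thr_u, "branch"), "unimodal")
  expect_equal(as.numeric(thr_u), 0.1)

  # data-poor branch on a tiny repertoire
  rec <- mk_records(c("TGTGCA", "TGTGGA"), cdr3_aa = c("CA", "CG"))
  expect_message(thr_p <- find_threshold(rec), "fallback")
  expect_identical(attr(thr_p, "branch"), "data_poor")
  expect_equal(as.numeric(thr_p), 0.1)
})

test_that("novel clone fraction is the share of on-treatment clones absent before", {
  pre <- mk_records("TGTGCA", cdr3_aa = "CA")
  post <- mk_records(c("TGTGCA", "TGTGGA", "TGTTGA", "TGTTCA"),
                     cdr3_aa = c("CA", "CG", "CL", "CS"))
  expect_equal(novel_clone_fraction(pre, post), 0.75)
  expect_equal(novel_clone_fraction(pre, pre), 0)
  disjoint <- mk_records("AAATGA", cdr3_aa = "KW")
  expect_equal(novel_clone_fraction(pre, disjoint), 1)
  expect_error(novel_clone_fraction(pre, pre[0, ]), "empty")
})

test_that("per-sample metrics table covers every sample-chain repertoire", {
  sim <- simulate_repertoire(n_germline_clones = 30, seed = 74)
  rec <- sim$records
  rec2 <- rec; rec2$sample_id <- "S2"; rec2$chain <- "TRB"
  # TRB junctions need no lineage call; reuse sequences
  metrics <- repertoire_metrics(rbind(rec, rec2), threshold = 0.2)
  expect_setequal(metrics$sample_id, c("S1", "S2"))
  expect_true(all(is.na(metrics$shm_frequency[metrics$chain == "TRB"])))
  expect_true(all(!is.na(metrics$shm_frequency[metrics$chain == "IGH"])))
  expect_true(all(metrics$clonality >= 0 & metrics$clonality <= 1))
  # clonality + normalized diversity = 1 whenever richness > 1
  multi <- metrics$richness > 1
  expect_equal(metrics$clonality[multi] + metrics$normalized_diversity[multi],
               rep(1, sum(multi)), tolerance = 1e-12)
})

test_that("clonotype tables round-trip through TSV and are validated", {
  sim <- simulate_repertoire(n_germline_clones = 10, seed = 75)
  path <- tempfile(fileext = ".tsv")
  write_clonotypes(sim$records, path)
  back <- read_clonotypes(path)
  expect_equal(back$cdr3_nt, sim$records$cdr3_nt)
  expect_equal(back$count, sim$records$count)

  bad <- sim$records; bad$count[1] <- 0
  expect_error(validate_clonotypes(bad), ">= 1")
  bad2 <- sim$records; bad2$cdr3_aa[2] <- paste0(bad2$cdr3_aa[2], "Q")
  expect_error(validate_clonotypes(bad2), "3 x")
  bad3 <- sim$records; bad3$chain[3] <- "IGX"
  expect_error(validate_clonotypes(bad3), "IGX")
})
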