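test_that("a planted separated gene is the only up-regulated call", {
  set.seed(50)
  vals <- matrix(rnorm(10 * 6, sd = 0.01), nrow = 10,
                 dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  vals["g3", 1:3] <- 2; vals["g3", 4:6] <- 0
  fc <- make_fc_table(vals, therapy = "ICI",
                      response = rep(c("R", "NR"), each = 3))
  res <- delta_fc_test(fc, "ICI")
  expect_identical(res$up, "g3")
  expect_length(res$down, 0)
  expect_equal(res$table$delta_fc[res$table$gene == "g3"], 2, tolerance = 1e-9)
})

test_that("t statistics and q-values match Welch and step-up oracles", {
  set.seed(51)
  vals <- matrix(rnorm(5 * 9), nrow = 5,
                 dimnames = list(paste0("g", 1:5), paste0("s", 1:9)))
  response <- c(rep("R", 4), rep("NR", 5))
  fc <- make_fc_table(vals, therapy = "ICI", response = response)
  res <- delta_fc_test(fc, "ICI")
  for (i in 1:5) {
    oracle <- welch_oracle(vals[i, response == "R"], vals[i, response == "NR"])
    expect_equal(res$table$t[i], oracle$t, tolerance = 1e-10)
    expect_equal(res$table$p[i], oracle$p, tolerance = 1e-10)
  }
  expect_equal(res$table$q, bh_oracle(res$table$p), tolerance = 1e-12)
  # delta is exactly the difference of the group means
  expect_identical(res$table$delta_fc,
                   res$table$mean_fc_R - res$table$mean_fc_NR)
})

test_that("responder contrast enforces group sizes and handles flat genes", {
  vals <- matrix(0, nrow = 3, ncol = 5,
                 dimnames = list(paste0("g", 1:3), paste0("s", 1:5)))
  fc <- make_fc_table(vals, "ICI", c("R", "NR", "NR", "NR", "NR"))
  expect_error(delta_fc_test(fc, "ICI"), "2 responder")
  expect_error(delta_fc_test(fc, "MAPKi"), "no pairs")

  vals2 <- matrix(c(rep(0, 6), rnorm(6)), nrow = 2, byrow = TRUE,
                  dimnames = list(c("flat", "ok"), paste0("s", 1:6)))
  fc2 <- make_fc_table(vals2, "ICI", rep(c("R", "NR"), each = 3))
  expect_message(res <- delta_fc_test(fc2, "ICI"), "zero variance")
  expect_equal(res$table$p[res$table$gene == "flat"], 1)
})

test_that("the contrast is antisymmetric under swapping responder labels", {
  set.seed(52)
  vals <- matrix(rnorm(20 * 8), nrow = 20,
                 dimnames = list(paste0("g", 1:20), paste0("s", 1:8)))
  resp <- rep(c("R", "NR"), each = 4)
  res1 <- delta_fc_test(make_fc_table(vals, "ICI", resp), "ICI")
  res2 <- delta_fc_test(make_fc_table(vals, "ICI",
                                      ifelse(resp == "R", "NR", "R")), "ICI")
  expect_equal(res1$table$delta_fc, -res2$table$delta_fc, tolerance = 1e-12)
  expect_equal(res1$table$p, res2$table$p, tolerance = 1e-12)
})

test_that("DEG calls are invariant to gene and sample order", {
  set.seed(53)
  vals <- matrix(rnorm(30 * 10), nrow = 30,
                 dimnames = list(paste0("g", 1:30), paste0("s", 1:10)))
  vals[1:3, 1:5] <- vals[1:3, 1:5] + 3
  resp <- rep(c("R", "NR"), each = 5)
  res <- delta_fc_test(make_fc_table(vals, "ICI", resp), "ICI")
  perm_g <- sample(30); perm_s <- sample(10)
  res_p <- delta_fc_test(make_fc_table(vals[perm_g, perm_s], "ICI",
                                       resp[perm_s]), "ICI")
  expect_setequal(res$up, res_p$up)
  expect_setequal(res$down, res_p$down)
})

test_that("BH adjustment reproduces hand-computed cases and rejects bad input", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04), tolerance = 1e-12)
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  set.seed(54)
  p <- runif(100)
  expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, -0.1)), "\\[0, 1\\]")
})

test_that("the cross-therapy rule applies both inequalities", {
  mk <- function(genes, delta, therapy) {
    structure(list(table = data.frame(gene = genes, delta_fc = delta,
                                      stringsAsFactors = FALSE),
                   therapy = therapy),
              class = "delta_fc_result")
  }
  a <- mk(c("g1", "g2"), c(2.0, 0.9), "ICI")
  b <- mk(c("g1", "g2"), c(0.5, -1.0), "MAPKi")
  ct <- cross_therapy_contrast(a, b)
  expect_equal(ct$ddfc, c(1.5, 1.9))
  # g1: both inequalities hold; g2: ddfc passes but the within-therapy
  # contrast (0.9 < 1) fails
  expect_identical(ct$selected_for, c("ICI", "neither"))

  expect_error(cross_therapy_contrast(a, mk("gX", 1, "MAPKi")), "no genes")
})

test_that("cross-therapy selection matches exhaustive rule evaluation", {
  set.seed(55)
  genes <- paste0("g", 1:100)
  da <- rnorm(100, sd = 1.5); db <- rnorm(100, sd = 1.5)
  mk <- function(delta, therapy) {
    structure(list(table = data.frame(gene = genes, delta_fc = delta,
                                      stringsAsFactors = FALSE),
                   therapy = therapy),
              class = "delta_fc_result")
  }
  ct <- cross_therapy_contrast(mk(da, "ICI"), mk(db, "MAPKi"))
  brute <- vapply(1:100, function(i) {
    if (da[i] - db[i] >= 1 && da[i] >= 1) "ICI"
    else if (db[i] - da[i] >= 1 && db[i] >= 1) "MAPKi"
    else "neither"
  }, character(1))
  expect_identical(ct$selected_for, brute)
  expect_identical(ct$ddfc, da - db)
})

test_that("DEG classification partitions the union of the two lists", {
  cls <- classify_degs(c("a", "b", "c"), c("b", "c", "d"),
                       labels = c("ICI", "MAPKi"))
  expect_identical(cls$ICI_specific, "a")
  expect_identical(cls$MAPKi_specific, "d")
  expect_setequal(cls$shared, c("b", "c"))

  disj <- classify_degs(c("a", "b"), c("c"))
  expect_length(disj$shared, 0)
  same <- classify_degs(c("a", "b"), c("a", "b"))
  expect_length(same$A_specific, 0)
  expect_length(same$B_specific, 0)
  expect_setequal(same$shared, c("a", "b"))
})

test_that("Wilcoxon comparison: exact enumeration and normal approximation", {
  # fully separated groups of 3: U = 0, exact two-sided p = 2/20
  res <- group_compare(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(res$p_value, 0.1, tolerance = 1e-12)
  expect_equal(res$statistic, 0)
  expect_match(res$method, "exact")
  # agreement with the exact distribution in stats for tie-free samples
  set.seed(56)
  x <- rnorm(5); y <- rnorm(6)
  ours <- group_compare(c(x, y), rep(c("a", "b"), c(5, 6)))
  ref <- wilcox.test(x, y, exact = TRUE)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)

  # identical groups: p = 1 by symmetry even with ties
  res2 <- group_compare(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(res2$p_value, 1)

  # large shifted Gaussians use the normal approximation and are significant
  set.seed(57)
  big <- group_compare(c(rnorm(50), rnorm(50, mean = 3)),
                       rep(c("a", "b"), each = 50))
  expect_match(big$method, "normal")
  expect_lt(big$p_value, 1e-6)

  expect_error(group_compare(1:3, c("a", "a", "a")), "two groups")
})

test_that("planted effects in a therapy-specific fold-change cohort are recovered", {
  # direct fold-change-level generator: 20 pairs per arm, noise sd 0.5,
  # 50 genes planted at a responder contrast of 2 in therapy A only
  set.seed(58)
  n_genes <- 500; n_pairs <- 20
  planted <- paste0("g", 1:50)
  genes <- paste0("g", 1:n_genes)
  mk_vals <- function(effect) {
    vals <- matrix(rnorm(n_genes * 2 * n_pairs, sd = 0.5), nrow = n_genes,
                   dimnames = list(genes, paste0("s", 1:(2 * n_pairs))))
    vals[1:50, 1:n_pairs] <- vals[1:50, 1:n_pairs] + effect
    vals
  }
  resp <- rep(c("R", "NR"), each = n_pairs)
  fc_a <- make_fc_table(mk_vals(2), "ICI", resp)
  fc_b <- make_fc_table(mk_vals(0), "MAPKi", resp)
  colnames(fc_b$log2fc) <- paste0("m", 1:(2 * n_pairs))
  fc_b$pairs$ot_sample_id <- colnames(fc_b$log2fc)
  res_a <- delta_fc_test(fc_a, "ICI")
  res_b <- delta_fc_test(fc_b, "MAPKi")
  expect_gte(mean(planted %in% res_a$up), 0.9)
  ct <- cross_therapy_contrast(res_a, res_b)
  recovered <- intersect(res_a$up, planted)
  expect_gte(mean(ct$selected_for[match(recovered, ct$gene)] == "ICI"), 0.8)
})

test_that("identically distributed groups produce (almost) no DEG calls", {
  # null simulation: 20 cohorts without any planted effect
  up_counts <- vapply(1:20, function(s) {
    set.seed(600 + s)
    vals <- matrix(rnorm(200 * 20, sd = 0.5), nrow = 200,
                   dimnames = list(paste0("g", 1:200), paste0("s", 1:20)))
    fc <- make_fc_table(vals, "ICI", rep(c("R", "NR"), each = 10))
    length(delta_fc_test(fc, "ICI")$up)
  }, numeric(1))
  # empirical false-call rate stays below the nominal FDR plus margin
  expect_lte(mean(up_counts > 0), 0.05 + 0.1)
})
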