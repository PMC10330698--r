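#' Run the full paired-biopsy analysis pipeline
#'
#' Orchestrates the stages in dependency order — read counts, TMM/log-CPM
#' normalization, optional batch centering, paired fold changes, the
#' within-therapy responder contrasts, the cross-therapy contrast and DEG
#' classification, then optional gene-set scoring, repertoire metrics and
#' survival stratification — writing every intermediate table plus a JSON
#' run manifest into the output directory. Re-running with an identical
#' config and inputs reproduces identical outputs; inputs are never
#' modified.
#'
#' @param config A named list (or path to a YAML file with the same keys):
#'   \describe{
#'     \item{counts, annotation}{Paths to the count and annotation TSVs
#'       (required).}
#'     \item{gene_sets}{Optional path to a GMT file to score.}
#'     \item{clonotypes}{Optional path to a clonotype TSV.}
#'     \item{survival}{Optional path to a survival CSV; requires
#'       `stratify_features`, two covariate column names to median-split.}
#'     \item{output_dir}{Output directory (required).}
#'     \item{fc_threshold, q_threshold, ddfc_threshold}{Contrast thresholds
#'       (defaults 1, 0.05, 1).}
#'     \item{score_method, min_overlap}{Gene-set scoring options.}
#'     \item{clone_threshold}{Lineage threshold or `"auto"`.}
#'     \item{batch_correct}{Remove batch effects (default `TRUE`).}
#'     \item{seed}{RNG seed recorded in the manifest (default 1).}
#'   }
#'
#' @return The run manifest (list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("reading a YAML config requires the 'yaml' package")
    }
    config <- yaml::read_yaml(config)
  }
  for (key in c("counts", "annotation", "output_dir")) {
    if (is.null(config[[key]])) abort("config lacks required key '%s'", key)
  }
  for (key in c("counts", "annotation", "gene_sets", "clonotypes", "survival")) {
    if (!is.null(config[[key]]) && !file.exists(config[[key]])) {
      abort("input path for '%s' does not exist: %s", key, config[[key]])
    }
  }
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1
  set.seed(seed)

  manifest <- list(package = "melresponse",
                   version = as.character(utils::packageVersion("melresponse")),
                   seed = seed,
                   config_hash = config_hash(config),
                   stages = list())
  record_stage <- function(name, status, rows = NA, note = "") {
    manifest$stages[[length(manifest$stages) + 1]] <<-
      list(name = name, status = status, rows = rows, note = note)
  }
  run_stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      record_stage(name, "failed", note = conditionMessage(e))
      manifest$failed_stage <<- name
      write_manifest(manifest, out_dir)
      abort("pipeline halted at stage '%s': %s", name, conditionMessage(e))
    })
    res
  }

  # 1: expression -----------------------------------------------------------
  data <- run_stage("read_counts", read_counts(config$counts, config$annotation))
  record_stage("read_counts", "completed", rows = nrow(data$counts))

  norm <- run_stage("normalize", {
    m <- tmm_normalize(data)
    if (isTRUE(config$batch_correct %||% TRUE) &&
        length(unique(data$annotation$batch)) > 1) {
      grp <- with(data$annotation, paste(therapy, timepoint, response, sep = "."))
      m <- remove_batch(m, batch = data$annotation$batch, preserve = grp)
    }
    write_normalized(m, file.path(out_dir, "normalized_log2cpm.tsv"))
    m
  })
  record_stage("normalize", "completed", rows = nrow(norm$values))

  # 2: paired fold changes and contrasts ------------------------------------
  fc <- run_stage("paired_fold_change", {
    f <- paired_log2fc(norm, data)
    write_matrix_tsv(f$log2fc, file.path(out_dir, "paired_log2fc.tsv"))
    utils::write.table(f$pairs, file.path(out_dir, "pairs.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    f
  })
  record_stage("paired_fold_change", "completed", rows = ncol(fc$log2fc))

  deg <- run_stage("responder_contrast", {
    therapies <- sort(unique(fc$pairs$therapy))
    res <- lapply(therapies, function(th) {
      r <- delta_fc_test(fc, th,
                         fc_threshold = config$fc_threshold %||% 1,
                         q_threshold = config$q_threshold %||% 0.05)
      write_deg_table(r, file.path(out_dir, sprintf("deg_%s.tsv", th)))
      r
    })
    names(res) <- therapies
    res
  })
  record_stage("responder_contrast", "completed",
               rows = sum(vapply(deg, function(r) nrow(r$table), integer(1))))

  if (length(deg) == 2) {
    run_stage("cross_therapy_contrast", {
      ct <- cross_therapy_contrast(deg[[1]], deg[[2]],
                                   ddfc_threshold = config$ddfc_threshold %||% 1)
      utils::write.table(as.data.frame(ct),
                         file.path(out_dir, "cross_therapy_contrast.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      cls <- classify_degs(deg[[1]]$up, deg[[2]]$up,
                           labels = names(deg))
      memb <- data.frame(
        gene = unlist(cls, use.names = FALSE),
        class = rep(names(cls), lengths(cls)))
      utils::write.table(memb, file.path(out_dir, "deg_classification.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      ct
    })
    record_stage("cross_therapy_contrast", "completed")
  } else {
    record_stage("cross_therapy_contrast", "skipped",
                 note = "needs exactly two therapies")
  }

  # 3: gene-set scores -------------------------------------------------------
  if (!is.null(config$gene_sets)) {
    run_stage("signature_scores", {
      sets <- read_gmt(config$gene_sets)
      scores <- score_gene_sets(norm, sets,
                                method = config$score_method %||% "ssgsea",
                                min_overlap = config$min_overlap %||% 3)
      write_matrix_tsv(scores, file.path(out_dir, "signature_scores.tsv"),
                       id_col = "gene_set")
      scores
    })
    record_stage("signature_scores", "completed")
  } else {
    record_stage("signature_scores", "skipped", note = "no gene_sets input")
  }

  # 4: repertoire ------------------------------------------------------------
  if (!is.null(config$clonotypes)) {
    run_stage("repertoire", {
      rec <- read_clonotypes(config$clonotypes)
      rec <- merge_convergent(filter_productive(rec))
      metrics <- repertoire_metrics(rec,
                                    threshold = config$clone_threshold %||% "auto")
      utils::write.table(metrics, file.path(out_dir, "repertoire_metrics.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      metrics
    })
    record_stage("repertoire", "completed")
  } else {
    record_stage("repertoire", "skipped", note = "no clonotype input")
  }

  # 5: survival --------------------------------------------------------------
  if (!is.null(config$survival) && length(config$stratify_features) == 2) {
    run_stage("survival_stratification", {
      surv <- read_survival(config$survival)
      f <- config$stratify_features
      res <- joint_strata_analysis(surv, surv[[f[1]]], surv[[f[2]]])
      if (!is.null(res$cox)) {
        write_cox_fit(res$cox, file.path(out_dir, "interaction_cox.tsv"))
      }
      utils::write.table(
        data.frame(subject_id = surv$subject_id, stratum = res$strata),
        file.path(out_dir, "survival_strata.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      res
    })
    record_stage("survival_stratification", "completed")
  } else {
    record_stage("survival_stratification", "skipped",
                 note = "no survival input or stratify_features")
  }

  write_manifest(manifest, out_dir)
  invisible(manifest)
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

write_manifest <- function(manifest, out_dir) {
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
}

#' Write a complete miniature synthetic cohort to disk
#'
#' Emits the exact file dialects consumed by the pipeline: a count TSV and
#' annotation TSV from [simulate_expression_cohort()], a clonotype TSV from
#' [simulate_repertoire()], a survival CSV from [simulate_survival()], and
#' the bundled tertiary-lymphoid-structure signature GMT.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer RNG seed.
#' @param n_patients_per_arm,n_genes Cohort size (kept small by default).
#' @return The directory path, invisibly.
#' @export
write_fixture_cohort <- function(dir, seed = 1, n_patients_per_arm = 4,
                                 n_genes = 200) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- simulate_expression_cohort(
    n_patients_per_arm = n_patients_per_arm, n_genes = n_genes,
    n_planted = 10, seed = seed)
  write_counts(cohort$data, file.path(dir, "counts.tsv"),
               file.path(dir, "annotation.tsv"))
  rep <- simulate_repertoire(n_germline_clones = 60, seed = seed + 1)
  write_clonotypes(rep$records, file.path(dir, "clonotypes.tsv"))
  covs <- with_seed(seed + 3, data.frame(bcr_diversity = stats::rnorm(40),
                                         ifng_score = stats::rnorm(40)))
  surv <- simulate_survival(covs,
                            betas = c(bcr_diversity = -0.4, ifng_score = -0.4),
                            seed = seed + 2)
  utils::write.csv(surv$records, file.path(dir, "survival.csv"),
                   row.names = FALSE)
  sets <- with_seed(seed + 4, {
    genes <- rownames(cohort$data$counts)
    lapply(1:3, function(i) {
      gene_set(sprintf("synthetic_set_%d", i), sample(genes, 15),
               source = "synthetic marker set")
    })
  })
  write_gmt(sets, file.path(dir, "gene_sets.gmt"))
  invisible(dir)
}
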