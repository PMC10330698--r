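# Synthetic cohort generators. Each generator is a pure function of its
# arguments: the seed fully determines the output and the caller's RNG
# state is untouched.

#' Simulate a two-therapy paired-biopsy expression cohort
#'
#' Generates negative-binomial counts for a cohort with one pre-treatment
#' (PT) and one on-treatment (OT) biopsy per patient, split into responder
#' and non-responder arms under each therapy. Gene baselines are log-normal;
#' each patient carries a log2-normal random effect shared by both biopsies;
#' per-batch, per-gene multiplicative log2 offsets emulate processing
#' batches; a block of planted genes receives a `2^delta` multiplier only in
#' the OT samples of responders of the designated therapy, so `delta` is the
#' asymptotic responder-contrast effect. The negative-binomial variance is
#' `mean + dispersion * mean^2`.
#'
#' @param n_patients_per_arm Patients per (therapy, response) arm.
#' @param n_genes Number of genes.
#' @param n_planted Number of planted response genes.
#' @param planted_delta Planted effect in log2 units.
#' @param planted_therapy Therapy whose responders carry the effect.
#' @param therapies Length-2 character vector of therapy labels.
#' @param dispersion Negative-binomial dispersion (0 = Poisson).
#' @param batch_effect_sd Per-batch SD of the per-gene log2 batch offsets
#'   (two batches; patients are alternately assigned).
#' @param patient_effect_sd SD of the per-patient log2 random effect.
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of the gene
#'   baseline means.
#' @param library_size_range Range of the per-sample depth multipliers.
#' @param seed Integer RNG seed.
#'
#' @return List with `data` (an [annotated_counts]) and `truth` (data frame
#'   of planted genes with their therapy and delta).
#' @export
simulate_expression_cohort <- function(n_patients_per_arm = 20,
                                       n_genes = 2000,
                                       n_planted = 50,
                                       planted_delta = 2,
                                       planted_therapy = "ICI",
                                       therapies = c("ICI", "MAPKi"),
                                       dispersion = 0.2,
                                       batch_effect_sd = 0.3,
                                       patient_effect_sd = 0.5,
                                       baseline_meanlog = 4,
                                       baseline_sdlog = 1,
                                       library_size_range = c(0.7, 1.3),
                                       seed = 1) {
  stopifnot(n_patients_per_arm >= 1, n_genes >= 1, n_planted >= 0,
            n_planted <= n_genes, length(therapies) == 2,
            planted_therapy %in% therapies, dispersion >= 0)
  with_seed(seed, {
    genes <- sprintf("G%05d", seq_len(n_genes))
    planted <- if (n_planted > 0) genes[seq_len(n_planted)] else character(0)
    baseline <- exp(stats::rnorm(n_genes, baseline_meanlog, baseline_sdlog))
    batches <- c("B1", "B2")
    batch_offset <- sapply(batches, function(b) {
      stats::rnorm(n_genes, 0, batch_effect_sd)
    })

    ann <- expand.grid(therapy = therapies, response = c("R", "NR"),
                       idx = seq_len(n_patients_per_arm),
                       stringsAsFactors = FALSE)
    ann$patient_id <- sprintf("%s_%s_%02d", ann$therapy, ann$response, ann$idx)
    ann$batch <- batches[(ann$idx %% 2) + 1]   # balanced within every arm

    cols <- list()
    sample_rows <- list()
    for (i in seq_len(nrow(ann))) {
      pat_effect <- stats::rnorm(1, 0, patient_effect_sd)
      for (tp in c("PT", "OT")) {
        sid <- paste0(ann$patient_id[i], "_", tp)
        depth <- stats::runif(1, library_size_range[1], library_size_range[2])
        log2_effect <- pat_effect + batch_offset[, ann$batch[i]]
        if (tp == "OT" && ann$response[i] == "R" &&
            ann$therapy[i] == planted_therapy && length(planted)) {
          log2_effect[seq_along(planted)] <-
            log2_effect[seq_along(planted)] + planted_delta
        }
        mu <- baseline * 2^log2_effect * depth
        counts <- if (dispersion > 0) {
          stats::rnbinom(n_genes, mu = mu, size = 1 / dispersion)
        } else {
          stats::rpois(n_genes, mu)
        }
        cols[[sid]] <- counts
        sample_rows[[sid]] <- data.frame(
          sample_id = sid, patient_id = ann$patient_id[i],
          therapy = ann$therapy[i], timepoint = tp,
          response = ann$response[i], batch = ann$batch[i],
          stringsAsFactors = FALSE)
      }
    }
    mat <- do.call(cbind, cols)
    rownames(mat) <- genes
    annotation <- do.call(rbind, sample_rows)
    rownames(annotation) <- NULL
    truth <- data.frame(gene = planted,
                        therapy = rep(planted_therapy, length(planted)),
                        delta = rep(planted_delta, length(planted)),
                        stringsAsFactors = FALSE)
    list(data = annotated_counts(mat, annotation), truth = truth)
  })
}

# 61 sense codons (no stop codons), used to draw in-frame junctions
sense_codons <- function() {
  bases <- c("A", "C", "G", "T")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  setdiff(codons, c("TAA", "TAG", "TGA"))
}

# standard-genetic-code translation of an in-frame nucleotide string
translate_nt <- function(nt) {
  codons <- substring(nt, seq(1, nchar(nt), 3), seq(3, nchar(nt), 3))
  code <- c(TTT="F",TTC="F",TTA="L",TTG="L",CTT="L",CTC="L",CTA="L",CTG="L",
            ATT="I",ATC="I",ATA="I",ATG="M",GTT="V",GTC="V",GTA="V",GTG="V",
            TCT="S",TCC="S",TCA="S",TCG="S",CCT="P",CCC="P",CCA="P",CCG="P",
            ACT="T",ACC="T",ACA="T",ACG="T",GCT="A",GCC="A",GCA="A",GCG="A",
            TAT="Y",TAC="Y",TAA="*",TAG="*",CAT="H",CAC="H",CAA="Q",CAG="Q",
            AAT="N",AAC="N",AAA="K",AAG="K",GAT="D",GAC="D",GAA="E",GAG="E",
            TGT="C",TGC="C",TGA="*",TGG="W",CGT="R",CGC="R",CGA="R",CGG="R",
            AGT="S",AGC="S",AGA="R",AGG="R",GGT="G",GGC="G",GGA="G",GGG="G")
  paste(code[codons], collapse = "")
}

# point-mutate nt with per-base probability mu; redrawn until productive
mutate_junction <- function(nt, mu, max_tries = 50) {
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(nt, "")[[1]]
  for (try in seq_len(max_tries)) {
    out <- chars
    hit <- which(stats::runif(length(chars)) < mu)
    for (i in hit) {
      out[i] <- sample(setdiff(bases, chars[i]), 1)
    }
    seq <- paste(out, collapse = "")
    if (!grepl("*", translate_nt(seq), fixed = TRUE)) return(seq)
  }
  nt  # give up on a productive mutant; return the germline sequence
}

#' Simulate a heavy-chain repertoire with somatic-hypermutation lineages
#'
#' Draws germline clones with random V/J assignments from small pools,
#' random in-frame junctions (no stop codons) and power-law clone sizes.
#' With probability `shm_probability`, a germline clone spawns descendant
#' sequences, each a copy of the germline junction with independent per-base
#' substitution probability `shm_per_base_rate` (length-preserving;
#' descendants are redrawn while they encode a stop codon). The realized
#' fraction of germline families containing at least two distinct productive
#' amino-acid junctions is stored in the truth metadata as the quantity the
#' lineage-inference pipeline should recover after convergent merging.
#'
#' @param n_germline_clones Number of germline clones.
#' @param zipf_exponent Power-law exponent of the clone-size distribution.
#' @param shm_probability Probability that a germline clone carries somatic
#'   hypermutation descendants.
#' @param shm_per_base_rate Per-base substitution probability per descendant.
#' @param descendants_range Integer range of descendants per mutated clone.
#' @param junction_length_range Junction length range in nt (multiples of 3).
#' @param v_pool,j_pool Sizes of the V- and J-gene pools.
#' @param sample_id Sample label written into the records.
#' @param seed Integer RNG seed.
#'
#' @return List with `records` (clonotype data frame), `truth` (data frame
#'   mapping each record's `cdr3_nt`/`cdr3_aa` to its `germline_id`) and
#'   `expected_shm_frequency` (realized fraction of multi-clone families).
#' @export
simulate_repertoire <- function(n_germline_clones = 200,
                                zipf_exponent = 2,
                                shm_probability = 0.3,
                                shm_per_base_rate = 0.02,
                                descendants_range = c(2, 4),
                                junction_length_range = c(36, 54),
                                v_pool = 5, j_pool = 3,
                                sample_id = "S1", seed = 1) {
  stopifnot(n_germline_clones >= 1, zipf_exponent > 0,
            shm_probability >= 0, shm_probability <= 1,
            shm_per_base_rate >= 0, shm_per_base_rate <= 1,
            all(junction_length_range %% 3 == 0))
  with_seed(seed, {
    codons <- sense_codons()
    lengths <- seq(junction_length_range[1], junction_length_range[2], by = 3)
    kmax <- 1000
    zipf_p <- (1:kmax)^(-zipf_exponent)
    draw_count <- function(n) sample.int(kmax, n, replace = TRUE, prob = zipf_p)

    rows <- list()
    truth <- list()
    multi <- logical(n_germline_clones)
    for (g in seq_len(n_germline_clones)) {
      gid <- sprintf("germ%04d", g)
      len <- sample(lengths, 1)
      nt <- paste(sample(codons, len / 3, replace = TRUE), collapse = "")
      fam_nt <- nt
      if (stats::runif(1) < shm_probability) {
        k <- sample(seq(descendants_range[1], descendants_range[2]), 1)
        fam_nt <- c(fam_nt, vapply(seq_len(k), function(i) {
          mutate_junction(nt, shm_per_base_rate)
        }, character(1)))
      }
      fam_nt <- unique(fam_nt)
      fam_aa <- vapply(fam_nt, translate_nt, character(1))
      multi[g] <- length(unique(fam_aa)) >= 2
      rows[[g]] <- data.frame(
        sample_id = sample_id, chain = "IGH", cdr3_nt = fam_nt,
        cdr3_aa = unname(fam_aa),
        v_gene = sprintf("IGHV%d", ((g - 1) %% v_pool) + 1),
        j_gene = sprintf("IGHJ%d", ((g - 1) %% j_pool) + 1),
        count = draw_count(length(fam_nt)), productive = TRUE,
        stringsAsFactors = FALSE)
      truth[[g]] <- data.frame(cdr3_nt = fam_nt, cdr3_aa = unname(fam_aa),
                               germline_id = gid, stringsAsFactors = FALSE)
    }
    records <- do.call(rbind, rows)
    rownames(records) <- NULL
    truth <- do.call(rbind, truth)
    rownames(truth) <- NULL
    list(records = validate_clonotypes(records), truth = truth,
         expected_shm_frequency = mean(multi))
  })
}

#' Simulate proportional-hazards survival records
#'
#' Event times are exponential with rate
#' `baseline_rate * exp(sum(betas * covariates))`; censoring times are
#' uniform on `(0, censoring_window)` (an infinite window disables
#' censoring).
#'
#' @param covariates Data frame of per-subject covariates (one column per
#'   named beta; extra columns are carried through).
#' @param betas Named numeric vector of log hazard ratios.
#' @param baseline_rate Baseline event rate (events/month).
#' @param censoring_window Upper bound of the uniform censoring time.
#' @param seed Integer RNG seed.
#'
#' @return List with `records` (data frame: `subject_id`, `time`, `event`,
#'   covariates) and `truth` (the betas).
#' @export
simulate_survival <- function(covariates, betas, baseline_rate = 0.1,
                              censoring_window = 32, seed = 1) {
  stopifnot(baseline_rate > 0, censoring_window > 0)
  covariates <- as.data.frame(covariates)
  miss <- setdiff(names(betas), names(covariates))
  if (length(miss)) abort("covariates lack column(s): %s",
                          paste(miss, collapse = ", "))
  n <- nrow(covariates)
  with_seed(seed, {
    lp <- as.matrix(covariates[names(betas)]) %*% betas
    t_event <- stats::rexp(n, rate = baseline_rate * exp(drop(lp)))
    if (is.finite(censoring_window)) {
      t_cens <- stats::runif(n, 0, censoring_window)
    } else {
      t_cens <- rep(Inf, n)
    }
    records <- data.frame(subject_id = sprintf("P%04d", seq_len(n)),
                          time = pmin(t_event, t_cens),
                          event = as.integer(t_event <= t_cens),
                          covariates, stringsAsFactors = FALSE)
    list(records = validate_survival(records), truth = betas)
  })
}
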