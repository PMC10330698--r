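# Independent brute-force oracles used by the derived-value tests. These are
# deliberately written from the published formulas, step by step, and stay
# independent of the package's code paths.

# trimmed weighted mean of M-values, computed directly from the formula:
# reference = sample whose 75th-percentile count fraction is closest to the
# mean fraction; per sample, M and A over genes nonzero in both, double
# rank-trim (30% on M, 5% on A), inverse asymptotic binomial variance
# weights; factors re-centered to geometric mean 1.
tmm_factors_oracle <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  lib <- colSums(counts)
  f75 <- apply(counts, 2, stats::quantile, probs = 0.75) / lib
  ref <- which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    obs <- counts[, j]; rfc <- counts[, ref]
    keep <- obs > 0 & rfc > 0
    obs <- obs[keep]; rfc <- rfc[keep]
    m <- log2((obs / lib[j]) / (rfc / lib[ref]))
    a <- (log2(obs / lib[j]) + log2(rfc / lib[ref])) / 2
    v <- (lib[j] - obs) / (lib[j] * obs) + (lib[ref] - rfc) / (lib[ref] * rfc)
    n <- length(m)
    lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
    lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
    keep2 <- rank(m) >= lo_m & rank(m) <= hi_m &
             rank(a) >= lo_a & rank(a) <= hi_a
    val <- sum(m[keep2] / v[keep2]) / sum(1 / v[keep2])
    if (!is.finite(val)) val <- 0
    2^val
  }, numeric(1))
  f / exp(mean(log(f)))
}

# Benjamini-Hochberg step-up by hand
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  out <- numeric(m)
  out[o] <- q_sorted
  out
}

# hypergeometric upper-tail sum: P(overlap >= a) for a query of size n and a
# set of size k over a universe of size n_u
hyper_tail_oracle <- function(a, k, n, n_u) {
  ks <- a:min(k, n)
  sum(choose(k, ks) * choose(n_u - k, n - ks)) / choose(n_u, n)
}

# Welch two-sample t statistic and two-sided p from the formula
welch_oracle <- function(a, b) {
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  t_stat <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t_stat, p = 2 * stats::pt(-abs(t_stat), df))
}

# Efron-corrected Cox partial log-likelihood, written from the definition
efron_loglik_oracle <- function(beta, time, event, x) {
  eta <- drop(as.matrix(x) %*% beta)
  w <- exp(eta)
  ll <- 0
  for (t in unique(time[event == 1])) {
    d_idx <- which(event == 1 & time == t)
    r_idx <- which(time >= t)
    d <- length(d_idx)
    s_risk <- sum(w[r_idx])
    s_tied <- sum(w[d_idx])
    ll <- ll + sum(eta[d_idx]) -
      sum(log(s_risk - (seq_len(d) - 1) / d * s_tied))
  }
  ll
}

# numeric maximization of the Efron partial likelihood
cox_beta_oracle <- function(time, event, x) {
  x <- as.matrix(x)
  neg <- function(b) -efron_loglik_oracle(b, time, event, x)
  stats::optim(rep(0, ncol(x)), neg, method = "BFGS",
               control = list(reltol = 1e-16, maxit = 1000))$par
}

# weighted-KS running sum for one sample, evaluated step by step
ssgsea_oracle <- function(v, member_genes, alpha = 0.25) {
  r <- rank(v)
  ord <- names(sort(r, decreasing = TRUE))
  in_set <- ord %in% member_genes
  w_total <- sum(r[ord][in_set]^alpha)
  p_in <- 0; p_out <- 0; score <- 0
  n_out <- sum(!in_set)
  for (i in seq_along(ord)) {
    if (in_set[i]) {
      p_in <- p_in + r[ord[i]]^alpha / w_total
    } else {
      p_out <- p_out + 1 / n_out
    }
    score <- score + (p_in - p_out)
  }
  unname(score)
}

# Kaplan-Meier product-limit evaluated by hand at the event times
km_oracle <- function(time, event) {
  ev_times <- sort(unique(time[event == 1]))
  surv <- numeric(length(ev_times))
  s <- 1
  for (i in seq_along(ev_times)) {
    t <- ev_times[i]
    n_risk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / n_risk)
    surv[i] <- s
  }
  data.frame(time = ev_times, survival = surv)
}

# adjusted Rand index between two partitions, from the contingency table
ari_oracle <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  maximum <- (si + sj) / 2
  if (maximum == expected) return(1)
  (sij - expected) / (maximum - expected)
}

# shared fixture: a small paired cohort with hand-settable values
make_fc_table <- function(values, therapy, response) {
  structure(list(
    log2fc = values,
    pairs = data.frame(patient_id = paste0("P", seq_len(ncol(values))),
                       ot_sample_id = colnames(values),
                       therapy = therapy, response = response,
                       stringsAsFactors = FALSE)),
    class = "fold_change_table")
}
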