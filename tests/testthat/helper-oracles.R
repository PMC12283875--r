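# Independent brute-force oracles, written directly from the metric and test
# definitions (explicit loops, no shared code with the implementation).

oracle_balanced_accuracy <- function(cm) {
  recalls <- c()
  for (i in seq_len(nrow(cm))) {
    support <- sum(cm[i, ])
    if (support > 0) recalls <- c(recalls, cm[i, i] / support)
  }
  mean(recalls)
}

oracle_weighted_f1 <- function(cm) {
  total <- sum(cm)
  out <- 0
  for (i in seq_len(nrow(cm))) {
    support <- sum(cm[i, ])
    predicted <- sum(cm[, i])
    recall <- if (support > 0) cm[i, i] / support else 0
    precision <- if (predicted > 0) cm[i, i] / predicted else 0
    f1 <- if (precision + recall > 0) {
      2 * precision * recall / (precision + recall)
    } else 0
    out <- out + (support / total) * f1
  }
  out
}

# Direct transcription of the corrected repeated k-fold CV test statistic:
# numerator (1/(k r)) * sum_ij x_ij, denominator sqrt((1/(k r) + n2/n1) *
# sigma2) with sigma2 = (1/(k r - 1)) * sum_ij (x_ij - m)^2, df = k r - 1.
oracle_corrected_t <- function(x_mat, k, r, n1, n2) {
  s <- 0
  for (i in seq_len(k)) for (j in seq_len(r)) s <- s + x_mat[i, j]
  m <- s / (k * r)
  ss <- 0
  for (i in seq_len(k)) for (j in seq_len(r)) ss <- ss + (x_mat[i, j] - m)^2
  sigma2 <- ss / (k * r - 1)
  t_stat <- (s / (k * r)) / sqrt((1 / (k * r) + n2 / n1) * sigma2)
  list(t = t_stat, df = k * r - 1, m = m, sigma2 = sigma2)
}

# Two interleaved Gaussian blobs with a 90:10 class imbalance.
make_imbalanced_blobs <- function(n_major = 90, n_minor = 10, shift = 1.5) {
  x <- data.frame(f1 = c(rnorm(n_major), rnorm(n_minor, shift)),
                  f2 = c(rnorm(n_major), rnorm(n_minor, shift)))
  y <- factor(rep(c("maj", "min"), c(n_major, n_minor)),
              levels = c("maj", "min"))
  list(x = x, y = y)
}

# Small labeled default cohort shared across tests (built once per run).
shared_cohort <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      memo <<- label_cohort(simulate_cohort(
        generation_config(n_subjects = 150, seed = 301)))
    }
    memo
  }
})
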