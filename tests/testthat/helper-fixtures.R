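# Shared fixture builders. Everything is generated in code; no data files.

# Hand-built contrast tibble with just the columns classify_states() uses.
make_contrast <- function(ids, q, lfc, detected = TRUE) {
  tibble::tibble(
    isoform_id = ids,
    log2fc = lfc,
    q_value = q,
    detected_A = detected,
    detected_B = detected
  )
}

# A small abundance table for one fraction, two stages, three replicates,
# with values supplied per isoform as list(A = c(...), B = c(...)).
make_single_fraction <- function(values, fraction = "input") {
  n_rep <- length(values[[1]]$A)
  samples <- tibble::tibble(
    sample_id = c(paste0("A_", fraction, "_", seq_len(n_rep)),
                  paste0("B_", fraction, "_", seq_len(n_rep))),
    stage = rep(c("A", "B"), each = n_rep),
    fraction = fraction,
    replicate = rep(seq_len(n_rep), 2)
  )
  rows <- lapply(seq_along(values), function(i) {
    tibble::tibble(isoform_id = sprintf("iso%03d", i),
                   !!!stats::setNames(
                     as.list(c(values[[i]]$A, values[[i]]$B)),
                     samples$sample_id))
  })
  list(abundance = dplyr::bind_rows(rows), samples = samples)
}

# Textbook Welch formula, kept deliberately independent of the package code.
welch_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- stats::var(a); vb <- stats::var(b)
  se2 <- va / na + vb / nb
  t <- (mean(b) - mean(a)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# Brute-force Benjamini-Hochberg step-up: q_(i) = min_{j >= i} p_(j) * m / j.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- vapply(seq_len(m), function(i) {
    min(1, min(p[ord][i:m] * m / (i:m)))
  }, numeric(1))
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# Exact overlap tail from direct binomial-coefficient arithmetic.
hyper_tail_oracle <- function(k, n_input, n_target, n_bg) {
  j <- k:min(n_input, n_target)
  sum(choose(n_target, j) * choose(n_bg - n_target, n_input - j)) /
    choose(n_bg, n_input)
}
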