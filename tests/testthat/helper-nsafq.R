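# Shared fixtures and independent oracles. Oracles deliberately avoid the
# package's code paths: plain loops, stats::t.test, choose()-based
# hypergeometric sums.

demo_path <- function(file) {
  system.file("extdata", file, package = "nsafq", mustWork = TRUE)
}

# 3v3 condition map used throughout
cmap_3v3 <- c(`2i_1` = "2i", `2i_2` = "2i", `2i_3` = "2i",
              serum_1 = "serum", serum_2 = "serum", serum_3 = "serum")

# build a counts tibble from a protein x 6 matrix (2i_1..3, serum_1..3)
make_counts <- function(m, length_aa = NULL, mw_da = NULL) {
  colnames(m) <- names(cmap_3v3)
  n <- nrow(m)
  if (is.null(length_aa) && is.null(mw_da)) length_aa <- rep(300, n)
  spectral_counts(m, protein_id = sprintf("P%03d", seq_len(n)),
                  condition_of = cmap_3v3,
                  mw_da = mw_da, length_aa = length_aa)
}

# brute-force reproducibility filter on one protein's two count vectors
oracle_filter_one <- function(xa, xb, min_total = 5, scope = "condition") {
  if (scope == "condition") {
    (all(xa > 0) && sum(xa) >= min_total) ||
      (all(xb > 0) && sum(xb) >= min_total)
  } else {
    (all(xa > 0) || all(xb > 0)) && (sum(xa) + sum(xb)) >= min_total
  }
}

# textbook two-sample t (pooled variance) via stats::t.test
oracle_t_p <- function(a, b, equal_var = TRUE) {
  stats::t.test(a, b, var.equal = equal_var)$p.value
}

# exhaustive hypergeometric upper tail P(X >= k) from binomial coefficients
oracle_hyper_upper <- function(k, K, N, n) {
  ks <- k:min(K, n)
  ks <- ks[ks >= max(0, n - (N - K))]
  if (!length(ks)) return(0)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# hand-coded Benjamini-Hochberg step-up
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# minimal diff-like input built directly from desired signed log2 folds
fake_diff <- function(gene_id, protein_log2fc, p_value = 0.01) {
  ratio <- 2^abs(protein_log2fc)
  mean_b <- 1e-3
  mean_a <- mean_b * 2^protein_log2fc
  out <- tibble::tibble(
    protein_id = gene_id,
    passed_filter = TRUE,
    mean_nsaf_a = mean_a,
    mean_nsaf_b = mean_b,
    ratio = ratio,
    direction = ifelse(p_value >= 0.05, "unchanged",
                       ifelse(protein_log2fc > 0, "up_in_a", "up_in_b")),
    t_stat = 1,
    p_value = p_value,
    bh_fdr = p_value
  )
  class(out) <- c("nsaf_diff", class(out))
  attr(out, "condition_a") <- "2i"
  attr(out, "condition_b") <- "serum"
  attr(out, "alpha") <- 0.05
  out
}

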