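#' Replicate reproducibility filter
#'
#' A protein is reproducibly identified when there is at least one condition
#' in which it was detected (raw count > 0) in *every* biological replicate
#' and its total raw spectral count within that same condition reaches
#' `min_total`. Proteins failing the rule are excluded from testing.
#'
#' `scope = "condition"` (the default) evaluates the count total within the
#' condition that satisfies the all-replicates clause. `scope = "overall"`
#' is the alternative reading in which the total is taken across all
#' samples, with the all-replicates clause still required in at least one
#' condition.
#'
#' @param counts long-format spectral-count tibble.
#' @param min_total minimum total spectral count (default 5).
#' @param scope `"condition"` or `"overall"`; see Details.
#' @return tibble with `protein_id`, `passed_filter`.
#' @export
#' @examples
#' m <- matrix(c(2, 2, 1, 0, 0, 0), nrow = 1,
#'             dimnames = list(NULL, c("a1", "a2", "a3", "b1", "b2", "b3")))
#' cnt <- spectral_counts(m, "P1",
#'                        c(a1 = "A", a2 = "A", a3 = "A",
#'                          b1 = "B", b2 = "B", b3 = "B"), length_aa = 300)
#' reproducibility_filter(cnt)  # TRUE: all 3 replicates of A, total 5
reproducibility_filter <- function(counts, min_total = 5,
                                   scope = c("condition", "overall")) {
  counts <- validate_counts(counts)
  scope <- match.arg(scope)
  per_cond <- dplyr::summarise(
    dplyr::group_by(counts, .data$protein_id, .data$condition),
    all_present = all(.data$count > 0),
    cond_total = sum(.data$count),
    .groups = "drop"
  )
  per_prot <- dplyr::summarise(
    dplyr::group_by(per_cond, .data$protein_id),
    passed_filter = if (scope == "condition") {
      any(.data$all_present & .data$cond_total >= min_total)
    } else {
      any(.data$all_present) && sum(.data$cond_total) >= min_total
    },
    .groups = "drop"
  )
  # restore input protein order
  ord <- unique(counts$protein_id)
  per_prot[match(ord, per_prot$protein_id), ]
}

# vectorized two-sample t-test on rows; Student (pooled) or Welch.
# Returns tibble(t_stat, df, p_value). Zero variance in both groups:
# identical means -> p = 1, t = 0; different means -> p = 0, t = +/-Inf.
row_t_test <- function(xa, xb, equal_var = TRUE) {
  dimnames(xa) <- NULL
  dimnames(xb) <- NULL
  na <- ncol(xa); nb <- ncol(xb)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- rowSums((xa - ma)^2) / (na - 1)
  vb <- rowSums((xb - mb)^2) / (nb - 1)
  d <- ma - mb
  if (equal_var) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2, length(d))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  t_stat <- d / se
  p <- 2 * stats::pt(-abs(t_stat), df)
  degenerate <- se == 0
  if (any(degenerate)) {
    same <- degenerate & d == 0
    t_stat[same] <- 0
    p[same] <- 1
    apart <- degenerate & d != 0
    t_stat[apart] <- sign(d[apart]) * Inf
    p[apart] <- 0
    df[degenerate & !equal_var] <- na + nb - 2
  }
  tibble::tibble(t_stat = t_stat, df = df, p_value = p)
}

#' Per-protein differential abundance test on log NSAF
#'
#' Runs an unpaired two-sample t-test (Student pooled-variance by default,
#' Welch via `equal_var = FALSE`) on the log-transformed NSAF values of
#' every protein passing the reproducibility filter, comparing the two
#' conditions. The fold ratio is computed from the condition means of the
#' *unlogged* NSAF and reported as `ratio = max(mean_a/mean_b,
#' mean_b/mean_a) >= 1` with a categorical `direction`; Benjamini-Hochberg
#' adjusted p-values are computed over the tested set as an adjunct to the
#' raw p < alpha criterion.
#'
#' @param nsaf output of [compute_nsaf()].
#' @param filter optional output of [reproducibility_filter()]; omit to test
#'   every protein.
#' @param alpha significance level for the `direction` call (default 0.05).
#' @param equal_var `TRUE` for Student's pooled-variance t (default),
#'   `FALSE` for Welch.
#' @param conditions optional length-2 vector fixing which condition is "a"
#'   (numerator of the signed fold change) and which is "b"; defaults to
#'   first-seen order in `nsaf`.
#' @return a `nsaf_diff` tibble with one row per protein: `protein_id`,
#'   `passed_filter`, `mean_nsaf_a`, `mean_nsaf_b`, `ratio`, `direction`
#'   (`"up_in_a"`, `"up_in_b"`, `"unchanged"`), `t_stat`, `p_value`,
#'   `bh_fdr` (statistics are `NA` for filtered-out proteins). Attributes
#'   `condition_a`, `condition_b`, `alpha` record the comparison.
#' @export
differential_test <- function(nsaf, filter = NULL, alpha = 0.05,
                              equal_var = TRUE, conditions = NULL) {
  if (is.null(conditions)) conditions <- condition_levels(nsaf)
  stopifnot(length(conditions) == 2)
  cond_a <- conditions[1]; cond_b <- conditions[2]

  prot <- unique(nsaf$protein_id)
  if (is.null(filter)) {
    filter <- tibble::tibble(protein_id = prot, passed_filter = TRUE)
  }
  passed <- filter$protein_id[filter$passed_filter]
  if (!length(passed)) {
    stop("no protein passes the reproducibility filter", call. = FALSE)
  }

  la <- counts_matrix(nsaf[nsaf$condition == cond_a, ], "log_nsaf")
  lb <- counts_matrix(nsaf[nsaf$condition == cond_b, ], "log_nsaf")
  ma <- mean_nsaf(nsaf, cond_a)
  mb <- mean_nsaf(nsaf, cond_b)

  keep <- intersect(prot, passed)
  tt <- row_t_test(la[keep, , drop = FALSE], lb[keep, , drop = FALSE],
                   equal_var = equal_var)
  tested <- tibble::tibble(protein_id = keep,
                           t_stat = tt$t_stat, p_value = tt$p_value,
                           bh_fdr = stats::p.adjust(tt$p_value, "BH"))

  out <- tibble::tibble(protein_id = prot)
  out <- dplyr::left_join(out, dplyr::rename(ma, mean_nsaf_a = "mean_nsaf"),
                          by = "protein_id")
  out <- dplyr::left_join(out, dplyr::rename(mb, mean_nsaf_b = "mean_nsaf"),
                          by = "protein_id")
  out <- dplyr::left_join(out, filter, by = "protein_id")
  out <- dplyr::left_join(out, tested, by = "protein_id")
  out <- dplyr::mutate(
    out,
    ratio = pmax(.data$mean_nsaf_a / .data$mean_nsaf_b,
                 .data$mean_nsaf_b / .data$mean_nsaf_a),
    ratio = ifelse(.data$passed_filter, .data$ratio, NA_real_),
    direction = dplyr::case_when(
      !.data$passed_filter | is.na(.data$p_value) ~ NA_character_,
      .data$p_value >= alpha ~ "unchanged",
      .data$mean_nsaf_a > .data$mean_nsaf_b ~ "up_in_a",
      TRUE ~ "up_in_b"
    )
  )
  out <- out[, c("protein_id", "passed_filter", "mean_nsaf_a", "mean_nsaf_b",
                 "ratio", "direction", "t_stat", "p_value", "bh_fdr")]
  class(out) <- c("nsaf_diff", class(out))
  attr(out, "condition_a") <- cond_a
  attr(out, "condition_b") <- cond_b
  attr(out, "alpha") <- alpha
  out
}

#' Summarize a differential-abundance result
#'
#' Headline counts of a two-condition comparison: proteins reproducibly
#' identified, differentially abundant at the raw-p criterion, split by
#' direction, and the percentage of identified proteins that are unchanged,
#' `100 * (n_identified - n_diff) / n_identified`.
#'
#' @param diff output of [differential_test()].
#' @return one-row tibble with `n_identified`, `n_diff`, `n_up_a`, `n_up_b`,
#'   `pct_unchanged`.
#' @export
summarize_counts <- function(diff) {
  n_identified <- sum(diff$passed_filter, na.rm = TRUE)
  n_up_a <- sum(diff$direction == "up_in_a", na.rm = TRUE)
  n_up_b <- sum(diff$direction == "up_in_b", na.rm = TRUE)
  n_diff <- n_up_a + n_up_b
  tibble::tibble(
    n_identified = n_identified,
    n_diff = n_diff,
    n_up_a = n_up_a,
    n_up_b = n_up_b,
    pct_unchanged = if (n_identified > 0) {
      100 * (n_identified - n_diff) / n_identified
    } else 0
  )
}

#' @export
tidy.nsaf_diff <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "nsaf_diff")
  attr(out, "condition_a") <- NULL
  attr(out, "condition_b") <- NULL
  attr(out, "alpha") <- NULL
  out
}

#' @export
glance.nsaf_diff <- function(x, ...) {
  s <- summarize_counts(x)
  s$alpha <- attr(x, "alpha")
  s$condition_a <- attr(x, "condition_a")
  s$condition_b <- attr(x, "condition_b")
  s
}

# signed log2 fold change (condition a over b) from ratio + direction
signed_log2fc <- function(diff) {
  ifelse(diff$mean_nsaf_a >= diff$mean_nsaf_b, 1, -1) *
    log2(diff$ratio)
}
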