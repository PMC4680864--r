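#' Condition-vs-condition log-NSAF scatter table
#'
#' One row per reproducibly identified protein with its mean log NSAF in
#' each condition and a significance flag mirroring the t-test call — the
#' data behind the classic between-condition abundance scatter in which
#' unchanged proteins hug the diagonal and differential proteins sit
#' `log(fold)` away from it.
#'
#' @param nsaf output of [compute_nsaf()].
#' @param diff output of [differential_test()] computed on the same protein
#'   set.
#' @return tibble with `protein_id`, `mean_log_nsaf_a`, `mean_log_nsaf_b`,
#'   `significant`.
#' @export
scatter_table <- function(nsaf, diff) {
  if (!all(diff$protein_id %in% nsaf$protein_id) ||
      !all(unique(nsaf$protein_id) %in% diff$protein_id)) {
    stop("`nsaf` and `diff` cover different protein sets", call. = FALSE)
  }
  cond_a <- attr(diff, "condition_a")
  cond_b <- attr(diff, "condition_b")
  mlog <- dplyr::summarise(
    dplyr::group_by(nsaf, .data$protein_id, .data$condition),
    mean_log_nsaf = mean(.data$log_nsaf), .groups = "drop"
  )
  wide <- tidyr::pivot_wider(mlog, names_from = "condition",
                             values_from = "mean_log_nsaf")
  out <- tibble::tibble(
    protein_id = wide$protein_id,
    mean_log_nsaf_a = wide[[cond_a]],
    mean_log_nsaf_b = wide[[cond_b]]
  )
  out <- dplyr::inner_join(
    out,
    tibble::tibble(protein_id = diff$protein_id,
                   passed_filter = diff$passed_filter,
                   significant = !is.na(diff$direction) &
                     diff$direction != "unchanged"),
    by = "protein_id"
  )
  out <- out[out$passed_filter, setdiff(names(out), "passed_filter")]
  tibble::as_tibble(out)
}

#' Pairwise Spearman correlation and hierarchical clustering of samples
#'
#' Rank correlation between every pair of samples on their per-sample NSAF
#' vectors (over the filtered protein set when a filter is supplied),
#' followed by agglomerative clustering of the samples on the distance
#' `1 - rho`. Because Spearman is rank-based, the result is identical on
#' NSAF, log NSAF, or any strictly monotone transform.
#'
#' @param nsaf output of [compute_nsaf()].
#' @param filter optional output of [reproducibility_filter()]; restricts
#'   the correlation to reproducibly identified proteins.
#' @param linkage agglomeration method for [stats::hclust()] (default
#'   `"average"`).
#' @return a `nsaf_samplecor` object: list with `rho` (symmetric matrix,
#'   unit diagonal), `hclust` (sample dendrogram), `samples`, `conditions`,
#'   `linkage`.
#' @export
spearman_matrix <- function(nsaf, filter = NULL, linkage = "average") {
  if (!is.null(filter)) {
    nsaf <- nsaf[nsaf$protein_id %in%
                   filter$protein_id[filter$passed_filter], ]
  }
  m <- counts_matrix(nsaf, "nsaf")
  if (ncol(m) < 2) stop("need at least 2 samples", call. = FALSE)
  const <- apply(m, 2, function(x) stats::sd(x) == 0)
  if (any(const)) {
    stop("constant NSAF vector, Spearman undefined for sample(s): ",
         paste(colnames(m)[const], collapse = ", "), call. = FALSE)
  }
  rho <- stats::cor(m, method = "spearman")
  hc <- stats::hclust(stats::as.dist(1 - rho), method = linkage)
  smap <- dplyr::distinct(nsaf, .data$sample, .data$condition)
  structure(
    list(rho = rho, hclust = hc, samples = colnames(m),
         conditions = stats::setNames(smap$condition, smap$sample),
         linkage = linkage),
    class = "nsaf_samplecor"
  )
}

#' @export
print.nsaf_samplecor <- function(x, ...) {
  cat("Sample Spearman correlation (", length(x$samples), " samples, ",
      x$linkage, " linkage on 1 - rho)\n", sep = "")
  print(round(x$rho, 3))
  invisible(x)
}

#' @export
tidy.nsaf_samplecor <- function(x, ...) {
  pairs <- which(upper.tri(x$rho), arr.ind = TRUE)
  tibble::tibble(
    sample_a = rownames(x$rho)[pairs[, 1]],
    sample_b = colnames(x$rho)[pairs[, 2]],
    rho = x$rho[pairs],
    same_condition = x$conditions[rownames(x$rho)[pairs[, 1]]] ==
      x$conditions[colnames(x$rho)[pairs[, 2]]]
  )
}

#' Top-level sample partition from the correlation dendrogram
#'
#' Cuts the sample dendrogram into `k` clusters; with `k = 2` this asks
#' whether the two culture conditions separate as the top two clusters.
#'
#' @param x a `nsaf_samplecor` object.
#' @param k number of clusters (default 2).
#' @return named integer vector of cluster memberships per sample.
#' @export
cut_samples <- function(x, k = 2) {
  stats::cutree(x$hclust, k = k)
}
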