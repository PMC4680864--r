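#' Fisher-exact (hypergeometric) term enrichment
#'
#' One-sided overrepresentation test of a query protein list against a
#' background, per annotation term: the p-value is the upper tail of the
#' hypergeometric distribution, `P(X >= k)` for `k` query hits among a term
#' of size `K` in a background of size `N` with a query of size `n`.
#' Benjamini-Hochberg step-up adjustment is applied across all tested
#' terms. This is a transparent local stand-in for web enrichment services;
#' no EASE-style score deflation is applied.
#'
#' @param query character vector of protein/gene ids (must be a subset of
#'   `background`).
#' @param background character vector of ids defining the universe —
#'   typically all reproducibly identified proteins.
#' @param sets annotation tibble from [read_gmt()] (`term_id`, `term_name`,
#'   `protein_id`). Members outside the background are ignored.
#' @param drop_empty if `TRUE`, terms with zero query overlap are omitted
#'   rather than reported with p = 1.
#' @return tibble with `term_id`, `term_name`, `k_in_list`, `n_list`,
#'   `K_in_bg`, `N_bg`, `p_value`, `bh_fdr`, ordered by p-value.
#' @export
fisher_enrich <- function(query, background, sets, drop_empty = FALSE) {
  query <- unique(query)
  background <- unique(background)
  extra <- setdiff(query, background)
  if (length(extra)) {
    stop("query ids absent from background: ",
         paste(utils::head(extra, 5), collapse = ", "), call. = FALSE)
  }
  sets_bg <- sets[sets$protein_id %in% background, ]
  n <- length(query)
  N <- length(background)
  res <- dplyr::summarise(
    dplyr::group_by(sets_bg, .data$term_id, .data$term_name),
    k_in_list = length(intersect(.data$protein_id, query)),
    K_in_bg = dplyr::n_distinct(.data$protein_id),
    .groups = "drop"
  )
  res$n_list <- n
  res$N_bg <- N
  # upper-tail hypergeometric: P(X >= k)
  res$p_value <- stats::phyper(res$k_in_list - 1, res$K_in_bg,
                               res$N_bg - res$K_in_bg, res$n_list,
                               lower.tail = FALSE)
  if (drop_empty) res <- res[res$k_in_list > 0, ]
  res$bh_fdr <- stats::p.adjust(res$p_value, "BH")
  res <- res[order(res$p_value, res$term_id),
             c("term_id", "term_name", "k_in_list", "n_list", "K_in_bg",
               "N_bg", "p_value", "bh_fdr")]
  tibble::as_tibble(res)
}

#' Summed mean NSAF per annotation category
#'
#' For each term, sums the per-condition mean NSAF over its member proteins
#' — the overall abundance a functional category accounts for in one
#' condition. Because NSAF is compositional, disjoint terms covering all
#' proteins have sums adding to 1.
#'
#' @param nsaf output of [compute_nsaf()].
#' @param sets annotation tibble from [read_gmt()].
#' @param condition a condition label present in `nsaf`.
#' @return tibble with `term_id`, `term_name`, `n_members` (quantified
#'   members), `summed_nsaf`. Terms with no quantified member get 0 with a
#'   warning.
#' @export
category_abundance <- function(nsaf, sets, condition) {
  mn <- mean_nsaf(nsaf, condition)
  joined <- dplyr::left_join(sets, mn, by = "protein_id")
  out <- dplyr::summarise(
    dplyr::group_by(joined, .data$term_id, .data$term_name),
    n_members = sum(!is.na(.data$mean_nsaf)),
    summed_nsaf = sum(.data$mean_nsaf, na.rm = TRUE),
    .groups = "drop"
  )
  if (any(out$n_members == 0)) {
    warning("term(s) with no quantified member reported as 0: ",
            paste(out$term_id[out$n_members == 0], collapse = ", "),
            call. = FALSE)
  }
  tibble::as_tibble(out)
}
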