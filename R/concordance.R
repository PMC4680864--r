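#' Classify proteome-transcriptome concordance quadrants
#'
#' Joins the per-protein differential result with an mRNA log2 fold-change
#' table (both oriented condition a over condition b) and assigns every
#' joined gene whose protein *and* mRNA fold changes both reach the
#' magnitude threshold to one of four sign-pattern groups:
#'
#' * `i` — both protein and mRNA up in condition b (both log2fc negative)
#' * `ii` — protein up in condition a, mRNA up in condition b
#' * `iii` — both up in condition a (both positive)
#' * `iv` — mRNA up in condition a, protein up in condition b
#'
#' Everything else is `"none"`. The protein fold change enters as the
#' signed log2 of the mean-NSAF ratio reconstructed from `ratio` and the
#' condition means. Genes present in only one of the two tables are kept
#' with `joined = FALSE` (never silently dropped) and classified `"none"`.
#'
#' @param diff output of [differential_test()].
#' @param mrna transcriptome tibble from [read_transcriptome()] (`gene_id`,
#'   `mrna_log2fc`, oriented a over b).
#' @param threshold_fold magnitude threshold as a fold ratio (> 1, default
#'   2, i.e. |log2fc| >= 1 in both layers).
#' @param significant_only if `TRUE` (default), only proteins called
#'   differential at the t-test alpha are eligible for groups i-iv; set
#'   `FALSE` to classify all quantified proteins by fold change alone.
#' @return tibble with `gene_id`, `protein_log2fc`, `mrna_log2fc`,
#'   `joined`, `group` (factor `i`/`ii`/`iii`/`iv`/`none`).
#' @export
classify_concordance <- function(diff, mrna, threshold_fold = 2,
                                 significant_only = TRUE) {
  if (threshold_fold <= 1) {
    stop("`threshold_fold` must exceed 1", call. = FALSE)
  }
  thr <- log2(threshold_fold)
  prot <- tibble::tibble(
    gene_id = diff$protein_id,
    protein_log2fc = signed_log2fc(diff),
    eligible = diff$passed_filter &
      (!significant_only |
         (!is.na(diff$direction) & diff$direction != "unchanged"))
  )
  joined <- dplyr::full_join(prot, mrna, by = "gene_id")
  joined$joined <- !is.na(joined$protein_log2fc) & !is.na(joined$mrna_log2fc)
  pass <- joined$joined & !is.na(joined$eligible) & joined$eligible &
    abs(joined$protein_log2fc) >= thr & abs(joined$mrna_log2fc) >= thr
  group <- rep("none", nrow(joined))
  sp <- joined$protein_log2fc > 0
  sm <- joined$mrna_log2fc > 0
  group[pass & !sp & !sm] <- "i"
  group[pass & sp & !sm] <- "ii"
  group[pass & sp & sm] <- "iii"
  group[pass & !sp & sm] <- "iv"
  tibble::tibble(
    gene_id = joined$gene_id,
    protein_log2fc = joined$protein_log2fc,
    mrna_log2fc = joined$mrna_log2fc,
    joined = joined$joined,
    group = factor(group, levels = c("i", "ii", "iii", "iv", "none"))
  )
}

#' Count and list members of the concordance groups
#'
#' @param records output of [classify_concordance()].
#' @return tibble with one row per group `i`-`iv`: `group`, `n`, `members`
#'   (list-column of gene ids). Counts sum to the number of non-`none`
#'   records.
#' @export
concordance_summary <- function(records) {
  grp <- records[records$group != "none", ]
  base <- tibble::tibble(group = factor(c("i", "ii", "iii", "iv"),
                                        levels = c("i", "ii", "iii", "iv")))
  counted <- dplyr::summarise(
    dplyr::group_by(grp, .data$group),
    n = dplyr::n(), members = list(.data$gene_id), .groups = "drop"
  )
  out <- dplyr::left_join(base, counted, by = "group")
  out$n[is.na(out$n)] <- 0L
  out$members <- purrr::map(out$members, function(m) m %||% character())
  out
}
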