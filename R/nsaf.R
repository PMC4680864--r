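#' Estimate protein length from molecular weight
#'
#' Sequence length in residues is approximated by dividing the molecular
#' weight by the average amino-acid residue mass. The result is left as a
#' real number (not rounded); an explicitly supplied `length_aa` always
#' takes precedence in [compute_nsaf()].
#'
#' @param mw_da molecular weight(s) in Daltons, strictly positive.
#' @param avg_aa_mw_da average residue mass in Daltons (default 111.1254).
#' @return estimated length(s) in residues.
#' @export
#' @examples
#' estimate_length(111125.4)  # 1000
estimate_length <- function(mw_da, avg_aa_mw_da = 111.1254) {
  if (any(!is.finite(mw_da) | mw_da <= 0)) {
    stop("`mw_da` must be strictly positive", call. = FALSE)
  }
  if (avg_aa_mw_da <= 0) {
    stop("`avg_aa_mw_da` must be strictly positive", call. = FALSE)
  }
  mw_da / avg_aa_mw_da
}

#' Compute normalized spectral abundance factors (NSAF)
#'
#' For protein k in sample i, NSAF is the length-normalized spectral count
#' rescaled to the per-sample total:
#' \deqn{NSAF_{ik} = \frac{(SpC_{ik} + f)/L_k}{\sum_j (SpC_{ij} + f)/L_j}}
#' where `f` is the spectral fraction (pseudo-count) added to every raw
#' count so that zero-count proteins have finite log abundance. With the
#' default `f = 0.5` all NSAF values are strictly positive and each sample's
#' NSAF column sums to exactly 1, making `log_nsaf` (natural log) safe for
#' t-testing.
#'
#' The pseudo-count is added to the raw counts *before* length division and
#' normalization. The alternative reading — adding `f/L` after length
#' division — is available via `pseudo_after_length = TRUE` for sensitivity
#' analysis; it perturbs low-count proteins slightly differently but keeps
#' the per-sample sum at 1.
#'
#' @param counts long-format spectral-count tibble (see [spectral_counts()]).
#' @param pseudo_fraction spectral fraction `f >= 0` added to all counts
#'   (default 0.5).
#' @param avg_aa_mw_da average residue mass used by [estimate_length()] when
#'   a protein has `mw_da` but no `length_aa`.
#' @param pseudo_after_length if `TRUE`, add `f/L_k` to the length-normalized
#'   count instead of adding `f` to the raw count.
#' @return tibble with columns `protein_id`, `sample`, `condition`, `count`,
#'   `length_aa`, `nsaf`, `log_nsaf`; attributes record `pseudo_fraction`
#'   and `avg_aa_mw_da`.
#' @export
#' @examples
#' m <- matrix(rep(c(10, 20, 70), 4), ncol = 4,
#'             dimnames = list(NULL, c("a1", "a2", "b1", "b2")))
#' cnt <- spectral_counts(m, paste0("P", 1:3),
#'                        c(a1 = "A", a2 = "A", b1 = "B", b2 = "B"),
#'                        length_aa = c(100, 200, 700))
#' compute_nsaf(cnt, pseudo_fraction = 0)  # equal SpC/L: NSAF = 1/3 each
compute_nsaf <- function(counts, pseudo_fraction = 0.5,
                         avg_aa_mw_da = 111.1254,
                         pseudo_after_length = FALSE) {
  counts <- validate_counts(counts)
  if (pseudo_fraction < 0) {
    stop("`pseudo_fraction` must be >= 0", call. = FALSE)
  }
  len <- counts$length_aa
  need <- is.na(len) | len <= 0
  if (any(need)) {
    len[need] <- estimate_length(counts$mw_da[need], avg_aa_mw_da)
  }

  spc_over_l <- if (pseudo_after_length) {
    counts$count / len + pseudo_fraction / len
  } else {
    (counts$count + pseudo_fraction) / len
  }

  out <- dplyr::mutate(
    dplyr::group_by(
      dplyr::mutate(counts, length_aa = len, .spcl = spc_over_l),
      .data$sample
    ),
    nsaf = {
      tot <- sum(.data$.spcl)
      if (tot == 0) {
        stop(sprintf("sample '%s' has all-zero counts and pseudo_fraction = 0: NSAF undefined",
                     .data$sample[1]), call. = FALSE)
      }
      .data$.spcl / tot
    },
    log_nsaf = log(.data$nsaf)
  )
  out <- dplyr::ungroup(out)
  out <- out[, c("protein_id", "sample", "condition", "count",
                 "length_aa", "nsaf", "log_nsaf")]
  attr(out, "pseudo_fraction") <- pseudo_fraction
  attr(out, "avg_aa_mw_da") <- avg_aa_mw_da
  out
}

#' Per-protein mean NSAF within one condition
#'
#' The arithmetic mean of the (unlogged) NSAF values across a condition's
#' replicates, the per-condition abundance summary used for fold ratios,
#' scatter plots and category abundance sums.
#'
#' @param nsaf output of [compute_nsaf()].
#' @param condition a condition label present in `nsaf`.
#' @return tibble with `protein_id`, `mean_nsaf`.
#' @export
mean_nsaf <- function(nsaf, condition) {
  if (!condition %in% nsaf$condition) {
    stop("unknown condition: ", condition, call. = FALSE)
  }
  dplyr::summarise(
    dplyr::group_by(nsaf[nsaf$condition == condition, ], .data$protein_id),
    mean_nsaf = mean(.data$nsaf), .groups = "drop"
  )
}
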