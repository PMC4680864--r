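#' Assemble a spectral-count table
#'
#' The central data structure of the package is an ordinary tibble in long
#' format with one row per (protein, sample) pair and columns `protein_id`,
#' `sample`, `condition`, `count`, plus per-protein size information in
#' `mw_da` (molecular weight, Daltons) and/or `length_aa` (sequence length,
#' residues). All downstream verbs take this tibble as their first argument.
#'
#' @param counts matrix or data frame of non-negative integer spectral
#'   counts, proteins in rows, samples in columns.
#' @param protein_id character vector of unique protein identifiers, one per
#'   row of `counts`.
#' @param condition_of named character vector mapping each sample (column)
#'   name to one of exactly two condition labels.
#' @param mw_da optional positive molecular weights in Daltons.
#' @param length_aa optional positive integer sequence lengths. At least one
#'   of `mw_da`/`length_aa` must be given for every protein.
#'
#' @return A long-format tibble with columns `protein_id`, `mw_da`,
#'   `length_aa`, `sample`, `condition`, `count`.
#' @export
#' @examples
#' m <- matrix(c(4, 0, 7, 2, 9, 1), nrow = 1,
#'             dimnames = list(NULL, paste0("s", 1:6)))
#' spectral_counts(m, protein_id = "P1",
#'                 condition_of = c(s1 = "2i", s2 = "2i", s3 = "2i",
#'                                  s4 = "serum", s5 = "serum", s6 = "serum"),
#'                 mw_da = 52000)
spectral_counts <- function(counts, protein_id, condition_of,
                            mw_da = NULL, length_aa = NULL) {
  counts <- as.matrix(counts)
  n <- nrow(counts)
  if (anyDuplicated(protein_id)) {
    stop("duplicated protein id(s): ",
         paste(unique(protein_id[duplicated(protein_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (length(protein_id) != n) {
    stop("`protein_id` must have one entry per row of `counts`", call. = FALSE)
  }
  if (is.null(colnames(counts))) {
    stop("`counts` must have sample names as column names", call. = FALSE)
  }
  if (is.null(mw_da)) mw_da <- rep(NA_real_, n)
  if (is.null(length_aa)) length_aa <- rep(NA_real_, n)
  tbl <- tibble::tibble(
    protein_id = as.character(protein_id),
    mw_da = as.numeric(mw_da),
    length_aa = as.numeric(length_aa)
  )
  long <- tidyr::pivot_longer(
    dplyr::bind_cols(tbl, tibble::as_tibble(counts)),
    cols = -c("protein_id", "mw_da", "length_aa"),
    names_to = "sample", values_to = "count"
  )
  long$condition <- unname(condition_of[long$sample])
  long <- long[, c("protein_id", "mw_da", "length_aa",
                   "sample", "condition", "count")]
  validate_counts(long)
}

#' Validate a spectral-count table
#'
#' Checks the invariants every pipeline stage relies on: unique protein ids,
#' non-negative integer counts, a molecular weight or length for every
#' protein, exactly two conditions with at least two replicate samples each.
#' Called internally by every verb; exported so scripts can fail fast.
#'
#' @param counts long-format spectral-count tibble (see [spectral_counts()]).
#' @return `counts`, invisibly unchanged, as a tibble.
#' @export
validate_counts <- function(counts) {
  counts <- tibble::as_tibble(counts)
  need <- c("protein_id", "sample", "condition", "count")
  missing_cols <- setdiff(need, names(counts))
  if (length(missing_cols)) {
    stop("count table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!("mw_da" %in% names(counts))) counts$mw_da <- NA_real_
  if (!("length_aa" %in% names(counts))) counts$length_aa <- NA_real_

  bad <- counts$count < 0 | is.na(counts$count) |
    counts$count != round(counts$count)
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf(
      "counts must be non-negative integers; offending cell: protein '%s', sample '%s', value %s",
      counts$protein_id[i], counts$sample[i], counts$count[i]
    ), call. = FALSE)
  }

  per_prot <- dplyr::distinct(counts, .data$protein_id, .data$mw_da,
                              .data$length_aa)
  dup <- per_prot$protein_id[duplicated(per_prot$protein_id)]
  if (length(dup)) {
    stop("duplicated protein id(s): ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  sizeless <- per_prot$protein_id[
    (is.na(per_prot$mw_da) | per_prot$mw_da <= 0) &
      (is.na(per_prot$length_aa) | per_prot$length_aa <= 0)
  ]
  if (length(sizeless)) {
    stop("protein(s) without positive mw_da or length_aa: ",
         paste(utils::head(sizeless, 5), collapse = ", "), call. = FALSE)
  }

  smap <- dplyr::distinct(counts, .data$sample, .data$condition)
  if (anyDuplicated(smap$sample)) {
    stop("a sample is assigned to more than one condition", call. = FALSE)
  }
  if (any(is.na(smap$condition))) {
    stop("sample(s) without a condition assignment: ",
         paste(smap$sample[is.na(smap$condition)], collapse = ", "),
         call. = FALSE)
  }
  conds <- unique(smap$condition)
  if (length(conds) != 2) {
    stop("exactly two condition labels are required, found: ",
         paste(conds, collapse = ", "), call. = FALSE)
  }
  n_rep <- table(smap$condition)
  if (any(n_rep < 2)) {
    stop("each condition needs at least 2 replicate samples", call. = FALSE)
  }
  # every protein must appear in every sample exactly once
  tab <- table(counts$protein_id, counts$sample)
  if (any(tab != 1)) {
    stop("count table is not a complete protein x sample grid", call. = FALSE)
  }
  invisible(counts)
}

# internal: the two condition labels in a stable order (first-seen)
condition_levels <- function(counts) {
  unique(dplyr::distinct(counts, .data$sample, .data$condition)$condition)
}

# internal: samples of one condition
samples_of <- function(counts, condition) {
  smap <- dplyr::distinct(counts, .data$sample, .data$condition)
  smap$sample[smap$condition == condition]
}

# internal: long table -> protein x sample matrix of `value`
counts_matrix <- function(counts, value = "count") {
  wide <- tidyr::pivot_wider(counts[, c("protein_id", "sample", value)],
                             names_from = "sample",
                             values_from = dplyr::all_of(value))
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$protein_id
  m
}
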