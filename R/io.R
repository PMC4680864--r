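#' Read a spectral-count table from tab-separated text
#'
#' Expects a header row; first column is the protein identifier, a `mw_da`
#' and/or `length_aa` column carries protein size, and every remaining
#' column is a sample of integer spectral counts. Sample-to-condition
#' assignment is supplied explicitly (the paper's sample naming is not
#' machine-readable), either as a named vector or as a YAML file mapping
#' `sample: condition`.
#'
#' @param path path to a tab-separated count file.
#' @param condition_map named character vector (`c(sample = condition)`), a
#'   two-column data frame (`sample`, `condition`), or path to a YAML file.
#' @return long-format spectral-count tibble (see [spectral_counts()]).
#' @export
read_counts <- function(path, condition_map) {
  condition_map <- as_condition_map(condition_map)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (ncol(raw) < 3) {
    stop("count file needs an id column, a size column and sample columns",
         call. = FALSE)
  }
  id_col <- names(raw)[1]
  size_cols <- intersect(c("mw_da", "length_aa"), names(raw))
  if (!length(size_cols)) {
    stop("count file has neither a 'mw_da' nor a 'length_aa' column",
         call. = FALSE)
  }
  sample_cols <- setdiff(names(raw), c(id_col, size_cols))
  unknown <- setdiff(sample_cols, names(condition_map))
  if (length(unknown)) {
    stop("sample column(s) missing from condition map: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (sc in sample_cols) {
    v <- suppressWarnings(as.numeric(raw[[sc]]))
    bad <- which(is.na(v) | v < 0 | v != round(v))
    if (length(bad)) {
      stop(sprintf(
        "non-integer or negative count in column '%s', row %d (protein '%s'): '%s'",
        sc, bad[1], raw[[id_col]][bad[1]], raw[[sc]][bad[1]]
      ), call. = FALSE)
    }
    raw[[sc]] <- v
  }
  m <- as.matrix(raw[, sample_cols, drop = FALSE])
  spectral_counts(
    m,
    protein_id = raw[[id_col]],
    condition_of = condition_map,
    mw_da = if ("mw_da" %in% size_cols) as.numeric(raw$mw_da),
    length_aa = if ("length_aa" %in% size_cols) as.numeric(raw$length_aa)
  )
}

as_condition_map <- function(x) {
  if (is.character(x) && is.null(names(x)) && length(x) == 1 &&
      file.exists(x)) {
    x <- unlist(yaml::read_yaml(x))
  }
  if (is.data.frame(x)) {
    x <- stats::setNames(as.character(x$condition), x$sample)
  }
  if (is.null(names(x))) {
    stop("condition map must be named by sample", call. = FALSE)
  }
  stats::setNames(as.character(x), names(x))
}

#' Write a spectral-count table as tab-separated text
#'
#' Inverse of [read_counts()]: emits `protein_id`, `mw_da`, `length_aa`,
#' then one column per sample, and (optionally) the condition map as YAML.
#'
#' @param counts long-format spectral-count tibble.
#' @param path output TSV path.
#' @param conditions_path optional path for a YAML sample-to-condition map.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path, conditions_path = NULL) {
  counts <- validate_counts(counts)
  wide <- tidyr::pivot_wider(
    counts[, c("protein_id", "mw_da", "length_aa", "sample", "count")],
    names_from = "sample", values_from = "count"
  )
  readr::write_tsv(wide, path, progress = FALSE)
  if (!is.null(conditions_path)) {
    smap <- dplyr::distinct(counts, .data$sample, .data$condition)
    yaml::write_yaml(as.list(stats::setNames(smap$condition, smap$sample)),
                     conditions_path)
  }
  invisible(path)
}

#' Read annotation sets in GMT format
#'
#' One term per line: `term_id<TAB>term_name<TAB>member1<TAB>member2...`.
#' Returned long so sets compose with joins.
#'
#' @param path path to a GMT file.
#' @return tibble with columns `term_id`, `term_name`, `protein_id`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parsed <- purrr::imap(lines, function(line, i) {
    parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
    members <- parts[-(1:2)]
    members <- members[nzchar(members)]
    if (length(parts) < 3 || !length(members)) {
      stop(sprintf("malformed GMT line %d: term needs an id, a name and >=1 member", i),
           call. = FALSE)
    }
    tibble::tibble(term_id = parts[1], term_name = parts[2],
                   protein_id = members)
  })
  sets <- dplyr::bind_rows(parsed)
  dup <- unique(sets$term_id[duplicated(dplyr::distinct(sets, .data$term_id, .data$term_name)$term_id)])
  if (anyDuplicated(unique(sets[, c("term_id", "term_name")])$term_id)) {
    stop("duplicated term_id in GMT file", call. = FALSE)
  }
  sets
}

#' Read a transcriptome fold-change table
#'
#' Tab-separated with a header; first column gene identifier, second column
#' mRNA log2 fold change (first condition over second, matching the protein
#' table's orientation).
#'
#' @param path path to a TSV file.
#' @return tibble with columns `gene_id`, `mrna_log2fc`.
#' @export
read_transcriptome <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  out <- tibble::tibble(gene_id = as.character(raw[[1]]),
                        mrna_log2fc = as.numeric(raw[[2]]))
  if (anyDuplicated(out$gene_id)) {
    stop("duplicated gene_id in transcriptome table: ",
         paste(unique(out$gene_id[duplicated(out$gene_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(out$mrna_log2fc))) {
    stop("non-finite mRNA log2 fold change", call. = FALSE)
  }
  out
}

#' Write any result tibble as tab-separated text
#'
#' Stable column order (as-is) with a header row; `read_table_tsv()` is the
#' lossless inverse for round-tripping result tables.
#'
#' @param x a data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(x), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_table_tsv
#' @export
read_table_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
}
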