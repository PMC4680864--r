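#' Run the full quantification pipeline from a single configuration
#'
#' Wires the stages together — (optionally) simulate or read spectral
#' counts, compute NSAF, apply the reproducibility filter, t-test on log
#' NSAF, sample diagnostics, and, when annotation / transcriptome inputs
#' are given, term enrichment and concordance classification — writing one
#' tab-separated table per stage plus a run log that records every
#' parameter and the protein counts at each stage (identified, filtered,
#' tested, significant). Outputs are deterministic given the seed and
#' inputs.
#'
#' The configuration is a named list, or the path to a YAML file holding
#' one. Recognised fields (all optional unless noted):
#' \describe{
#'   \item{counts, conditions}{path to a count TSV and its sample-condition
#'     YAML map (see [read_counts()]); if absent, a dataset is simulated.}
#'   \item{simulate}{list of [simulate_spectral_counts()] arguments used
#'     when no `counts` path is given.}
#'   \item{out_dir}{output directory (required).}
#'   \item{alpha, pseudo_fraction, min_total, avg_aa_mw_da,
#'     fold_threshold}{analysis parameters; defaults 0.05, 0.5, 5,
#'     111.1254, 2.}
#'   \item{filter_scope, equal_var, pseudo_after_length,
#'     concord_significant_only}{the documented alternative readings;
#'     defaults `"condition"`, `TRUE`, `FALSE`, `TRUE`.}
#'   \item{gmt}{path to a GMT annotation file (enables enrichment).}
#'   \item{mrna}{path to a transcriptome TSV (enables concordance).}
#'   \item{seed}{integer RNG seed used for simulation.}
#' }
#'
#' @param config named list or path to a YAML config file.
#' @return (invisibly) a list with the per-stage tibbles (`counts`,
#'   `truth`, `nsaf`, `filter`, `diff`, `summary`, `scatter`, `correlation`,
#'   and when enabled `enrichment`, `concordance`, `concordance_summary`)
#'   plus `log`, the character vector written to `run_log.txt`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) {
      stop("config file not found: ", config, call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(
    list(alpha = 0.05, pseudo_fraction = 0.5, min_total = 5,
         avg_aa_mw_da = 111.1254, fold_threshold = 2,
         filter_scope = "condition", equal_var = TRUE,
         pseudo_after_length = FALSE, concord_significant_only = TRUE,
         seed = NULL, simulate = list()),
    config
  )
  if (is.null(cfg$out_dir)) stop("config needs `out_dir`", call. = FALSE)
  for (f in c("counts", "conditions", "gmt", "mrna")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]])) {
      stop("input path does not exist: ", cfg[[f]], " (", f, ")",
           call. = FALSE)
    }
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  log_lines <- c(
    "# nsafq run log",
    paste0("date: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    paste0("parameters: alpha=", cfg$alpha,
           " pseudo_fraction=", cfg$pseudo_fraction,
           " min_total=", cfg$min_total,
           " avg_aa_mw_da=", cfg$avg_aa_mw_da,
           " fold_threshold=", cfg$fold_threshold,
           " filter_scope=", cfg$filter_scope,
           " equal_var=", cfg$equal_var,
           " pseudo_after_length=", cfg$pseudo_after_length,
           " seed=", if (is.null(cfg$seed)) "none" else cfg$seed)
  )
  res <- list()

  if (!is.null(cfg$counts)) {
    if (is.null(cfg$conditions)) {
      stop("`conditions` map is required with a `counts` path", call. = FALSE)
    }
    res$counts <- read_counts(cfg$counts, cfg$conditions)
    log_lines <- c(log_lines, paste0("input: ", cfg$counts))
  } else {
    sim_args <- cfg$simulate
    if (!is.null(cfg$seed)) sim_args$seed <- cfg$seed
    sim <- do.call(simulate_spectral_counts, sim_args)
    res$counts <- sim$counts
    res$truth <- sim$truth
    write_table_tsv(res$truth, file.path(cfg$out_dir, "truth.tsv"))
    log_lines <- c(log_lines, "input: simulated")
  }
  write_counts(res$counts, file.path(cfg$out_dir, "counts.tsv"),
               file.path(cfg$out_dir, "conditions.yaml"))
  n_total <- dplyr::n_distinct(res$counts$protein_id)

  res$nsaf <- compute_nsaf(res$counts, pseudo_fraction = cfg$pseudo_fraction,
                           avg_aa_mw_da = cfg$avg_aa_mw_da,
                           pseudo_after_length = cfg$pseudo_after_length)
  write_table_tsv(res$nsaf, file.path(cfg$out_dir, "nsaf.tsv"))

  res$filter <- reproducibility_filter(res$counts, min_total = cfg$min_total,
                                       scope = cfg$filter_scope)
  res$diff <- differential_test(res$nsaf, res$filter, alpha = cfg$alpha,
                                equal_var = cfg$equal_var)
  write_table_tsv(tidy(res$diff), file.path(cfg$out_dir, "diff.tsv"))
  res$summary <- summarize_counts(res$diff)
  write_table_tsv(res$summary, file.path(cfg$out_dir, "summary.tsv"))

  res$scatter <- scatter_table(res$nsaf, res$diff)
  write_table_tsv(res$scatter, file.path(cfg$out_dir, "scatter.tsv"))
  res$correlation <- spearman_matrix(res$nsaf, res$filter)
  write_table_tsv(tidy(res$correlation),
                  file.path(cfg$out_dir, "sample_correlation.tsv"))

  log_lines <- c(log_lines, paste0(
    "stage counts: total=", n_total,
    " identified=", res$summary$n_identified,
    " tested=", sum(!is.na(res$diff$p_value)),
    " significant=", res$summary$n_diff,
    " (up_in_", attr(res$diff, "condition_a"), "=", res$summary$n_up_a,
    ", up_in_", attr(res$diff, "condition_b"), "=", res$summary$n_up_b, ")"
  ))

  if (!is.null(cfg$gmt)) {
    sets <- read_gmt(cfg$gmt)
    background <- res$filter$protein_id[res$filter$passed_filter]
    for (dir_lab in c("up_in_a", "up_in_b")) {
      query <- res$diff$protein_id[!is.na(res$diff$direction) &
                                     res$diff$direction == dir_lab]
      if (length(query)) {
        enr <- fisher_enrich(query, background, sets)
        cond <- attr(res$diff,
                     if (dir_lab == "up_in_a") "condition_a" else "condition_b")
        res$enrichment[[cond]] <- enr
        write_table_tsv(enr, file.path(cfg$out_dir,
                                       paste0("enrichment_up_in_", cond, ".tsv")))
      }
    }
    log_lines <- c(log_lines, paste0("enrichment: ", cfg$gmt))
  }

  if (!is.null(cfg$mrna)) {
    mrna <- read_transcriptome(cfg$mrna)
    res$concordance <- classify_concordance(
      res$diff, mrna, threshold_fold = cfg$fold_threshold,
      significant_only = cfg$concord_significant_only
    )
    res$concordance_summary <- concordance_summary(res$concordance)
    write_table_tsv(res$concordance,
                    file.path(cfg$out_dir, "concordance.tsv"))
    write_table_tsv(
      dplyr::mutate(res$concordance_summary,
                    members = purrr::map_chr(.data$members, paste,
                                             collapse = ",")),
      file.path(cfg$out_dir, "concordance_summary.tsv")
    )
    log_lines <- c(log_lines, paste0(
      "concordance groups: ",
      paste(res$concordance_summary$group, res$concordance_summary$n,
            sep = "=", collapse = " ")
    ))
  }

  writeLines(log_lines, file.path(cfg$out_dir, "run_log.txt"))
  res$log <- log_lines
  invisible(res)
}
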