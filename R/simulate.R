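#' Simulate a spectral-count experiment with planted differential abundance
#'
#' Generates protein-level spectral counts with the statistical structure
#' spectral counting is assumed to have: counts within a sample are a single
#' multinomial draw of `depth` spectra, with per-protein spectrum-generation
#' probability proportional to abundance times sequence length (longer
#' proteins yield more spectra; NSAF's division by length undoes exactly
#' this). Base abundances are lognormal; a planted fraction of proteins
#' carries a fold change between the two conditions, sign-balanced so that
#' half are up in each condition; biological replicates receive optional
#' lognormal abundance jitter on top of multinomial counting noise.
#'
#' Defaults emulate a 2-condition, 3-replicate mouse embryonic stem cell
#' comparison ("2i" ground-state medium vs "serum"): ~1,800 proteins at a
#' modest ion-trap sequencing depth, so most proteins have low, zero-inflated
#' counts.
#'
#' @param n_proteins number of proteins (default 1800).
#' @param n_replicates biological replicates per condition (default 3).
#' @param depth total spectra per sample; the multinomial size (default 30000).
#' @param frac_diff fraction of proteins with a planted fold change, in
#'   `[0, 1]` (default 0.1).
#' @param fold_levels positive fold ratios (> 1) cycled over planted
#'   proteins (default `c(2, 4, 8)`); the direction alternates so planted
#'   effects are sign-balanced across conditions.
#' @param abundance_logsd sd of base log abundance (natural log, default 1.5).
#' @param mw_log_meanlog,mw_log_sdlog lognormal parameters of molecular
#'   weight in Da; defaults give a median of ~50 kDa.
#' @param replicate_logsd sd of per-replicate lognormal abundance jitter
#'   (natural log, default 0.1); 0 disables biological overdispersion.
#' @param conditions length-2 character vector of condition labels; the
#'   planted fold is expressed as first over second.
#' @param seed integer RNG seed; the simulation is deterministic given it.
#'
#' @return list with elements
#'   \describe{
#'     \item{counts}{long-format spectral-count tibble (see
#'       [spectral_counts()]); samples are named `<condition>_<r>`.}
#'     \item{truth}{tibble with `protein_id`, `true_fold` (first condition
#'       over second), `is_diff`, `base_abundance`, and per-condition
#'       expected counts per replicate (`expected_count_<condition>`,
#'       computed from the jitter-free multinomial probabilities).}
#'   }
#' @export
#' @examples
#' sim <- simulate_spectral_counts(n_proteins = 50, depth = 2000, seed = 1)
#' dplyr::count(sim$counts, sample, wt = count)   # column sums == depth
simulate_spectral_counts <- function(n_proteins = 1800,
                                     n_replicates = 3,
                                     depth = 30000,
                                     frac_diff = 0.1,
                                     fold_levels = c(2, 4, 8),
                                     abundance_logsd = 1.5,
                                     mw_log_meanlog = log(50000),
                                     mw_log_sdlog = 0.5,
                                     replicate_logsd = 0.1,
                                     conditions = c("2i", "serum"),
                                     seed = NULL) {
  if (n_proteins < 1 || n_proteins != round(n_proteins)) {
    stop("`n_proteins` must be a positive integer", call. = FALSE)
  }
  if (depth < 1 || depth != round(depth)) {
    stop("`depth` must be a positive integer", call. = FALSE)
  }
  if (n_replicates < 2 || n_replicates != round(n_replicates)) {
    stop("`n_replicates` must be an integer >= 2", call. = FALSE)
  }
  if (frac_diff < 0 || frac_diff > 1) {
    stop("`frac_diff` must lie in [0, 1]", call. = FALSE)
  }
  if (any(fold_levels <= 1)) {
    stop("`fold_levels` must all exceed 1", call. = FALSE)
  }
  if (length(conditions) != 2 || anyDuplicated(conditions)) {
    stop("`conditions` must be two distinct labels", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  id_width <- nchar(as.character(n_proteins))
  protein_id <- sprintf(paste0("P%0", id_width, "d"), seq_len(n_proteins))
  mw_da <- stats::rlnorm(n_proteins, mw_log_meanlog, mw_log_sdlog)
  length_aa <- mw_da / 111.1254
  base_abundance <- stats::rlnorm(n_proteins, 0, abundance_logsd)

  n_diff <- round(frac_diff * n_proteins)
  true_fold <- rep(1, n_proteins)
  if (n_diff > 0) {
    planted <- sample.int(n_proteins, n_diff)
    folds <- rep_len(fold_levels, n_diff)
    # alternate direction: even-indexed planted proteins are up in condition 2
    sign_up_first <- rep_len(c(TRUE, FALSE), n_diff)
    true_fold[planted] <- ifelse(sign_up_first, folds, 1 / folds)
  }

  # condition-level mean abundances (first condition carries the fold)
  abund_a <- base_abundance * true_fold
  abund_b <- base_abundance

  expected_share <- function(ab) {
    w <- ab * length_aa
    w / sum(w)
  }
  p_a <- expected_share(abund_a)
  p_b <- expected_share(abund_b)

  sample_names <- c(paste0(conditions[1], "_", seq_len(n_replicates)),
                    paste0(conditions[2], "_", seq_len(n_replicates)))
  condition_of <- stats::setNames(rep(conditions, each = n_replicates),
                                  sample_names)

  draw_sample <- function(ab) {
    jitter <- if (replicate_logsd > 0) {
      stats::rlnorm(n_proteins, 0, replicate_logsd)
    } else 1
    w <- ab * jitter * length_aa
    as.vector(stats::rmultinom(1, size = depth, prob = w / sum(w)))
  }
  cmat <- vapply(sample_names, function(s) {
    draw_sample(if (condition_of[s] == conditions[1]) abund_a else abund_b)
  }, integer(n_proteins))
  if (n_proteins == 1) {
    cmat <- matrix(cmat, nrow = 1, dimnames = list(NULL, sample_names))
  }

  counts <- spectral_counts(cmat, protein_id = protein_id,
                            condition_of = condition_of, mw_da = mw_da,
                            length_aa = length_aa)

  truth <- tibble::tibble(
    protein_id = protein_id,
    true_fold = true_fold,
    is_diff = true_fold != 1,
    base_abundance = base_abundance
  )
  truth[[paste0("expected_count_", conditions[1])]] <- depth * p_a
  truth[[paste0("expected_count_", conditions[2])]] <- depth * p_b

  list(counts = counts, truth = truth)
}
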