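test_that("reproducibility filter applies the all-replicates + total rule", {
  cases <- list(
    list(a = c(2, 2, 1), b = c(0, 0, 0), want = TRUE),   # all of A, total 5
    list(a = c(1, 1, 1), b = c(0, 0, 0), want = FALSE),  # total 3 < 5
    list(a = c(5, 5, 0), b = c(0, 0, 4), want = FALSE),  # no all-present cond
    list(a = c(0, 0, 0), b = c(9, 9, 9), want = TRUE),
    list(a = c(4, 1, 0), b = c(1, 1, 3), want = TRUE)    # B all present, 5
  )
  m <- do.call(rbind, lapply(cases, function(cs) c(cs$a, cs$b)))
  got <- reproducibility_filter(make_counts(m))
  expect_equal(got$passed_filter, vapply(cases, `[[`, logical(1), "want"))
})

test_that("filter agrees with brute force on random 3v3 matrices", {
  set.seed(202)
  n <- 10000
  m <- matrix(rpois(n * 6, lambda = rep(runif(n, 0.2, 4), 6)), nrow = n)
  cnt <- make_counts(m)
  for (scope in c("condition", "overall")) {
    got <- reproducibility_filter(cnt, min_total = 5, scope = scope)
    want <- vapply(seq_len(n), function(i) {
      oracle_filter_one(m[i, 1:3], m[i, 4:6], 5, scope)
    }, logical(1))
    expect_equal(got$passed_filter, want)
  }
})

test_that("t-test on log NSAF matches stats::t.test to 1e-10", {
  set.seed(303)
  m <- matrix(rpois(60 * 6, 15) + 1, nrow = 60)
  cnt <- make_counts(m, mw_da = runif(60, 10000, 150000))
  ns <- compute_nsaf(cnt)
  for (ev in c(TRUE, FALSE)) {
    d <- differential_test(ns, equal_var = ev)
    ln <- tidyr::pivot_wider(ns[, c("protein_id", "sample", "log_nsaf")],
                             names_from = sample, values_from = log_nsaf)
    want <- vapply(seq_len(nrow(ln)), function(i) {
      oracle_t_p(unlist(ln[i, c("2i_1", "2i_2", "2i_3")]),
                 unlist(ln[i, c("serum_1", "serum_2", "serum_3")]),
                 equal_var = ev)
    }, numeric(1))
    expect_equal(d$p_value[match(ln$protein_id, d$protein_id)], want,
                 tolerance = 1e-10)
  }
})

test_that("a textbook separation is called with the exact Student t p-value", {
  # log NSAF a = (-5.0, -5.1, -4.9) vs b = (-7.0, -7.1, -6.9):
  # pooled t = 24.4949, df = 4, p = 1.648e-05 (independent closed form)
  la <- c(-5.0, -5.1, -4.9)
  lb <- c(-7.0, -7.1, -6.9)
  ns <- tibble::tibble(
    protein_id = "P1",
    sample = names(cmap_3v3),
    condition = unname(cmap_3v3),
    nsaf = exp(c(la, lb)),
    log_nsaf = c(la, lb)
  )
  d <- differential_test(ns)
  expect_equal(d$t_stat, 24.494897, tolerance = 1e-6)
  expect_equal(d$p_value, 1.6481e-05, tolerance = 1e-4)
  expect_lt(d$p_value, 0.01)
  expect_equal(d$direction, "up_in_a")
})

test_that("degenerate groups follow the stated conventions", {
  # identical values in both groups -> unchanged, p = 1
  ns_same <- tibble::tibble(
    protein_id = "P1", sample = names(cmap_3v3),
    condition = unname(cmap_3v3),
    nsaf = rep(0.5, 6), log_nsaf = rep(log(0.5), 6)
  )
  d <- differential_test(ns_same)
  expect_equal(d$p_value, 1)
  expect_equal(d$direction, "unchanged")

  # zero variance in both groups, different means -> p = 0
  ns_apart <- ns_same
  ns_apart$log_nsaf <- rep(c(-2, -9), each = 3)
  ns_apart$nsaf <- exp(ns_apart$log_nsaf)
  d2 <- differential_test(ns_apart)
  expect_equal(d2$p_value, 0)
  expect_equal(d2$direction, "up_in_a")
})

test_that("ratio, direction and BH columns satisfy their contracts", {
  set.seed(404)
  sim <- simulate_spectral_counts(n_proteins = 300, depth = 20000,
                                  frac_diff = 0.2, seed = 404)
  ns <- compute_nsaf(sim$counts)
  filt <- reproducibility_filter(sim$counts)
  d <- differential_test(ns, filt)

  tested <- d[!is.na(d$p_value), ]
  expect_true(all(tested$ratio >= 1))
  expect_equal(tested$direction == "unchanged", tested$p_value >= 0.05)
  up_a <- tested$direction == "up_in_a"
  expect_true(all(tested$mean_nsaf_a[up_a] > tested$mean_nsaf_b[up_a]))
  # p present only for proteins passing the filter
  expect_true(all(is.na(d$p_value[!d$passed_filter])))
  expect_true(all(!is.na(d$p_value[d$passed_filter])))
  # BH matches hand-coded step-up over the tested set
  expect_equal(tested$bh_fdr, oracle_bh(tested$p_value))
  expect_true(all(tested$bh_fdr >= tested$p_value - 1e-12))

  # n_diff monotone non-increasing in alpha
  alphas <- c(0.2, 0.1, 0.05, 0.01, 0.001)
  n_diff <- vapply(alphas, function(a) {
    summarize_counts(differential_test(ns, filt, alpha = a))$n_diff
  }, numeric(1))
  expect_true(all(diff(n_diff) <= 0))
})

test_that("summary arithmetic reproduces the headline percentages", {
  # 1582 identified with 164 + 107 = 271 differential -> ~83% unchanged
  fake <- tibble::tibble(
    protein_id = sprintf("P%04d", 1:1582),
    passed_filter = TRUE,
    direction = c(rep("up_in_a", 164), rep("up_in_b", 107),
                  rep("unchanged", 1582 - 271))
  )
  s <- summarize_counts(fake)
  expect_equal(s$n_diff, 271)
  expect_equal(round(s$pct_unchanged, 2), 82.87)
  expect_equal(round(s$pct_unchanged), 83)

  empty <- fake[0, ]
  s0 <- summarize_counts(empty)
  expect_equal(unlist(s0[1, 1:4]), c(n_identified = 0, n_diff = 0,
                                     n_up_a = 0, n_up_b = 0))
})

test_that("glance and tidy expose the comparison metadata", {
  cnt <- read_counts(demo_path("demo_counts.tsv"),
                     demo_path("demo_conditions.yaml"))
  d <- differential_test(compute_nsaf(cnt), reproducibility_filter(cnt))
  g <- glance(d)
  expect_equal(g$condition_a, "2i")
  expect_equal(g$condition_b, "serum")
  expect_equal(g$alpha, 0.05)
  expect_false(inherits(tidy(d), "nsaf_diff"))
})
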