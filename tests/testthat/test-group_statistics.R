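# group_statistics: tvd, d/r, permutation test, group split

test_that("tvd has the stated boundary behaviour", {
  x <- c(0.1, 0.4, 0.7, 1.3, 2.2)
  expect_equal(total_variation_distance(x, x), 0)
  # disjoint supports spanning different bins
  expect_equal(total_variation_distance(runif(50, 0, 1),
                                        runif(50, 10, 11)), 1)
  # categorical toy case: {0,0,1,1} vs {0,1,1,1} with two bins
  # oracle: 0.5 * (|.5 - .25| + |.5 - .75|) = 0.25
  expect_equal(total_variation_distance(c(0, 0, 1, 1), c(0, 1, 1, 1),
                                        nbins = 2), 0.25)
  # symmetry
  set.seed(101)
  a <- rnorm(200); b <- rnorm(150, 0.5)
  expect_equal(total_variation_distance(a, b),
               total_variation_distance(b, a))
  expect_error(total_variation_distance(numeric(0), a), "empty")
})

test_that("tvd equals the exact discrete tvd on categorical data", {
  set.seed(103)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    a <- sample(seq_len(k), 80, replace = TRUE)
    b <- sample(seq_len(k), 60, replace = TRUE)
    # bins aligned with the categories
    edges <- seq(0.5, k + 0.5, by = 1)
    got <- total_variation_distance(a, b, edges = edges)
    want <- 0.5 * sum(abs(tabulate(a, k) / 80 - tabulate(b, k) / 60))
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("adding shared data never pushes tvd above its prior value", {
  set.seed(107)
  for (i in 1:20) {
    a <- rnorm(120); b <- rnorm(120, 1)
    extra <- rnorm(60, 0.5)
    edges <- tvd_bin_edges(c(a, b, extra))
    t0 <- total_variation_distance(a, b, edges = edges)
    t1 <- total_variation_distance(c(a, extra), c(b, extra), edges = edges)
    expect_lte(t1, t0 + 1e-12)
  }
})

test_that("d/r matches the quantile-arithmetic oracle", {
  expect_equal(normalized_mean_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  set.seed(109)
  for (i in 1:20) {
    a <- rnorm(80, sd = runif(1, 0.5, 3))
    b <- rnorm(120, mean = runif(1, -2, 2))
    pooled <- c(a, b)
    want <- abs(mean(a) - mean(b)) /
      (oracle_quantile7(pooled, 0.975) - oracle_quantile7(pooled, 0.025))
    expect_equal(normalized_mean_distance(a, b), want, tolerance = 1e-12)
    # scale invariance
    k <- runif(1, 0.1, 50)
    expect_equal(normalized_mean_distance(k * a, k * b),
                 normalized_mean_distance(a, b), tolerance = 1e-12)
  }
  # zero trimmed range with a genuine mean difference is degenerate
  expect_error(normalized_mean_distance(rep(0, 200), 100), "degenerate")
})

make_sd <- function(ids, n_frames = 30, mean = 0, sim_sd = 1, frame_sd = 1) {
  vals <- unlist(lapply(ids, function(i)
    rnorm(n_frames, mean + rnorm(1, 0, sim_sd), frame_sd)))
  sample_distribution(vals, rep(ids, each = n_frames))
}

test_that("permutation test is seeded, reproducible and sane", {
  set.seed(113)
  a <- make_sd(sprintf("a%d", 1:5))
  b <- make_sd(sprintf("b%d", 1:5))
  r1 <- permutation_test(a, b, n_perm = 200, seed = 99)
  r2 <- permutation_test(a, b, n_perm = 200, seed = 99)
  expect_identical(r1$null_tvd, r2$null_tvd)
  expect_identical(r1$pct_dr, r2$pct_dr)
  r3 <- permutation_test(a, b, n_perm = 200, seed = 100)
  expect_false(identical(r1$null_tvd, r3$null_tvd))
  expect_true(all(r1$null_tvd >= 0 & r1$null_tvd <= 1))
  expect_error(permutation_test(a, b, n_perm = 10), "seed")

  # constant data: zero observed tvd and d/r, category none
  cst <- sample_distribution(rep(1, 40), rep(sprintf("c%d", 1:4), each = 10))
  cst2 <- sample_distribution(rep(1, 40), rep(sprintf("d%d", 1:4), each = 10))
  rc <- permutation_test(cst, cst2, n_perm = 50, seed = 1)
  expect_equal(rc$observed_tvd, 0)
  expect_equal(rc$observed_dr, 0)
  expect_equal(rc$category, "none")

  # fewer than two simulations per group is an input error
  one <- sample_distribution(rnorm(10), rep("only", 10))
  expect_error(permutation_test(one, b, n_perm = 10, seed = 1),
               "at least 2")
})

test_that("a gross planted shift is recovered as strong", {
  set.seed(127)
  a <- make_sd(sprintf("a%d", 1:10), mean = 0, sim_sd = 0.2)
  b <- make_sd(sprintf("b%d", 1:10), mean = 5, sim_sd = 0.2)
  r <- permutation_test(a, b, n_perm = 500, seed = 5)
  expect_equal(r$category, "strong")
  expect_equal(r$category_dr, "strong")
  expect_gte(r$pct_tvd, 0.99)
})

test_that("null percentiles are uniform under exchangeability", {
  # with exchangeable labels the percentile of the observed statistic is
  # uniform on a discrete grid; KS sanity check over replicates
  set.seed(131)
  reps <- 200
  pct <- replicate(reps, {
    a <- make_sd(sprintf("a%d", 1:6), n_frames = 20)
    b <- make_sd(sprintf("b%d", 1:6), n_frames = 20)
    permutation_test(a, b, n_perm = 100, seed = sample.int(1e6, 1))$pct_dr
  })
  ks <- suppressWarnings(stats::ks.test(pct, "punif"))
  expect_gt(ks$p.value, 0.001)
  expect_gt(mean(pct), 0.35)
  expect_lt(mean(pct), 0.65)
})

test_that("categories follow the 0.90/0.95/0.99 thresholds", {
  expect_equal(difference_category(0.899), "none")
  expect_equal(difference_category(0.90), "slight")
  expect_equal(difference_category(0.95), "difference")
  expect_equal(difference_category(0.99), "strong")
})

test_that("split_groups applies the lysis-concentration rules", {
  tb <- data.frame(
    peptide_sequence = c("AAA", "BBB", "CCC", "DDD", "EEE"),
    lysis50_neg_log10_molar = c("never", "7.2", "5.0", "6.94", ""),
    stringsAsFactors = FALSE
  )
  sp <- split_groups(tb)
  expect_setequal(sp$groupL_ids, c("AAA", "EEE"))   # "never" entries
  expect_setequal(sp$groupM_ids, c("BBB", "DDD"))   # 10^-7.2, boundary
  expect_setequal(sp$excluded_ids, "CCC")           # in between
  # no id in two groups
  expect_length(intersect(sp$groupM_ids, sp$groupL_ids), 0)

  # numeric column with NA-as-never works too
  tb2 <- data.frame(peptide_sequence = c("X", "Y"),
                    lysis50_neg_log10_molar = c(NA, 8))
  sp2 <- split_groups(tb2)
  expect_equal(sp2$groupL_ids, "X")
  expect_equal(sp2$groupM_ids, "Y")

  # malformed value -> parse error
  tb3 <- data.frame(peptide_sequence = "Z",
                    lysis50_neg_log10_molar = "ten")
  expect_error(split_groups(tb3), "malformed")

  # top-n policy
  sp3 <- split_groups(tb, policy = list(type = "top_n", n = 1))
  expect_equal(sp3$groupM_ids, "BBB")
})

test_that("compare_descriptor emits a complete report row", {
  set.seed(137)
  a <- make_sd(sprintf("a%d", 1:4))
  b <- make_sd(sprintf("b%d", 1:4))
  cmp <- compare_descriptor("DC", a, b, n_perm = 100, seed = 3)
  row <- cmp$row
  expect_named(row, c("descriptor", "observed_tvd", "observed_dr",
                      "pct_tvd", "pct_dr", "category_tvd", "category_dr",
                      "category"))
  expect_equal(row$descriptor, "DC")
  expect_equal(row$observed_tvd, cmp$result$observed_tvd)
  expect_true(row$category %in% c("none", "slight", "difference", "strong"))
})
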