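test_that("diet-breadth counting and specialist classification", {
  tbl <- tiny_trait_table()
  expect_identical(count_diet_types(tbl), c(1L, 2L, 2L, 1L, 1L, 3L))
  expect_identical(classify_specialist(tbl),
                   c("specialist", "generalist", "generalist",
                     "specialist", "specialist", "generalist"))
  # a minimum-share cutoff can demote marginal categories
  tbl$diet_seed[2] <- 4
  tbl$diet_fruit[2] <- 96
  expect_identical(count_diet_types(tbl, min_share = 5)[2], 1L)

  bad <- tbl
  bad[2, paste0("diet_", diet_categories)] <- 0
  expect_error(count_diet_types(bad), "all-zero")
})

test_that("primary diet classification follows the animal/plant divide", {
  tbl <- tiny_trait_table()
  expect_identical(classify_primary_diet(tbl),
                   c("carnivore", "herbivore", "omnivore",
                     "carnivore", "herbivore", "carnivore"))
})

test_that("quantile bins are balanced, deterministic and permutation
           invariant", {
  expect_identical(quantile_bins(1:10, 5), rep(1:5, each = 2L))

  set.seed(3)
  masses <- 10^runif(137, 0, 6)
  bins <- quantile_bins(masses, 20)
  sizes <- tabulate(bins, 20)
  expect_identical(sum(sizes), 137L)
  expect_lte(diff(range(sizes)), 1L)
  # bins are contiguous rank blocks along the mass axis
  rk <- rank(masses, ties.method = "first")
  hi <- tapply(rk, bins, max)
  lo <- tapply(rk, bins, min)
  expect_true(all(hi[-20] < lo[-1]))

  # heavy ties: still balanced, and stable under row permutation
  tied <- rep(100, 30)
  names_tied <- sprintf("sp_%02d", 30:1)
  b1 <- quantile_bins(tied, 5, names_tied)
  expect_lte(diff(range(tabulate(b1, 5))), 1L)
  perm <- sample(30)
  b2 <- quantile_bins(tied[perm], 5, names_tied[perm])
  expect_identical(b1[perm], b2)

  expect_error(quantile_bins(1:5, 10), "at least")
})

test_that("binomial confidence intervals: closed form, boundaries,
           coverage of the point estimate", {
  ci <- binomial_ci(0, 10)
  expect_identical(unname(ci[, "low"]), 0)
  expect_equal(unname(ci[, "high"]), 1 - 0.025^(1 / 10), tolerance = 1e-10)
  expect_identical(unname(binomial_ci(10, 10)[, "high"]), 1)

  set.seed(5)
  for (m in c("clopper-pearson", "wilson")) {
    n <- sample(5:200, 20, replace = TRUE)
    k <- rbinom(20, n, runif(20))
    ci <- binomial_ci(k, n, method = m)
    expect_true(all(ci[, "low"] <= k / n & k / n <= ci[, "high"]))
    expect_true(all(ci[, "low"] >= 0 & ci[, "high"] <= 1))
  }
  expect_error(binomial_ci(5, 3), "k <= n")
})

test_that("bin summaries: partition, pooled-null identity, degenerate
           tables and deviation flags", {
  synth <- generate_trait_table(synth_config(n_species = 400, seed = 21,
                                             with_tree = FALSE))
  bins <- bin_specialist_proportions(synth$traits, n_bins = 20)
  expect_identical(sum(bins$n_species), nrow(synth$traits))
  expect_true(all(bins$ci_low <= bins$proportion &
                    bins$proportion <= bins$ci_high))
  # with the pooled null, the abundance-weighted mean of bin proportions
  # equals the null exactly
  expect_equal(sum(bins$proportion * bins$n_species) / sum(bins$n_species),
               bins$null_proportion[1], tolerance = 1e-12)
  expect_identical(attr(bins, "ci_method"), "clopper-pearson")

  # all-specialist table: proportions 1, nothing flagged below
  tbl <- tiny_trait_table()[c(1, 4, 5), ]
  tbl <- rbind(tbl, tbl, tbl, tbl)
  tbl$species <- sprintf("sp_%02d", 1:12)
  all_bins <- bin_specialist_proportions(tbl, n_bins = 3)
  expect_true(all(all_bins$proportion == 1))
  expect_false(any(all_bins$deviation == "below"))

  # deviation flags against an external null
  dev <- bin_specialist_proportions(synth$traits, n_bins = 5,
                                    null_proportion = 0.999)
  expect_true(all(dev$deviation == "below"))
})

test_that("deviation flags are reproducible under row permutation", {
  synth <- generate_trait_table(synth_config(n_species = 300, seed = 8,
                                             with_tree = FALSE))
  b1 <- bin_specialist_proportions(synth$traits, n_bins = 10)
  set.seed(9)
  shuffled <- synth$traits[sample(nrow(synth$traits)), ]
  b2 <- bin_specialist_proportions(shuffled, n_bins = 10)
  expect_identical(b1$deviation, b2$deviation)
  expect_equal(b1$proportion, b2$proportion)
})

test_that("realm subsetting and island filtering", {
  tbl <- tiny_trait_table()
  expect_identical(subset_by_realm(tbl, "Neotropical")$species,
                   c("sp_1", "sp_2", "sp_5"))
  expect_error(subset_by_realm(tbl, "Atlantis"), "unknown realm")
  # sp_3 occurs only in the Oceanian (island) realm
  expect_identical(exclude_island_only(tbl)$species,
                   setdiff(tbl$species, "sp_3"))
  # species may occupy several realms: union of realm subsets can exceed n
  n_union <- sum(vapply(realm_labels, function(rl)
    nrow(subset_by_realm(tbl, rl)), 0L))
  expect_gte(n_union, nrow(exclude_island_only(tbl)))
})

test_that("one-sided KS statistic matches its definition and oracles", {
  expect_equal(ks_one_sided(c(1, 2), c(3, 4))$D, 1)
  expect_equal(ks_one_sided(c(1, 3), c(2, 4))$D, 0.5)
  expect_equal(ks_one_sided(c(1, 2, 3), c(1, 2, 3))$D, 0)
  expect_error(ks_one_sided(numeric(0), 1), "non-empty")

  # brute-force oracle: double loop over pooled evaluation points
  brute <- function(x, y) {
    pts <- c(x, y)
    max(vapply(pts, function(t) mean(x <= t) - mean(y <= t), 0))
  }
  set.seed(13)
  for (i in 1:20) {
    x <- round(rnorm(sample(2:30, 1)), 1)  # rounding induces ties
    y <- round(rnorm(sample(2:30, 1), mean = runif(1, -1, 1)), 1)
    res <- ks_one_sided(x, y)
    expect_equal(res$D, max(0, brute(x, y)), tolerance = 1e-12)
    # cross-check against the standard implementation
    D_ref <- suppressWarnings(
      stats::ks.test(x, y, alternative = "greater")$statistic)
    expect_equal(res$D, unname(D_ref), tolerance = 1e-12)
  }
})

test_that("median-split covariates put ties in the lower half", {
  tbl <- tiny_trait_table()
  out <- median_split_covariates(tbl)
  med <- attr(out, "median_log10_mass")
  expect_equal(out$abs_median_dev, abs(log10(tbl$body_mass_g) - med))
  expect_true(all(out$size_class[out$log10_mass <= med] == "below_or_equal"))

  # a species exactly at the median goes below, with zero deviation
  odd <- tbl[1:5, ]
  out_odd <- median_split_covariates(odd)
  at_med <- which(out_odd$abs_median_dev == 0)
  expect_length(at_med, 1)
  expect_identical(out_odd$size_class[at_med], "below_or_equal")

  # near-even split on a large synthetic table (ties included below)
  synth <- generate_trait_table(synth_config(n_species = 501, seed = 2,
                                             with_tree = FALSE))
  sp <- median_split_covariates(synth$traits)
  expect_identical(sum(sp$size_class == "below_or_equal"), 251L)
  expect_identical(sum(sp$size_class == "above"), 250L)
})
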