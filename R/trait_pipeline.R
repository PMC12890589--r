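#' Diet categories and zoogeographic realm labels
#'
#' The ten diet categories follow the EltonTraits convention: six
#' animal-side categories (invertebrates; endothermic, ectothermic, fish
#' and unclassified vertebrates; scavenged material) and four plant-side
#' categories (fruit, nectar, seed, other plant material). Realm labels are
#' the eleven zoogeographic realms used for regional assemblages; the
#' Oceanian and Madagascan realms are flagged as island-dominated.
#'
#' @format `diet_categories` and `realm_labels` are character vectors;
#'   `animal_diet_categories`, `plant_diet_categories` and `island_realms`
#'   are subsets of the above.
#' @name trait-vocab
NULL

#' @rdname trait-vocab
#' @export
diet_categories <- c("inv", "vend", "vect", "vfish", "vunk", "scav",
                     "fruit", "nect", "seed", "planto")

#' @rdname trait-vocab
#' @export
animal_diet_categories <- c("inv", "vend", "vect", "vfish", "vunk", "scav")

#' @rdname trait-vocab
#' @export
plant_diet_categories <- c("fruit", "nect", "seed", "planto")

#' @rdname trait-vocab
#' @export
realm_labels <- c("Afrotropical", "Australian", "Madagascan", "Nearctic",
                  "Neotropical", "Oceanian", "Oriental", "Palearctic",
                  "Panamanian", "Saharo_Arabian", "Sino_Japanese")

#' @rdname trait-vocab
#' @export
island_realms <- c("Oceanian", "Madagascan")

diet_cols <- function() paste0("diet_", diet_categories)
realm_cols <- function() paste0("realm_", tolower(realm_labels))

#' Validate a trait table
#'
#' A trait table is a data frame with one row per species: `species`,
#' `body_mass_g`, ten `diet_*` consumption-share columns in `[0, 100]`
#' (at least one strictly positive per species), eleven logical `realm_*`
#' occupancy columns, and optionally `order`. Row-level failures are
#' reported with row numbers.
#'
#' @param table A data frame.
#' @param drop_invalid Drop offending rows with a warning instead of
#'   erroring.
#' @return The validated (possibly filtered) table, invisibly classed as
#'   `"trait_table"`.
#' @export
validate_trait_table <- function(table, drop_invalid = FALSE) {
  required <- c("species", "body_mass_g", diet_cols())
  missing <- setdiff(required, names(table))
  if (length(missing))
    stop("trait table schema error; missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  have_realms <- all(realm_cols() %in% names(table))
  mass <- suppressWarnings(as.numeric(table$body_mass_g))
  diet <- as.matrix(table[diet_cols()])
  bad <- !is.finite(mass) | mass <= 0 |
    rowSums(!is.finite(diet)) > 0 |
    rowSums(diet < 0 | diet > 100) > 0 |
    rowSums(diet > 0) == 0
  if (have_realms) {
    occ <- as.matrix(table[realm_cols()]) != 0
    bad <- bad | rowSums(occ, na.rm = TRUE) == 0
  }
  if (any(bad)) {
    msg <- paste0("invalid trait row(s): ",
                  paste(utils::head(which(bad), 20), collapse = ", "),
                  if (sum(bad) > 20) sprintf(" ... (%d total)", sum(bad)))
    if (!drop_invalid) stop(msg, call. = FALSE)
    warning(msg, " -- dropped", call. = FALSE)
    table <- table[!bad, , drop = FALSE]
  }
  table$body_mass_g <- as.numeric(table$body_mass_g)
  class(table) <- unique(c("trait_table", class(table)))
  invisible(table)
}

#' Number of diet categories consumed
#'
#' Counts, per species, the diet categories with a consumption share
#' strictly above `min_share` (0 by default: any recorded consumption
#' counts). Empirically mammals consume one to six of the ten categories.
#'
#' @param table A trait table (see [validate_trait_table()]).
#' @param min_share Minimum share (percent) for a category to count as
#'   consumed; a sensitivity knob.
#' @return Integer vector of diet-breadth counts in `[1, 10]`.
#' @export
count_diet_types <- function(table, min_share = 0) {
  diet <- as.matrix(table[diet_cols()])
  n <- rowSums(diet > min_share)
  if (any(n == 0))
    stop("species with all-zero diet vector at row(s): ",
         paste(utils::head(which(n == 0), 10), collapse = ", "), call. = FALSE)
  as.integer(n)
}

#' Classify species as dietary specialists or generalists
#'
#' A species is a specialist when it consumes exactly one of the ten diet
#' categories, and a generalist otherwise.
#'
#' @inheritParams count_diet_types
#' @return Character vector, `"specialist"` or `"generalist"`.
#' @export
classify_specialist <- function(table, min_share = 0) {
  ifelse(count_diet_types(table, min_share) == 1, "specialist", "generalist")
}

#' Classify primary diet
#'
#' `"carnivore"`: only animal-side categories consumed (invertebrates, all
#' vertebrate classes, scavenged material); `"herbivore"`: only plant-side
#' categories (fruit, nectar, seed, other plant material); `"omnivore"`:
#' both sides. Omnivores are generalists by construction.
#'
#' @inheritParams count_diet_types
#' @return Character vector: `"carnivore"`, `"herbivore"` or `"omnivore"`.
#' @export
classify_primary_diet <- function(table, min_share = 0) {
  animal <- rowSums(as.matrix(table[paste0("diet_", animal_diet_categories)]) >
                      min_share) > 0
  plant <- rowSums(as.matrix(table[paste0("diet_", plant_diet_categories)]) >
                     min_share) > 0
  out <- rep("omnivore", nrow(table))
  out[animal & !plant] <- "carnivore"
  out[plant & !animal] <- "herbivore"
  out
}

#' Assign species to body-mass quantile bins
#'
#' Species are ranked by (log10 mass, species name) with a stable sort and
#' partitioned into `n_bins` contiguous rank blocks whose sizes differ by
#' at most one. The name tie-break makes assignments deterministic under
#' row permutation even with heavily tied masses.
#'
#' @param masses Positive body masses (g).
#' @param n_bins Number of bins (20 for 5% quantiles, 10 for 10%).
#' @param species Optional species names used to break mass ties; row order
#'   is used if omitted.
#' @return Integer bin index per species, in `1:n_bins`.
#' @export
quantile_bins <- function(masses, n_bins = 20, species = NULL) {
  n <- length(masses)
  if (n < n_bins)
    stop(sprintf("need at least n_bins = %d species, got %d", n_bins, n),
         call. = FALSE)
  if (any(masses <= 0)) stop("masses must be positive", call. = FALSE)
  ord <- if (is.null(species)) order(log10(masses))
         else order(log10(masses), species, method = "radix")
  rank <- integer(n)
  rank[ord] <- seq_len(n)
  as.integer(floor((rank - 1) * n_bins / n) + 1L)
}

#' Binomial proportion confidence interval
#'
#' Two-sided confidence interval for a binomial proportion. The default is
#' the Clopper-Pearson "exact" interval (the interval implied by the exact
#' binomial test); Wilson's score interval is available as an option.
#'
#' @param k Number of successes (vectorized).
#' @param n Number of trials (> 0).
#' @param level Confidence level (default 0.95, i.e. the 2.5-97.5%
#'   interval).
#' @param method `"clopper-pearson"` or `"wilson"`.
#' @return A two-column matrix `(low, high)`.
#' @examples
#' binomial_ci(0, 10)  # upper limit 1 - 0.025^(1/10)
#' @export
binomial_ci <- function(k, n, level = 0.95,
                        method = c("clopper-pearson", "wilson")) {
  method <- match.arg(method)
  if (any(n <= 0) || any(k < 0) || any(k > n))
    stop("require 0 <= k <= n and n > 0", call. = FALSE)
  a <- 1 - level
  if (method == "clopper-pearson") {
    low <- ifelse(k == 0, 0, qbeta(a / 2, k, n - k + 1))
    high <- ifelse(k == n, 1, qbeta(1 - a / 2, k + 1, n - k))
  } else {
    z <- qnorm(1 - a / 2)
    phat <- k / n
    den <- 1 + z^2 / n
    centre <- (phat + z^2 / (2 * n)) / den
    half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / den
    low <- pmax(0, centre - half)
    high <- pmin(1, centre + half)
  }
  cbind(low = low, high = high)
}

#' Specialist proportions by body-mass quantile bin
#'
#' Bins the table into body-mass quantile bins, computes per-bin specialist
#' proportions with binomial confidence intervals, and flags bins whose
#' interval excludes the null expectation (by default the pooled specialist
#' proportion of the table itself; regional analyses pass their
#' realm-specific null).
#'
#' @param table A trait table.
#' @param n_bins Number of quantile bins.
#' @param null_proportion Null specialist proportion; defaults to the
#'   pooled proportion of `table`.
#' @param level Confidence level for the intervals.
#' @param method Interval method, see [binomial_ci()].
#' @param min_share Diet-presence threshold, see [count_diet_types()].
#' @return A data frame (one row per bin): `bin_index`, `q_low`, `q_high`,
#'   `n_species`, `n_specialists`, `proportion`, `ci_low`, `ci_high`,
#'   `null_proportion`, `deviation` (`"above"`, `"below"` or `"none"`).
#'   The CI method is recorded in `attr(, "ci_method")`.
#' @export
bin_specialist_proportions <- function(table, n_bins = 20,
                                       null_proportion = NULL, level = 0.95,
                                       method = c("clopper-pearson", "wilson"),
                                       min_share = 0) {
  method <- match.arg(method)
  spec <- classify_specialist(table, min_share) == "specialist"
  if (is.null(null_proportion)) null_proportion <- mean(spec)
  bins <- quantile_bins(table$body_mass_g, n_bins, table$species)
  n_k <- tapply(spec, bins, length)
  k_k <- tapply(spec, bins, sum)
  idx <- sort(unique(bins))
  ci <- binomial_ci(as.integer(k_k), as.integer(n_k), level, method)
  out <- data.frame(bin_index = idx,
                    q_low = (idx - 1) / n_bins,
                    q_high = idx / n_bins,
                    n_species = as.integer(n_k),
                    n_specialists = as.integer(k_k),
                    proportion = as.numeric(k_k / n_k),
                    ci_low = ci[, "low"],
                    ci_high = ci[, "high"],
                    null_proportion = null_proportion)
  out$deviation <- ifelse(null_proportion < out$ci_low, "above",
                          ifelse(null_proportion > out$ci_high, "below",
                                 "none"))
  attr(out, "ci_method") <- method
  attr(out, "level") <- level
  out
}

#' Subset a trait table to one zoogeographic realm
#'
#' @param table A trait table with `realm_*` occupancy columns.
#' @param realm One of [realm_labels].
#' @return The subset trait table (species occurring in the realm).
#' @export
subset_by_realm <- function(table, realm) {
  if (!realm %in% realm_labels)
    stop("unknown realm '", realm, "'; expected one of: ",
         paste(realm_labels, collapse = ", "), call. = FALSE)
  col <- paste0("realm_", tolower(realm))
  if (!col %in% names(table))
    stop("trait table lacks occupancy column ", col, call. = FALSE)
  table[table[[col]] != 0, , drop = FALSE]
}

#' Drop species confined to island realms
#'
#' For continental comparisons (e.g. among primary diet groups), species
#' occurring only in the island-dominated Oceanian and Madagascan realms
#' are excluded; species that also occur in a continental realm are kept.
#'
#' @param table A trait table with `realm_*` columns.
#' @return The filtered trait table.
#' @export
exclude_island_only <- function(table) {
  missing <- setdiff(realm_cols(), names(table))
  if (length(missing))
    stop("trait table lacks realm columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  continental <- setdiff(realm_labels, island_realms)
  occ <- as.matrix(table[paste0("realm_", tolower(continental))]) != 0
  table[rowSums(occ) > 0, , drop = FALSE]
}

#' One-sided two-sample Kolmogorov-Smirnov statistic
#'
#' `D = sup_t [F_x(t) - F_y(t)]` over the pooled sample points, for the
#' hypothesis that `x` is stochastically smaller than `y` (its empirical
#' CDF lies above). The p-value uses the one-sided asymptotic formula
#' `exp(-2 D^2 n m / (n + m))`.
#'
#' @param x Sample hypothesized stochastically smaller.
#' @param y Comparison sample.
#' @return A list with `D`, `p_value`, `n_x`, `n_y`.
#' @examples
#' ks_one_sided(c(1, 3), c(2, 4))$D  # 0.5
#' @export
ks_one_sided <- function(x, y) {
  if (!length(x) || !length(y))
    stop("both samples must be non-empty", call. = FALSE)
  pooled <- sort(unique(c(x, y)))
  D <- max(ecdf(x)(pooled) - ecdf(y)(pooled))
  D <- max(0, D)
  n <- length(x); m <- length(y)
  list(D = D, p_value = exp(-2 * D^2 * n * m / (n + m)),
       n_x = n, n_y = m)
}

#' Median-split body-size covariates
#'
#' Adds the covariates used by the phylogenetic regressions: log10 body
#' mass, the absolute difference from the median log10 mass, and a size
#' class assigning species smaller than *or equal to* the median to the
#' lower half (so ties go below).
#'
#' @param table A trait table.
#' @return The table with columns `log10_mass`, `abs_median_dev` and
#'   `size_class` (`"below_or_equal"` / `"above"`) appended; the median is
#'   stored in `attr(, "median_log10_mass")`.
#' @export
median_split_covariates <- function(table) {
  lm10 <- log10(table$body_mass_g)
  med <- median(lm10)
  table$log10_mass <- lm10
  table$abs_median_dev <- abs(lm10 - med)
  table$size_class <- ifelse(lm10 <= med, "below_or_equal", "above")
  attr(table, "median_log10_mass") <- med
  table
}
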