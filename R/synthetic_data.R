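#' Configuration for the synthetic trait-table generator
#'
#' Collects every knob of the generator in one validated list. Defaults
#' emulate the macroecological structure of the global terrestrial-mammal
#' trait dataset the pipeline is designed for: ~3,500 species, a
#' right-skewed log10 body-mass spectrum clipped to `[1.75, 3.9e6]` g
#' (seven orders of magnitude), ten diet categories with one to six
#' consumed per species, eleven zoogeographic realms, and phylogenetic
#' signal in log mass from Brownian motion on a Yule tree.
#'
#' The specialist probability follows a U-shaped curve in the mass quantile
#' `q`: `p(q) = p_mid + amplitude * (2q - 1)^2`, clipped to `[0, 1]`. With
#' the defaults `p_mid = 0.25`, `amplitude = 0.25` the pooled expectation
#' is `p_mid + amplitude/3 = 1/3`, matching the observed pooled specialist
#' proportion of about a third.
#'
#' @param n_species Number of species (>= 20).
#' @param seed Integer seed governing all stages via a single splitting
#'   scheme (stage sub-seeds are drawn once from this seed).
#' @param mass_location,mass_scale,mass_skew Skew-normal parameters of the
#'   log10 body-mass marginal (location, scale, shape; positive shape =
#'   right skew).
#' @param mass_range_g Two-element clip range for body mass in grams.
#' @param p_mid Specialist probability at the median mass quantile.
#' @param amplitude Height of the U: added specialist probability at the
#'   extreme quantiles relative to the middle.
#' @param diet_count_probs Probabilities of a generalist consuming
#'   2, 3, 4, 5 or 6 categories.
#' @param primary_weights Target overall composition of carnivore,
#'   herbivore and omnivore primary diets. Since an omnivore cannot have
#'   diet breadth 1, specialists draw carnivore/herbivore in the margin
#'   ratio and the generalist mixture is adjusted so the realized overall
#'   composition matches these weights in expectation.
#' @param realm_probs Named occupancy probability per realm (length 11);
#'   defaults loosely follow relative realm richness, with the Neotropical,
#'   Oriental and Afrotropical realms richest.
#' @param birth_rate Yule birth rate for the simulated tree.
#' @param signal_strength Phylogenetic-signal weight in `[0, 1]` for log
#'   mass: 1 = pure Brownian ranks, 0 = independent of the tree.
#' @param with_tree Simulate a tree and phylogenetically structured masses
#'   (`TRUE`), or draw masses i.i.d. (`FALSE`, faster; no tree returned).
#' @param n_orders Number of synthetic taxonomic-order labels.
#' @return A validated list of class `"synth_config"`.
#' @export
synth_config <- function(n_species = 3487, seed = 1,
                         mass_location = 0.9, mass_scale = 1.6,
                         mass_skew = 5,
                         mass_range_g = c(1.75, 3.9e6),
                         p_mid = 0.25, amplitude = 0.25,
                         diet_count_probs = c(0.35, 0.30, 0.20, 0.10, 0.05),
                         primary_weights = c(carnivore = 0.276,
                                             herbivore = 0.336,
                                             omnivore = 0.388),
                         realm_probs = NULL,
                         birth_rate = 1, signal_strength = 0.8,
                         with_tree = TRUE, n_orders = 6) {
  if (is.null(realm_probs)) {
    realm_probs <- c(Afrotropical = 0.20, Australian = 0.10,
                     Madagascan = 0.033, Nearctic = 0.12,
                     Neotropical = 0.23, Oceanian = 0.085,
                     Oriental = 0.22, Palearctic = 0.15,
                     Panamanian = 0.06, Saharo_Arabian = 0.05,
                     Sino_Japanese = 0.10)
  }
  stopifnot(n_species >= 20,
            length(mass_range_g) == 2, all(mass_range_g > 0),
            mass_range_g[1] < mass_range_g[2],
            p_mid >= 0, p_mid <= 1, amplitude >= 0,
            length(diet_count_probs) == 5, all(diet_count_probs >= 0),
            sum(diet_count_probs) > 0,
            length(primary_weights) == 3, all(primary_weights > 0),
            length(realm_probs) == 11,
            all(realm_probs > 0), all(realm_probs <= 1),
            birth_rate > 0,
            signal_strength >= 0, signal_strength <= 1,
            n_orders >= 1)
  if (is.null(names(realm_probs))) names(realm_probs) <- realm_labels
  structure(list(n_species = as.integer(n_species), seed = as.integer(seed),
                 mass_location = mass_location, mass_scale = mass_scale,
                 mass_skew = mass_skew, mass_range_g = mass_range_g,
                 p_mid = p_mid, amplitude = amplitude,
                 diet_count_probs = diet_count_probs / sum(diet_count_probs),
                 primary_weights = primary_weights / sum(primary_weights),
                 realm_probs = realm_probs,
                 birth_rate = birth_rate,
                 signal_strength = signal_strength,
                 with_tree = isTRUE(with_tree),
                 n_orders = as.integer(n_orders)),
            class = "synth_config")
}

# Azzalini skew-normal draws: delta*|u| + sqrt(1-delta^2)*v
rskewnorm <- function(n, location, scale, shape) {
  delta <- shape / sqrt(1 + shape^2)
  u <- abs(rnorm(n))
  v <- rnorm(n)
  location + scale * (delta * u + sqrt(1 - delta^2) * v)
}

#' Simulate a Yule (pure-birth) tree
#'
#' Ultrametric pure-birth tree with `n_tips` tips, reproducible under the
#' seed; a stand-in for a published species-level phylogeny.
#'
#' @param n_tips Number of tips (>= 2).
#' @param birth_rate Speciation rate.
#' @param seed Optional integer seed.
#' @return An `ape::phylo` tree with tip labels `species_0001`, ...
#' @export
simulate_tree <- function(n_tips, birth_rate = 1, seed = NULL) {
  stopifnot(n_tips >= 2, birth_rate > 0)
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rphylo(n_tips, birth = birth_rate, death = 0)
  tree$tip.label <- sprintf("species_%04d", seq_len(n_tips))
  tree
}

#' Simulate log10 body masses with phylogenetic signal
#'
#' Brownian motion on the tree is blended with independent noise according
#' to `signal_strength`, and the blend is rank-mapped (copula-style) onto a
#' right-skewed skew-normal marginal. Signal structure and marginal shape
#' are therefore controlled independently; the result is clipped to the
#' configured mass range.
#'
#' @param tree An `ape::phylo` tree.
#' @param signal_strength Weight in `[0, 1]`: 1 keeps pure Brownian ranks,
#'   0 yields masses independent of the tree.
#' @param location,scale,shape Skew-normal parameters of the log10-mass
#'   marginal.
#' @param range_g Two-element clip range in grams.
#' @param seed Optional integer seed.
#' @return Named numeric vector of log10 masses (names = tip labels).
#' @export
simulate_log_mass <- function(tree, signal_strength = 0.8,
                              location = 0.9, scale = 1.6, shape = 5,
                              range_g = c(1.75, 3.9e6), seed = NULL) {
  stopifnot(inherits(tree, "phylo"),
            signal_strength >= 0, signal_strength <= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- length(tree$tip.label)
  bm <- ape::rTraitCont(tree, model = "BM", sigma = 1)
  z <- if (signal_strength > 0) {
    bm_std <- (bm - mean(bm)) / sd(bm)
    sqrt(signal_strength) * bm_std + sqrt(1 - signal_strength) * rnorm(n)
  } else {
    rnorm(n)
  }
  marginal <- sort(rskewnorm(n, location, scale, shape))
  marginal <- pmin(pmax(marginal, log10(range_g[1])), log10(range_g[2]))
  out <- marginal[rank(z, ties.method = "first")]
  names(out) <- tree$tip.label
  out
}

# positive integer composition of 100 across n_cat categories
random_shares <- function(n_cat) {
  if (n_cat == 1) return(100L)
  w <- rgamma(n_cat, shape = 1) + 1e-9
  as.integer(rmultinom(1, 100 - n_cat, w)) + 1L
}

#' Assign diet-category consumption shares
#'
#' Each species is first drawn specialist or generalist with probability
#' `p(q)` of its mass quantile (the configured U-shaped curve), then
#' assigned a primary diet (carnivore/herbivore for specialists;
#' carnivore/herbivore/omnivore for generalists) and consumption shares:
#' specialists put 100% in one category; generalists spread a positive
#' integer composition of 100 over 2-6 categories, with omnivores forced
#' to straddle the animal/plant divide.
#'
#' @param log_masses Numeric vector of log10 body masses.
#' @param config A `"synth_config"`.
#' @param seed Optional integer seed.
#' @return A list: `diet` (matrix, species x 10 categories),
#'   `specialist` (logical), `primary` (character),
#'   `p_specialist` (the per-species probability used).
#' @export
assign_diets <- function(log_masses, config = synth_config(), seed = NULL) {
  stopifnot(inherits(config, "synth_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- length(log_masses)
  q <- (rank(log_masses, ties.method = "first") - 0.5) / n
  p_spec <- pmin(1, pmax(0, config$p_mid + config$amplitude * (2 * q - 1)^2))
  specialist <- runif(n) < p_spec

  # primary_weights are overall margins. Specialists cannot be omnivores,
  # so specialists draw carnivore/herbivore in the margin ratio and the
  # generalist mixture is solved so the realized composition still matches
  # the configured margins in expectation.
  w <- config$primary_weights
  e_spec <- mean(p_spec)
  w_spec <- w[c("carnivore", "herbivore")] /
    sum(w[c("carnivore", "herbivore")])
  gen_target <- pmax(0, w - e_spec * c(w_spec, omnivore = 0)[names(w)])
  gen_w <- gen_target / sum(gen_target)
  primary <- character(n)
  primary[specialist] <- sample(names(w_spec), sum(specialist),
                                replace = TRUE, prob = w_spec)
  primary[!specialist] <- sample(names(w), sum(!specialist),
                                 replace = TRUE, prob = gen_w)

  diet <- matrix(0L, n, length(diet_categories),
                 dimnames = list(NULL, diet_categories))
  counts <- integer(n)
  counts[specialist] <- 1L
  counts[!specialist] <- sample(2:6, sum(!specialist), replace = TRUE,
                                prob = config$diet_count_probs)
  for (i in seq_len(n)) {
    k <- counts[i]
    cats <- switch(primary[i],
      carnivore = sample(animal_diet_categories,
                         min(k, length(animal_diet_categories))),
      herbivore = sample(plant_diet_categories,
                         min(k, length(plant_diet_categories))),
      omnivore = {
        # at least one category from each side of the divide
        k_animal <- sample(seq_len(k - 1), 1)
        c(sample(animal_diet_categories, min(k_animal,
                                             length(animal_diet_categories))),
          sample(plant_diet_categories, min(k - k_animal,
                                            length(plant_diet_categories))))
      })
    diet[i, cats] <- random_shares(length(cats))
  }
  list(diet = diet, specialist = specialist, primary = primary,
       p_specialist = p_spec)
}

#' Assign realm occupancy flags
#'
#' Independent Bernoulli occupancy per realm; species drawing no realm at
#' all are resampled until they occupy at least one.
#'
#' @param n_species Number of species.
#' @param realm_probs Named occupancy probability per realm (length 11).
#' @param seed Optional integer seed.
#' @return Logical matrix (species x 11 realms).
#' @export
assign_realms <- function(n_species, realm_probs, seed = NULL) {
  stopifnot(length(realm_probs) == 11)
  if (is.null(names(realm_probs))) names(realm_probs) <- realm_labels
  if (!is.null(seed)) set.seed(seed)
  draw <- function(m) {
    matrix(runif(m * 11) < rep(realm_probs, each = m), m, 11,
           dimnames = list(NULL, names(realm_probs)))
  }
  occ <- draw(n_species)
  empty <- which(rowSums(occ) == 0)
  while (length(empty)) {
    occ[empty, ] <- draw(length(empty))
    empty <- empty[rowSums(occ[empty, , drop = FALSE]) == 0]
  }
  occ
}

#' Generate a complete synthetic trait table
#'
#' Runs the full generator: Yule tree, phylogenetically structured skewed
#' log masses, U-shaped specialist assignment with diet shares, realm
#' occupancy and synthetic order labels. All stages derive their seeds
#' from `config$seed` through a single splitting scheme, so a given
#' configuration is fully reproducible.
#'
#' @param config A `"synth_config"`.
#' @return A list with `traits` (a validated trait table), `tree` (an
#'   `ape::phylo`, or NULL when `with_tree = FALSE`) and `truth` (the
#'   ground-truth generator state: config, specialist flags, per-species
#'   specialist probabilities, primary diets).
#' @examples
#' synth <- generate_trait_table(synth_config(n_species = 100, seed = 1,
#'                                            with_tree = FALSE))
#' head(synth$traits)
#' @export
generate_trait_table <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  stage_seeds <- sample.int(.Machine$integer.max - 1, 5)
  n <- config$n_species

  if (config$with_tree) {
    tree <- simulate_tree(n, config$birth_rate, stage_seeds[1])
    log_mass <- simulate_log_mass(tree, config$signal_strength,
                                  config$mass_location, config$mass_scale,
                                  config$mass_skew, config$mass_range_g,
                                  stage_seeds[2])
    species <- tree$tip.label
  } else {
    tree <- NULL
    set.seed(stage_seeds[2])
    log_mass <- sort(rskewnorm(n, config$mass_location, config$mass_scale,
                               config$mass_skew))
    log_mass <- pmin(pmax(log_mass, log10(config$mass_range_g[1])),
                     log10(config$mass_range_g[2]))
    log_mass <- sample(log_mass)  # random species order
    species <- sprintf("species_%04d", seq_len(n))
    names(log_mass) <- species
  }

  diets <- assign_diets(log_mass, config, stage_seeds[3])
  realms <- assign_realms(n, config$realm_probs, stage_seeds[4])
  set.seed(stage_seeds[5])
  orders <- paste0("order_", sample.int(config$n_orders, n, replace = TRUE,
                                        prob = config$n_orders:1))

  traits <- data.frame(species = species,
                       body_mass_g = 10^log_mass,
                       diets$diet, check.names = FALSE)
  names(traits)[match(diet_categories, names(traits))] <- diet_cols()
  realm_df <- as.data.frame(realms * 1L)
  names(realm_df) <- realm_cols()
  traits <- cbind(traits, realm_df, order = orders)
  traits <- validate_trait_table(traits)

  list(traits = traits, tree = tree,
       truth = list(config = unclass(config),
                    specialist = diets$specialist,
                    p_specialist = diets$p_specialist,
                    primary = diets$primary))
}

#' Write a synthetic dataset to disk
#'
#' Writes `traits.csv`, `tree.nwk` (if a tree was simulated) and
#' `truth.json` into `out_dir`.
#'
#' @param synth Output of [generate_trait_table()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_synthetic <- function(synth, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(synth$traits, file.path(out_dir, "traits.csv"),
                   row.names = FALSE)
  if (!is.null(synth$tree))
    ape::write.tree(synth$tree, file.path(out_dir, "tree.nwk"))
  jsonlite::write_json(synth$truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
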