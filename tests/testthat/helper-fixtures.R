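# Shared fixtures: tiny trait tables and random parameter draws.

# suppresses the advisory warning for masses below the empirical range
default_params <- function(b = 100, ...)
  suppressWarnings(model_params(b = b, ...))

# a minimal hand-built trait table with known composition
tiny_trait_table <- function() {
  diet <- matrix(0, 6, 10,
                 dimnames = list(NULL, paste0("diet_", diet_categories)))
  diet[1, "diet_inv"] <- 100                      # carnivore specialist
  diet[2, c("diet_fruit", "diet_seed")] <- c(60, 40)   # herbivore generalist
  diet[3, c("diet_inv", "diet_fruit")] <- c(50, 50)    # omnivore
  diet[4, "diet_scav"] <- 100                     # carnivore specialist
  diet[5, "diet_planto"] <- 100                   # herbivore specialist
  diet[6, c("diet_vend", "diet_vect", "diet_vfish")] <- c(30, 30, 40)
  realms <- matrix(0L, 6, 11,
                   dimnames = list(NULL, paste0("realm_",
                                                tolower(realm_labels))))
  realms[, "realm_neotropical"] <- c(1L, 1L, 0L, 0L, 1L, 0L)
  realms[, "realm_oceanian"] <- c(0L, 0L, 1L, 0L, 0L, 0L)
  realms[, "realm_palearctic"] <- c(0L, 0L, 0L, 1L, 0L, 1L)
  tbl <- data.frame(species = paste0("sp_", 1:6),
                    body_mass_g = c(10, 200, 5000, 35, 1.2e5, 900),
                    diet, realms, order = rep(c("o1", "o2"), 3))
  validate_trait_table(tbl)
}

# random valid parameter draw used by property tests
random_params <- function() {
  k2 <- runif(1, 0.3, 0.8)
  model_params(b = 10^runif(1, 0.3, 6.5),
               k1 = k2 + runif(1, 0.05, 0.4), k2 = k2,
               alpha = runif(1, 0.05, 0.8),
               g = runif(1, 0.5, 2),
               kappa = runif(1, 10, 200),
               beta = runif(1, 0.1, 0.5),
               gamma = runif(1, 10, 300),
               R1 = runif(1, 0.5, 2), R2 = runif(1, 0.1, 1))
}
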