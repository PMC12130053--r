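# Shared fixtures and independent oracles for the test suite.

# Random partition instance: community size N, positive monoculture yields,
# non-negative observed yields.
random_partition_instance <- function(N = sample(2:8, 1)) {
  list(
    M = exp(rnorm(N, mean = 2, sd = 1)),
    Y = exp(rnorm(N, mean = 1.5, sd = 1)) * rbinom(N, 1, 0.98)
  )
}

# Brute-force term-by-term oracle for the partition: accumulates
# sum_i dRY_i * Mbar (complementarity) and sum_i dRY_i * (M_i - Mbar)
# (selection) in an explicit loop, independently of the closed formulas.
oracle_partition <- function(Y, M) {
  N <- length(M)
  ry <- Y / M
  dry <- ry - 1 / N
  Mbar <- mean(M)
  ce <- 0
  se <- 0
  for (i in seq_len(N)) {
    ce <- ce + dry[i] * Mbar
    se <- se + dry[i] * (M[i] - Mbar)
  }
  list(ce = ce, se = se, nbe = sum(Y) - sum(M) / N)
}

# Hand-derived closed form for a 2-species mixture under the generator's
# yield model at cv = 0: ranks give standardized scores -1 and +1 (for
# mu1 < mu2), dominance weights w_i = 2 exp(s z_i) / (exp(-s) + exp(s)),
# relative yields RY_i = gamma w_i / 2, hence
#   CE = (gamma - 1) * mean(M)
#   SE = gamma * [ (w1 - 1)(M1 - Mbar) + (w2 - 1)(M2 - Mbar) ] / 2
closed_form_2sp <- function(M, gamma, skew) {
  stopifnot(length(M) == 2, M[1] != M[2])
  z <- if (M[1] < M[2]) c(-1, 1) else c(1, -1)
  w <- exp(skew * z)
  w <- 2 * w / sum(w)
  Mbar <- mean(M)
  list(
    ce = (gamma - 1) * Mbar,
    se = gamma * ((w[1] - 1) * (M[1] - Mbar) +
                    (w[2] - 1) * (M[2] - Mbar)) / 2
  )
}

# Minimal individual-level fixture: one pot, explicit numbers.
make_individuals <- function(pot_id, species, shoot, root,
                             height = 30, leaf_area = 400, leaf_mass = 30,
                             root_length = 800) {
  n <- length(species)
  tibble::tibble(
    pot_id = rep(pot_id, n), species = species,
    height_cm = rep_len(height, n),
    leaf_area_mm2 = rep_len(leaf_area, n),
    leaf_dry_mass_mg = rep_len(leaf_mass, n),
    root_length_cm = rep_len(root_length, n),
    root_dry_mass_g = root, shoot_dry_mass_g = shoot
  )
}

# A small two-species experiment built without the balanced sampler:
# monocultures of S1 and S2 plus the S1+S2 mixture, optionally replicated.
two_species_design <- function(replicates = 1L,
                               treatments = treatment_table()) {
  design_from_compositions(list("S1", "S2", c("S1", "S2")),
                           treatments = treatments,
                           replicates = replicates)
}

two_species_generator <- function(mu = c(10, 20), gamma2 = 1.2, skew = 0,
                                  cv = 0, seed = 1L, ...) {
  generator_config(
    design = design_config(species_pool = c("S1", "S2"),
                           richness_levels = c(1L, 2L),
                           replicates_per_cell = 1L, seed = seed),
    mu = mu,
    gamma = c("1" = 1, "2" = gamma2),
    skew = skew, cv = cv, seed = seed, ...
  )
}
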