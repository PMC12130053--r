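# Synthetic experiments with known ground truth.
#
# Species-level pot yield model:
#   Y_i = (1/N) * mu_i * d^drought * b^biochar * gamma(N) * w_i(s) * eps_i
# with lognormal noise eps_i (mean 1, coefficient of variation cv) and
# dominance weights w_i(s) proportional to exp(s * z_i), z_i the
# standardized rank of mu_i within the community, normalized to mean 1.
# Monocultures use N = 1, gamma = 1, w = 1, so the noiseless monoculture
# yield is mu_i * d^drought * b^biochar — exactly the baseline the
# partition estimates.

#' Default species-level trait parameters
#'
#' Baseline trait values for a species pool: plant height, leaf area, SLA
#' (from which leaf dry mass derives), SRL (from which root length derives)
#' and RSR. Magnitudes are typical of small herbaceous greenhouse plants.
#'
#' @param species Character vector of species labels.
#' @return A tibble with one row per species.
#' @export
default_species_params <- function(species = paste0("S", 1:5)) {
  k <- length(species)
  tibble::tibble(
    species = as.character(species),
    height_cm = seq(20, 45, length.out = k),
    leaf_area_mm2 = seq(300, 900, length.out = k),
    sla_mm2_mg = seq(10, 20, length.out = k),
    srl_cm_g = seq(1500, 3000, length.out = k),
    rsr = seq(0.4, 0.7, length.out = k)
  )
}

#' Configure the synthetic-experiment generator
#'
#' All biological structure of the simulated experiment lives here: the
#' per-species monoculture biomass baselines `mu` (g per pot), the
#' multiplicative drought and biochar treatment effects, the per-richness
#' complementarity boost `gamma` (gamma(1) must be 1), the dominance skew
#' `skew` that biases mixture yields toward high-`mu` (skew > 0) or
#' low-`mu` (skew < 0) species and thereby sets the selection effect's
#' sign, and the lognormal noise coefficient of variation `cv`.
#'
#' Defaults describe a drought that removes ~30% of biomass, a biochar
#' amendment adding ~30%, modest overyielding growing with richness, and a
#' negative dominance skew (subordinate, low-yield species overperform in
#' mixture), so that complementarity effects are positive and selection
#' effects negative.
#'
#' @param design A [design_config()].
#' @param mu Named or positional numeric vector of per-species monoculture
#'   biomass baselines (g per pot, > 0), one per pool species.
#' @param drought_mult Multiplicative drought effect on yield, in (0, 1].
#' @param biochar_mult Multiplicative biochar effect on yield, >= 1.
#' @param gamma Named numeric vector of per-richness complementarity
#'   multipliers on per-capita yield; must cover every richness level and
#'   satisfy `gamma["1"] == 1`.
#' @param skew Dominance skew s (real; 0 means no selection structure).
#' @param cv Coefficient of variation of the multiplicative lognormal
#'   noise (>= 0; 0 gives a noiseless experiment).
#' @param species_params Trait baselines, see [default_species_params()].
#' @param rsr_drought_mult Multiplier applied to RSR under drought (>= 1;
#'   plants shift allocation belowground when water is short).
#' @param height_drought_mult,height_biochar_mult Multiplicative treatment
#'   effects on plant height.
#' @param seed Integer seed.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(design = design_config(),
                             mu = c(4, 6, 8, 10, 12),
                             drought_mult = 0.7,
                             biochar_mult = 1.3,
                             gamma = c("1" = 1, "2" = 1.15, "4" = 1.3),
                             skew = -0.5,
                             cv = 0.15,
                             species_params =
                               default_species_params(design$species_pool),
                             rsr_drought_mult = 1.4,
                             height_drought_mult = 0.85,
                             height_biochar_mult = 1.1,
                             seed = 1L) {
  stopifnot(inherits(design, "design_config"))
  if (length(mu) != length(design$species_pool)) {
    abort_befpart("`mu` needs one baseline per pool species.",
                  "befpart_config_error")
  }
  mu <- stats::setNames(as.numeric(mu), design$species_pool)
  check_positive(mu, "mu")
  if (!(drought_mult > 0 && drought_mult <= 1)) {
    abort_befpart("`drought_mult` must lie in (0, 1].", "befpart_config_error")
  }
  if (biochar_mult < 1) {
    abort_befpart("`biochar_mult` must be >= 1.", "befpart_config_error")
  }
  if (cv < 0) {
    abort_befpart("`cv` must be >= 0.", "befpart_config_error")
  }
  need <- as.character(design$richness_levels)
  if (!all(need %in% names(gamma))) {
    abort_befpart("`gamma` must name every richness level.",
                  "befpart_config_error")
  }
  if (any(gamma <= 0)) {
    abort_befpart("`gamma` values must be positive.", "befpart_config_error")
  }
  if ("1" %in% names(gamma) && abs(gamma[["1"]] - 1) > 1e-12) {
    abort_befpart("`gamma` for richness 1 must equal 1.",
                  "befpart_config_error")
  }
  if (!all(design$species_pool %in% species_params$species)) {
    abort_befpart("`species_params` must cover every pool species.",
                  "befpart_config_error")
  }
  structure(
    list(design = design, mu = mu, drought_mult = drought_mult,
         biochar_mult = biochar_mult, gamma = gamma, skew = skew, cv = cv,
         species_params = species_params,
         rsr_drought_mult = rsr_drought_mult,
         height_drought_mult = height_drought_mult,
         height_biochar_mult = height_biochar_mult,
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

# Dominance weights within one community: proportional to exp(s * z) with z
# the standardized (population sd) rank of mu, normalized to mean 1. All-equal
# mu gives w = 1 for every species.
dominance_weights <- function(mu_members, skew) {
  n <- length(mu_members)
  r <- rank(mu_members, ties.method = "average")
  s_r <- sqrt(mean((r - mean(r))^2))
  z <- if (s_r > 0) (r - mean(r)) / s_r else rep(0, n)
  w <- exp(skew * z)
  w / mean(w)
}

# Lognormal multipliers with mean 1 and the requested coefficient of
# variation; cv = 0 returns exact ones.
lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# Noiseless species-level expected yields for every pot in a design, plus
# the true monoculture baseline M of each species under each pot's
# treatment. Shared by the generator (x noise) and the ground-truth pass.
expected_yields <- function(design, config) {
  members <- split_species(design$species_list)
  n_sp <- lengths(members)
  pot_id <- rep(design$pot_id, n_sp)
  species <- unlist(members, use.names = FALSE)
  trt <- rep(config$drought_mult^design$drought *
               config$biochar_mult^design$biochar, n_sp)
  mu <- unname(config$mu[species])
  M_true <- mu * trt
  richness <- rep(design$richness, n_sp)

  w <- unlist(lapply(members, function(sp) {
    if (length(sp) == 1L) 1 else dominance_weights(config$mu[sp], config$skew)
  }), use.names = FALSE)
  g <- ifelse(richness == 1L, 1,
              unname(config$gamma[as.character(richness)]))
  y <- ifelse(richness == 1L, M_true, M_true * g * w / richness)

  tibble::new_tibble(list(pot_id = pot_id, species = species,
                          y_expected_g = y, M_true_g = M_true),
                     nrow = length(pot_id))
}

# Ground truth: partition every mixture pot of the noiseless experiment
# against the true monoculture baselines (self-oracle; a hand-derived
# closed form for the 2-species case backs this in the test suite).
synthetic_truth <- function(design, config) {
  ey <- expected_yields(design, config)
  mixtures <- design[design$richness >= 2L, ]
  ey_by_pot <- split(ey[, c("y_expected_g", "M_true_g")], ey$pot_id)
  n_mix <- nrow(mixtures)
  nbe <- ce <- se <- numeric(n_mix)
  for (i in seq_len(n_mix)) {
    sub <- ey_by_pot[[mixtures$pot_id[i]]]
    part <- partition_mixture(sub$y_expected_g, sub$M_true_g)
    nbe[i] <- part$nbe
    ce[i] <- part$ce
    se[i] <- part$se
  }
  pots <- tibble::new_tibble(list(
    pot_id = mixtures$pot_id, richness = mixtures$richness,
    drought = mixtures$drought, biochar = mixtures$biochar,
    treatment = mixtures$treatment,
    nbe_true_g = nbe, ce_true_g = ce, se_true_g = se
  ), nrow = n_mix)
  cells <- pots |>
    dplyr::group_by(.data$richness, .data$drought, .data$biochar,
                    .data$treatment) |>
    dplyr::summarise(nbe_true_g = mean(.data$nbe_true_g),
                     ce_true_g = mean(.data$ce_true_g),
                     se_true_g = mean(.data$se_true_g),
                     .groups = "drop")
  list(pots = pots, cells = cells,
       params = list(mu = as.list(config$mu),
                     drought_mult = config$drought_mult,
                     biochar_mult = config$biochar_mult,
                     gamma = as.list(config$gamma),
                     skew = config$skew, cv = config$cv,
                     seed = config$seed))
}

# Seedling allocation: individuals split as evenly as possible among the
# community's species (4 seedlings -> 4/2/1 per species at richness 1/2/4),
# earlier species (sorted order) taking any remainder.
allocate_individuals <- function(n_individuals, members) {
  N <- length(members)
  base <- n_individuals %/% N
  extra <- n_individuals %% N
  counts <- rep(base, N) + as.integer(seq_len(N) <= extra)
  counts[counts == 0L] <- 1L   # never plant zero of a listed member
  rep(members, counts)
}

#' Generate a synthetic experiment
#'
#' Simulates an individual-level measurement table for every pot of a
#' design under the yield model described in [generator_config()], and
#' returns the generator's ground truth (per-mixture and per-cell true
#' NBE/CE/SE at cv = 0) for recovery testing. A pot's species-level yield
#' is split evenly among that species' seedlings; shoot and root dry mass
#' derive from the species RSR (inflated under drought), and leaf and root
#' morphometrics from the species trait baselines with multiplicative
#' lognormal noise. Output is deterministic given the config seed.
#'
#' @param config A [generator_config()].
#' @param design Optional pre-built design tibble; by default the design is
#'   enumerated from `config$design`.
#' @return A list with `individuals` (one row per seedling, in the raw
#'   measurement schema of [compute_traits()]), `design`, and `truth`
#'   (`$pots`, `$cells`, `$params`).
#' @examples
#' sim <- generate_experiment(generator_config(seed = 11))
#' nrow(sim$design)   # 60 pots
#' @export
generate_experiment <- function(config, design = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (is.null(design)) design <- enumerate_design(config$design)
  truth <- synthetic_truth(design, config)

  withr::local_seed(config$seed)
  ey <- expected_yields(design, config)
  ey$y_g <- ey$y_expected_g * lognormal_noise(nrow(ey), config$cv)

  members <- split_species(design$species_list)
  planted <- lapply(members, function(m)
    allocate_individuals(config$design$individuals_per_pot, m))
  k <- lengths(planted)
  pot_id <- rep(design$pot_id, k)
  drought <- rep(design$drought, k)
  biochar <- rep(design$biochar, k)
  species <- unlist(planted, use.names = FALSE)
  # seedlings of the same species in a pot share its yield evenly
  n_conspecifics <- unlist(lapply(planted, function(p) {
    tab <- table(p)
    as.numeric(tab[p])
  }), use.names = FALSE)

  y_sp <- ey$y_g[match(paste(pot_id, species),
                       paste(ey$pot_id, ey$species))]
  total <- y_sp / n_conspecifics

  par <- config$species_params[match(species, config$species_params$species), ]
  m <- length(pot_id)
  rsr_eff <- par$rsr * config$rsr_drought_mult^drought *
    lognormal_noise(m, config$cv)
  shoot <- total / (1 + rsr_eff)
  root <- total - shoot
  height <- par$height_cm * config$height_drought_mult^drought *
    config$height_biochar_mult^biochar * lognormal_noise(m, config$cv)
  leaf_area <- par$leaf_area_mm2 * lognormal_noise(m, config$cv)
  leaf_mass <- leaf_area / (par$sla_mm2_mg * lognormal_noise(m, config$cv))
  root_len <- root * par$srl_cm_g * lognormal_noise(m, config$cv)

  individuals <- tibble::tibble(
    pot_id = pot_id, species = species,
    height_cm = height,
    leaf_area_mm2 = leaf_area,
    leaf_dry_mass_mg = leaf_mass,
    root_length_cm = root_len,
    root_dry_mass_g = root,
    shoot_dry_mass_g = shoot
  )

  list(individuals = individuals, design = design, truth = truth)
}

#' Compare partition estimates against the generator's ground truth
#'
#' Groups partition results by richness x treatment cell, and reports the
#' mean estimated NBE/CE/SE with its Monte-Carlo standard error
#' (sd / sqrt(n)) and the bias against the generator's true values. Cells
#' whose absolute bias exceeds `3 * MCSE` for any effect are flagged.
#'
#' @param truth The `truth` element returned by [generate_experiment()]
#'   (or a compatible `$cells` tibble).
#' @param results The `results` tibble from [partition_dataset()].
#' @return A tibble with one row per cell x effect: `n`, `estimate_mean`,
#'   `mcse`, `truth`, `bias`, `flagged`.
#' @export
recovery_report <- function(truth, results) {
  cells <- if (is.list(truth) && !is.null(truth$cells)) truth$cells else truth
  est <- results |>
    tidyr::pivot_longer(cols = c("nbe_g", "ce_g", "se_g"),
                        names_to = "effect", values_to = "value") |>
    dplyr::mutate(effect = sub("_g$", "", .data$effect)) |>
    dplyr::group_by(.data$richness, .data$drought, .data$biochar,
                    .data$effect) |>
    dplyr::summarise(
      n = dplyr::n(),
      estimate_mean = mean(.data$value),
      mcse = if (dplyr::n() > 1L) sd(.data$value) / sqrt(dplyr::n()) else 0,
      .groups = "drop"
    )
  tru <- cells |>
    tidyr::pivot_longer(cols = c("nbe_true_g", "ce_true_g", "se_true_g"),
                        names_to = "effect", values_to = "truth") |>
    dplyr::mutate(effect = sub("_true_g$", "", .data$effect)) |>
    dplyr::select("richness", "drought", "biochar", "effect", "truth")
  out <- dplyr::inner_join(est, tru,
                           by = c("richness", "drought", "biochar", "effect"))
  if (nrow(out) == 0L) {
    abort_befpart("Truth and estimates share no richness x treatment cells.",
                  "befpart_pairing_error")
  }
  out |>
    dplyr::mutate(bias = .data$estimate_mean - .data$truth,
                  flagged = abs(.data$bias) > 3 * .data$mcse)
}
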