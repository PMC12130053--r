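# Synthetic-experiment generator and ground-truth recovery.

test_that("the reference configuration simulates all 60 pots, 4 seedlings each", {
  sim <- suppressMessages(generate_experiment(generator_config(seed = 2)))
  expect_equal(nrow(sim$design), 60L)
  expect_equal(length(unique(sim$individuals$pot_id)), 60L)
  expect_equal(nrow(sim$individuals), 240L)
  counts <- table(sim$individuals$pot_id)
  expect_true(all(counts == 4L))
})

test_that("identical seeds reproduce identical tables, different seeds differ", {
  a <- suppressMessages(generate_experiment(generator_config(seed = 5)))
  b <- suppressMessages(generate_experiment(generator_config(seed = 5)))
  expect_identical(a$individuals, b$individuals)
  expect_identical(a$truth$cells, b$truth$cells)
  c_ <- suppressMessages(generate_experiment(generator_config(seed = 6)))
  expect_false(identical(a$individuals, c_$individuals))
})

test_that("the null model (no overyielding, no skew, no noise) gives zero effects", {
  cfg <- generator_config(gamma = c("1" = 1, "2" = 1, "4" = 1), skew = 0,
                          cv = 0, seed = 3)
  sim <- suppressMessages(generate_experiment(cfg))
  agg <- aggregate_pots(sim$individuals, sim$design)
  part <- suppressMessages(partition_dataset(agg, sim$design))
  expect_equal(nrow(part$results), 40L)
  expect_equal(max(abs(part$results$nbe_g)), 0, tolerance = 1e-10)
  expect_equal(max(abs(part$results$ce_g)), 0, tolerance = 1e-10)
  expect_equal(max(abs(part$results$se_g)), 0, tolerance = 1e-10)
  expect_equal(max(abs(sim$truth$pots$nbe_true_g)), 0, tolerance = 1e-12)
})

test_that("injected overyielding is recovered exactly without noise", {
  # gamma(2) = 1.2 on mu = (10, 20): dRY = 0.1 each, CE = 2 * 0.1 * 15 = 3.
  cfg <- two_species_generator(mu = c(10, 20), gamma2 = 1.2, skew = 0, cv = 0)
  design <- two_species_design()
  sim <- suppressMessages(generate_experiment(cfg, design = design))
  agg <- aggregate_pots(sim$individuals, sim$design)
  part <- suppressMessages(partition_dataset(agg, sim$design))
  ctrl <- part$results[part$results$drought == 0 & part$results$biochar == 0, ]
  expect_equal(ctrl$ce_g, 3.0, tolerance = 1e-12)
  expect_equal(ctrl$se_g, 0.0, tolerance = 1e-12)
  expect_equal(ctrl$nbe_g, 3.0, tolerance = 1e-12)
})

test_that("noiseless estimates equal the exported truth for every mixture", {
  cfg <- generator_config(cv = 0, seed = 17)
  sim <- suppressMessages(generate_experiment(cfg))
  agg <- aggregate_pots(sim$individuals, sim$design)
  part <- suppressMessages(partition_dataset(agg, sim$design))
  merged <- dplyr::inner_join(part$results, sim$truth$pots,
                              by = "pot_id", suffix = c("", ".t"))
  expect_equal(nrow(merged), 40L)
  expect_lte(max(abs(merged$nbe_g - merged$nbe_true_g)), 1e-9)
  expect_lte(max(abs(merged$ce_g - merged$ce_true_g)), 1e-9)
  expect_lte(max(abs(merged$se_g - merged$se_true_g)), 1e-9)
})

test_that("generator truth matches the hand-derived two-species closed form", {
  for (skew in c(-0.8, 0, 0.6)) {
    cfg <- two_species_generator(mu = c(10, 20), gamma2 = 1.25, skew = skew)
    design <- two_species_design(treatments = treatment_table()[1, ])
    sim <- suppressMessages(generate_experiment(cfg, design = design))
    hand <- closed_form_2sp(c(10, 20), gamma = 1.25, skew = skew)
    expect_equal(sim$truth$pots$ce_true_g, hand$ce, tolerance = 1e-12)
    expect_equal(sim$truth$pots$se_true_g, hand$se, tolerance = 1e-12)
  }
})

test_that("truth invariants: no skew means no selection, null model means no NBE", {
  cfg <- generator_config(skew = 0, seed = 4)
  sim <- suppressMessages(generate_experiment(cfg))
  expect_equal(max(abs(sim$truth$pots$se_true_g)), 0, tolerance = 1e-12)
  expect_true(all(sim$truth$pots$ce_true_g > 0))
})

test_that("treatment multipliers act in the configured directions", {
  cfg <- generator_config(cv = 0, seed = 8)
  sim <- suppressMessages(generate_experiment(cfg))
  agg <- aggregate_pots(sim$individuals, sim$design)
  pots <- agg$pots
  key <- paste(pots$richness, pots$replicate)
  ctrl <- pots[pots$drought == 0 & pots$biochar == 0, ]
  drt <- pots[pots$drought == 1 & pots$biochar == 0, ]
  bio <- pots[pots$drought == 0 & pots$biochar == 1, ]
  ctrl_b <- ctrl$pot_biomass_g[order(paste(ctrl$richness, ctrl$replicate))]
  expect_true(all(drt$pot_biomass_g[order(paste(drt$richness, drt$replicate))] <
                    ctrl_b))
  expect_true(all(bio$pot_biomass_g[order(paste(bio$richness, bio$replicate))] >
                    ctrl_b))
})

test_that("drought inflates the root-to-shoot ratio", {
  cfg <- generator_config(cv = 0, seed = 9)
  sim <- suppressMessages(generate_experiment(cfg))
  traits <- compute_traits(sim$individuals)
  design <- sim$design
  drought_pots <- design$pot_id[design$drought == 1 & design$biochar == 0]
  control_pots <- design$pot_id[design$drought == 0 & design$biochar == 0]
  rsr_d <- mean(traits$rsr[traits$pot_id %in% drought_pots])
  rsr_c <- mean(traits$rsr[traits$pot_id %in% control_pots])
  expect_equal(rsr_d / rsr_c, 1.4, tolerance = 1e-6)
})

test_that("recovery at cv = 0 is bias-free and unflagged", {
  cfg <- generator_config(cv = 0, seed = 12)
  sim <- suppressMessages(generate_experiment(cfg))
  agg <- aggregate_pots(sim$individuals, sim$design)
  part <- suppressMessages(partition_dataset(agg, sim$design))
  rec <- recovery_report(sim$truth, part$results)
  expect_equal(nrow(rec), 8L * 3L)   # 2 mixture levels x 4 treatments x 3 effects
  expect_lte(max(abs(rec$bias)), 1e-9)
  expect_false(any(rec$flagged))
})

test_that("noisy recovery stays within Monte-Carlo error of the truth", {
  cfg <- two_species_generator(mu = c(10, 20), gamma2 = 1.2, skew = 0,
                               cv = 0.1, seed = 7)
  design <- two_species_design(replicates = 50,
                               treatments = treatment_table()[1, ])
  sim <- suppressMessages(generate_experiment(cfg, design = design))
  agg <- aggregate_pots(sim$individuals, sim$design)
  part <- suppressMessages(partition_dataset(agg, sim$design))
  rec <- recovery_report(sim$truth, part$results)
  ce <- rec[rec$effect == "ce", ]
  expect_equal(ce$truth, 3.0, tolerance = 1e-12)
  expect_lte(abs(ce$bias), 3 * ce$mcse)
})

test_that("mismatched truth and estimates raise a pairing error", {
  cfg <- generator_config(seed = 13)
  sim <- suppressMessages(generate_experiment(cfg))
  agg <- aggregate_pots(sim$individuals, sim$design)
  part <- suppressMessages(partition_dataset(agg, sim$design))
  res <- part$results
  res$richness <- res$richness + 100L
  expect_error(recovery_report(sim$truth, res),
               class = "befpart_pairing_error")
})

test_that("invalid generator configurations are rejected", {
  expect_error(generator_config(drought_mult = 1.2),
               class = "befpart_config_error")
  expect_error(generator_config(biochar_mult = 0.9),
               class = "befpart_config_error")
  expect_error(generator_config(cv = -0.1), class = "befpart_config_error")
  expect_error(generator_config(gamma = c("1" = 1.1, "2" = 1.2, "4" = 1.3)),
               class = "befpart_config_error")
  expect_error(generator_config(mu = c(1, 2)), class = "befpart_config_error")
})
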