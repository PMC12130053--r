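# The additive biodiversity-effect partition: NBE = CE + SE.

test_that("hand-derived two-species cases reproduce exactly", {
  # Uniform overyielding: equal relative-yield deviations, no selection.
  r1 <- partition_mixture(Y = c(6, 12), M = c(10, 20))
  expect_equal(r1$nbe, 3, tolerance = 1e-12)
  expect_equal(r1$ce, 3, tolerance = 1e-12)
  expect_equal(r1$se, 0, tolerance = 1e-12)
  expect_equal(r1$species$ry, c(0.6, 0.6))
  expect_equal(r1$species$dry, c(0.1, 0.1))

  # Asymmetric yields: the weak-baseline species overperforms, SE < 0.
  r2 <- partition_mixture(Y = c(8, 8), M = c(10, 20))
  expect_equal(r2$nbe, 1, tolerance = 1e-12)
  expect_equal(r2$ce, 3, tolerance = 1e-12)
  expect_equal(r2$se, -2, tolerance = 1e-12)
  expect_equal(r2$species$ry, c(0.8, 0.4))
  expect_equal(r2$species$dry, c(0.3, -0.1))
})

test_that("a community meeting its null expectation has zero effects", {
  M <- c(7, 13, 21)
  r <- partition_mixture(Y = M / 3, M = M)
  expect_equal(r$nbe, 0, tolerance = 1e-12)
  expect_equal(r$ce, 0, tolerance = 1e-12)
  expect_equal(r$se, 0, tolerance = 1e-12)
})

test_that("expected biomass is the proportion-weighted monoculture mean", {
  expect_equal(expected_biomass(c(10, 20), c(0.5, 0.5)), 15)
  expect_equal(expected_biomass(7, 1), 7)
  expect_equal(expected_biomass(c(8, 12, 16, 4)), 10)   # default p = 1/N
  expect_error(expected_biomass(c(10, NA), c(0.5, 0.5)),
               class = "befpart_missing_baseline_error")
  expect_error(expected_biomass(c(10, 20), c(0.9, 0.5)),
               class = "befpart_domain_error")
})

test_that("additivity identity holds on randomized instances", {
  withr::local_seed(202)
  for (i in 1:2000) {
    inst <- random_partition_instance()
    r <- partition_mixture(inst$Y, inst$M)
    expect_lte(abs(r$residual), 1e-9 * max(1, abs(r$nbe)))
  }
})

test_that("closed formulas match the term-by-term brute-force oracle", {
  withr::local_seed(303)
  for (i in 1:1000) {
    inst <- random_partition_instance()
    r <- partition_mixture(inst$Y, inst$M)
    o <- oracle_partition(inst$Y, inst$M)
    scale_ce <- max(1e-300, abs(o$ce))
    scale_se <- max(1e-300, abs(o$se))
    expect_lte(abs(r$ce - o$ce), 1e-12 * max(1, scale_ce))
    expect_lte(abs(r$se - o$se), 1e-12 * max(1, scale_se))
  }
})

test_that("selection vanishes under equal deviations or equal baselines", {
  # All dRY equal (proportional yields) -> zero covariance.
  r <- partition_mixture(Y = 0.55 * c(5, 10, 15), M = c(5, 10, 15))
  expect_equal(r$se, 0, tolerance = 1e-12)
  # All M equal -> zero covariance regardless of yields.
  r <- partition_mixture(Y = c(1, 7, 2), M = c(10, 10, 10))
  expect_equal(r$se, 0, tolerance = 1e-12)
  # mean(dRY) = 0 -> zero complementarity.
  M <- c(10, 20)
  Y <- c((0.5 + 0.2) * 10, (0.5 - 0.2) * 20)
  r <- partition_mixture(Y, M)
  expect_equal(r$ce, 0, tolerance = 1e-12)
})

test_that("effects scale linearly with biomass units, relative yields do not", {
  withr::local_seed(404)
  inst <- random_partition_instance(4)
  r <- partition_mixture(inst$Y, inst$M)
  c_ <- 12.5
  rs <- partition_mixture(inst$Y * c_, inst$M * c_)
  expect_equal(rs$nbe, r$nbe * c_)
  expect_equal(rs$ce, r$ce * c_)
  expect_equal(rs$se, r$se * c_)
  expect_equal(rs$species$ry, r$species$ry)
})

test_that("degenerate inputs are rejected with specific errors", {
  expect_error(partition_mixture(Y = 5, M = 10),
               class = "befpart_monoculture_error")
  expect_error(partition_mixture(Y = c(1, 2), M = c(10, 0)),
               class = "befpart_domain_error")
  expect_error(partition_mixture(Y = c(1, 2), M = c(10, NA)),
               class = "befpart_missing_baseline_error")
  expect_error(partition_mixture(Y = c(-1, 2), M = c(10, 20)),
               class = "befpart_domain_error")
  # A species that died in mixture is allowed: RY = 0.
  r <- partition_mixture(Y = c(0, 8), M = c(10, 20))
  expect_equal(r$species$ry[1], 0)
  expect_equal(r$nbe, r$ce + r$se)
})

test_that("monoculture baselines average replicate pots within treatment", {
  design <- design_from_compositions(list("S1"),
                                     treatments = treatment_table()[1:2, ],
                                     replicates = 2)
  ctrl <- design$pot_id[design$drought == 0]
  drt <- design$pot_id[design$drought == 1]
  ind <- dplyr::bind_rows(
    make_individuals(ctrl[1], "S1", shoot = 6, root = 3),    # 9 g
    make_individuals(ctrl[2], "S1", shoot = 8, root = 3),    # 11 g
    make_individuals(drt[1], "S1", shoot = 4, root = 3),     # 7 g
    make_individuals(drt[2], "S1", shoot = 4, root = 3)      # 7 g
  )
  refs <- monoculture_yields(aggregate_pots(ind, design), design)
  expect_equal(refs$M_g[refs$drought == 0], 10)   # mean of 9 and 11
  expect_equal(refs$M_g[refs$drought == 1], 7)    # same-treatment pots only
  expect_equal(refs$n_pots, c(2L, 2L))
})

test_that("a full factorial dataset partitions its 40 mixture pots", {
  sim <- suppressMessages(generate_experiment(generator_config(seed = 21)))
  agg <- aggregate_pots(sim$individuals, sim$design)
  part <- suppressMessages(partition_dataset(agg, sim$design))
  expect_equal(nrow(part$results), 40L)   # 2 mixture levels x 4 trt x 5 reps
  expect_equal(sum(part$skipped$reason == "monoculture (partition undefined)"),
               20L)
  expect_true(all(abs(part$results$additivity_residual_g) <=
                    1e-9 * pmax(1, abs(part$results$nbe_g))))
  # Per-species export covers every partitioned pot.
  expect_setequal(unique(part$species$pot_id), part$results$pot_id)
})

test_that("mixtures missing a monoculture baseline are skipped and logged", {
  design <- two_species_design(treatments = treatment_table()[1, ])
  # No S2 monoculture: drop it from the design.
  design <- design[design$species_list != "S2", ]
  ind <- dplyr::bind_rows(
    make_individuals(design$pot_id[design$richness == 1], "S1",
                     shoot = 6, root = 3),
    make_individuals(design$pot_id[design$richness == 2], c("S1", "S2"),
                     shoot = c(3, 4), root = c(1, 2))
  )
  part <- suppressMessages(partition_dataset(aggregate_pots(ind, design),
                                             design))
  expect_equal(nrow(part$results), 0L)
  expect_true(any(grepl("missing monoculture baseline for S2",
                        part$skipped$reason)))
})

test_that("empty input yields empty output without error", {
  design <- two_species_design()[0, ]
  ind <- make_individuals(character(0), character(0), numeric(0), numeric(0))
  part <- suppressMessages(partition_dataset(
    suppressWarnings(aggregate_pots(ind, design)), design))
  expect_equal(nrow(part$results), 0L)
})

test_that("observed proportions change NBE but not CE/SE, and skip the certificate", {
  design <- two_species_design(treatments = treatment_table()[1, ])
  ind <- dplyr::bind_rows(
    make_individuals(design$pot_id[design$species_list == "S1"], "S1",
                     shoot = 7, root = 3),
    make_individuals(design$pot_id[design$species_list == "S2"], "S2",
                     shoot = 14, root = 6),
    make_individuals(design$pot_id[design$richness == 2], c("S1", "S2"),
                     shoot = c(6, 2), root = c(2, 2))
  )
  agg <- aggregate_pots(ind, design)
  planted <- suppressMessages(partition_dataset(agg, design, "planted"))
  observed <- suppressMessages(partition_dataset(agg, design, "observed"))
  expect_equal(planted$results$ce_g, observed$results$ce_g)
  expect_equal(planted$results$se_g, observed$results$se_g)
  # Realized shares (2/3, 1/3) weight the expectation away from 1/N.
  expect_false(isTRUE(all.equal(planted$results$nbe_g,
                                observed$results$nbe_g)))
  expect_equal(observed$results$nbe_g,
               observed$results$observed_biomass_g -
                 observed$results$expected_biomass_g)
})

test_that("the control-baseline option compares against control monocultures", {
  design <- two_species_design(treatments = treatment_table()[1:2, ])
  mono <- design[design$richness == 1, ]
  ind <- dplyr::bind_rows(
    make_individuals(mono$pot_id[mono$species_list == "S1" & mono$drought == 0],
                     "S1", shoot = 7, root = 3),
    make_individuals(mono$pot_id[mono$species_list == "S2" & mono$drought == 0],
                     "S2", shoot = 14, root = 6),
    make_individuals(mono$pot_id[mono$species_list == "S1" & mono$drought == 1],
                     "S1", shoot = 3.5, root = 1.5),
    make_individuals(mono$pot_id[mono$species_list == "S2" & mono$drought == 1],
                     "S2", shoot = 7, root = 3),
    make_individuals(design$pot_id[design$richness == 2 & design$drought == 1],
                     c("S1", "S2"), shoot = c(3, 6), root = c(1, 2))
  )
  # the control mixture pot is deliberately left unplanted
  expect_warning(agg <- aggregate_pots(ind, design), "no individuals")
  matched <- suppressMessages(partition_dataset(agg, design,
                                                baseline = "matched"))
  control <- suppressMessages(partition_dataset(agg, design,
                                                baseline = "control"))
  drt <- matched$results$drought == 1
  # Drought mixture against drought baselines (M = 5, 10) vs control (10, 20).
  expect_equal(matched$results$expected_biomass_g[drt], 7.5)
  expect_equal(control$results$expected_biomass_g[control$results$drought == 1],
               15)
})
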