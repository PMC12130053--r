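# Additive partition of the net biodiversity effect (Loreau-Hector):
#   NBE = observed - expected,  expected = sum_i p_i * M_i
#   RY_i = Y_i / M_i,  dRY_i = RY_i - 1/N
#   CE  = N * mean(dRY) * mean(M)
#   SE  = N * cov_pop(dRY, M)          (population covariance, denominator N)
# With planted proportions p_i = 1/N the identity NBE = CE + SE is exact.

#' Monoculture baseline yields
#'
#' Computes the partition's baseline M_i: the mean per-pot biomass of each
#' species across its monoculture replicate pots, separately for every
#' treatment. Mixtures are compared against baselines of the same treatment
#' unless the caller later opts into the control baseline.
#'
#' @param aggregates Output of [aggregate_pots()].
#' @param design Design tibble.
#' @return A tibble with `species`, `drought`, `biochar`, `M_g` (mean
#'   monoculture yield, g) and `n_pots`.
#' @export
monoculture_yields <- function(aggregates, design) {
  mono <- design[design$richness == 1L,
                 c("pot_id", "species_list", "drought", "biochar")]
  if (nrow(mono) == 0L) {
    return(tibble::tibble(species = character(0), drought = integer(0),
                          biochar = integer(0), M_g = numeric(0),
                          n_pots = integer(0)))
  }
  mono$species <- unlist(split_species(mono$species_list))
  dplyr::inner_join(mono, aggregates$species[, c("pot_id", "biomass_g")],
                    by = "pot_id") |>
    dplyr::group_by(.data$species, .data$drought, .data$biochar) |>
    dplyr::summarise(M_g = mean(.data$biomass_g), n_pots = dplyr::n(),
                     .groups = "drop")
}

#' Expected mixture biomass
#'
#' The null expectation for a mixture's biomass: the monoculture yields of
#' its member species weighted by their expected proportions,
#' `sum(p * M)`.
#'
#' @param M Monoculture yields of the member species (g, all > 0).
#' @param p Expected proportions, summing to one.
#' @return Expected biomass in g.
#' @examples
#' expected_biomass(c(10, 20), c(0.5, 0.5))   # 15
#' @export
expected_biomass <- function(M, p = rep(1 / length(M), length(M))) {
  if (length(M) != length(p)) {
    abort_befpart("`M` and `p` must have equal length.", "befpart_domain_error")
  }
  if (anyNA(M)) {
    abort_befpart("Missing monoculture baseline in `M`.",
                  "befpart_missing_baseline_error")
  }
  check_positive(M, "M")
  if (abs(sum(p) - 1) > 1e-8 || any(p < 0)) {
    abort_befpart("`p` must be non-negative and sum to 1.",
                  "befpart_domain_error")
  }
  sum(p * M)
}

#' Partition one mixture into complementarity and selection effects
#'
#' Applies the additive partition to a single mixture pot. Relative yields
#' are `RY_i = Y_i / M_i`, their deviations `dRY_i = RY_i - 1/N`, and
#'
#' * `NBE = sum(Y) - sum(p * M)`
#' * `CE  = N * mean(dRY) * mean(M)`
#' * `SE  = N * cov_pop(dRY, M)` with the population covariance
#'   (denominator N).
#'
#' With planted proportions (`p = 1/N`, the default) the identity
#' `NBE = CE + SE` holds exactly; the residual is computed and certified
#' against `tolerance * max(1, |NBE|)`, and a violation raises a diagnostic
#' error rather than passing silently. With observed proportions the
#' identity is not expected to hold and the residual is only reported.
#'
#' @param Y Observed per-species yields in the mixture (g, >= 0; a species
#'   that died may contribute 0).
#' @param M Monoculture baseline yields of the same species (g, > 0).
#' @param p Expected proportions (default planted, 1/N each).
#' @param species Optional species labels carried into the output.
#' @param certify Enforce the additivity certificate (default `TRUE` when
#'   `p` is uniform).
#' @param tolerance Relative tolerance of the certificate.
#' @return A list with `observed`, `expected`, `nbe`, `ce`, `se`,
#'   `residual`, and a `species` tibble holding `Y`, `M`, `ry`, `dry`.
#' @examples
#' r <- partition_mixture(Y = c(8, 8), M = c(10, 20))
#' c(r$nbe, r$ce, r$se)   # 1, 3, -2
#' @export
partition_mixture <- function(Y, M, p = rep(1 / length(M), length(M)),
                              species = NULL,
                              certify = NULL, tolerance = 1e-9) {
  N <- length(M)
  if (N < 2L) {
    abort_befpart("The partition is undefined for monocultures (N must be >= 2).",
                  "befpart_monoculture_error")
  }
  if (length(Y) != N || length(p) != N) {
    abort_befpart("`Y`, `M` and `p` must have equal length.",
                  "befpart_domain_error")
  }
  if (anyNA(M)) {
    abort_befpart("Missing monoculture baseline.",
                  "befpart_missing_baseline_error")
  }
  check_positive(M, "M")
  if (any(is.na(Y)) || any(Y < 0)) {
    abort_befpart("Observed yields must be non-negative and non-missing.",
                  "befpart_domain_error")
  }

  ry <- Y / M
  dry <- ry - 1 / N
  observed <- sum(Y)
  expected <- expected_biomass(M, p)
  nbe <- observed - expected
  ce <- N * mean(dry) * mean(M)
  se <- N * cov_pop(dry, M)
  residual <- nbe - (ce + se)

  planted <- all(abs(p - 1 / N) < 1e-12)
  if (is.null(certify)) certify <- planted
  if (certify && abs(residual) > tolerance * max(1, abs(nbe))) {
    abort_befpart(
      sprintf("Additivity certificate violated: |NBE - (CE + SE)| = %.3e exceeds %.1e * max(1, |NBE|).",
              abs(residual), tolerance),
      "befpart_additivity_error"
    )
  }

  list(
    observed = observed, expected = expected,
    nbe = nbe, ce = ce, se = se, residual = residual,
    species = tibble::new_tibble(list(
      species = if (is.null(species)) sprintf("sp%d", seq_len(N)) else species,
      Y_g = as.numeric(Y), M_g = as.numeric(M), p = as.numeric(p),
      ry = ry, dry = dry
    ), nrow = N)
  )
}

#' Partition every mixture pot in a dataset
#'
#' Batch application of [partition_mixture()]: monoculture baselines are
#' computed per treatment (or taken from the control treatment), and every
#' mixture pot (richness >= 2) is partitioned. Monoculture pots, pots with
#' no surviving biomass, and mixtures lacking a baseline for some member
#' under the relevant treatment are skipped with a logged reason.
#'
#' @param aggregates Output of [aggregate_pots()].
#' @param design Design tibble.
#' @param proportions Expected proportions entering the NBE: `"planted"`
#'   (1/N, default; preserves the additivity identity) or `"observed"`
#'   (realized biomass shares; NBE then loses exact additivity and the
#'   certificate is disabled).
#' @param baseline `"matched"` compares each mixture against monocultures of
#'   its own treatment (default); `"control"` uses control-treatment
#'   monocultures throughout (sensitivity analysis).
#' @param tolerance Relative tolerance of the additivity certificate.
#' @return A list with `results` (one row per partitioned pot: expected,
#'   observed, NBE, CE, SE, residual in g), `species` (per-pot per-species
#'   RY and dRY), and `skipped` (pot_id, reason).
#' @export
partition_dataset <- function(aggregates, design,
                              proportions = c("planted", "observed"),
                              baseline = c("matched", "control"),
                              tolerance = 1e-9) {
  proportions <- match.arg(proportions)
  baseline <- match.arg(baseline)

  refs <- monoculture_yields(aggregates, design)
  if (baseline == "control") {
    refs <- refs[refs$drought == 0L & refs$biochar == 0L, ]
  }
  yield_by_pot <- split(aggregates$species[, c("species", "biomass_g")],
                        aggregates$species$pot_id)

  mixtures <- design[design$richness >= 2L, ]
  n_mix <- nrow(mixtures)
  members_all <- split_species(mixtures$species_list)
  ok <- logical(n_mix)
  expected_v <- observed_v <- nbe_v <- ce_v <- se_v <- resid_v <-
    rep(NA_real_, n_mix)
  species_rows <- vector("list", n_mix)
  skip_id <- character(0)
  skip_reason <- character(0)

  for (i in seq_len(n_mix)) {
    members <- members_all[[i]]
    N <- length(members)

    ref <- if (baseline == "matched") {
      refs[refs$drought == mixtures$drought[i] &
             refs$biochar == mixtures$biochar[i], ]
    } else {
      refs
    }
    M <- ref$M_g[match(members, ref$species)]
    if (anyNA(M)) {
      skip_id <- c(skip_id, mixtures$pot_id[i])
      skip_reason <- c(skip_reason,
                       sprintf("missing monoculture baseline for %s",
                               paste(members[is.na(M)], collapse = ", ")))
      next
    }

    obs <- yield_by_pot[[mixtures$pot_id[i]]]
    Y <- if (is.null(obs)) rep(0, N) else {
      y <- obs$biomass_g[match(members, obs$species)]
      y[is.na(y)] <- 0   # member with no surviving individuals
      y
    }
    if (sum(Y) <= 0) {
      skip_id <- c(skip_id, mixtures$pot_id[i])
      skip_reason <- c(skip_reason, "no surviving biomass in pot")
      next
    }

    p <- if (proportions == "planted") rep(1 / N, N) else Y / sum(Y)
    part <- partition_mixture(Y, M, p = p, species = members,
                              certify = proportions == "planted",
                              tolerance = tolerance)

    ok[i] <- TRUE
    expected_v[i] <- part$expected
    observed_v[i] <- part$observed
    nbe_v[i] <- part$nbe
    ce_v[i] <- part$ce
    se_v[i] <- part$se
    resid_v[i] <- part$residual
    sp <- part$species
    sp$pot_id <- rep(mixtures$pot_id[i], N)
    species_rows[[i]] <- sp
  }

  results <- tibble::new_tibble(list(
    pot_id = mixtures$pot_id[ok], richness = mixtures$richness[ok],
    drought = mixtures$drought[ok], biochar = mixtures$biochar[ok],
    treatment = mixtures$treatment[ok], replicate = mixtures$replicate[ok],
    expected_biomass_g = expected_v[ok], observed_biomass_g = observed_v[ok],
    nbe_g = nbe_v[ok], ce_g = ce_v[ok], se_g = se_v[ok],
    additivity_residual_g = resid_v[ok]
  ), nrow = sum(ok))
  skipped <- list(
    tibble::tibble(pot_id = design$pot_id[design$richness == 1L],
                   reason = "monoculture (partition undefined)"),
    tibble::tibble(pot_id = skip_id, reason = skip_reason)
  )

  skipped <- dplyr::bind_rows(skipped)
  n_mono <- sum(skipped$reason == "monoculture (partition undefined)")
  if (n_mono > 0L) {
    log_stage("partition",
              sprintf("excluded %d monoculture pot(s); the partition needs N >= 2",
                      n_mono))
  }
  other <- skipped[skipped$reason != "monoculture (partition undefined)", ]
  for (j in seq_len(nrow(other))) {
    log_stage("partition", sprintf("skipping %s: %s", other$pot_id[j],
                                   other$reason[j]), level = "WARN")
  }

  species <- dplyr::bind_rows(species_rows)
  if (nrow(species) > 0L) {
    species <- species[, c("pot_id", "species", "Y_g", "M_g", "p", "ry",
                           "dry")]
  }
  list(results = results, species = species, skipped = skipped)
}
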