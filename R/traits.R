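# Plant functional traits from raw morphometrics, and pot-level aggregates.

#' Specific leaf area (SLA)
#'
#' SLA is the ratio of leaf area to leaf dry mass. With area in mm^2 and
#' mass in mg (the means of three sampled leaves per individual), the result
#' is in mm^2 mg^-1. Missing values propagate; non-positive values are a
#' domain error rather than silently producing nonsense ratios.
#'
#' @param leaf_area Leaf area in mm^2 (> 0).
#' @param leaf_dry_mass Leaf dry mass in mg (> 0).
#' @return SLA in mm^2 mg^-1.
#' @examples
#' compute_sla(300, 30)   # 10
#' @export
compute_sla <- function(leaf_area, leaf_dry_mass) {
  check_positive(leaf_area, "leaf_area")
  check_positive(leaf_dry_mass, "leaf_dry_mass")
  leaf_area / leaf_dry_mass
}

#' Specific root length (SRL)
#'
#' Root length divided by root dry mass; with length in cm and mass in g the
#' result is in cm g^-1.
#'
#' @param root_length Root length in cm (> 0).
#' @param root_dry_mass Root dry mass in g (> 0).
#' @return SRL in cm g^-1.
#' @examples
#' compute_srl(200, 2)   # 100
#' @export
compute_srl <- function(root_length, root_dry_mass) {
  check_positive(root_length, "root_length")
  check_positive(root_dry_mass, "root_dry_mass")
  root_length / root_dry_mass
}

#' Root-to-shoot ratio (RSR)
#'
#' Root dry mass over shoot dry mass (dimensionless). RSR rises when plants
#' shift allocation belowground, e.g. under drought.
#'
#' @param root_dry_mass Root dry mass in g (> 0).
#' @param shoot_dry_mass Shoot dry mass in g (> 0).
#' @return The dimensionless ratio root/shoot.
#' @examples
#' compute_rsr(1, 2)   # 0.5
#' @export
compute_rsr <- function(root_dry_mass, shoot_dry_mass) {
  check_positive(root_dry_mass, "root_dry_mass")
  check_positive(shoot_dry_mass, "shoot_dry_mass")
  root_dry_mass / shoot_dry_mass
}

#' Per-individual trait table
#'
#' Derives the functional-trait record for every individual from its raw
#' measurements: height (carried through), SLA, SRL, RSR, and total biomass
#' (shoot + root dry mass). Missing measurements yield missing traits
#' (never zero-filled, never imputed); present measurements must be
#' strictly positive.
#'
#' @param individuals Tibble with columns `pot_id`, `species`, `height_cm`,
#'   `leaf_area_mm2`, `leaf_dry_mass_mg`, `root_length_cm`,
#'   `root_dry_mass_g`, `shoot_dry_mass_g`.
#' @return A tibble with `pot_id`, `species`, `height_cm`, `sla_mm2_mg`,
#'   `srl_cm_g`, `rsr`, `total_biomass_g`, `aboveground_biomass_g`.
#' @export
compute_traits <- function(individuals) {
  required <- c("pot_id", "species", "height_cm", "leaf_area_mm2",
                "leaf_dry_mass_mg", "root_length_cm", "root_dry_mass_g",
                "shoot_dry_mass_g")
  missing_cols <- setdiff(required, names(individuals))
  if (length(missing_cols) > 0L) {
    abort_befpart(paste0("Missing individual-level columns: ",
                         paste(missing_cols, collapse = ", ")),
                  "befpart_schema_error")
  }
  tibble::tibble(
    pot_id = individuals$pot_id,
    species = individuals$species,
    height_cm = check_positive(individuals$height_cm, "height_cm"),
    sla_mm2_mg = compute_sla(individuals$leaf_area_mm2,
                             individuals$leaf_dry_mass_mg),
    srl_cm_g = compute_srl(individuals$root_length_cm,
                           individuals$root_dry_mass_g),
    rsr = compute_rsr(individuals$root_dry_mass_g,
                      individuals$shoot_dry_mass_g),
    total_biomass_g = individuals$shoot_dry_mass_g +
      individuals$root_dry_mass_g,
    aboveground_biomass_g = individuals$shoot_dry_mass_g
  )
}

#' Aggregate individuals to pot level
#'
#' Produces the two pot-level tables the partition and the exports consume:
#' per-pot-per-species biomass totals, and per-pot trait means. Individuals
#' must belong to a pot in the design and to a species in that pot's
#' composition; violations are integrity errors, not silent drops. Trait
#' means are taken over non-missing values only, so an individual with a
#' missing leaf record still contributes to the biomass sum and to the
#' other trait means.
#'
#' @param individuals Individual-level measurement tibble
#'   (see [compute_traits()] for the required columns).
#' @param design Design tibble (see [enumerate_design()]).
#' @param biomass Which biomass enters the per-species totals used by the
#'   partition: `"total"` (shoot + root, default) or `"aboveground"`
#'   (shoot only).
#' @return A list with elements `species` (pot_id, species, n_individuals,
#'   biomass_g, total_biomass_g, aboveground_biomass_g) and `pots` (pot_id,
#'   design columns, n_individuals, total biomass, and mean height, SLA,
#'   SRL, RSR).
#' @export
aggregate_pots <- function(individuals, design,
                           biomass = c("total", "aboveground")) {
  biomass <- match.arg(biomass)
  traits <- compute_traits(individuals)

  unknown_pot <- setdiff(unique(traits$pot_id), design$pot_id)
  if (length(unknown_pot) > 0L) {
    abort_befpart(paste0("Individuals reference pots absent from the design: ",
                         paste(unknown_pot, collapse = ", ")),
                  "befpart_integrity_error")
  }
  comp <- stats::setNames(split_species(design$species_list), design$pot_id)
  in_comp <- mapply(function(p, s) s %in% comp[[p]],
                    traits$pot_id, traits$species)
  if (!all(in_comp)) {
    bad <- traits[!in_comp, c("pot_id", "species")]
    abort_befpart(
      sprintf("Species outside the pot composition: %s",
              paste(sprintf("%s in %s", bad$species, bad$pot_id),
                    collapse = "; ")),
      "befpart_integrity_error"
    )
  }

  empty <- setdiff(design$pot_id, unique(traits$pot_id))
  if (length(empty) > 0L) {
    warning(sprintf("%d pot(s) have no individuals and are omitted: %s",
                    length(empty), paste(empty, collapse = ", ")),
            call. = FALSE)
  }

  species <- traits |>
    dplyr::group_by(.data$pot_id, .data$species) |>
    dplyr::summarise(
      n_individuals = dplyr::n(),
      total_biomass_g = sum(.data$total_biomass_g),
      aboveground_biomass_g = sum(.data$aboveground_biomass_g),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      biomass_g = if (biomass == "total") .data$total_biomass_g
                  else .data$aboveground_biomass_g
    ) |>
    dplyr::select("pot_id", "species", "n_individuals", "biomass_g",
                  "total_biomass_g", "aboveground_biomass_g")

  mean_na <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  pots <- traits |>
    dplyr::group_by(.data$pot_id) |>
    dplyr::summarise(
      n_individuals = dplyr::n(),
      pot_biomass_g = sum(if (biomass == "total") .data$total_biomass_g
                          else .data$aboveground_biomass_g),
      mean_height_cm = mean_na(.data$height_cm),
      mean_sla_mm2_mg = mean_na(.data$sla_mm2_mg),
      mean_srl_cm_g = mean_na(.data$srl_cm_g),
      mean_rsr = mean_na(.data$rsr),
      .groups = "drop"
    )
  pots <- dplyr::inner_join(
    dplyr::select(design, "pot_id", "richness", "species_list", "drought",
                  "biochar", "treatment", "replicate"),
    pots, by = "pot_id"
  )

  list(species = species, pots = pots, biomass = biomass)
}
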