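# Balanced factorial design: species pool x richness x treatment x replicate.

#' Configure a factorial diversity experiment
#'
#' Bundles the design parameters consumed by [enumerate_design()] and the
#' synthetic generator: the species pool, the richness gradient, the number
#' of replicate communities per richness level (each distinct community is
#' one replicate and is grown under every treatment), and how many seedlings
#' are planted per pot.
#'
#' The default reproduces a 5-species pool with richness levels 1, 2 and 4,
#' five replicate communities per level, four seedlings per pot and the four
#' crossed drought x biochar treatments: 3 levels x 4 treatments x
#' 5 replicates = 60 pots.
#'
#' @param species_pool Character vector of unique, non-empty species labels.
#' @param richness_levels Positive integers, each at most the pool size.
#' @param replicates_per_cell Number of replicate communities per richness
#'   level (>= 1).
#' @param individuals_per_pot Seedlings planted per pot (default 4), split
#'   as evenly as possible among the community's species.
#' @param seed Integer seed driving the random mixture selection.
#' @return An object of class `design_config`.
#' @examples
#' cfg <- design_config()
#' cfg$richness_levels
#' @export
design_config <- function(species_pool = paste0("S", 1:5),
                          richness_levels = c(1L, 2L, 4L),
                          replicates_per_cell = 5L,
                          individuals_per_pot = 4L,
                          seed = 1L) {
  species_pool <- as.character(species_pool)
  if (length(species_pool) < 1L || anyDuplicated(species_pool) ||
      any(!nzchar(species_pool)) || anyNA(species_pool)) {
    abort_befpart("`species_pool` must be unique, non-empty labels.",
                  "befpart_config_error")
  }
  richness_levels <- as.integer(sort(unique(richness_levels)))
  if (any(richness_levels < 1L)) {
    abort_befpart("`richness_levels` must be positive integers.",
                  "befpart_config_error")
  }
  if (any(richness_levels > length(species_pool))) {
    abort_befpart("A richness level exceeds the species pool size.",
                  "befpart_config_error")
  }
  replicates_per_cell <- as.integer(replicates_per_cell)
  individuals_per_pot <- as.integer(individuals_per_pot)
  if (replicates_per_cell < 1L) {
    abort_befpart("`replicates_per_cell` must be >= 1.", "befpart_config_error")
  }
  if (individuals_per_pot < 1L) {
    abort_befpart("`individuals_per_pot` must be >= 1.", "befpart_config_error")
  }
  structure(
    list(species_pool = species_pool,
         richness_levels = richness_levels,
         replicates_per_cell = replicates_per_cell,
         individuals_per_pot = individuals_per_pot,
         seed = as.integer(seed)),
    class = "design_config"
  )
}

#' @export
print.design_config <- function(x, ...) {
  cat("<design_config>\n")
  cat("  species pool:       ", paste(x$species_pool, collapse = ", "), "\n")
  cat("  richness levels:    ", paste(x$richness_levels, collapse = ", "), "\n")
  cat("  replicates/cell:    ", x$replicates_per_cell, "\n")
  cat("  individuals/pot:    ", x$individuals_per_pot, "\n")
  cat("  seed:               ", x$seed, "\n")
  invisible(x)
}

#' Select balanced random species mixtures
#'
#' Draws `count` distinct communities of a given richness from the pool such
#' that species occurrence counts across the drawn communities differ by at
#' most one (and are exactly equal whenever `count * richness` is divisible
#' by the pool size). Selection is rejection sampling over seeded shuffles of
#' the concatenated pool, chunked into richness-sized groups, retried until
#' every chunk holds distinct species and all communities are distinct.
#'
#' @param pool Character vector of species labels.
#' @param richness Community size to draw.
#' @param count Number of distinct communities required.
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param max_tries Retry cap before declaring the balance infeasible.
#' @return A list of `count` sorted character vectors of length `richness`.
#' @examples
#' select_balanced_mixtures(paste0("S", 1:5), richness = 2, count = 5, seed = 42)
#' @export
select_balanced_mixtures <- function(pool, richness, count, seed = NULL,
                                     max_tries = 10000L) {
  pool <- as.character(pool)
  n <- length(pool)
  richness <- as.integer(richness)
  count <- as.integer(count)
  if (richness < 1L || richness > n) {
    abort_befpart("`richness` must lie in [1, pool size].",
                  "befpart_config_error")
  }
  if (count < 1L) {
    abort_befpart("`count` must be >= 1.", "befpart_config_error")
  }
  if (count > choose(n, richness)) {
    abort_befpart(
      sprintf("Cannot draw %d distinct communities of richness %d from %d species (only %d exist).",
              count, richness, n, choose(n, richness)),
      "befpart_infeasible_error"
    )
  }
  if (!is.null(seed)) {
    withr::local_seed(as.integer(seed))
  }

  slots <- count * richness
  full_copies <- slots %/% n
  remainder <- slots %% n
  base <- rep(pool, full_copies)

  for (try in seq_len(max_tries)) {
    extra <- if (remainder > 0L) sample(pool, remainder) else character(0)
    shuffled <- sample(c(base, extra))
    groups <- split(shuffled, rep(seq_len(count), each = richness))
    if (any(vapply(groups, anyDuplicated, integer(1)) > 0L)) next
    keys <- vapply(groups, function(g) paste(sort(g), collapse = ";"),
                   character(1))
    if (anyDuplicated(keys)) next
    return(unname(lapply(groups, sort)))
  }
  abort_befpart(
    sprintf("No balanced selection found in %d tries (pool %d, richness %d, count %d).",
            max_tries, n, richness, count),
    "befpart_infeasible_error"
  )
}

#' Enumerate the full factorial design
#'
#' Builds one pot record per richness level x treatment x replicate. Within
#' each richness level the replicate communities are drawn once with
#' [select_balanced_mixtures()] and reused across all four treatments, so
#' every community experiences every treatment. The replicate index labels
#' the community (each distinct community is one replicate of its diversity
#' level).
#'
#' @param config A [design_config()].
#' @return A tibble with columns `pot_id`, `richness`, `species_list`
#'   (semicolon-joined, sorted labels), `drought`, `biochar`, `treatment`,
#'   `replicate`.
#' @examples
#' design <- enumerate_design(design_config(seed = 7))
#' nrow(design)   # 3 richness levels x 4 treatments x 5 replicates = 60
#' @export
enumerate_design <- function(config = design_config()) {
  stopifnot(inherits(config, "design_config"))
  withr::local_seed(config$seed)

  per_level <- lapply(config$richness_levels, function(r) {
    mixtures <- select_balanced_mixtures(config$species_pool, r,
                                         config$replicates_per_cell,
                                         seed = NULL)
    tibble::tibble(
      richness = r,
      replicate = seq_along(mixtures),
      species_list = join_species(mixtures)
    )
  })
  communities <- dplyr::bind_rows(per_level)

  design <- tidyr::crossing(communities, treatment_table()) |>
    dplyr::arrange(.data$richness, .data$drought, .data$biochar,
                   .data$replicate) |>
    dplyr::mutate(
      pot_id = sprintf("N%d_%s_m%d", .data$richness, .data$treatment,
                       .data$replicate)
    ) |>
    dplyr::select("pot_id", "richness", "species_list", "drought",
                  "biochar", "treatment", "replicate")
  design
}

#' Build a design from explicit community compositions
#'
#' Constructs a pot table directly from a list of species vectors, crossing
#' each composition with the given treatments and a replicate count. This is
#' the entry point for real experiments whose communities were fixed by the
#' experimenter rather than drawn by [select_balanced_mixtures()], and for
#' simulation studies that replicate the same composition many times.
#'
#' @param compositions List of character vectors (one community each).
#' @param treatments Treatment table, defaulting to all four combinations
#'   from [treatment_table()]; subset its rows for partial designs.
#' @param replicates Number of replicate pots per composition x treatment.
#' @return A design tibble in the same format as [enumerate_design()].
#' @examples
#' design_from_compositions(list("S1", "S2", c("S1", "S2")), replicates = 2)
#' @export
design_from_compositions <- function(compositions,
                                     treatments = treatment_table(),
                                     replicates = 1L) {
  stopifnot(is.list(compositions), length(compositions) >= 1L,
            replicates >= 1L)
  comp <- tibble::tibble(
    species_list = join_species(compositions),
    richness = lengths(compositions),
    comp_idx = seq_along(compositions)
  )
  if (any(vapply(compositions, anyDuplicated, integer(1)) > 0L)) {
    abort_befpart("Compositions must not contain duplicate species.",
                  "befpart_config_error")
  }
  tidyr::crossing(comp, treatments,
                  replicate = seq_len(as.integer(replicates))) |>
    dplyr::mutate(
      pot_id = sprintf("C%d_%s_r%d", .data$comp_idx, .data$treatment,
                       .data$replicate)
    ) |>
    dplyr::select("pot_id", "richness", "species_list", "drought",
                  "biochar", "treatment", "replicate")
}

#' Validate a design against its configuration
#'
#' Diagnostic check of the design invariants: unique pot ids, richness
#' consistent with the species list, species drawn from the pool, configured
#' richness levels only, full treatment crossing with the configured
#' replicate count in every richness x treatment cell, identical community
#' sets across treatments within a richness level, and the <=1 spread
#' species-balance constraint.
#'
#' @param design A design tibble (see [enumerate_design()]).
#' @param config The [design_config()] the design should satisfy.
#' @return A tibble of violations with columns `check` and `detail`;
#'   zero rows if and only if the design is valid.
#' @examples
#' cfg <- design_config(seed = 3)
#' validate_design(enumerate_design(cfg), cfg)   # 0 rows
#' @export
validate_design <- function(design, config) {
  stopifnot(inherits(config, "design_config"))
  v <- list()
  add <- function(check, detail) {
    v[[length(v) + 1L]] <<- tibble::tibble(check = check, detail = detail)
  }

  dup <- design$pot_id[duplicated(design$pot_id)]
  for (id in unique(dup)) add("duplicate_pot_id", id)

  members <- split_species(design$species_list)
  n_mem <- lengths(members)
  bad_rich <- which(n_mem != design$richness |
                      vapply(members, anyDuplicated, integer(1)) > 0L)
  for (i in bad_rich) {
    add("richness_mismatch",
        sprintf("%s: %d species listed, richness %d",
                design$pot_id[i], n_mem[i], design$richness[i]))
  }
  unknown <- setdiff(unique(unlist(members)), config$species_pool)
  for (s in unknown) add("unknown_species", s)

  off_level <- setdiff(unique(design$richness), config$richness_levels)
  for (r in off_level) add("unconfigured_richness", as.character(r))

  bad_rep <- design$pot_id[design$replicate < 1L |
                             design$replicate > config$replicates_per_cell]
  for (id in bad_rep) add("replicate_out_of_range", id)

  # Cell counts: every richness x treatment cell needs the configured
  # replicate count.
  cells <- tidyr::crossing(richness = config$richness_levels,
                           treatment_table()) |>
    dplyr::left_join(
      dplyr::count(design, .data$richness, .data$drought, .data$biochar),
      by = c("richness", "drought", "biochar")
    ) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L)) |>
    dplyr::filter(.data$n != config$replicates_per_cell)
  for (i in seq_len(nrow(cells))) {
    add("cell_replicate_count",
        sprintf("richness %d, %s: %d pots (expected %d)",
                cells$richness[i], cells$treatment[i], cells$n[i],
                config$replicates_per_cell))
  }

  # Same community set under every treatment within a richness level.
  for (r in intersect(unique(design$richness), config$richness_levels)) {
    sub <- design[design$richness == r, ]
    sets <- tapply(sub$species_list, sub$treatment,
                   function(x) paste(sort(x), collapse = "|"))
    if (length(unique(sets)) > 1L) {
      add("communities_differ_across_treatments", sprintf("richness %d", r))
    }
    # Balance over the distinct communities of this level.
    occ <- table(factor(unlist(split_species(unique(sub$species_list))),
                        levels = config$species_pool))
    if (max(occ) - min(occ) > 1L) {
      add("unbalanced_species_occurrence",
          sprintf("richness %d: spread %d", r, max(occ) - min(occ)))
    }
  }

  if (length(v) == 0L) {
    tibble::tibble(check = character(0), detail = character(0))
  } else {
    dplyr::bind_rows(v)
  }
}
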