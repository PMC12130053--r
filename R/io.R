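# CSV interchange: schema validation, headered readers and writers.
#
# Dialect: UTF-8, comma-delimited, mandatory header row, "." decimal
# separator; comment lines prefixed "#". Every file written by the package
# carries a header comment with the tool version, a config hash and the
# seed, so outputs are traceable to the run that produced them.

befpart_schemas <- function() {
  list(
    design = list(
      required = c("pot_id", "richness", "species_list", "drought",
                   "biochar", "replicate"),
      optional = "treatment",
      checks = list(
        pot_id = function(x) ifelse(is.na(x) | !nzchar(x),
                                    "empty pot_id", NA_character_),
        richness = function(x) ifelse(is.na(x) | x < 1,
                                      "richness must be >= 1", NA_character_),
        drought = function(x) ifelse(!x %in% c(0, 1),
                                     "drought must be 0/1", NA_character_),
        biochar = function(x) ifelse(!x %in% c(0, 1),
                                     "biochar must be 0/1", NA_character_),
        replicate = function(x) ifelse(is.na(x) | x < 1,
                                       "replicate must be >= 1",
                                       NA_character_)
      )
    ),
    individuals = list(
      required = c("pot_id", "species", "height_cm", "leaf_area_mm2",
                   "leaf_dry_mass_mg", "root_length_cm", "root_dry_mass_g",
                   "shoot_dry_mass_g"),
      optional = character(0),
      checks = {
        pos <- function(name) {
          force(name)
          function(x) ifelse(!is.na(x) & x <= 0,
                             sprintf("%s must be positive when present", name),
                             NA_character_)
        }
        list(
          pot_id = function(x) ifelse(is.na(x) | !nzchar(x),
                                      "empty pot_id", NA_character_),
          species = function(x) ifelse(is.na(x) | !nzchar(x),
                                       "empty species", NA_character_),
          height_cm = pos("height_cm"),
          leaf_area_mm2 = pos("leaf_area_mm2"),
          leaf_dry_mass_mg = pos("leaf_dry_mass_mg"),
          root_length_cm = pos("root_length_cm"),
          root_dry_mass_g = pos("root_dry_mass_g"),
          shoot_dry_mass_g = pos("shoot_dry_mass_g")
        )
      }
    ),
    pots = list(
      required = c("pot_id", "richness", "drought", "biochar", "replicate",
                   "pot_biomass_g"),
      optional = c("species_list", "treatment", "n_individuals",
                   "mean_height_cm", "mean_sla_mm2_mg", "mean_srl_cm_g",
                   "mean_rsr"),
      checks = list(
        pot_biomass_g = function(x) ifelse(!is.na(x) & x < 0,
                                           "pot_biomass_g must be >= 0",
                                           NA_character_)
      )
    ),
    effects = list(
      required = c("pot_id", "richness", "drought", "biochar",
                   "expected_biomass_g", "observed_biomass_g", "nbe_g",
                   "ce_g", "se_g", "additivity_residual_g"),
      optional = c("treatment", "replicate"),
      checks = list(
        expected_biomass_g = function(x) ifelse(!is.na(x) & x <= 0,
                                                "expected_biomass_g must be positive",
                                                NA_character_)
      )
    )
  )
}

#' Validate a table against a befpart CSV schema
#'
#' Checks a file or data frame against one of the package's interchange
#' schemas (`design`, `individuals`, `pots`, `effects`): required columns
#' must be present, and per-column value constraints hold row by row.
#' Unknown columns raise a warning only (forward compatibility), never an
#' error.
#'
#' @param x A data frame, or a path to a CSV file.
#' @param schema One of `"design"`, `"individuals"`, `"pots"`, `"effects"`.
#' @return A tibble of violations with columns `row`, `column`, `message`;
#'   zero rows means the table conforms.
#' @export
validate_schema <- function(x, schema = c("design", "individuals", "pots",
                                          "effects")) {
  schema <- match.arg(schema)
  spec <- befpart_schemas()[[schema]]
  if (is.character(x)) {
    if (!file.exists(x)) {
      abort_befpart(sprintf("File not found: %s", x), "befpart_io_error")
    }
    x <- readr::read_csv(x, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  }

  viol <- list()
  missing_cols <- setdiff(spec$required, names(x))
  for (col in missing_cols) {
    viol[[length(viol) + 1L]] <- tibble::tibble(
      row = NA_integer_, column = col, message = "required column missing")
  }
  unknown <- setdiff(names(x), c(spec$required, spec$optional))
  if (length(unknown) > 0L) {
    warning(sprintf("Unknown column(s) ignored in %s table: %s",
                    schema, paste(unknown, collapse = ", ")), call. = FALSE)
  }
  for (col in intersect(names(spec$checks), names(x))) {
    msg <- spec$checks[[col]](x[[col]])
    bad <- which(!is.na(msg))
    if (length(bad) > 0L) {
      viol[[length(viol) + 1L]] <- tibble::tibble(
        row = bad, column = col, message = msg[bad])
    }
  }
  if (length(viol) == 0L) {
    tibble::tibble(row = integer(0), column = character(0),
                   message = character(0))
  } else {
    dplyr::bind_rows(viol)
  }
}

stop_on_violations <- function(viol, path, schema) {
  if (nrow(viol) > 0L) {
    first <- viol[1, ]
    abort_befpart(
      sprintf("%s does not conform to the %s schema (%d violation(s)); first: row %s, column %s: %s",
              path, schema, nrow(viol),
              ifelse(is.na(first$row), "-", first$row),
              first$column, first$message),
      "befpart_validation_error"
    )
  }
  invisible(NULL)
}

#' Write a befpart CSV with a traceability header
#'
#' @param x Data frame to write.
#' @param path Output path.
#' @param seed Seed recorded in the header.
#' @param config Optional configuration object; its hash is recorded.
#' @return `path`, invisibly.
#' @export
write_befpart_csv <- function(x, path, seed = NA_integer_, config = NULL) {
  version <- as.character(utils::packageVersion("befpart"))
  hash <- if (is.null(config)) "-" else rlang::hash(config)
  header <- sprintf("# befpart %s | seed=%s | config_hash=%s",
                    version, seed, hash)
  writeLines(header, path)
  readr::write_csv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a befpart CSV, validating its schema
#'
#' @param path CSV path (header comments prefixed `#` are skipped).
#' @param schema Schema name, see [validate_schema()]; `NULL` to skip
#'   validation.
#' @return A tibble.
#' @export
read_befpart_csv <- function(path, schema = NULL) {
  if (!file.exists(path)) {
    abort_befpart(sprintf("File not found: %s", path), "befpart_io_error")
  }
  x <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                       progress = FALSE)
  if (!is.null(schema)) {
    stop_on_violations(validate_schema(x, schema), path, schema)
  }
  x
}
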