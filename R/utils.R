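# Internal helpers shared across modules.

#' The four treatment combinations
#'
#' Returns the fully crossed drought x biochar treatment table used
#' throughout the package: control, drought, biochar, and biochar+drought.
#' Flags are 0/1 integers; `treatment` is a stable human-readable label.
#'
#' @return A tibble with columns `treatment`, `drought`, `biochar`.
#' @examples
#' treatment_table()
#' @export
treatment_table <- function() {
  tibble::tibble(
    treatment = c("control", "drought", "biochar", "biochar_drought"),
    drought   = c(0L, 1L, 0L, 1L),
    biochar   = c(0L, 0L, 1L, 1L)
  )
}

treatment_label <- function(drought, biochar) {
  dplyr::case_when(
    drought == 0L & biochar == 0L ~ "control",
    drought == 1L & biochar == 0L ~ "drought",
    drought == 0L & biochar == 1L ~ "biochar",
    TRUE                          ~ "biochar_drought"
  )
}

# Population covariance (denominator n). The additive partition is exact
# only with this denominator; stats::cov divides by n - 1.
cov_pop <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 1L)
  mean((x - mean(x)) * (y - mean(y)))
}

# Split semicolon-joined species lists into character vectors.
split_species <- function(species_list) {
  strsplit(as.character(species_list), ";", fixed = TRUE)
}

join_species <- function(members) {
  vapply(members, function(m) paste(sort(m), collapse = ";"), character(1))
}

abort_befpart <- function(message, class) {
  rlang::abort(message, class = c(class, "befpart_error"))
}

check_positive <- function(x, name) {
  bad <- !is.na(x) & x <= 0
  if (any(bad)) {
    abort_befpart(
      sprintf("`%s` must be strictly positive (found %s).",
              name, paste(utils::head(x[bad], 3), collapse = ", ")),
      class = "befpart_domain_error"
    )
  }
  invisible(x)
}

log_stage <- function(stage, ..., level = "INFO") {
  message(sprintf("[%s] %s %s: %s",
                  format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  level, stage, paste0(...)))
}
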