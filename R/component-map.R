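#' Read a chemical-component map
#'
#' The component map tells [classify_components()] how to translate chemical
#' component ids (wwPDB CCD ids such as `PSU` or `SPD`) into residue
#' categories and modification classes. The packaged default covers
#' pseudouridine, the 2'-O-methyl nucleotides, the base methylations
#' (m1A, m4C, m5C, m6A, m3U), the modified amino acids
#' (beta-hydroxy-histidine, tau-N-methyl-histidine, epsilon-N-methyl-lysine),
#' the polyamines (SPM, SPD, PUT), common metals and water. It is an editable
#' TSV resource; pass your own file to override or extend it.
#'
#' @param path Path to a TSV file with columns `component_id`, `category`,
#'   `modification_class` (use `NA` for unmodified categories). Lines starting
#'   with `#` are comments. Defaults to the packaged map.
#' @return A tibble with columns `component_id`, `category`,
#'   `modification_class`.
#' @export
#' @examples
#' default_component_map()
read_component_map <- function(path = NULL) {
  path <- path %||% system.file("extdata", "component_map.tsv", package = "ribomod")
  if (!nzchar(path) || !file.exists(path)) {
    abort("component map file not found")
  }
  map <- readr::read_tsv(
    path,
    comment = "#",
    na = character(),
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  required <- c("component_id", "category", "modification_class")
  if (!all(required %in% names(map))) {
    abort(paste(
      "component map must have columns:",
      paste(required, collapse = ", ")
    ))
  }
  map <- map |>
    mutate(modification_class = na_if(.data$modification_class, "NA"))
  if (anyDuplicated(map$component_id)) {
    abort("component map has duplicated component_id rows")
  }
  map
}

#' @rdname read_component_map
#' @export
default_component_map <- function() read_component_map()

#' Modification classes contributing to each tally
#'
#' A residue of class `combined` (2'-O-methylpseudouridine) is one modified
#' position that contributes to both the pseudouridine and the ribose
#' 2'-O-methyl tallies.
#' @keywords internal
psu_classes <- c("pseudouridine", "combined")
nm_classes <- c("ribose-2prime-O-methyl", "combined")
base_mod_classes <- c("m1A", "m4C", "m5C", "m6A", "m3U")
protein_mod_classes <- c(
  "beta-hydroxy-histidine", "tau-N-methyl-histidine", "epsilon-N-methyl-lysine"
)
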