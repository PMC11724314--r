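#' Annotate a structure end-to-end
#'
#' The machine-readable counterpart of a modification-landscape figure: runs
#' the whole pipeline on one model and returns a bundle of reports --
#' modification census (optionally compared to a reference list),
#' pseudouridine validation and uridine screening, ion classification with
#' its deposited-vs-assigned confusion table, and a polyamine contact map
#' per polyamine.
#'
#' @param input Path to an mmCIF/PDB file, or a `ribo_structure`.
#' @param component_map See [read_component_map()].
#' @param chain_roles Named character vector chain -> role, or `NULL` for
#'   the size heuristic (see [assign_chain_roles()]).
#' @param thresholds See [ribomod_thresholds()].
#' @param anchor Optional PTC anchor residue keys for [distance_to_ptc()].
#' @param reference Optional reference modification list (tibble or TSV
#'   path), see [compare_reference()].
#' @return A `ribo_annotation`: list with `model`, `census`, `psu`,
#'   `uridine_screen`, `ions`, `ion_confusion`, `polyamines` and `config`.
#' @export
annotate_structure <- function(input, component_map = default_component_map(),
                               chain_roles = NULL,
                               thresholds = ribomod_thresholds(),
                               anchor = NULL, reference = NULL) {
  model <- if (inherits(input, "ribo_structure")) input else read_structure(input)
  model <- classify_components(model, component_map)
  model <- assign_chain_roles(model, chain_roles)

  census <- modification_census(model, anchor = anchor)
  if (!is.null(reference)) {
    if (is.character(reference)) reference <- read_reference_list(reference)
    census <- compare_reference(census, model, reference)
  }
  psu <- validate_modeled_psu(model,
                              cutoff = thresholds$psu_cutoff,
                              coplanarity_tol = thresholds$coplanarity_tol,
                              search_radius = thresholds$env_radius)
  uridines <- screen_uridines(model,
                              cutoff = thresholds$psu_cutoff,
                              coplanarity_tol = thresholds$coplanarity_tol,
                              search_radius = thresholds$env_radius)
  ions <- classify_ions(model, mode = "deposited", thresholds = thresholds,
                        r_max = thresholds$shell_radius)
  confusion <- if (nrow(ions) > 0) cross_validate_ions(ions) else NULL

  pa_keys <- model$residues |>
    filter(.data$category == "polyamine") |>
    arrange(.data$chain, .data$resno) |>
    pull("res_key")
  polyamines <- purrr::map(pa_keys, ~ map_polyamine_contacts(
    model, .x,
    d_min = thresholds$hbond_window[1], d_max = thresholds$hbond_window[2]))
  names(polyamines) <- pa_keys

  structure(
    list(model = model, census = census, psu = psu,
         uridine_screen = uridines, ions = ions, ion_confusion = confusion,
         polyamines = polyamines,
         config = list(thresholds = thresholds, anchor = anchor)),
    class = "ribo_annotation"
  )
}

#' @export
print.ribo_annotation <- function(x, ...) {
  cat("<ribo_annotation>\n")
  print(x$census)
  cat("  ", nrow(x$psu), " pseudouridine assessment(s), ",
      sum(x$uridine_screen$candidate %||% logical(0)),
      " uridine candidate(s)\n", sep = "")
  cat("  ", nrow(x$ions), " ion/water site(s), ",
      length(x$polyamines), " polyamine(s)\n", sep = "")
  invisible(x)
}

#' @method glance ribo_annotation
#' @export
glance.ribo_annotation <- function(x, ...) {
  glance(x$census) |>
    mutate(
      n_psu_supported = sum(x$psu$verdict == "supported"),
      n_uridine_candidates = sum(x$uridine_screen$candidate),
      n_ion_sites = nrow(x$ions),
      n_polyamines = length(x$polyamines)
    )
}

#' Write an annotation bundle to a directory
#'
#' One TSV (and JSON) per report, plus `run_metadata.json` recording the
#' package version, configuration and an MD5 checksum of the input so any
#' reproduction is self-documenting.
#'
#' @param bundle A `ribo_annotation`.
#' @param dir Output directory (created if needed).
#' @param format `"tsv"` or `"json"`.
#' @return `dir`, invisibly.
#' @export
write_annotation <- function(bundle, dir, format = c("tsv", "json")) {
  stopifnot(inherits(bundle, "ribo_annotation"))
  format <- match.arg(format)
  ext <- paste0(".", format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_report(tidy(bundle$census), file.path(dir, paste0("census", ext)), format)
  write_report(glance(bundle$census), file.path(dir, paste0("census_totals", ext)), format)
  write_report(bundle$psu, file.path(dir, paste0("psu_assessments", ext)), format)
  write_report(bundle$uridine_screen, file.path(dir, paste0("uridine_screen", ext)), format)
  write_report(bundle$ions, file.path(dir, paste0("ion_sites", ext)), format)
  if (!is.null(bundle$ion_confusion)) {
    write_report(bundle$ion_confusion, file.path(dir, paste0("ion_confusion", ext)), format)
  }
  if (length(bundle$polyamines) > 0) {
    contacts <- purrr::list_rbind(purrr::map(bundle$polyamines, tidy))
    write_report(contacts, file.path(dir, paste0("polyamine_contacts", ext)), format)
  }
  if (!is.null(bundle$census$reference)) {
    ref <- bundle$census$reference
    for (nm in names(ref)) {
      write_report(ref[[nm]], file.path(dir, paste0("reference_", nm, ext)), format)
    }
  }
  meta <- list(
    package = "ribomod",
    version = as.character(utils::packageVersion("ribomod")),
    input = bundle$model$source,
    input_md5 = unname(tools::md5sum(bundle$model$source)),
    thresholds = bundle$config$thresholds,
    anchor = bundle$config$anchor
  )
  jsonlite::write_json(meta, file.path(dir, "run_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
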