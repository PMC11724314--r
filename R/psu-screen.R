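# partner class from the partner atom's name and residue
classify_partner <- function(atom, comp_id, category) {
  case_when(
    comp_id == "HOH" | category == "water" ~ "water",
    atom %in% phosphate_oxygens ~ "phosphate",
    atom == "O2'" ~ "ribose-O2prime",
    TRUE ~ "other"
  )
}

psu_assessment_cols <- function() {
  tibble(
    res_key = character(), comp_id = character(), chain = character(),
    resno = integer(), probe_atom = character(),
    partner_serial = integer(), partner_atom = character(),
    partner_res_key = character(), distance = double(),
    out_of_plane = double(), partner_class = character(),
    verdict = character()
  )
}

#' Assess the pseudouridine hydrogen-bond pattern of one residue
#'
#' Pseudouridine's C--C glycosidic bond frees N1 as an extra hydrogen-bond
#' donor; in a well-ordered environment that donor binds an acceptor (a
#' water, a neighbouring phosphate oxygen, or a ribose 2'-OH) at a
#' heavy-atom distance below 3.2 Angstrom, lying in the plane of the
#' aromatic ring. For a modelled pseudouridine the probe is N1; for a
#' modelled uridine the probe is C5 -- the atom that would occupy the N1
#' position were the base flipped -- so plain uridines can be screened for a
#' pseudouridine-like acceptor.
#'
#' Verdicts: `supported` (an external O/N acceptor closer than `cutoff`,
#' within `coplanarity_tol` of the base plane), `unsupported` (acceptors
#' exist nearby but none meets the pattern), `unresolved-environment` (no
#' O/N at all within `search_radius`, i.e. no ordered solvent to judge
#' from). The probed residue's own atoms are never counted as partners.
#'
#' @param model A classified `ribo_structure`.
#' @param res_key Residue key of a uridine or pseudouridine.
#' @param cutoff Acceptor distance cutoff, Angstrom, strict `<` (default 3.2).
#' @param coplanarity_tol Maximum perpendicular offset of the acceptor from
#'   the base plane, Angstrom (default 1.0).
#' @param search_radius Radius within which any O/N counts as "ordered
#'   environment", Angstrom (default 6).
#' @return One-row tibble: probe, best partner, distance, out-of-plane
#'   offset, partner class, verdict.
#' @export
assess_pseudouridine <- function(model, res_key, cutoff = 3.2,
                                 coplanarity_tol = 1.0, search_radius = 6) {
  stopifnot(inherits(model, "ribo_structure"))
  res <- model$residues |> filter(.data$res_key == .env$res_key)
  if (nrow(res) == 0) abort(paste0("residue not found: ", res_key))
  is_psu <- !is.na(res$modification_class) &&
    res$modification_class %in% psu_classes
  is_u <- res$comp_id == "U"
  if (!is_psu && !is_u) {
    abort(paste0("residue ", res_key, " is neither uridine nor pseudouridine"))
  }
  probe_name <- if (is_psu) "N1" else "C5"
  probe_serial <- find_atom(model, res_key, probe_name)
  probe <- model$atoms |> filter(.data$serial == .env$probe_serial)
  p <- c(probe$x, probe$y, probe$z)

  covalent <- ribomod_thresholds()$covalent_cutoff
  env <- neighbor_search(model, p, search_radius, exclude = res_key) |>
    filter(.data$element %in% c("N", "O"), .data$distance >= covalent)

  base <- res |>
    select("res_key", "comp_id", "chain", "resno") |>
    mutate(probe_atom = probe_name)

  if (nrow(env) == 0) {
    return(base |> mutate(
      partner_serial = NA_integer_, partner_atom = NA_character_,
      partner_res_key = NA_character_, distance = NA_real_,
      out_of_plane = NA_real_, partner_class = "none",
      verdict = "unresolved-environment"
    ))
  }

  plane <- fit_base_plane(model, res_key)
  env$oop <- vapply(
    seq_len(nrow(env)),
    function(i) out_of_plane(plane, c(env$x[i], env$y[i], env$z[i])),
    numeric(1)
  )
  res_cat <- model$residues |> select("res_key", partner_cat = "category")
  env <- env |> left_join(res_cat, by = "res_key")
  qualifying <- env |>
    filter(.data$distance < cutoff, .data$oop <= coplanarity_tol)

  best <- if (nrow(qualifying) > 0) qualifying[1, ] else env[1, ]
  verdict <- if (nrow(qualifying) > 0) "supported" else "unsupported"

  base |> mutate(
    partner_serial = best$serial,
    partner_atom = best$atom,
    partner_res_key = best$res_key,
    distance = best$distance,
    out_of_plane = best$oop,
    partner_class = classify_partner(best$atom, best$comp_id, best$partner_cat),
    verdict = verdict
  )
}

#' Validate every modelled pseudouridine in a structure
#'
#' One assessment per residue whose modification class is pseudouridine
#' (including the combined 2'-O-methylpseudouridine).
#'
#' @inheritParams assess_pseudouridine
#' @return Tibble of assessments (possibly empty), ordered by chain and
#'   residue number.
#' @export
validate_modeled_psu <- function(model, cutoff = 3.2, coplanarity_tol = 1.0,
                                 search_radius = 6) {
  stopifnot(inherits(model, "ribo_structure"))
  targets <- model$residues |>
    filter(!is.na(.data$modification_class),
           .data$modification_class %in% psu_classes) |>
    arrange(.data$chain, .data$resno, .data$ins)
  if (nrow(targets) == 0) return(psu_assessment_cols())
  purrr::list_rbind(purrr::map(
    targets$res_key,
    ~ assess_pseudouridine(model, .x, cutoff, coplanarity_tol, search_radius)
  ))
}

#' Screen modelled uridines for a pseudouridine-like acceptor
#'
#' Probes the C5 position of every standard uridine; residues whose verdict
#' is `supported` are pseudouridine candidates (`candidate = TRUE`).
#'
#' @inheritParams assess_pseudouridine
#' @return Tibble of assessments with an extra `candidate` column.
#' @export
screen_uridines <- function(model, cutoff = 3.2, coplanarity_tol = 1.0,
                            search_radius = 6) {
  stopifnot(inherits(model, "ribo_structure"))
  targets <- model$residues |>
    filter(.data$comp_id == "U",
           .data$category == "standard-ribonucleotide") |>
    arrange(.data$chain, .data$resno, .data$ins)
  if (nrow(targets) == 0) {
    return(psu_assessment_cols() |> mutate(candidate = logical()))
  }
  purrr::list_rbind(purrr::map(
    targets$res_key,
    ~ assess_pseudouridine(model, .x, cutoff, coplanarity_tol, search_radius)
  )) |>
    mutate(candidate = .data$verdict == "supported")
}
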