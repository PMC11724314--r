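# angle RMS deviation from the nearest ideal octahedral angle (90/180)
octahedral_score <- function(angles) {
  if (length(angles) < 1) return(NA_real_)
  rms(pmin(abs(angles - 90), abs(angles - 180)))
}

# angle RMS deviation from the nearest multiple of 72 (pentagonal shell)
pentagonal_score <- function(angles) {
  if (length(angles) < 1) return(NA_real_)
  rms(pmin(abs(angles - 72), abs(angles - 144)))
}

#' Classify a coordination shell as Mg2+, K+, water or unassigned
#'
#' Mg2+ binds its ligands at covalent-like 1.8--2.4 Angstrom in an octahedral
#' arrangement; K+ at 2.8--3.2 Angstrom in a pentagonal arrangement; water
#' partners sit in the ordinary H-bond window 2.4--3.5. The decision rules
#' (defaults, see [ribomod_thresholds()]):
#' * Mg: >= 4 ligands inside the Mg window and octahedral angle RMS
#'   deviation <= 20 degrees;
#' * K: >= 3 ligands inside the K window, none closer than its lower edge,
#'   and pentagonal angle RMS deviation <= 20 degrees;
#' * water: neither metal rule fires and all partners lie in the H-bond
#'   window;
#' * otherwise unassigned.
#' If both metal rules fire, the label whose mean distance is closer to its
#' window midpoint wins and the conflict is recorded in the rationale.
#'
#' A non-metal centre that is itself a ligand of a metal (a coordination
#' water: nearest metal within the coordination window) is labelled water
#' directly -- its own O/N shell is the metal's ligand cage, not a
#' coordination sphere of its own.
#'
#' @param shell A `ribo_shell` from [coordination_sphere()], extracted with
#'   `r_max` at least the upper K window.
#' @param thresholds See [ribomod_thresholds()].
#' @param nearest_metal Distance from the centre to the nearest metal atom
#'   of another residue, Angstrom (`Inf` if none); filled in by
#'   [classify_ions()].
#' @return One-row tibble: centre identity, ligand counts (total and water),
#'   distance summary, both geometry scores, `label` and `rationale`.
#' @export
classify_site <- function(shell, thresholds = ribomod_thresholds(),
                          nearest_metal = Inf) {
  stopifnot(inherits(shell, "ribo_shell"))
  th <- thresholds
  d <- shell$ligands$distance
  n <- length(d)
  water_ligands <- sum(shell$ligands$comp_id == "HOH")
  oct <- octahedral_score(shell$angles)
  pent <- pentagonal_score(shell$angles)
  centre_is_metal <- shell$center$element %in% metal_elements

  in_mg <- sum(d >= th$mg_window[1] & d <= th$mg_window[2])
  in_k <- sum(d >= th$k_window[1] & d <= th$k_window[2])
  mg_fire <- in_mg >= th$mg_min_ligands && !is.na(oct) && oct <= th$oct_tol
  k_fire <- in_k >= th$k_min_ligands && n > 0 && min(d) >= th$k_window[1] &&
    !is.na(pent) && pent <= th$pent_tol
  in_hb <- n > 0 && all(d >= th$hbond_window[1] & d <= th$hbond_window[2])

  if (!centre_is_metal && nearest_metal <= th$coordination_window[2]) {
    label <- "water"
    rationale <- sprintf("coordination water (metal at %.2f A)", nearest_metal)
  } else if (n == 0) {
    label <- "unassigned"
    rationale <- "empty shell"
  } else if (mg_fire && k_fire) {
    mg_mid <- mean(th$mg_window)
    k_mid <- mean(th$k_window)
    mg_dev <- abs(mean(d[d >= th$mg_window[1] & d <= th$mg_window[2]]) - mg_mid)
    k_dev <- abs(mean(d[d >= th$k_window[1] & d <= th$k_window[2]]) - k_mid)
    label <- if (mg_dev <= k_dev) "Mg" else "K"
    rationale <- paste0("both metal rules fired; mean distance closer to the ",
                        label, " window midpoint")
  } else if (mg_fire) {
    label <- "Mg"
    rationale <- sprintf(
      "%d ligands in [%.2f, %.2f], octahedral deviation %.1f deg",
      in_mg, th$mg_window[1], th$mg_window[2], oct)
  } else if (k_fire) {
    label <- "K"
    rationale <- sprintf(
      "%d ligands in [%.2f, %.2f], pentagonal deviation %.1f deg",
      in_k, th$k_window[1], th$k_window[2], pent)
  } else if (in_hb) {
    label <- "water"
    rationale <- "all partners within the H-bond window, no metal rule fired"
  } else {
    label <- "unassigned"
    rationale <- "no rule fired"
  }

  tibble(
    res_key = shell$center$res_key,
    center_atom = shell$center$atom,
    element = shell$center$element,
    n_ligands = n,
    water_ligands = water_ligands,
    nonwater_ligands = n - water_ligands,
    min_distance = if (n) min(d) else NA_real_,
    mean_distance = if (n) mean(d) else NA_real_,
    max_distance = if (n) max(d) else NA_real_,
    geometry_score_oct = oct,
    geometry_score_pent = pent,
    label = label,
    rationale = rationale
  )
}

# deposited label from the component id
deposited_ion_label <- function(comp_id, category) {
  case_when(
    comp_id == "MG" ~ "Mg",
    comp_id == "K" ~ "K",
    category == "water" ~ "water",
    category == "metal" ~ comp_id,
    TRUE ~ "unassigned"
  )
}

#' Classify every candidate ion/water centre in a model
#'
#' In `deposited` mode each residue of category metal or water is taken as a
#' centre; deposited metals other than Mg/K are passed through with their
#' deposited label and flagged. In `label_stripped` mode all single-atom O or
#' metal centres are treated as unknowns, so the classifier runs blind.
#'
#' @param model A classified `ribo_structure`.
#' @param mode `"deposited"` or `"label_stripped"`.
#' @param thresholds See [ribomod_thresholds()].
#' @param r_max Shell extraction radius, Angstrom.
#' @return Tibble, one row per site, with the [classify_site()] columns plus
#'   `deposited`.
#' @export
classify_ions <- function(model, mode = c("deposited", "label_stripped"),
                          thresholds = ribomod_thresholds(), r_max = 3.5) {
  stopifnot(inherits(model, "ribo_structure"))
  mode <- match.arg(mode)
  if (all(is.na(model$residues$category))) {
    abort("run classify_components() first")
  }
  res <- model$residues
  if (mode == "deposited") {
    centres <- res |> filter(.data$category %in% c("metal", "water"))
  } else {
    single <- res |> filter(.data$n_atoms == 1)
    centres <- single |>
      inner_join(
        model$atoms |> select("res_key", "element"),
        by = "res_key"
      ) |>
      filter(.data$element == "O" | .data$element %in% metal_elements) |>
      select(-"element")
  }
  if (nrow(centres) == 0) {
    return(tibble(
      res_key = character(), center_atom = character(), element = character(),
      n_ligands = integer(), water_ligands = integer(),
      nonwater_ligands = integer(), min_distance = double(),
      mean_distance = double(), max_distance = double(),
      geometry_score_oct = double(), geometry_score_pent = double(),
      label = character(), rationale = character(), deposited = character()
    ))
  }
  centres <- centres |> arrange(.data$chain, .data$resno, .data$ins)
  rows <- purrr::map(seq_len(nrow(centres)), function(i) {
    key <- centres$res_key[[i]]
    at <- model$atoms |> filter(.data$res_key == .env$key)
    if (nrow(at) > 1) at <- at |> filter(.data$element != "H") |> slice(1)
    shell <- coordination_sphere(model, at$serial[[1]], r_max = r_max)
    metals <- model$atoms |>
      filter(.data$element %in% metal_elements, .data$res_key != .env$key)
    nearest_metal <- if (nrow(metals) > 0) {
      min(dist_to_point(metals, c(at$x[[1]], at$y[[1]], at$z[[1]])))
    } else {
      Inf
    }
    site <- classify_site(shell, thresholds, nearest_metal = nearest_metal)
    site$deposited <- deposited_ion_label(centres$comp_id[[i]], centres$category[[i]])
    if (mode == "deposited" && centres$category[[i]] == "metal" &&
        !(centres$comp_id[[i]] %in% c("MG", "K"))) {
      site$label <- centres$comp_id[[i]]
      site$rationale <- "deposited non-Mg/K metal; passed through and flagged"
    }
    site
  })
  purrr::list_rbind(rows)
}

#' Confusion table of deposited versus assigned ion labels
#'
#' Cross-tabulates the deposited identity of each metal/water residue against
#' the geometry-based label. Row sums equal the deposited counts, so a
#' perfectly recovered model gives a diagonal table.
#'
#' @param model A classified `ribo_structure`, or the tibble returned by
#'   [classify_ions()] in deposited mode.
#' @param thresholds See [ribomod_thresholds()].
#' @return Tibble with columns `deposited`, `assigned`, `n` over the full
#'   label grid.
#' @export
cross_validate_ions <- function(model, thresholds = ribomod_thresholds()) {
  sites <- if (inherits(model, "ribo_structure")) {
    classify_ions(model, mode = "deposited", thresholds = thresholds)
  } else {
    model
  }
  labels <- sort(unique(c("Mg", "K", "water", "unassigned",
                          sites$deposited, sites$label)))
  sites |>
    count(.data$deposited, assigned = .data$label) |>
    complete(
      deposited = labels, assigned = labels,
      fill = list(n = 0L)
    )
}
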