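#' Default geometric thresholds
#'
#' One place for every distance window and tolerance the pipeline uses
#' (Angstrom / degrees):
#' * `hbond_window` 2.4--3.5: heavy-atom donor--acceptor distance taken as a
#'   hydrogen bond (hydrogens are not modelled at these resolutions).
#' * `covalent_cutoff` 1.8: pairs closer than this are bonded, never H-bonds.
#' * `mg_window` 1.8--2.4 with >= `mg_min_ligands` ligands and an octahedral
#'   angle RMS deviation <= `oct_tol` identifies Mg2+.
#' * `k_window` 2.55--3.35 (strict mode: the observed 2.8--3.2) with >=
#'   `k_min_ligands` ligands and a pentagonal angle RMS deviation <=
#'   `pent_tol` identifies K+.
#' * `psu_cutoff` 3.2 (strict <) and `coplanarity_tol` 1.0 define the
#'   pseudouridine binding pattern; `env_radius` 6 separates "no pattern"
#'   from "no ordered environment at all".
#'
#' @param strict Use the strictly observed K+ window 2.8--3.2 instead of the
#'   tolerant decision window.
#' @return A named list of thresholds.
#' @export
ribomod_thresholds <- function(strict = FALSE) {
  list(
    hbond_window = c(2.4, 3.5),
    covalent_cutoff = 1.8,
    mg_window = c(1.8, 2.4),
    mg_min_ligands = 4L,
    oct_tol = 20,
    k_window = if (strict) c(2.8, 3.2) else c(2.55, 3.35),
    k_min_ligands = 3L,
    pent_tol = 20,
    shell_radius = 3.5,
    coordination_window = c(1.8, 3.35),
    psu_cutoff = 3.2,
    coplanarity_tol = 1.0,
    env_radius = 6
  )
}

#' Exact radial neighbour search
#'
#' Returns exactly the atoms whose distance to `center` is `<= radius`
#' (closed interval), sorted by distance with ties broken by atom serial.
#' The contract is exactness: results are verified against a brute-force
#' all-pairs scan in the test-suite.
#'
#' @param model A `ribo_structure`.
#' @param center Length-3 numeric, Angstrom.
#' @param radius Search radius, Angstrom (> 0).
#' @param exclude Optional character vector of residue keys to omit.
#' @return Atom tibble with an extra `distance` column.
#' @export
neighbor_search <- function(model, center, radius, exclude = NULL) {
  stopifnot(inherits(model, "ribo_structure"))
  if (!is.numeric(radius) || length(radius) != 1 || radius <= 0) {
    abort("radius must be a positive number")
  }
  at <- model$atoms
  if (!is.null(exclude)) at <- at |> filter(!(.data$res_key %in% exclude))
  at$distance <- dist_to_point(at, center)
  at |>
    filter(.data$distance <= radius) |>
    arrange(.data$distance, .data$serial)
}

# ring-atom name tables; the six-membered ring is always present and is what
# the plane is fitted through (purines additionally carry the imidazole)
ring_atom_table <- list(
  pyrimidine = c("N1", "C2", "N3", "C4", "C5", "C6"),
  purine = c("N9", "C8", "N7", "C5", "C4", "N3", "C2", "N1", "C6"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2"),
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2")
)

ring_atoms_for <- function(atoms) {
  comp <- atoms$comp_id[[1]]
  names_ <- atoms$atom
  if (comp %in% names(ring_atom_table)) {
    return(ring_atom_table[[comp]])
  }
  if ("N9" %in% names_) ring_atom_table$purine else ring_atom_table$pyrimidine
}

#' Least-squares plane through a residue's aromatic ring
#'
#' Fits a plane through the ring atoms (nucleobase ring, or aromatic
#' side-chain ring for His/Phe/Tyr/Trp) by singular value decomposition of
#' the centred coordinates. The normal's sign is fixed (first non-zero
#' component positive) for determinism.
#'
#' @param model A `ribo_structure`.
#' @param res_key Residue key.
#' @return A `ribo_plane`: list with `normal` (unit 3-vector), `centroid`,
#'   `fit_rms` (Angstrom) and `ring_atoms` (tibble).
#' @export
fit_base_plane <- function(model, res_key) {
  stopifnot(inherits(model, "ribo_structure"))
  atoms <- model$atoms |> filter(.data$res_key == .env$res_key)
  if (nrow(atoms) == 0) abort(paste0("residue not found: ", res_key))
  ring <- atoms |> filter(.data$atom %in% ring_atoms_for(atoms))
  if (nrow(ring) < 3) abort("ring incomplete")
  xyz <- coords(ring)
  centroid <- colMeans(xyz)
  centred <- sweep(xyz, 2, centroid)
  sv <- svd(centred)
  normal <- sv$v[, 3]
  nz <- which(abs(normal) > 1e-12)[1]
  if (!is.na(nz) && normal[nz] < 0) normal <- -normal
  resid <- centred %*% normal
  structure(
    list(
      normal = as.numeric(normal),
      centroid = as.numeric(centroid),
      fit_rms = rms(as.numeric(resid)),
      ring_atoms = ring
    ),
    class = "ribo_plane"
  )
}

#' @export
print.ribo_plane <- function(x, ...) {
  cat("<ribo_plane> centroid (", paste(sprintf("%.2f", x$centroid), collapse = ", "),
      "), fit RMS ", sprintf("%.4f", x$fit_rms), " A, ",
      nrow(x$ring_atoms), " ring atoms\n", sep = "")
  invisible(x)
}

# perpendicular offset of a point from a ribo_plane, Angstrom
out_of_plane <- function(plane, p) {
  abs(sum((p - plane$centroid) * plane$normal))
}

#' Heavy-atom hydrogen-bond detection around one atom
#'
#' Hydrogens are absent from sub-2-Angstrom cryo-EM models, so hydrogen bonds
#' are inferred from heavy-atom donor--acceptor distances alone. Partners are
#' O or N atoms within `[d_min, d_max]` (closed); pairs closer than the
#' covalent cutoff (1.8) are bonded, never H-bonds.
#'
#' @param model A `ribo_structure`.
#' @param atom Probe atom serial (see [find_atom()]).
#' @param d_min,d_max Distance window, Angstrom (defaults 2.4 and 3.5).
#' @param elements Partner element filter (default O and N).
#' @param exclude_same_residue Drop all partners from the probe's own residue
#'   (used by the pseudouridine screen, where the pattern is defined by
#'   external partners).
#' @param allow_any_probe Skip the check that the probe itself is O/N (the
#'   uridine C5 probe needs this).
#' @return Tibble of partners with `distance`; sorted by distance, ties by
#'   serial.
#' @export
detect_hbonds <- function(model, atom, d_min = 2.4, d_max = 3.5,
                          elements = c("N", "O"),
                          exclude_same_residue = FALSE,
                          allow_any_probe = FALSE) {
  stopifnot(inherits(model, "ribo_structure"))
  if (d_min >= d_max) abort("d_min must be smaller than d_max")
  probe <- model$atoms |> filter(.data$serial == .env$atom)
  if (nrow(probe) == 0) abort(paste0("no atom with serial ", atom))
  if (!allow_any_probe && !(probe$element %in% elements)) {
    abort(paste0("probe atom is ", probe$element,
                 "; expected one of ", paste(elements, collapse = "/"),
                 " (set allow_any_probe = TRUE to override)"))
  }
  covalent <- ribomod_thresholds()$covalent_cutoff
  p <- c(probe$x, probe$y, probe$z)
  at <- model$atoms |> filter(.data$serial != .env$atom)
  at$distance <- dist_to_point(at, p)
  at <- at |>
    filter(
      .data$element %in% elements,
      .data$distance >= d_min,
      .data$distance <= d_max,
      .data$distance >= covalent
    )
  if (exclude_same_residue) {
    at <- at |> filter(.data$res_key != probe$res_key)
  } else {
    at <- at |> filter(!(.data$res_key == probe$res_key & .data$distance < covalent))
  }
  at |> arrange(.data$distance, .data$serial)
}

#' Extract the coordination shell around a centre atom
#'
#' All O/N atoms within `r_max` of the centre (other residues only), sorted
#' by distance, plus every pairwise ligand--centre--ligand angle.
#'
#' @param model A `ribo_structure`.
#' @param center Centre atom serial.
#' @param r_max Shell radius, Angstrom.
#' @param elements Ligand element filter.
#' @return A `ribo_shell`: list with `center` (one-row atom tibble),
#'   `ligands` (atom tibble + `distance`), `angles` (degrees).
#' @export
coordination_sphere <- function(model, center, r_max = 3.5, elements = c("N", "O")) {
  stopifnot(inherits(model, "ribo_structure"))
  ctr <- model$atoms |> filter(.data$serial == .env$center)
  if (nrow(ctr) == 0) abort(paste0("no atom with serial ", center))
  p <- c(ctr$x, ctr$y, ctr$z)
  at <- model$atoms |>
    filter(.data$serial != .env$center, .data$res_key != ctr$res_key,
           .data$element %in% elements)
  at$distance <- dist_to_point(at, p)
  ligands <- at |>
    filter(.data$distance <= r_max, .data$distance > 0) |>
    arrange(.data$distance, .data$serial)
  angles <- numeric(0)
  if (nrow(ligands) >= 2) {
    xyz <- coords(ligands)
    idx <- utils::combn(nrow(ligands), 2)
    angles <- vapply(
      seq_len(ncol(idx)),
      function(k) angle_deg(xyz[idx[1, k], ], p, xyz[idx[2, k], ]),
      numeric(1)
    )
  }
  structure(
    list(center = ctr, ligands = ligands, angles = angles, r_max = r_max),
    class = "ribo_shell"
  )
}

#' @export
print.ribo_shell <- function(x, ...) {
  cat("<ribo_shell> centre ", x$center$res_key, " (", x$center$atom, "), ",
      nrow(x$ligands), " ligand(s) within ", x$r_max, " A\n", sep = "")
  invisible(x)
}

#' @method tidy ribo_shell
#' @export
tidy.ribo_shell <- function(x, ...) {
  x$ligands |>
    select("serial", "atom", "element", "comp_id", "res_key", "distance") |>
    mutate(center_key = x$center$res_key, .before = 1)
}
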