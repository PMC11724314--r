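# --- minimal mmCIF atom_site writer -----------------------------------------
# No installed R package writes mmCIF, so the fixture generator carries its
# own writer. It emits the full canonical wwPDB atom_site column layout
# (which is also what bio3d's CIF reader expects) and quotes primed atom
# names. Coordinates are fixed to 3 decimals so regeneration from the same
# seed is byte-identical.

mmcif_quote <- function(x) ifelse(grepl("'", x), paste0('"', x, '"'), x)

#' Write an atom table as a minimal mmCIF file
#'
#' The low-level emitter behind the fixture generators; also usable directly
#' to build bespoke synthetic structures in tests. Only the `atom_site`
#' loop is written.
#'
#' @param atoms Tibble with at least `atom`, `element`, `x`, `y`, `z`,
#'   `comp_id`, `chain`, `resno`; optional `record` ("ATOM"/"HETATM",
#'   default "HETATM"), `ins`, `occ`, `b`, `altloc`.
#' @param path Output path.
#' @param data_name mmCIF data block name.
#' @return `path`, invisibly.
#' @export
write_synthetic_mmcif <- function(atoms, path, data_name = "synthetic") {
  atoms <- as_tibble(atoms)
  n <- nrow(atoms)
  if (!"record" %in% names(atoms)) atoms$record <- "HETATM"
  if (!"ins" %in% names(atoms)) atoms$ins <- ""
  if (!"occ" %in% names(atoms)) atoms$occ <- 1
  if (!"b" %in% names(atoms)) atoms$b <- 20
  if (!"altloc" %in% names(atoms)) atoms$altloc <- ""
  header <- c(
    paste0("data_", data_name),
    "#",
    "loop_",
    paste0("_atom_site.", c(
      "group_PDB", "id", "type_symbol", "label_atom_id", "label_alt_id",
      "label_comp_id", "label_asym_id", "label_entity_id", "label_seq_id",
      "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
      "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id", "auth_comp_id",
      "auth_asym_id", "auth_atom_id", "pdbx_PDB_model_num"
    ))
  )
  lines <- sprintf(
    "%s %d %s %s %s %s %s 1 %d %s %.3f %.3f %.3f %.2f %.2f ? %d %s %s %s 1",
    atoms$record, seq_len(n), atoms$element, mmcif_quote(atoms$atom),
    ifelse(atoms$altloc == "", ".", atoms$altloc),
    atoms$comp_id, atoms$chain, atoms$resno,
    ifelse(atoms$ins == "", "?", atoms$ins),
    atoms$x, atoms$y, atoms$z, atoms$occ, atoms$b,
    atoms$resno, atoms$comp_id, atoms$chain, mmcif_quote(atoms$atom)
  )
  writeLines(c(header, lines, "#"), path)
  invisible(path)
}

write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a fixture manifest
#' @param path Path to a `.manifest.json` written by a fixture generator.
#' @return The manifest as a list; the `sites` element is a tibble.
#' @export
read_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(m$sites)) m$sites <- as_tibble(m$sites)
  m
}

# ideal direction sets
octahedral_dirs <- function() {
  rbind(diag(3), -diag(3))
}
pentagonal_dirs <- function() {
  th <- (0:4) * 2 * pi / 5
  cbind(cos(th), sin(th), 0)
}
tetrahedral_dirs <- function() {
  rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
}

# jitter a ligand position, keeping the centre distance inside `window`;
# bounded retries so an out-of-spec site is never emitted
jitter_ligand <- function(centre, ideal_pos, sigma, window, max_tries = 500) {
  for (i in seq_len(max_tries)) {
    p <- ideal_pos + rnorm(3, 0, sigma)
    d <- vnorm(p - centre)
    if (d >= window[1] && d <= window[2]) return(p)
  }
  abort("could not keep a planted ligand inside its distance window")
}

# cubic-lattice site centres, spacing Angstrom
site_grid <- function(n, spacing) {
  k <- ceiling(n^(1 / 3))
  idx <- seq_len(n) - 1
  cbind(idx %% k, (idx %/% k) %% k, idx %/% (k * k)) * spacing
}

atom_row <- function(atom, element, pos, comp_id, chain, resno,
                     record = "HETATM") {
  tibble(record = record, atom = atom, element = element,
         x = pos[1], y = pos[2], z = pos[3],
         comp_id = comp_id, chain = chain, resno = resno)
}

# --- ion field ---------------------------------------------------------------

#' Generate a synthetic ion/water field with a ground-truth manifest
#'
#' Plants jittered octahedral Mg2+ sites (ligand distances uniform in
#' 1.8--2.4 Angstrom), planar-pentagonal K+ sites (2.8--3.2) and waters with
#' 1--3 tetrahedrally arranged partners (2.6--3.4), each site on a lattice
#' with >= 12 Angstrom separation so shells never cross-talk. Ligands mix
#' phosphate-like oxygens of an unmapped ligand component with water
#' oxygens, mirroring the deposited coordination patterns. Jitter that would
#' push a planted distance out of its window is re-drawn (bounded retries);
#' an out-of-spec site is never emitted. Regeneration with the same
#' arguments is byte-identical.
#'
#' @param n_mg,n_k,n_water Site counts (>= 0).
#' @param jitter_sigma Gaussian jitter on each ligand coordinate, Angstrom.
#' @param seed Integer seed; recorded in the manifest.
#' @param path Output mmCIF path; the manifest is written to
#'   `<path>.manifest.json`.
#' @param mg_water_ligands,k_water_ligands How many of the 6 (Mg) / 5 (K)
#'   ligands are waters rather than ligand oxygens/nitrogens.
#' @return List with `structure` (path), `manifest_path` and `manifest`
#'   (list; `sites` is a tibble keyed by residue).
#' @export
make_ion_field <- function(n_mg, n_k, n_water, jitter_sigma = 0.05, seed = 1,
                           path = tempfile(fileext = ".cif"),
                           mg_water_ligands = 2L, k_water_ligands = 3L) {
  stopifnot(n_mg >= 0, n_k >= 0, n_water >= 0)
  withr::with_seed(seed, {
    n_sites <- n_mg + n_k + n_water
    centres <- site_grid(max(1, n_sites), 14)
    kinds <- c(rep("Mg", n_mg), rep("K", n_k), rep("water", n_water))
    rows <- list()
    sites <- list()
    resno <- 0L
    for (i in seq_len(n_sites)) {
      ctr <- centres[i, ]
      kind <- kinds[i]
      rot <- random_rotation()
      resno <- resno + 1L
      centre_resno <- resno
      if (kind == "Mg") {
        rows[[length(rows) + 1]] <- atom_row("MG", "MG", ctr, "MG", "A", resno)
        dirs <- octahedral_dirs() %*% t(rot)
        dists <- runif(6, 1.8, 2.4)
        water_idx <- sample(6, mg_water_ligands)
        for (j in 1:6) {
          p <- jitter_ligand(ctr, ctr + dists[j] * dirs[j, ], jitter_sigma,
                             c(1.8, 2.4))
          resno <- resno + 1L
          rows[[length(rows) + 1]] <- if (j %in% water_idx) {
            atom_row("O", "O", p, "HOH", "A", resno)
          } else {
            atom_row("OP1", "O", p, "LGX", "A", resno)
          }
        }
        key <- make_res_key("A", centre_resno, "", "MG")
      } else if (kind == "K") {
        rows[[length(rows) + 1]] <- atom_row("K", "K", ctr, "K", "A", resno)
        dirs <- pentagonal_dirs() %*% t(rot)
        dists <- runif(5, 2.8, 3.2)
        water_idx <- sample(5, k_water_ligands)
        for (j in 1:5) {
          p <- jitter_ligand(ctr, ctr + dists[j] * dirs[j, ], jitter_sigma,
                             c(2.8, 3.2))
          resno <- resno + 1L
          rows[[length(rows) + 1]] <- if (j %in% water_idx) {
            atom_row("O", "O", p, "HOH", "A", resno)
          } else {
            atom_row("N7", "N", p, "LGX", "A", resno)
          }
        }
        key <- make_res_key("A", centre_resno, "", "K")
      } else {
        rows[[length(rows) + 1]] <- atom_row("O", "O", ctr, "HOH", "A", resno)
        n_partners <- sample(1:3, 1)
        dirs <- (tetrahedral_dirs() %*% t(rot))[seq_len(n_partners), ,
                                                drop = FALSE]
        dists <- runif(n_partners, 2.6, 3.4)
        for (j in seq_len(n_partners)) {
          p <- jitter_ligand(ctr, ctr + dists[j] * dirs[j, ], jitter_sigma,
                             c(2.6, 3.4))
          resno <- resno + 1L
          rows[[length(rows) + 1]] <- atom_row("OP1", "O", p, "LGX", "A", resno)
        }
        key <- make_res_key("A", centre_resno, "", "HOH")
      }
      sites[[length(sites) + 1]] <- tibble(
        kind = kind, res_key = key, chain = "A", resno = centre_resno,
        comp_id = c(Mg = "MG", K = "K", water = "HOH")[[kind]]
      )
    }
    atoms <- purrr::list_rbind(rows)
    site_tbl <- purrr::list_rbind(sites)
    if (nrow(site_tbl) >= 2) {
      cd <- as.matrix(stats::dist(centres[seq_len(nrow(site_tbl)), ,
                                          drop = FALSE]))
      stopifnot(min(cd[upper.tri(cd)]) >= 12)
    }
    if (nrow(atoms) == 0) {
      # valid empty structure: a single placeholder comment-only file is not
      # parseable, so emit one far-away carbon sentinel? No -- an empty model
      # must error on load; write the header with zero atom rows instead.
      writeLines(c("data_empty", "#"), path)
    } else {
      write_synthetic_mmcif(atoms, path, "ion_field")
    }
    manifest <- list(
      generator = "make_ion_field",
      seed = seed,
      jitter_sigma = jitter_sigma,
      counts = list(mg = n_mg, k = n_k, water = n_water),
      sites = site_tbl
    )
    manifest_path <- paste0(path, ".manifest.json")
    write_manifest(manifest, manifest_path)
    list(structure = path, manifest_path = manifest_path, manifest = manifest)
  })
}

# --- pseudouridine cases -----------------------------------------------------

# build one pyrimidine-like hexagonal ring (1.4 A bonds) in a random plane;
# returns list(atoms, probe position, in-plane outward dir at probe, normal)
build_ring <- function(centre, comp_id, chain, resno, probe_name = "N1") {
  rot <- random_rotation()
  u <- rot[, 1]
  v <- rot[, 2]
  nrm <- rot[, 3]
  names_ <- c("N1", "C2", "N3", "C4", "C5", "C6")
  elements <- substr(names_, 1, 1)
  th <- (0:5) * pi / 3
  pos <- t(vapply(th, function(a) centre + 1.4 * (cos(a) * u + sin(a) * v),
                  numeric(3)))
  atoms <- purrr::list_rbind(purrr::map(1:6, function(i) {
    atom_row(names_[i], elements[i], pos[i, ], comp_id, chain, resno,
             record = "ATOM")
  }))
  k <- match(probe_name, names_)
  probe <- pos[k, ]
  list(atoms = atoms, probe = probe,
       outward = unitize(probe - centre), normal = nrm)
}

psu_partner_atom <- function(partner_class, pos, chain, resno) {
  switch(partner_class,
    water = atom_row("O", "O", pos, "HOH", chain, resno),
    phosphate = atom_row("OP1", "O", pos, "LGX", chain, resno),
    `ribose-O2prime` = atom_row("O2'", "O", pos, "LGX", chain, resno),
    abort(paste0("unknown partner class: ", partner_class))
  )
}

#' Generate the canonical pseudouridine test cases
#'
#' Four planted pseudouridines exercise every verdict the screen can return:
#' an in-plane acceptor at 3.0 Angstrom (`supported`), an acceptor at 3.4
#' (`unsupported`: beyond the 3.2 cutoff), an in-window acceptor displaced
#' 2.0 Angstrom out of the base plane (`unsupported`: fails coplanarity) and
#' a bare ring with no O/N within 6 Angstrom (`unresolved-environment`).
#' Acceptor chemistry cycles through the three partner classes (water,
#' phosphate oxygen, ribose 2'-O). Two uridines are added for the C5 screen:
#' one with an in-plane water at 3.1 Angstrom (a candidate) and one with its
#' nearest acceptor at 3.4 (not a candidate).
#'
#' @param seed Integer seed.
#' @param path Output mmCIF path; manifest at `<path>.manifest.json`.
#' @return List with `structure`, `manifest_path`, `manifest` (the `sites`
#'   tibble carries the expected verdicts).
#' @export
make_psu_cases <- function(seed = 1, path = tempfile(fileext = ".cif")) {
  withr::with_seed(seed, {
    centres <- site_grid(6, 14)
    cases <- tibble(
      resno = 1:6,
      comp_id = c("PSU", "PSU", "PSU", "PSU", "U", "U"),
      kind = c("psu-supported", "psu-far", "psu-out-of-plane", "psu-bare",
               "u-candidate", "u-noncandidate"),
      partner_class = c("water", "phosphate", "ribose-O2prime", "none",
                        "water", "water"),
      distance = c(3.0, 3.4, 3.0, NA, 3.1, 3.4),
      out_of_plane = c(0, 0, 2.0, NA, 0, 0),
      expected_verdict = c("supported", "unsupported", "unsupported",
                           "unresolved-environment", "supported",
                           "unsupported")
    )
    rows <- list()
    keys <- character(nrow(cases))
    partner_resno <- 100L
    for (i in seq_len(nrow(cases))) {
      probe_name <- if (cases$comp_id[i] == "PSU") "N1" else "C5"
      ring <- build_ring(centres[i, ], cases$comp_id[i], "A", cases$resno[i],
                         probe_name)
      rows[[length(rows) + 1]] <- ring$atoms
      keys[i] <- make_res_key("A", cases$resno[i], "", cases$comp_id[i])
      if (cases$partner_class[i] != "none") {
        d <- cases$distance[i]
        h <- cases$out_of_plane[i]
        in_plane <- sqrt(d^2 - h^2)
        pos <- ring$probe + in_plane * ring$outward + h * ring$normal
        partner_resno <- partner_resno + 1L
        rows[[length(rows) + 1]] <- psu_partner_atom(
          cases$partner_class[i], pos, "A", partner_resno)
      }
    }
    atoms <- purrr::list_rbind(rows)
    write_synthetic_mmcif(atoms, path, "psu_cases")
    manifest <- list(
      generator = "make_psu_cases",
      seed = seed,
      sites = cases |> mutate(res_key = keys, .before = 1)
    )
    manifest_path <- paste0(path, ".manifest.json")
    write_manifest(manifest, manifest_path)
    list(structure = path, manifest_path = manifest_path, manifest = manifest)
  })
}

#' Plant a single uridine/pseudouridine with one acceptor at a set geometry
#'
#' The workhorse behind distance-sweep and coplanarity properties: one ring,
#' one acceptor at exactly `distance` Angstrom from the probe atom with a
#' chosen perpendicular offset from the base plane. The geometry is
#' axis-aligned (ring in the z = 0 plane, probe at the origin, in-plane
#' acceptor along +x) so the planted distance survives the 3-decimal
#' coordinate serialisation exactly; frame invariance is a separate property
#' tested with [transform_structure()].
#'
#' @param distance Probe--acceptor distance, Angstrom (at most 3 decimals
#'   for exactness).
#' @param out_of_plane Perpendicular offset of the acceptor, Angstrom.
#' @param partner_class `"water"`, `"phosphate"` or `"ribose-O2prime"`.
#' @param comp_id `"PSU"` or `"U"`.
#' @param path Output mmCIF path.
#' @return List with `structure` (path) and `res_key` of the planted residue.
#' @export
make_psu_single <- function(distance, out_of_plane = 0,
                            partner_class = "water", comp_id = "PSU",
                            path = tempfile(fileext = ".cif")) {
  probe_name <- if (comp_id == "PSU") "N1" else "C5"
  names_ <- c("N1", "C2", "N3", "C4", "C5", "C6")
  k <- match(probe_name, names_)
  th <- (0:5) * pi / 3
  centre <- -1.4 * c(cos(th[k]), sin(th[k]), 0)
  rows <- purrr::map(1:6, function(i) {
    pos <- centre + 1.4 * c(cos(th[i]), sin(th[i]), 0)
    atom_row(names_[i], substr(names_[i], 1, 1), pos, comp_id, "A", 1L,
             record = "ATOM")
  })
  in_plane <- sqrt(distance^2 - out_of_plane^2)
  pos <- c(in_plane, 0, out_of_plane)
  atoms <- bind_rows(purrr::list_rbind(rows),
                     psu_partner_atom(partner_class, pos, "A", 101L))
  write_synthetic_mmcif(atoms, path, "psu_single")
  list(structure = path, res_key = make_res_key("A", 1L, "", comp_id))
}

# --- toy assembly ------------------------------------------------------------

polyamine_atom_names <- list(
  PUT = c("N1", "C2", "C3", "C4", "N5"),
  SPD = c("N1", "C2", "C3", "C4", "N5", "C6", "C7", "C8", "N9"),
  SPM = c("N1", "C2", "C3", "C4", "N5", "C6", "C7", "C8", "N9",
          "C10", "C11", "C12", "N13")
)

# a polyamine arranged on a circle (arc length 1.5 A per bond), with two
# phosphate-oxygen anchors at the terminal amines and one water bridge
build_polyamine <- function(centre, comp_id, chain, resno, anchor_resno) {
  names_ <- polyamine_atom_names[[comp_id]]
  n <- length(names_)
  r <- max(2.0, n * 1.5 / (2 * pi) * 1.15)
  rot <- random_rotation()
  u <- rot[, 1]; v <- rot[, 2]; nrm <- rot[, 3]
  th <- (seq_len(n) - 1) * (1.5 / r)
  pos <- t(vapply(th, function(a) centre + r * (cos(a) * u + sin(a) * v),
                  numeric(3)))
  atoms <- purrr::list_rbind(purrr::map(seq_len(n), function(i) {
    atom_row(names_[i], substr(names_[i], 1, 1), pos[i, ], comp_id, chain,
             resno)
  }))
  extras <- list()
  for (k in c(1, n)) {
    radial <- unitize(pos[k, ] - centre)
    anchor_resno <- anchor_resno + 1L
    extras[[length(extras) + 1]] <- atom_row(
      "OP1", "O", pos[k, ] + 2.9 * radial, "LGX", chain, anchor_resno)
  }
  water_pos <- pos[1, ] + 2.85 * nrm
  anchor_resno <- anchor_resno + 1L
  extras[[length(extras) + 1]] <- atom_row("O", "O", water_pos, "HOH", chain,
                                           anchor_resno)
  anchor_resno <- anchor_resno + 1L
  extras[[length(extras) + 1]] <- atom_row(
    "OP2", "O", water_pos + 2.8 * nrm, "LGX", chain, anchor_resno)
  list(atoms = bind_rows(atoms, purrr::list_rbind(extras)),
       next_resno = anchor_resno)
}

nm_comps <- c("OMC", "OMG", "OMU", "A2M")
base_mod_comps <- c(m1A = "1MA", m4C = "M4C", m5C = "5MC", m6A = "6MZ",
                    m3U = "UR3")

#' Default toy-assembly specification
#'
#' Counts per planted feature; matches the worked example used throughout
#' the tests (3 pseudouridines, 4 ribose methylations, 1 combined
#' 2'-O-methylpseudouridine, 2 spermidines, purine filler).
#' @param ... Overrides, e.g. `toy_spec(psu = 5, put = 1)`.
#' @return A named list.
#' @export
toy_spec <- function(...) {
  modifyList(
    list(psu = 3L, nm = 4L, combined = 1L, base = c(),
         standard = 4L, spd = 2L, spm = 0L, put = 0L),
    list(...)
  )
}

#' Generate a multi-chain toy assembly with a known modification manifest
#'
#' Builds an RNA chain `R` carrying the requested modified and standard
#' nucleotides (idealised hexagonal rings), and a ligand chain `S` with
#' polyamines anchored to phosphate oxygens and bridged through waters.
#' Everything the census, the pseudouridine validator, the polyamine mapper
#' and the reference comparison should find is predicted by the manifest.
#' Sites sit on a 20-Angstrom lattice (>= 12 Angstrom separation verified
#' post-generation).
#'
#' @param spec See [toy_spec()].
#' @param seed Integer seed.
#' @param path Output mmCIF path; manifest at `<path>.manifest.json`.
#' @return List with `structure`, `manifest_path`, `manifest`; the manifest
#'   carries `sites`, predicted census `totals`, a `roles` chain map and a
#'   `reference` modification list (tibble rows chain_role/auth_number/class)
#'   derived from the planted sites.
#' @export
make_toy_assembly <- function(spec = toy_spec(), seed = 1,
                              path = tempfile(fileext = ".cif")) {
  withr::with_seed(seed, {
    base_counts <- spec$base %||% c()
    nt_plan <- c(
      rep("PSU", spec$psu),
      nm_comps[(seq_len(spec$nm) - 1) %% length(nm_comps) + 1],
      rep("PSM", spec$combined),
      rep(base_mod_comps[names(base_counts)], base_counts),
      rep(c("G", "A"), length.out = spec$standard)
    )
    pa_plan <- c(rep("SPD", spec$spd), rep("SPM", spec$spm),
                 rep("PUT", spec$put))
    n_sites <- length(nt_plan) + length(pa_plan)
    centres <- site_grid(max(1, n_sites), 20)
    rows <- list()
    sites <- list()
    i_site <- 0L
    resno <- 0L
    for (comp in nt_plan) {
      i_site <- i_site + 1L
      resno <- resno + 1L
      ring <- build_ring(centres[i_site, ], comp, "R", resno)
      rows[[length(rows) + 1]] <- ring$atoms
      sites[[length(sites) + 1]] <- tibble(
        kind = "nucleotide", comp_id = comp, chain = "R", resno = resno,
        res_key = make_res_key("R", resno, "", comp)
      )
    }
    pa_resno <- 0L
    extra_resno <- 1000L
    for (comp in pa_plan) {
      i_site <- i_site + 1L
      pa_resno <- pa_resno + 1L
      built <- build_polyamine(centres[i_site, ], comp, "S", pa_resno,
                               extra_resno)
      extra_resno <- built$next_resno
      rows[[length(rows) + 1]] <- built$atoms
      sites[[length(sites) + 1]] <- tibble(
        kind = "polyamine", comp_id = comp, chain = "S", resno = pa_resno,
        res_key = make_res_key("S", pa_resno, "", comp)
      )
    }
    atoms <- purrr::list_rbind(rows)
    if (is.null(atoms) || nrow(atoms) == 0) {
      writeLines(c("data_empty", "#"), path)
      atoms <- tibble()
    } else {
      write_synthetic_mmcif(atoms, path, "toy_assembly")
    }
    site_tbl <- if (length(sites)) purrr::list_rbind(sites) else
      tibble(kind = character(), comp_id = character(), chain = character(),
             resno = integer(), res_key = character())
    if (n_sites >= 2) {
      cd <- as.matrix(stats::dist(centres[seq_len(n_sites), , drop = FALSE]))
      stopifnot(min(cd[upper.tri(cd)]) >= 12)
    }
    n_base <- sum(base_counts)
    totals <- list(
      psu_tally = spec$psu + spec$combined,
      nm_tally = spec$nm + spec$combined,
      base_tally = n_base,
      combined = spec$combined,
      total_rrna_modifications = spec$psu + spec$nm + spec$combined + n_base,
      total_protein_modifications = 0L,
      n_polyamines = length(pa_plan)
    )
    class_of <- c(
      PSU = "pseudouridine", PSM = "combined",
      setNames(rep("ribose-2prime-O-methyl", length(nm_comps)), nm_comps),
      setNames(names(base_mod_comps), base_mod_comps)
    )
    reference <- site_tbl |>
      filter(.data$kind == "nucleotide",
             .data$comp_id %in% names(class_of)) |>
      transmute(chain_role = "28S", auth_number = .data$resno,
                class = unname(class_of[.data$comp_id]))
    manifest <- list(
      generator = "make_toy_assembly",
      seed = seed,
      spec = spec,
      roles = list(R = "28S", S = "ligands"),
      sites = site_tbl,
      totals = totals,
      reference = reference
    )
    manifest_path <- paste0(path, ".manifest.json")
    write_manifest(manifest, manifest_path)
    list(structure = path, manifest_path = manifest_path, manifest = manifest)
  })
}
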