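shell_of <- function(atoms, comp, atom) {
  m <- local_model(atoms)
  coordination_sphere(m, find_atom(m, paste0("A:1::", comp), atom))
}

test_that("canonical coordination patterns get their textbook labels", {
  # octahedral site, ligand distances spread over the Mg window
  oct <- octahedron_atoms(r = 2.1)
  oct$x[2] <- 1.85; oct$x[5] <- -2.35   # spread two trans ligands
  site <- classify_site(shell_of(oct, "MG", "MG"))
  expect_equal(site$label, "Mg")

  # pentagonal site at K distances
  site_k <- classify_site(shell_of(pentagon_atoms(r = 3.0), "K", "K"))
  expect_equal(site_k$label, "K")

  # empty shell
  iso <- test_atom(0, 0, 0, atom = "MG", element = "MG", comp_id = "MG")
  site_e <- classify_site(shell_of(iso, "MG", "MG"))
  expect_equal(site_e$label, "unassigned")
  expect_match(site_e$rationale, "empty")

  # water with two partners at 2.8 and 3.0
  wat <- dplyr::bind_rows(
    test_atom(0, 0, 0, resno = 1L),
    test_atom(2.8, 0, 0, resno = 2L, comp_id = "LGX", atom = "OP1"),
    test_atom(0, 3.0, 0, resno = 3L, comp_id = "LGX", atom = "OP1")
  )
  site_w <- classify_site(shell_of(wat, "HOH", "O"))
  expect_equal(site_w$label, "water")
})

test_that("a 5-ligand octahedral fragment is still Mg (rule needs only 4)", {
  oct <- octahedron_atoms(r = 2.1)[-7, ]   # drop one ligand
  site <- classify_site(shell_of(oct, "MG", "MG"))
  expect_equal(site$label, "Mg")
})

test_that("water ligand counts follow the complex formula n + (6 - n)", {
  f <- make_ion_field(5, 0, 0, jitter_sigma = 0.02, seed = 9,
                      mg_water_ligands = 2)
  m <- classify_components(read_structure(f$structure))
  sites <- classify_ions(m, "deposited")
  mg <- sites[sites$deposited == "Mg", ]
  expect_equal(mg$water_ligands, rep(2L, 5))
  expect_equal(mg$water_ligands + mg$nonwater_ligands, mg$n_ligands)
})

test_that("classify_ions recovers every planted label on a jittered field", {
  f <- make_ion_field(20, 20, 20, jitter_sigma = 0.05, seed = 1)
  m <- classify_components(read_structure(f$structure))
  sites <- classify_ions(m, "deposited")
  j <- dplyr::inner_join(f$manifest$sites, sites, by = "res_key")
  expect_equal(nrow(j), 60)
  expect_equal(j$label, j$kind)

  # label-stripped mode reaches the same answers for the planted centres
  stripped <- classify_ions(m, "label_stripped")
  js <- dplyr::inner_join(f$manifest$sites, stripped, by = "res_key")
  expect_equal(js$label, js$kind)
})

test_that("a model without metals or waters yields an empty site list", {
  m <- local_model(hexagon_atoms(comp_id = "U"))
  expect_equal(nrow(classify_ions(m, "deposited")), 0)
})

test_that("labels are invariant under rigid transforms and ligand order", {
  f <- make_ion_field(5, 5, 5, jitter_sigma = 0.05, seed = 23)
  m <- classify_components(read_structure(f$structure))
  base <- classify_ions(m, "deposited")
  mt <- transform_structure(m, test_rotation(), c(-3, 8, 12))
  expect_equal(classify_ions(mt, "deposited")$label, base$label)
  # permute atom order on disk and reload
  perm <- withr::with_seed(4, sample(nrow(m$atoms)))
  path <- withr::local_tempfile(fileext = ".cif")
  write_synthetic_mmcif(m$atoms[perm, ], path)
  m2 <- classify_components(read_structure(path))
  sites2 <- classify_ions(m2, "deposited")
  j <- dplyr::inner_join(base, sites2, by = "res_key")
  expect_equal(j$label.y, j$label.x)
})

test_that("uniformly scaling an Mg site never flips back towards Mg", {
  labels <- character(0)
  for (s in c(1, 1.1, 1.25, 1.45, 1.6, 2.0)) {
    site <- classify_site(shell_of(octahedron_atoms(r = 2.1 * s), "MG", "MG"))
    labels <- c(labels, site$label)
  }
  expect_equal(labels[1], "Mg")
  left_mg <- which(labels != "Mg")[1]
  expect_false(any(labels[left_mg:length(labels)] == "Mg"))
  # once ligands leave the shell radius the site is unassigned
  expect_equal(labels[length(labels)], "unassigned")
  # water can only appear after the Mg window is left
  expect_false(any(labels[seq_len(left_mg - 1)] == "water"))
})

test_that("recovery degrades monotonically with jitter", {
  recovery <- function(sigma, seed) {
    f <- make_ion_field(10, 10, 10, jitter_sigma = sigma, seed = seed)
    m <- classify_components(read_structure(f$structure))
    sites <- classify_ions(m, "deposited")
    j <- dplyr::inner_join(f$manifest$sites, sites, by = "res_key")
    mean(j$label == j$kind)
  }
  rates <- vapply(c(0.05, 0.15, 0.3), function(s) {
    mean(vapply(1:3, function(r) recovery(s, seed = 100 + r), numeric(1)))
  }, numeric(1))
  expect_equal(rates[1], 1)
  expect_true(all(diff(rates) <= 0))
})

test_that("cross-validation is diagonal for a clean field and flags one planted mislabel", {
  f <- make_ion_field(4, 4, 4, jitter_sigma = 0.02, seed = 13,
                      mg_water_ligands = 0, k_water_ligands = 0)
  m <- classify_components(read_structure(f$structure))
  sites <- classify_ions(m, "deposited")
  conf <- cross_validate_ions(sites)
  off <- conf[conf$deposited != conf$assigned, ]
  expect_equal(sum(off$n), 0)
  # row sums equal deposited counts
  rows <- conf |> dplyr::summarise(n = sum(n), .by = deposited)
  dep <- sites |> dplyr::count(deposited)
  j <- dplyr::inner_join(rows, dep, by = "deposited")
  expect_equal(j$n.x, j$n.y)

  # deposit an octahedral site as K: exactly one off-diagonal entry
  at <- m$atoms
  mg1 <- f$manifest$sites$res_key[f$manifest$sites$kind == "Mg"][1]
  at$comp_id[at$res_key == mg1] <- "K"
  at$atom[at$res_key == mg1] <- "K"
  at$element[at$res_key == mg1] <- "K"
  m2 <- classify_components(read_structure({
    p <- withr::local_tempfile(fileext = ".cif")
    write_synthetic_mmcif(at, p)
    p
  }))
  conf2 <- cross_validate_ions(classify_ions(m2, "deposited"))
  off2 <- conf2[conf2$deposited != conf2$assigned & conf2$n > 0, ]
  expect_equal(nrow(off2), 1)
  expect_equal(off2$deposited, "K")
  expect_equal(off2$assigned, "Mg")
})

test_that("waters inside a metal's ligand cage are labelled as coordination waters", {
  f <- make_ion_field(4, 4, 0, jitter_sigma = 0.05, seed = 6,
                      mg_water_ligands = 2, k_water_ligands = 3)
  m <- classify_components(read_structure(f$structure))
  sites <- classify_ions(m, "deposited")
  lig_waters <- sites[sites$deposited == "water", ]
  expect_gt(nrow(lig_waters), 0)
  expect_true(all(lig_waters$label == "water"))
  expect_true(all(grepl("coordination water", lig_waters$rationale)))
})

test_that("non-Mg/K metals are passed through with their deposited label", {
  atoms <- dplyr::bind_rows(
    test_atom(0, 0, 0, atom = "ZN", element = "ZN", comp_id = "ZN",
              resno = 1L),
    test_atom(2.1, 0, 0, resno = 2L, comp_id = "LGX", atom = "OP1")
  )
  m <- local_model(atoms)
  sites <- classify_ions(m, "deposited")
  expect_equal(sites$label, "ZN")
  expect_match(sites$rationale, "passed through")
})
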