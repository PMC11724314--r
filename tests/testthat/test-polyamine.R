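test_that("planted polyamines anchor to phosphates and bridge through water", {
  t <- make_toy_assembly(toy_spec(psu = 0, nm = 0, combined = 0, standard = 0,
                                  spd = 0, put = 1), seed = 41)
  m <- classify_components(read_structure(t$structure))
  key <- t$manifest$sites$res_key[t$manifest$sites$kind == "polyamine"][1]
  pa <- map_polyamine_contacts(m, key)
  expect_equal(pa$species, "PUT")
  # both terminal amines see a phosphate oxygen at 2.9
  phos <- pa$contacts[pa$contacts$partner_class == "phosphate-O", ]
  expect_equal(nrow(phos), 2)
  expect_equal(phos$distance, c(2.9, 2.9), tolerance = 0.01)
  expect_setequal(phos$amine_atom, c("N1", "N5"))
  # one amine-water-partner bridge with both legs in-window
  expect_equal(nrow(pa$water_bridges), 1)
  wb <- pa$water_bridges
  expect_equal(wb$d_amine_water, 2.85, tolerance = 0.01)
  expect_equal(wb$d_water_partner, 2.8, tolerance = 0.01)
})

test_that("water-bridge legs re-validate independently through detect_hbonds", {
  t <- make_toy_assembly(toy_spec(psu = 0, nm = 0, combined = 0, standard = 0,
                                  spd = 1, spm = 1), seed = 12)
  m <- classify_components(read_structure(t$structure))
  keys <- t$manifest$sites$res_key[t$manifest$sites$kind == "polyamine"]
  for (key in keys) {
    pa <- map_polyamine_contacts(m, key)
    for (i in seq_len(nrow(pa$water_bridges))) {
      wb <- pa$water_bridges[i, ]
      amine <- find_atom(m, key, wb$amine_atom)
      water <- find_atom(m, wb$water_res_key, "O")
      leg1 <- detect_hbonds(m, amine, exclude_same_residue = TRUE)
      expect_true(water %in% leg1$serial)
      leg2 <- detect_hbonds(m, water, exclude_same_residue = TRUE)
      expect_true(wb$partner_serial %in% leg2$serial)
    }
  }
})

test_that("an isolated polyamine has no contacts and non-polyamines are refused", {
  atoms <- tibble::tibble(
    record = "HETATM",
    atom = c("N1", "C2", "C3", "C4", "N5"),
    element = c("N", "C", "C", "C", "N"),
    x = c(0, 1.5, 3, 4.5, 6), y = 0, z = 0,
    comp_id = "PUT", chain = "A", resno = 1L
  )
  m <- local_model(atoms)
  pa <- map_polyamine_contacts(m, "A:1::PUT")
  expect_equal(nrow(pa$contacts), 0)
  expect_equal(nrow(pa$water_bridges), 0)
  m2 <- local_model(hexagon_atoms(comp_id = "U"))
  expect_error(map_polyamine_contacts(m2, "A:1::U"), "not a polyamine")
})

test_that("network expansion is truncated, monotone and seed-order independent", {
  m <- local_model(make_cloud(250, box = 22, seed = 19))
  seeds <- c(5L, 120L)
  net0 <- hbond_network(m, seeds, max_depth = 0)
  expect_setequal(net0$nodes$serial, seeds)
  expect_equal(nrow(net0$edges), 0)

  sizes <- vapply(0:4, function(k) {
    nrow(hbond_network(m, seeds, max_depth = k)$nodes)
  }, numeric(1))
  expect_true(all(diff(sizes) >= 0))
  n2 <- hbond_network(m, seeds, max_depth = 2)$nodes$serial
  n3 <- hbond_network(m, seeds, max_depth = 3)$nodes$serial
  expect_true(all(n2 %in% n3))

  expect_equal(hbond_network(m, rev(seeds), max_depth = 3)$nodes$serial, n3)
  expect_error(hbond_network(m, integer(0), 2), "empty")
})

test_that("network node sets match the exhaustive path-enumeration oracle", {
  m <- local_model(make_cloud(250, box = 22, seed = 19))
  for (seed_atom in c(5L, 60L, 200L)) {
    for (k in 0:3) {
      got <- sort(hbond_network(m, seed_atom, max_depth = k)$nodes$serial)
      want <- enumerate_network_nodes(m, seed_atom, k)
      expect_equal(got, want)
    }
  }
})

test_that("networks cross metal coordination bonds", {
  # water -H-bond- water -coordination- Mg -coordination- water
  atoms <- dplyr::bind_rows(
    test_atom(0, 0, 0, resno = 1L),
    test_atom(3.0, 0, 0, resno = 2L),
    test_atom(5.1, 0, 0, atom = "MG", element = "MG", comp_id = "MG",
              resno = 3L),
    test_atom(7.2, 0, 0, resno = 4L),
    test_atom(30, 30, 30, resno = 5L)      # disconnected
  )
  m <- local_model(atoms)
  net <- hbond_network(m, find_atom(m, "A:1::HOH", "O"), max_depth = 3)
  expect_setequal(net$nodes$serial, 1:4)
  expect_setequal(unique(net$edges$kind), c("hbond", "coordination"))
})

test_that("network export writes GraphML and TSV that round-trip node counts", {
  m <- local_model(make_cloud(80, box = 14, seed = 5))
  net <- hbond_network(m, 1L, max_depth = 3)
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_network(net, gml, format = "graphml")
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g), nrow(net$nodes))
  expect_equal(igraph::ecount(g), nrow(net$edges))
  base <- withr::local_tempfile()
  paths <- write_network(net, base, format = "tsv")
  expect_equal(nrow(readr::read_tsv(paste0(base, "_nodes.tsv"),
                                    show_col_types = FALSE)),
               nrow(net$nodes))
})

test_that("stacking descriptors reproduce constructed ring arrangements", {
  # identical rings translated 3.4 A along the shared normal
  stacked <- dplyr::bind_rows(
    hexagon_atoms(centre = c(0, 0, 0), resno = 1L, comp_id = "U"),
    hexagon_atoms(centre = c(0, 0, 3.4), resno = 2L, comp_id = "U")
  )
  m <- local_model(stacked)
  d <- stacking_descriptor(m, "A:1::U", "A:2::U")
  expect_equal(d$plane_distance, 3.4, tolerance = 1e-6)
  expect_equal(d$angle, 0, tolerance = 1e-6)
  expect_equal(d$lateral_offset, 0, tolerance = 1e-6)

  # coplanar side-by-side rings
  side <- dplyr::bind_rows(
    hexagon_atoms(centre = c(0, 0, 0), resno = 1L, comp_id = "U"),
    hexagon_atoms(centre = c(8, 0, 0), resno = 2L, comp_id = "U")
  )
  m2 <- local_model(side)
  d2 <- stacking_descriptor(m2, "A:1::U", "A:2::U")
  expect_equal(d2$plane_distance, 0, tolerance = 1e-6)
  expect_equal(d2$angle, 0, tolerance = 1e-6)
  expect_equal(d2$lateral_offset, 8, tolerance = 1e-6)
})

test_that("contact maps are invariant under rigid-body transforms", {
  t <- make_toy_assembly(toy_spec(psu = 0, nm = 0, combined = 0, standard = 0,
                                  spd = 1), seed = 3)
  m <- classify_components(read_structure(t$structure))
  key <- t$manifest$sites$res_key[t$manifest$sites$kind == "polyamine"][1]
  base <- map_polyamine_contacts(m, key)
  mt <- transform_structure(m, test_rotation(9), c(4, 4, -9))
  moved <- map_polyamine_contacts(mt, key)
  expect_equal(moved$contacts$partner_serial, base$contacts$partner_serial)
  expect_equal(moved$contacts$distance, base$contacts$distance,
               tolerance = 1e-6)
})
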