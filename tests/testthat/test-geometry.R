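test_that("neighbor_search honours the closed interval and sort contract", {
  atoms <- dplyr::bind_rows(
    test_atom(3, 0, 0, resno = 1L),
    test_atom(0, 5, 0, resno = 2L),
    test_atom(0, 0, 7, resno = 3L)
  )
  m <- local_model(atoms)
  expect_error(neighbor_search(m, c(0, 0, 0), 0), "positive")
  expect_error(neighbor_search(m, c(0, 0, 0), -1), "positive")
  # radius below the nearest atom -> empty
  expect_equal(nrow(neighbor_search(m, c(0, 0, 0), 2.999)), 0)
  # atom exactly at distance == radius is included (closed interval)
  hit <- neighbor_search(m, c(0, 0, 0), 5)
  expect_equal(hit$distance, c(3, 5))
  # excluded residues are omitted
  expect_equal(nrow(neighbor_search(m, c(0, 0, 0), 5,
                                    exclude = c("A:1::HOH", "A:2::HOH"))), 0)
})

test_that("neighbor_search equals the brute-force all-pairs oracle on a random cloud", {
  m <- local_model(make_cloud(2000, box = 40, seed = 31))
  centres <- list(c(5, 5, 5), c(20, 20, 20), c(35, 10, 25))
  for (ctr in centres) {
    got <- neighbor_search(m, ctr, 5)
    expect_equal(got$serial[order(got$serial)], brute_neighbors(m, ctr, 5))
    # sorted by distance, ties by serial
    expect_true(all(diff(got$distance) >= 0))
  }
})

test_that("neighbourhoods are symmetric: b in shell(a) iff a in shell(b)", {
  m <- local_model(make_cloud(300, box = 25, seed = 8))
  at <- m$atoms
  for (i in c(1, 50, 150, 300)) {
    a <- c(at$x[i], at$y[i], at$z[i])
    nb <- neighbor_search(m, a, 6)
    for (j in head(setdiff(nb$serial, i), 5)) {
      b <- c(at$x[j], at$y[j], at$z[j])
      back <- neighbor_search(m, b, 6)
      expect_true(i %in% back$serial)
    }
  }
})

test_that("a planar hexagon fits with zero residual and the analytic normal", {
  m <- local_model(hexagon_atoms(), classify = FALSE)
  plane <- fit_base_plane(m, "A:1::U")
  expect_lt(plane$fit_rms, 1e-9)
  expect_equal(abs(sum(plane$normal * c(0, 0, 1))), 1, tolerance = 1e-9)
})

test_that("a displaced ring atom reproduces the independent least-squares residual", {
  atoms <- hexagon_atoms()
  atoms$z[3] <- 0.3   # one atom 0.3 A out of plane
  m <- local_model(atoms, classify = FALSE)
  plane <- fit_base_plane(m, "A:1::U")
  oracle <- plane_rms_oracle(as.matrix(m$atoms[, c("x", "y", "z")]))
  expect_equal(plane$fit_rms, oracle, tolerance = 1e-6)
  expect_gt(plane$fit_rms, 0)
})

test_that("plane fitting needs at least three ring atoms", {
  atoms <- hexagon_atoms()[1:2, ]
  m <- local_model(atoms, classify = FALSE)
  expect_error(fit_base_plane(m, "A:1::U"), "ring incomplete")
})

test_that("H-bond detection applies the element filter and distance window", {
  atoms <- dplyr::bind_rows(
    test_atom(0, 0, 0, resno = 1L),
    test_atom(3.0, 0, 0, resno = 2L, atom = "C1", element = "C",
              comp_id = "LGX"),                       # carbon: never an H-bond
    test_atom(0, 3.1, 0, resno = 3L),                 # water O at 3.1
    test_atom(0, 0, 3.6, resno = 4L)                  # beyond d_max
  )
  m <- local_model(atoms)
  probe <- find_atom(m, "A:1::HOH", "O")
  hb <- detect_hbonds(m, probe)
  expect_equal(nrow(hb), 1)
  expect_equal(hb$distance, 3.1, tolerance = 1e-9)
  expect_error(detect_hbonds(m, probe, d_min = 3.5, d_max = 3.5), "d_min")
  # carbon probes are rejected unless overridden
  cprobe <- find_atom(m, "A:2::LGX", "C1")
  expect_error(detect_hbonds(m, cprobe), "probe")
  expect_silent(detect_hbonds(m, cprobe, allow_any_probe = TRUE))
})

test_that("an ideal octahedron yields the textbook angle set", {
  m <- local_model(octahedron_atoms(r = 2.1))
  shell <- coordination_sphere(m, find_atom(m, "A:1::MG", "MG"))
  expect_equal(nrow(shell$ligands), 6)
  expect_equal(shell$ligands$distance, rep(2.1, 6), tolerance = 1e-6)
  ang <- sort(shell$angles)
  expect_equal(ang, c(rep(90, 12), rep(180, 3)), tolerance = 1e-6)
  # isolated centre -> empty shell
  iso <- local_model(test_atom(0, 0, 0, atom = "MG", element = "MG",
                               comp_id = "MG"))
  expect_equal(nrow(coordination_sphere(iso, 1)$ligands), 0)
})

test_that("a jittered octahedron matches direct recomputation from its coordinates", {
  f <- make_ion_field(1, 0, 0, jitter_sigma = 0.05, seed = 17,
                      mg_water_ligands = 0)
  m <- classify_components(read_structure(f$structure))
  ctr <- find_atom(m, f$manifest$sites$res_key[1], "MG")
  shell <- coordination_sphere(m, ctr)
  at <- m$atoms
  p <- c(at$x[ctr], at$y[ctr], at$z[ctr])
  lig <- at[at$comp_id == "LGX", ]
  d_direct <- sort(sqrt((lig$x - p[1])^2 + (lig$y - p[2])^2 + (lig$z - p[3])^2))
  expect_equal(sort(shell$ligands$distance), d_direct, tolerance = 1e-12)
  xyz <- as.matrix(lig[, c("x", "y", "z")])
  idx <- utils::combn(nrow(lig), 2)
  ang_direct <- sort(vapply(seq_len(ncol(idx)), function(k) {
    u <- xyz[idx[1, k], ] - p; v <- xyz[idx[2, k], ] - p
    acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
  }, numeric(1)))
  expect_equal(sort(shell$angles), ang_direct, tolerance = 1e-9)
})

test_that("geometric outputs are invariant under a rigid-body transform", {
  rot <- test_rotation()
  shift <- c(11.3, -7.2, 4.9)

  atoms <- hexagon_atoms()
  atoms$z[2] <- 0.25
  m <- local_model(atoms, classify = FALSE)
  mt <- transform_structure(m, rot, shift)
  expect_equal(fit_base_plane(mt, "A:1::U")$fit_rms,
               fit_base_plane(m, "A:1::U")$fit_rms, tolerance = 1e-9)

  cloud <- local_model(make_cloud(200, box = 20, seed = 3))
  cloudt <- transform_structure(cloud, rot, shift)
  probe <- 7L
  expect_equal(detect_hbonds(cloudt, probe)$distance,
               detect_hbonds(cloud, probe)$distance, tolerance = 1e-6)
  expect_equal(detect_hbonds(cloudt, probe)$serial,
               detect_hbonds(cloud, probe)$serial)

  mo <- local_model(octahedron_atoms())
  mot <- transform_structure(mo, rot, shift)
  c0 <- find_atom(mo, "A:1::MG", "MG")
  expect_equal(sort(coordination_sphere(mot, c0)$angles),
               sort(coordination_sphere(mo, c0)$angles), tolerance = 1e-6)
})
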