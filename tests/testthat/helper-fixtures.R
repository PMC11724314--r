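# shared builders and independent oracles for the test-suite
# (fixtures are generated programmatically; nothing is stored on disk)

# write an atom tibble to a temp mmCIF and load it back, classified
local_model <- function(atoms, classify = TRUE) {
  path <- withr::local_tempfile(fileext = ".cif", .local_envir = parent.frame())
  write_synthetic_mmcif(atoms, path)
  m <- read_structure(path)
  if (classify) m <- classify_components(m) else m
}

# one atom row, defaulting to a free water oxygen
test_atom <- function(x, y, z, atom = "O", element = "O", comp_id = "HOH",
                      chain = "A", resno = 1L, record = "HETATM") {
  tibble::tibble(record = record, atom = atom, element = element,
                 x = x, y = y, z = z, comp_id = comp_id, chain = chain,
                 resno = resno)
}

# random cloud of single-atom water residues in a cubic box
make_cloud <- function(n, box = 40, seed = 1) {
  withr::with_seed(seed, {
    tibble::tibble(
      record = "HETATM", atom = "O", element = "O",
      x = round(runif(n, 0, box), 3),
      y = round(runif(n, 0, box), 3),
      z = round(runif(n, 0, box), 3),
      comp_id = "HOH", chain = "A", resno = seq_len(n)
    )
  })
}

# brute-force all-pairs oracle for neighbor_search
brute_neighbors <- function(model, center, radius) {
  at <- model$atoms
  d <- sqrt((at$x - center[1])^2 + (at$y - center[2])^2 + (at$z - center[3])^2)
  sort(at$serial[d <= radius])
}

# exhaustive path-enumeration oracle for hbond_network node sets: all atoms
# reachable from a seed by paths of <= depth steps, each step an O/N pair
# within [d_min, d_max] (no metals in the clouds this is used on)
enumerate_network_nodes <- function(model, seeds, depth,
                                    d_min = 2.4, d_max = 3.5) {
  at <- model$atoms
  xyz <- as.matrix(at[, c("x", "y", "z")])
  dm <- as.matrix(stats::dist(xyz))
  on <- at$element %in% c("N", "O")
  adj <- dm >= d_min & dm <= d_max & outer(on, on, "&")
  diag(adj) <- FALSE
  reach <- function(serial, k) {
    if (k == 0) return(serial)
    out <- serial
    for (nb in at$serial[adj[which(at$serial == serial), ]]) {
      out <- union(out, reach(nb, k - 1))
    }
    out
  }
  sort(unique(unlist(lapply(seeds, reach, k = depth))))
}

# exact hexagon in the z = 0 plane (planar by construction even after
# 3-decimal serialisation); pyrimidine atom names
hexagon_atoms <- function(centre = c(0, 0, 0), radius = 1.4, comp_id = "U",
                          resno = 1L, chain = "A") {
  names_ <- c("N1", "C2", "N3", "C4", "C5", "C6")
  th <- (0:5) * pi / 3
  purrr::list_rbind(purrr::map(1:6, function(i) {
    test_atom(centre[1] + radius * cos(th[i]), centre[2] + radius * sin(th[i]),
              centre[3], atom = names_[i], element = substr(names_[i], 1, 1),
              comp_id = comp_id, resno = resno, chain = chain,
              record = "ATOM")
  }))
}

# axis-aligned ideal octahedron site: centre atom plus 6 ligands
octahedron_atoms <- function(r = 2.1, centre_comp = "MG", ligand_comp = "LGX") {
  dirs <- rbind(diag(3), -diag(3))
  centre <- test_atom(0, 0, 0, atom = "MG", element = "MG",
                      comp_id = centre_comp, resno = 1L)
  ligands <- purrr::list_rbind(purrr::map(1:6, function(i) {
    test_atom(r * dirs[i, 1], r * dirs[i, 2], r * dirs[i, 3],
              atom = "OP1", comp_id = ligand_comp, resno = i + 1L)
  }))
  dplyr::bind_rows(centre, ligands)
}

# planar pentagon site for K+
pentagon_atoms <- function(r = 3.0, centre_comp = "K", ligand_comp = "LGX") {
  th <- (0:4) * 2 * pi / 5
  centre <- test_atom(0, 0, 0, atom = "K", element = "K",
                      comp_id = centre_comp, resno = 1L)
  ligands <- purrr::list_rbind(purrr::map(1:5, function(i) {
    test_atom(round(r * cos(th[i]), 3), round(r * sin(th[i]), 3), 0,
              atom = "OP1", comp_id = ligand_comp, resno = i + 1L)
  }))
  dplyr::bind_rows(centre, ligands)
}

# a fixed, well-conditioned rotation for invariance checks
test_rotation <- function(seed = 42) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(9), 3, 3)
    q <- qr.Q(qr(m))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    q
  })
}

# independent numerical plane-fit oracle: minimise the residual RMS over
# plane orientation + offset directly (no SVD)
plane_rms_oracle <- function(xyz) {
  obj <- function(par) {
    n <- c(sin(par[1]) * cos(par[2]), sin(par[1]) * sin(par[2]), cos(par[1]))
    d <- xyz %*% n - par[3]
    mean(d^2)
  }
  best <- Inf
  for (start in list(c(0.1, 0.1, 0), c(1, 1, 0), c(2, -1, 1))) {
    o <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
    best <- min(best, o$value)
  }
  sqrt(best)
}
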