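# base-ring and exocyclic O/N atoms of nucleobases (partner class "base")
nucleobase_atoms <- c(
  "N1", "C2", "N3", "C4", "C5", "C6", "N7", "C8", "N9",
  "O2", "O4", "O6", "N2", "N4", "N6"
)

# partner class for polyamine contacts
polyamine_partner_class <- function(atom, comp_id, category) {
  case_when(
    comp_id == "HOH" | category == "water" ~ "water",
    atom %in% phosphate_oxygens | comp_id == "PO4" ~ "phosphate-O",
    grepl("amino-acid", category) ~ "protein",
    atom %in% ribose_oxygens & grepl("ribonucleotide", category) ~ "ribose",
    atom %in% nucleobase_atoms & grepl("ribonucleotide", category) ~ "base",
    TRUE ~ "other"
  )
}

#' Map the binding environment of one polyamine
#'
#' Polyamines (putrescine, spermidine, spermine) are aliphatic polycations
#' whose amine nitrogens hydrogen-bond to phosphate oxygens, waters, bases
#' and proteins. For every amine nitrogen of the residue this lists all
#' partners within the H-bond window, classified, and enumerates
#' amine--water--partner bridges (both legs in-window).
#'
#' @param model A classified `ribo_structure`.
#' @param res_key Residue key of a polyamine.
#' @param d_min,d_max H-bond window, Angstrom.
#' @return A `ribo_polyamine`: list with `res_key`, `species` (SPM/SPD/PUT),
#'   `contacts` tibble (amine atom, partner, class, distance) and
#'   `water_bridges` tibble (amine, water, second-shell partner, two
#'   distances).
#' @export
map_polyamine_contacts <- function(model, res_key, d_min = 2.4, d_max = 3.5) {
  stopifnot(inherits(model, "ribo_structure"))
  res <- model$residues |> filter(.data$res_key == .env$res_key)
  if (nrow(res) == 0) abort(paste0("residue not found: ", res_key))
  if (is.na(res$category) || res$category != "polyamine") {
    abort(paste0("residue ", res_key, " is not a polyamine"))
  }
  res_cat <- model$residues |> select("res_key", partner_cat = "category")
  amines <- model$atoms |>
    filter(.data$res_key == .env$res_key, .data$element == "N")

  contact_rows <- purrr::map(seq_len(nrow(amines)), function(i) {
    partners <- detect_hbonds(model, amines$serial[[i]], d_min, d_max,
                              exclude_same_residue = TRUE)
    if (nrow(partners) == 0) return(NULL)
    partners |>
      left_join(res_cat, by = "res_key") |>
      transmute(
        amine_atom = amines$atom[[i]],
        amine_serial = amines$serial[[i]],
        partner_serial = .data$serial,
        partner_atom = .data$atom,
        partner_res_key = .data$res_key,
        partner_class = polyamine_partner_class(
          .data$atom, .data$comp_id, .data$partner_cat),
        distance = .data$distance
      )
  })
  contacts <- purrr::list_rbind(purrr::compact(contact_rows))
  if (is.null(contacts) || nrow(contacts) == 0) {
    contacts <- tibble(
      amine_atom = character(), amine_serial = integer(),
      partner_serial = integer(), partner_atom = character(),
      partner_res_key = character(), partner_class = character(),
      distance = double()
    )
  }

  bridge_rows <- contacts |>
    filter(.data$partner_class == "water")
  bridges <- purrr::map(seq_len(nrow(bridge_rows)), function(i) {
    w <- bridge_rows[i, ]
    second <- detect_hbonds(model, w$partner_serial, d_min, d_max,
                            exclude_same_residue = TRUE) |>
      filter(.data$res_key != .env$res_key)
    if (nrow(second) == 0) return(NULL)
    second |>
      left_join(res_cat, by = "res_key") |>
      transmute(
        amine_atom = w$amine_atom,
        water_res_key = w$partner_res_key,
        partner_serial = .data$serial,
        partner_atom = .data$atom,
        partner_res_key = .data$res_key,
        partner_class = polyamine_partner_class(
          .data$atom, .data$comp_id, .data$partner_cat),
        d_amine_water = w$distance,
        d_water_partner = .data$distance
      )
  })
  water_bridges <- purrr::list_rbind(purrr::compact(bridges))
  if (is.null(water_bridges) || nrow(water_bridges) == 0) {
    water_bridges <- tibble(
      amine_atom = character(), water_res_key = character(),
      partner_serial = integer(), partner_atom = character(),
      partner_res_key = character(), partner_class = character(),
      d_amine_water = double(), d_water_partner = double()
    )
  }

  structure(
    list(res_key = res_key, species = res$comp_id,
         contacts = contacts, water_bridges = water_bridges),
    class = "ribo_polyamine"
  )
}

#' @export
print.ribo_polyamine <- function(x, ...) {
  cat("<ribo_polyamine> ", x$species, " ", x$res_key, ": ",
      nrow(x$contacts), " contact(s), ", nrow(x$water_bridges),
      " water bridge(s)\n", sep = "")
  invisible(x)
}

#' @method tidy ribo_polyamine
#' @export
tidy.ribo_polyamine <- function(x, ...) {
  x$contacts |> mutate(res_key = x$res_key, species = x$species, .before = 1)
}

#' Trace a hydrogen-bond network from seed atoms
#'
#' Breadth-first expansion over heavy-atom H-bond edges between O/N atoms,
#' crossing waters freely; when a metal is encountered its coordination
#' bonds (1.8--3.35 Angstrom) are crossed as well. Expansion stops at
#' `max_depth` steps from the nearest seed. Node and edge order is
#' deterministic (by atom serial), and the node set is independent of seed
#' iteration order.
#'
#' @param model A `ribo_structure`.
#' @param seeds Integer vector of seed atom serials (see [find_atom()]).
#' @param max_depth Maximum number of bonds from a seed (>= 0).
#' @param d_min,d_max H-bond window, Angstrom.
#' @param coordination_window Metal coordination-bond window, Angstrom.
#' @return A `ribo_network`: list with `nodes` (atom tibble + `depth`),
#'   `edges` (`from`, `to`, `distance`, `kind`), `seeds`, `max_depth`.
#' @export
hbond_network <- function(model, seeds, max_depth, d_min = 2.4, d_max = 3.5,
                          coordination_window = c(1.8, 3.35)) {
  stopifnot(inherits(model, "ribo_structure"))
  if (length(seeds) == 0) abort("seed set is empty")
  if (max_depth < 0) abort("max_depth must be >= 0")
  seeds <- sort(unique(as.integer(seeds)))
  if (!all(seeds %in% model$atoms$serial)) abort("unknown seed atom serial")
  covalent <- ribomod_thresholds()$covalent_cutoff

  atoms <- model$atoms
  is_metal <- atoms$element %in% metal_elements

  # neighbours of one atom under the network chemistry rules
  expand_atom <- function(serial) {
    a <- atoms[atoms$serial == serial, ]
    p <- c(a$x, a$y, a$z)
    metal_centre <- is_metal[atoms$serial == serial]
    d <- dist_to_point(atoms, p)
    if (metal_centre) {
      sel <- atoms$element %in% c("N", "O") &
        d >= coordination_window[1] & d <= coordination_window[2] &
        atoms$serial != serial
      kind <- rep("coordination", sum(sel))
    } else {
      hb <- atoms$element %in% c("N", "O") &
        d >= d_min & d <= d_max & d >= covalent &
        atoms$serial != serial &
        !(atoms$res_key == a$res_key & d < covalent)
      met <- is_metal &
        d >= coordination_window[1] & d <= coordination_window[2]
      sel <- hb | met
      kind <- ifelse(met[sel], "coordination", "hbond")
    }
    tibble(to = atoms$serial[sel], distance = d[sel], kind = kind) |>
      arrange(.data$to)
  }

  depth <- setNames(rep(NA_integer_, nrow(atoms)), atoms$serial)
  depth[as.character(seeds)] <- 0L
  frontier <- seeds
  edges <- list()
  level <- 0L
  while (level < max_depth && length(frontier) > 0) {
    next_frontier <- integer(0)
    for (s in frontier) {
      nb <- expand_atom(s)
      if (nrow(nb) == 0) next
      nb <- nb |> mutate(from = s, .before = 1)
      edges[[length(edges) + 1]] <- nb
      new <- nb$to[is.na(depth[as.character(nb$to)])]
      depth[as.character(new)] <- level + 1L
      next_frontier <- c(next_frontier, new)
    }
    frontier <- sort(unique(next_frontier))
    level <- level + 1L
  }

  node_serials <- as.integer(names(depth)[!is.na(depth)])
  nodes <- atoms |>
    filter(.data$serial %in% node_serials) |>
    mutate(depth = as.integer(depth[as.character(.data$serial)])) |>
    select("serial", "atom", "element", "comp_id", "res_key",
           "x", "y", "z", "depth") |>
    arrange(.data$depth, .data$serial)

  edge_tbl <- if (length(edges) > 0) {
    purrr::list_rbind(edges) |>
      mutate(
        a = pmin(.data$from, .data$to),
        b = pmax(.data$from, .data$to)
      ) |>
      distinct(.data$a, .data$b, .keep_all = TRUE) |>
      transmute(from = .data$a, to = .data$b,
                distance = .data$distance, kind = .data$kind) |>
      arrange(.data$from, .data$to)
  } else {
    tibble(from = integer(), to = integer(),
           distance = double(), kind = character())
  }

  structure(
    list(nodes = nodes, edges = edge_tbl, seeds = seeds,
         max_depth = as.integer(max_depth)),
    class = "ribo_network"
  )
}

#' @export
print.ribo_network <- function(x, ...) {
  cat("<ribo_network> ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " edges (", length(x$seeds), " seed(s), depth <= ", x$max_depth,
      ")\n", sep = "")
  invisible(x)
}

#' @method tidy ribo_network
#' @export
tidy.ribo_network <- function(x, ...) x$edges

#' @method glance ribo_network
#' @export
glance.ribo_network <- function(x, ...) {
  tibble(
    n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
    n_seeds = length(x$seeds), max_depth = x$max_depth,
    n_hbond = sum(x$edges$kind == "hbond"),
    n_coordination = sum(x$edges$kind == "coordination")
  )
}

#' Convert a network to an igraph object
#'
#' @param network A `ribo_network`.
#' @return An undirected igraph graph with `distance`/`kind` edge attributes.
#' @export
as_igraph_network <- function(network) {
  stopifnot(inherits(network, "ribo_network"))
  nodes <- network$nodes |>
    mutate(name = as.character(.data$serial)) |>
    select("name", "atom", "element", "comp_id", "res_key", "depth")
  edges <- network$edges |>
    mutate(from = as.character(.data$from), to = as.character(.data$to))
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
}

#' Export a network as node/edge TSVs or GraphML
#'
#' @param network A `ribo_network`.
#' @param path Output path; for `format = "tsv"` two files are written,
#'   `<path>_nodes.tsv` and `<path>_edges.tsv`.
#' @param format `"tsv"` or `"graphml"`.
#' @return The path(s) written, invisibly.
#' @export
write_network <- function(network, path, format = c("tsv", "graphml")) {
  stopifnot(inherits(network, "ribo_network"))
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(as_igraph_network(network), path, format = "graphml")
    return(invisible(path))
  }
  paths <- paste0(path, c("_nodes.tsv", "_edges.tsv"))
  write_report(network$nodes |> select(-"x", -"y", -"z"), paths[1], "tsv")
  write_report(network$edges, paths[2], "tsv")
  invisible(paths)
}

#' Base-stacking geometry descriptors for two rings
#'
#' Purely geometric descriptors -- no energy model: the distance between the
#' ring planes along the shared normal, the angle between the plane normals
#' (folded to 0--90 degrees) and the lateral centroid offset in the plane.
#' Parallel rings ~3.4 Angstrom apart with small angle and offset are the
#' classic stacking arrangement.
#'
#' @param model A `ribo_structure`.
#' @param res_a,res_b Residue keys; both need a fittable ring
#'   (nucleobase or aromatic side chain).
#' @return One-row tibble: `plane_distance` (Angstrom), `angle` (degrees),
#'   `lateral_offset` (Angstrom).
#' @export
stacking_descriptor <- function(model, res_a, res_b) {
  pa <- fit_base_plane(model, res_a)
  pb <- fit_base_plane(model, res_b)
  nb <- pb$normal
  if (sum(pa$normal * nb) < 0) nb <- -nb
  n_mean <- unitize(pa$normal + nb)
  d <- pb$centroid - pa$centroid
  along <- sum(d * n_mean)
  ct <- min(1, abs(sum(pa$normal * pb$normal)))
  tibble(
    res_a = res_a,
    res_b = res_b,
    plane_distance = abs(along),
    angle = acos(ct) * 180 / pi,
    lateral_offset = sqrt(max(0, sum(d^2) - along^2))
  )
}
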