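#' Minimum heavy-atom distance from a residue to an anchor residue set
#'
#' Used to measure how modifications cluster around the peptidyl transferase
#' centre; the default anchor in a full 60S model is the catalytic base
#' (28S A4397), supplied by the caller as residue keys. The metric is the
#' minimum over all heavy-atom pairs, which is deterministic and agnostic to
#' which atom pair a figure legend meant.
#'
#' @param model A `ribo_structure`.
#' @param res_key Residue key.
#' @param anchor Character vector of anchor residue keys.
#' @return Distance in Angstrom.
#' @export
distance_to_ptc <- function(model, res_key, anchor) {
  stopifnot(inherits(model, "ribo_structure"))
  a <- model$atoms |> filter(.data$res_key == .env$res_key)
  b <- model$atoms |> filter(.data$res_key %in% anchor)
  if (nrow(a) == 0) abort(paste0("residue not found: ", res_key))
  if (nrow(b) == 0) {
    abort(paste0("PTC anchor not found: ", paste(anchor, collapse = ", ")))
  }
  xa <- coords(a)
  xb <- coords(b)
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
  sqrt(max(0, min(d2)))
}

#' Census of chemical modifications in a structure
#'
#' Inventories every modified residue per chain and class, applying the
#' combined-class tally rule: a 2'-O-methylpseudouridine is one modified
#' position that adds +1 to both the pseudouridine and the ribose
#' 2'-O-methyl tallies, so
#' `total RNA positions = psu_tally + nm_tally + base_tally - combined`.
#' Optionally measures each position's distance to a PTC anchor.
#'
#' @param model A classified `ribo_structure`.
#' @param anchor Optional character vector of anchor residue keys for
#'   [distance_to_ptc()].
#' @return A `ribo_census`: list with `positions` (per-residue rows, ordered
#'   by chain then residue number), `class_counts` (per chain x class),
#'   `totals` (named list) and `reference` (`NULL` until
#'   [compare_reference()] fills it).
#' @export
modification_census <- function(model, anchor = NULL) {
  stopifnot(inherits(model, "ribo_structure"))
  if (all(is.na(model$residues$category))) {
    abort("run classify_components() first")
  }
  res <- model$residues
  if (!"role" %in% names(res)) {
    res <- res |> left_join(model$chain_roles, by = "chain")
  }
  positions <- res |>
    filter(.data$category %in% c("modified-ribonucleotide", "modified-amino-acid")) |>
    transmute(
      res_key = .data$res_key, chain = .data$chain, role = .data$role,
      resno = .data$resno, ins = .data$ins, comp_id = .data$comp_id,
      class = .data$modification_class,
      kind = ifelse(.data$category == "modified-ribonucleotide", "rna", "protein")
    ) |>
    arrange(.data$chain, .data$resno, .data$ins)
  if (!is.null(anchor)) {
    positions$distance_to_ptc <- vapply(
      positions$res_key, function(k) distance_to_ptc(model, k, anchor), numeric(1)
    )
  }
  class_counts <- positions |> count(.data$chain, .data$class, name = "n")

  n_combined <- sum(positions$class == "combined")
  totals <- list(
    psu_tally = sum(positions$class %in% psu_classes),
    nm_tally = sum(positions$class %in% nm_classes),
    base_tally = sum(positions$class %in% base_mod_classes),
    combined = n_combined,
    total_rrna_modifications = sum(positions$kind == "rna"),
    total_protein_modifications = sum(positions$kind == "protein")
  )
  structure(
    list(positions = positions, class_counts = class_counts,
         totals = totals, anchor = anchor, reference = NULL),
    class = "ribo_census"
  )
}

#' @export
print.ribo_census <- function(x, ...) {
  t <- x$totals
  cat("<ribo_census> ", t$total_rrna_modifications, " rRNA + ",
      t$total_protein_modifications, " protein modified positions\n",
      "  pseudouridine tally ", t$psu_tally,
      ", 2'-O-methyl tally ", t$nm_tally,
      ", base-modification tally ", t$base_tally,
      " (", t$combined, " combined)\n", sep = "")
  if (!is.null(x$reference)) {
    r <- x$reference
    cat("  vs reference: ", nrow(r$confirmed), " confirmed, ",
        nrow(r$reported_but_absent), " reported-but-absent, ",
        nrow(r$observed_but_unreported), " observed-but-unreported, ",
        nrow(r$unresolved), " unresolved\n", sep = "")
  }
  invisible(x)
}

#' @method tidy ribo_census
#' @export
tidy.ribo_census <- function(x, ...) x$positions

#' @method glance ribo_census
#' @export
glance.ribo_census <- function(x, ...) as_tibble(x$totals)

#' Read a reference modification list
#'
#' TSV with columns `chain_role`, `auth_number`, `class` (e.g. a
#' mass-spectrometry catalogue). Keys must be unique per (role, number).
#'
#' @param path TSV path.
#' @return Tibble.
#' @export
read_reference_list <- function(path) {
  ref <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  required <- c("chain_role", "auth_number", "class")
  if (!all(required %in% names(ref))) {
    abort(paste("reference list must have columns:",
                paste(required, collapse = ", ")))
  }
  if (anyDuplicated(ref[, c("chain_role", "auth_number")])) {
    abort("reference list has duplicated (chain_role, auth_number) keys")
  }
  ref |> mutate(auth_number = as.integer(.data$auth_number))
}

#' Compare a census against a reference modification list
#'
#' Splits positions into four disjoint sets: `confirmed` (reference key
#' present in the model with a matching class), `reported_but_absent`
#' (reference position modelled but not carrying that modification),
#' `unresolved` (reference position in a region with no modelled residue)
#' and `observed_but_unreported` (modelled modification absent from the
#' reference). Reference chains are mapped to model chains through the
#' chain-role table.
#'
#' @param census A `ribo_census`.
#' @param model The classified `ribo_structure` the census came from.
#' @param reference Tibble from [read_reference_list()] (columns
#'   `chain_role`, `auth_number`, `class`).
#' @return The census with `reference` filled.
#' @export
compare_reference <- function(census, model, reference) {
  stopifnot(inherits(census, "ribo_census"), inherits(model, "ribo_structure"))
  roles <- model$chain_roles
  unmatched <- setdiff(unique(reference$chain_role), roles$role)
  if (length(unmatched) > 0) {
    abort(paste0("reference chain roles not present in the model: ",
                 paste(unmatched, collapse = ", ")))
  }
  ref <- reference |>
    left_join(roles, by = c(chain_role = "role")) |>
    mutate(key = paste(.data$chain, .data$auth_number, sep = ":"))

  obs <- census$positions |>
    mutate(key = paste(.data$chain, .data$resno, sep = ":"))
  modeled_keys <- model$residues |>
    transmute(key = paste(.data$chain, .data$resno, sep = ":")) |>
    distinct() |>
    pull()

  confirmed <- ref |>
    inner_join(obs |> select("key", obs_class = "class", "res_key"),
               by = "key") |>
    filter(.data$class == .data$obs_class) |>
    select("chain_role", "auth_number", "class", "res_key")
  leftover <- ref |> anti_join(confirmed, by = c("chain_role", "auth_number"))
  unresolved <- leftover |>
    filter(!(.data$key %in% modeled_keys)) |>
    select("chain_role", "auth_number", "class")
  reported_but_absent <- leftover |>
    filter(.data$key %in% modeled_keys) |>
    select("chain_role", "auth_number", "class")
  observed_but_unreported <- obs |>
    anti_join(confirmed, by = "res_key") |>
    select("res_key", "chain", "role", "resno", "class")

  census$reference <- list(
    confirmed = confirmed,
    reported_but_absent = reported_but_absent,
    observed_but_unreported = observed_but_unreported,
    unresolved = unresolved
  )
  census
}
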