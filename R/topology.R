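#' Define a chromophore bond topology
#'
#' A topology names the carbon atoms of interest, the C-C bonds connecting
#' them, and the ring each atom belongs to. It is the bookkeeping backbone for
#' bond-length series, sensitivity matrices and conjugation summaries.
#'
#' @param atoms Tibble or data frame with columns `atom` (character labels,
#'   e.g. `"C13"`) and `ring` (one of `"A"`, `"B"`, `"C"`, `"D"`, `"bridge"`).
#' @param bonds Tibble or data frame with columns `atom_a` and `atom_b`
#'   (labels present in `atoms`). A canonical `bond` label column
#'   (`"C13-C14"`) is added if absent.
#'
#' @return An object of class `chromophore_topology`: a list with tibbles
#'   `atoms` and `bonds`.
#' @examples
#' topo <- pcb_topology()
#' topo$bonds
#' @export
chromophore_topology <- function(atoms, bonds) {
  atoms <- as_tibble(atoms)
  bonds <- as_tibble(bonds)
  stopifnot(all(c("atom", "ring") %in% names(atoms)),
            all(c("atom_a", "atom_b") %in% names(bonds)))
  if (anyDuplicated(atoms$atom))
    abort("duplicate atom labels in topology")
  missing <- setdiff(c(bonds$atom_a, bonds$atom_b), atoms$atom)
  if (length(missing))
    abort(paste0("bond endpoints not in atom list: ",
                 paste(missing, collapse = ", ")))
  if (!"bond" %in% names(bonds))
    bonds$bond <- bond_label(bonds$atom_a, bonds$atom_b)
  if (anyDuplicated(bonds$bond))
    abort("duplicate bonds in topology")
  bad_ring <- setdiff(unique(atoms$ring), c("A", "B", "C", "D", "bridge"))
  if (length(bad_ring))
    abort(paste0("unknown ring identifier: ", paste(bad_ring, collapse = ", ")))
  structure(list(atoms = atoms, bonds = select(bonds, "bond", "atom_a", "atom_b")),
            class = "chromophore_topology")
}

#' Canonical bond label from two atom labels
#'
#' @param a,b Character vectors of atom labels.
#' @return Character vector like `"C13-C14"`.
#' @export
bond_label <- function(a, b) paste0(a, "-", b)

#' Default phycocyanobilin ring C/D topology
#'
#' The chain C12 through C19 spanning pyrrole ring C, the C15 methine bridge
#' and pyrrole ring D — the part of the conjugated system involved in colour
#' tuning. Bonds are the consecutive pairs C12-C13 ... C18-C19.
#'
#' @return A `chromophore_topology`.
#' @export
pcb_topology <- function() {
  atoms <- tibble(
    atom = paste0("C", 12:19),
    ring = c("C", "C", "C", "bridge", "D", "D", "D", "D")
  )
  bonds <- tibble(atom_a = paste0("C", 12:18), atom_b = paste0("C", 13:19))
  chromophore_topology(atoms, bonds)
}

#' @export
print.chromophore_topology <- function(x, ...) {
  cat("<chromophore_topology> ", nrow(x$atoms), " atoms, ",
      nrow(x$bonds), " bonds\n", sep = "")
  rings <- split(x$atoms$atom, x$atoms$ring)
  for (r in names(rings))
    cat("  ", r, ": ", paste(rings[[r]], collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Restrict a topology to a subset of bonds
#'
#' @param topo A `chromophore_topology`.
#' @param bonds Character vector of bond labels to keep.
#' @return A `chromophore_topology` containing only those bonds (all atoms
#'   are retained so ring lookups still work).
#' @export
subset_topology <- function(topo, bonds) {
  stopifnot(inherits(topo, "chromophore_topology"))
  missing <- setdiff(bonds, topo$bonds$bond)
  if (length(missing))
    abort(paste0("bonds not in topology: ", paste(missing, collapse = ", ")))
  kept <- topo$bonds[match(bonds, topo$bonds$bond), ]
  chromophore_topology(topo$atoms, kept)
}

#' Read / write a topology as JSON
#'
#' @param path File path.
#' @return `read_topology()` returns a `chromophore_topology`;
#'   `write_topology()` returns `path` invisibly.
#' @export
read_topology <- function(path) {
  x <- jsonlite::fromJSON(path)
  chromophore_topology(as_tibble(x$atoms), as_tibble(x$bonds))
}

#' @rdname read_topology
#' @param topo A `chromophore_topology`.
#' @export
write_topology <- function(topo, path) {
  stopifnot(inherits(topo, "chromophore_topology"))
  jsonlite::write_json(list(atoms = topo$atoms, bonds = topo$bonds), path,
                       dataframe = "columns", digits = NA)
  invisible(path)
}
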