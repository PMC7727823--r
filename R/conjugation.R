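#' Classify predicted bond lengths into single/double/intermediate orders
#'
#' Adds each predicted length change (pm) to a reference bond length
#' (Angstrom, typically the trajectory average in the dark state) and labels
#' the result by two thresholds: below `t_double_A` is `double`, above
#' `t_single_A` is `single`, in between is `intermediate`. The defaults
#' bracket typical conjugated C=C / C-C lengths; classification is
#' deliberately semi-quantitative, since bonds inside a delocalised pi
#' system never match pure single or double bonds.
#'
#' Predicted lengths outside the physically plausible window 1.0-1.8
#' Angstrom are flagged `implausible` (the label is still emitted): large
#' predicted changes are to be read as strong trends, not literal
#' geometries.
#'
#' @param reference Named numeric vector (or `(bond, length)` frame) of
#'   reference lengths in Angstrom, covering every predicted bond.
#' @param delta A `bond_delta_prediction` (or any frame with `bond` and
#'   `delta_pm` columns).
#' @param t_double_A,t_single_A Classification thresholds (Angstrom),
#'   `t_double_A < t_single_A`.
#' @param state Photostate name recorded in the output.
#'
#' @return A `bond_order_pattern`: tibble with `state`, `bond`,
#'   `reference_A`, `delta_pm`, `predicted_A`, `order`, `implausible`, and
#'   the thresholds as attributes.
#' @export
classify_bond_orders <- function(reference, delta, t_double_A = 1.40,
                                 t_single_A = 1.44, state = NULL) {
  if (t_double_A >= t_single_A) abort("t_double_A must be < t_single_A")
  ref <- as_label_map(reference)
  delta <- as_tibble(delta)
  stopifnot(all(c("bond", "delta_pm") %in% names(delta)))
  missing <- setdiff(delta$bond, names(ref))
  if (length(missing))
    abort(paste0("reference lengths missing for: ",
                 paste(missing, collapse = ", ")))
  state <- state %||% (if ("transition" %in% names(delta))
    delta$transition[1] else NA_character_)
  pred <- unname(ref[delta$bond]) + delta$delta_pm / 100
  out <- tibble(state = state, bond = delta$bond,
                reference_A = unname(ref[delta$bond]),
                delta_pm = delta$delta_pm,
                predicted_A = pred,
                order = dplyr::case_when(pred < t_double_A ~ "double",
                                         pred > t_single_A ~ "single",
                                         TRUE ~ "intermediate"),
                implausible = pred <= 1.0 | pred >= 1.8)
  if (any(out$implausible))
    warn(paste0("implausible predicted length for ",
                paste(out$bond[out$implausible], collapse = ", "),
                " - treat as a trend, not a geometry"))
  structure(out, class = c("bond_order_pattern", class(tibble())),
            t_double_A = t_double_A, t_single_A = t_single_A)
}

#' Extent of conjugation implied by a bond-order pattern
#'
#' Finds the longest contiguous run of strictly alternating single/double
#' labels along the bond chain; `intermediate` labels terminate a run
#' (conservative rule). Reports the run length and the rings it spans: a
#' ring is included only when the run contains at least one bond with both
#' endpoints inside that ring. A run reaching ring D corresponds to "full"
#' conjugation (bathochromic shift); one confined to the core corresponds
#' to "short" conjugation (hypsochromic shift).
#'
#' @param pattern A [classify_bond_orders()] result (bonds in chain order).
#' @param topo A [chromophore_topology()] containing the pattern's bonds.
#' @return One-row tibble: `state`, `n_alternating_bonds`,
#'   `included_rings` (list column), `run_bonds` (list column).
#' @export
conjugation_extent <- function(pattern, topo = pcb_topology()) {
  pattern <- as_tibble(pattern)
  if (!nrow(pattern)) abort("empty bond-order pattern")
  stopifnot(inherits(topo, "chromophore_topology"))
  missing <- setdiff(pattern$bond, topo$bonds$bond)
  if (length(missing))
    abort(paste0("pattern bonds not in topology: ",
                 paste(missing, collapse = ", ")))

  lab <- pattern$order
  n <- length(lab)
  best_len <- 0L; best_idx <- integer(0)
  run_start <- NA_integer_
  for (i in seq_len(n)) {
    extends <- !is.na(run_start) &&
      lab[i] != "intermediate" && lab[i] != lab[i - 1]
    if (lab[i] == "intermediate") {
      run_start <- NA_integer_
    } else if (is.na(run_start) || (i > 1 && !extends)) {
      run_start <- i
    }
    if (!is.na(run_start)) {
      len <- i - run_start + 1L
      if (len > best_len) { best_len <- len; best_idx <- run_start:i }
    }
  }

  rings <- character(0)
  if (best_len > 0) {
    bonds <- topo$bonds[match(pattern$bond[best_idx], topo$bonds$bond), ]
    ring_of <- setNames(topo$atoms$ring, topo$atoms$atom)
    both_in <- ring_of[bonds$atom_a] == ring_of[bonds$atom_b]
    rings <- sort(unique(ring_of[bonds$atom_a][both_in]))
    rings <- setdiff(rings, "bridge")
  }
  tibble(state = pattern$state[1],
         n_alternating_bonds = best_len,
         included_rings = list(rings),
         run_bonds = list(pattern$bond[best_idx]))
}

#' Compare bond-order patterns between two photostates
#'
#' Flags each shared bond whose character is strictly opposite in the two
#' states (`single` vs `double`) and reports the fraction of shared bonds
#' that toggle — the antagonism expected when one photoproduct extends and
#' the other shortens the conjugated system relative to the dark state.
#'
#' @param a,b [classify_bond_orders()] results for the two states.
#' @return A `state_comparison`: list with per-bond tibble `bonds`
#'   (`bond`, `order_a`, `order_b`, `opposite`) and `fraction_opposite`.
#' @export
compare_states <- function(a, b) {
  a <- as_tibble(a); b <- as_tibble(b)
  shared <- intersect(a$bond, b$bond)
  if (!length(shared)) abort("states share no bonds")
  oa <- setNames(a$order, a$bond)[shared]
  ob <- setNames(b$order, b$bond)[shared]
  opposite <- (oa == "single" & ob == "double") |
              (oa == "double" & ob == "single")
  structure(list(bonds = tibble(bond = shared, order_a = unname(oa),
                                order_b = unname(ob),
                                opposite = unname(opposite)),
                 state_a = a$state[1], state_b = b$state[1],
                 fraction_opposite = mean(opposite)),
            class = "state_comparison")
}

#' @export
print.state_comparison <- function(x, ...) {
  cat(sprintf("<state_comparison> %s vs %s: %.0f%% of shared bonds opposite\n",
              x$state_a, x$state_b, 100 * x$fraction_opposite))
  print(x$bonds)
  invisible(x)
}

#' @rdname compare_states
#' @param x A `state_comparison`.
#' @param ... Unused.
#' @method tidy state_comparison
#' @export
tidy.state_comparison <- function(x, ...) x$bonds

#' @rdname compare_states
#' @method glance state_comparison
#' @export
glance.state_comparison <- function(x, ...) {
  tibble(state_a = x$state_a, state_b = x$state_b,
         n_shared = nrow(x$bonds),
         n_opposite = sum(x$bonds$opposite),
         fraction_opposite = x$fraction_opposite)
}

#' Write a conjugation report as JSON
#'
#' Bundles per-state patterns, conjugation extents and the two-state
#' antagonism summary into one machine-readable report.
#'
#' @param patterns Named list of `bond_order_pattern`s (one per state).
#' @param comparison Optional `state_comparison`.
#' @param topo Topology used for the extents.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_conjugation_report <- function(patterns, comparison = NULL,
                                     topo = pcb_topology(), path) {
  extents <- purrr::map(patterns, function(p) {
    e <- conjugation_extent(p, topo)
    list(n_alternating_bonds = e$n_alternating_bonds,
         included_rings = e$included_rings[[1]],
         run_bonds = e$run_bonds[[1]])
  })
  payload <- list(
    states = purrr::map(patterns, function(p) as_tibble(p)),
    extents = extents,
    antagonism = if (!is.null(comparison))
      list(bonds = comparison$bonds,
           fraction_opposite = comparison$fraction_opposite)
  )
  jsonlite::write_json(payload, path, dataframe = "columns",
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
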