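#' Read a multi-frame XYZ trajectory
#'
#' Parses the standard multi-frame XYZ dialect: each block is an atom count,
#' a comment line, then one `element x y z` line per atom (coordinates in
#' Angstrom). Frame times are taken from the comment line when it contains
#' `time = <x>` or a bare number (assumed femtoseconds); otherwise they fall
#' back to `0, dt, 2 dt, ...`.
#'
#' @param path Path to an XYZ file.
#' @param labels Optional character vector renaming atoms in file order
#'   (e.g. `c("C12", "C13", ...)`). Defaults to the element symbols in the
#'   file, disambiguated with an index suffix when repeated.
#' @param dt_fs Frame spacing used when no time can be parsed from the
#'   comment lines. Default 200 fs, the usual snapshot spacing for
#'   ab initio trajectories of this kind.
#'
#' @return A tibble of frames in long form with columns `time_fs`, `atom`,
#'   `x`, `y`, `z` (Angstrom).
#' @seealso [write_xyz_trajectory()], [compute_bond_series()]
#' @export
read_xyz_trajectory <- function(path, labels = NULL, dt_fs = 200) {
  lines <- readLines(path)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0))]
  if (!length(lines)) abort("empty XYZ file")

  frames <- list()
  i <- 1L
  frame_idx <- 0L
  n_atoms_ref <- NA_integer_
  while (i <= length(lines)) {
    frame_idx <- frame_idx + 1L
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n))
      abort(paste0("frame ", frame_idx, ": expected atom count at line ", i))
    if (is.na(n_atoms_ref)) n_atoms_ref <- n
    if (n != n_atoms_ref)
      abort(paste0("inconsistent atom count in frame ", frame_idx,
                   " (", n, " vs ", n_atoms_ref, ")"))
    if (i + 1L + n > length(lines))
      abort(paste0("frame ", frame_idx, ": truncated block"))
    comment <- lines[i + 1L]
    body <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(body), "\\s+")
    bad <- which(vapply(parts, length, 1L) < 4L)
    if (length(bad))
      abort(paste0("unparsable coordinate line ", i + 1L + bad[1], ": '",
                   body[bad[1]], "'"))
    elem <- vapply(parts, `[[`, "", 1L)
    xyz <- vapply(parts, function(p) {
      v <- suppressWarnings(as.numeric(p[2:4]))
      v
    }, numeric(3))
    if (anyNA(xyz)) {
      bad <- which(apply(is.na(xyz), 2, any))[1]
      abort(paste0("unparsable coordinate line ", i + 1L + bad, ": '",
                   body[bad], "'"))
    }
    frames[[frame_idx]] <- list(comment = comment, elem = elem,
                                x = xyz[1, ], y = xyz[2, ], z = xyz[3, ])
    i <- i + 2L + n
  }

  if (is.null(labels)) {
    elem <- frames[[1]]$elem
    labels <- if (anyDuplicated(elem)) paste0(elem, seq_along(elem)) else elem
  }
  if (length(labels) != n_atoms_ref)
    abort("labels length does not match atom count")

  times <- vapply(frames, function(f) parse_xyz_time(f$comment), numeric(1))
  if (anyNA(times) || any(diff(times) <= 0))
    times <- (seq_along(frames) - 1) * dt_fs

  purrr::map2_dfr(frames, times, function(f, t)
    tibble(time_fs = t, atom = labels, x = f$x, y = f$y, z = f$z))
}

# "time = 400.0" (any key=value containing 'time'), or a bare leading number
parse_xyz_time <- function(comment) {
  m <- regmatches(comment,
                  regexpr("time\\s*=\\s*([-+0-9.eE]+)", comment, perl = TRUE))
  if (length(m))
    return(suppressWarnings(as.numeric(sub(".*=\\s*", "", m))))
  tok <- strsplit(trimws(comment), "\\s+")[[1]]
  if (length(tok) == 1L) {
    v <- suppressWarnings(as.numeric(tok))
    if (!is.na(v)) return(v)
  }
  NA_real_
}

#' Write a multi-frame XYZ trajectory
#'
#' @param frames Long-form frame tibble (`time_fs`, `atom`, `x`, `y`, `z`)
#'   as returned by [read_xyz_trajectory()] or [simulate_trajectory()].
#' @param path Output file path.
#' @param element Symbol written in the first column; by default the atom
#'   labels themselves (e.g. `"C13"`), so a re-read recovers the labelling.
#' @return `path`, invisibly.
#' @export
write_xyz_trajectory <- function(frames, path, element = NULL) {
  frames <- as_tibble(frames)
  stopifnot(all(c("time_fs", "atom", "x", "y", "z") %in% names(frames)))
  con <- file(path, "w")
  on.exit(close(con))
  for (t in unique(frames$time_fs)) {
    f <- frames[frames$time_fs == t, ]
    writeLines(as.character(nrow(f)), con)
    writeLines(sprintf("time = %.6f fs", t), con)
    writeLines(sprintf("%s %.9f %.9f %.9f", element %||% f$atom,
                       f$x, f$y, f$z), con)
  }
  invisible(path)
}

#' Derive a bond-length time series from coordinates
#'
#' Computes the Euclidean distance of every topology bond in every frame.
#'
#' @param frames Long-form frame tibble (`time_fs`, `atom`, `x`, `y`, `z`).
#' @param topo A [chromophore_topology()]; only bonds whose endpoints are
#'   present as atoms in `frames` are allowed.
#'
#' @return A wide tibble: column `time_fs` plus one column per bond label,
#'   lengths in Angstrom.
#' @examples
#' f <- tibble::tibble(time_fs = 0, atom = c("C13", "C14"),
#'                     x = c(0, 0), y = c(0, 0), z = c(0, 1.45))
#' topo <- chromophore_topology(
#'   tibble::tibble(atom = c("C13", "C14"), ring = c("C", "C")),
#'   tibble::tibble(atom_a = "C13", atom_b = "C14"))
#' compute_bond_series(f, topo)
#' @export
compute_bond_series <- function(frames, topo) {
  stopifnot(inherits(topo, "chromophore_topology"))
  frames <- as_tibble(frames)
  present <- unique(frames$atom)
  for (k in seq_len(nrow(topo$bonds))) {
    b <- topo$bonds[k, ]
    if (!all(c(b$atom_a, b$atom_b) %in% present))
      abort(paste0("bond ", b$bond, ": endpoint missing from frames"))
  }
  times <- unique(frames$time_fs)
  # wide per-coordinate matrices, atoms in fixed order
  atom_order <- present
  wide <- function(v) {
    m <- matrix(NA_real_, length(times), length(atom_order),
                dimnames = list(NULL, atom_order))
    m[cbind(match(frames$time_fs, times), match(frames$atom, atom_order))] <- v
    m
  }
  X <- wide(frames$x); Y <- wide(frames$y); Z <- wide(frames$z)
  out <- tibble(time_fs = times)
  for (k in seq_len(nrow(topo$bonds))) {
    b <- topo$bonds[k, ]
    d <- sqrt((X[, b$atom_a] - X[, b$atom_b])^2 +
              (Y[, b$atom_a] - Y[, b$atom_b])^2 +
              (Z[, b$atom_a] - Z[, b$atom_b])^2)
    out[[b$bond]] <- d
  }
  out
}

#' Read / write a per-frame series table (shifts or bond lengths)
#'
#' CSV with a header: one row per frame, a `time_fs` column (the first
#' column, whatever its name, is treated as time) and one column per atom or
#' bond label. Used for isotropic shift tables (ppm) and bond-length tables
#' (Angstrom) alike.
#'
#' @param path File path.
#' @return A wide tibble with `time_fs` plus one numeric column per label.
#' @export
read_series_table <- function(path) {
  header <- strsplit(readLines(path, n = 1L), ",")[[1]]
  header <- trimws(header)
  if (anyDuplicated(header[-1]))
    abort(paste0("duplicate header label: ",
                 header[-1][duplicated(header[-1])][1]))
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (nrow(raw) == 0L) {
    out <- as_tibble(setNames(rep(list(numeric(0)), length(header)),
                              c("time_fs", header[-1])))
    return(out)
  }
  num <- lapply(raw, function(col) suppressWarnings(as.numeric(col)))
  for (j in seq_along(num)) {
    bad <- is.na(num[[j]]) & !(trimws(raw[[j]]) %in% c("NA", ""))
    if (any(bad)) {
      i <- which(bad)[1]
      abort(paste0("non-numeric value at row ", i, ", column '",
                   names(raw)[j], "': '", raw[[j]][i], "'"))
    }
  }
  out <- as_tibble(num)
  names(out)[1] <- "time_fs"
  out
}

#' @rdname read_series_table
#' @param series Wide series tibble (`time_fs` + label columns).
#' @export
write_series_table <- function(series, path) {
  series <- as_tibble(series)
  stopifnot(names(series)[1] == "time_fs")
  readr::write_csv(series, path)
  invisible(path)
}

#' @rdname read_series_table
#' @export
read_shift_table <- read_series_table

series_labels <- function(series) setdiff(names(series), "time_fs")

series_matrix <- function(series) {
  m <- as.matrix(series[series_labels(series)])
  rownames(m) <- NULL
  m
}

#' Align a bond series and a shift series on a common time grid
#'
#' Frames are matched by nearest time within `tol_fs`; each shift frame is
#' used at most once, and unmatched frames on either side are dropped. The
#' returned pair shares the bond series' times.
#'
#' @param bonds Wide bond-length series (`time_fs` + bond columns).
#' @param shifts Wide shift series (`time_fs` + atom columns).
#' @param tol_fs Matching tolerance in femtoseconds.
#' @return A list with elements `bonds` and `shifts`, row-aligned with
#'   identical `time_fs`.
#' @export
align_series <- function(bonds, shifts, tol_fs = 1) {
  bonds <- as_tibble(bonds); shifts <- as_tibble(shifts)
  tb <- bonds$time_fs; ts <- shifts$time_fs
  used <- logical(length(ts))
  keep_b <- integer(0); keep_s <- integer(0)
  for (i in seq_along(tb)) {
    dt <- abs(ts - tb[i])
    dt[used] <- Inf
    j <- which.min(dt)
    if (length(j) && is.finite(dt[j]) && dt[j] <= tol_fs) {
      used[j] <- TRUE
      keep_b <- c(keep_b, i); keep_s <- c(keep_s, j)
    }
  }
  if (!length(keep_b))
    abort(paste0("no frames matched within ", tol_fs, " fs"))
  b <- bonds[keep_b, ]
  s <- shifts[keep_s, ]
  s$time_fs <- b$time_fs
  list(bonds = b, shifts = s)
}
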