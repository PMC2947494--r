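#' Atomic structures with charges and radii
#'
#' A structure is the content of a PQR file: an ordered set of atoms, each
#' with a position, a partial charge (elementary charges) and a radius
#' (Angstrom).  Internally it is a data frame with columns `serial`, `name`,
#' `residue_name`, `residue_number`, `x`, `y`, `z`, `charge`, `radius`, plus
#' a `label` attribute.  Atom identity is list position; duplicate serials
#' are permitted (PQR files sometimes restart numbering).
#'
#' @param atoms data frame with the columns above.
#' @param label free-text label.
#' @return an object of class `pqr_structure` (also a data.frame).
#' @export
pqr_structure <- function(atoms, label = "") {
  req <- c("serial", "name", "residue_name", "residue_number",
           "x", "y", "z", "charge", "radius")
  if (!all(req %in% names(atoms)))
    stop("atoms must have columns: ", paste(req, collapse = ", "))
  atoms <- as.data.frame(atoms)[req]
  if (nrow(atoms) == 0) stop("structure must contain at least one atom")
  if (any(!is.finite(as.matrix(atoms[c("x", "y", "z")]))))
    stop("atom positions must be finite")
  if (any(atoms$radius < 0)) stop("atom radii must be non-negative")
  structure(atoms, label = label, class = c("pqr_structure", "data.frame"))
}

#' @export
print.pqr_structure <- function(x, ...) {
  cat(sprintf("pqr_structure '%s': %d atoms, net charge %+.4f e\n",
              attr(x, "label"), nrow(x), net_charge(x)))
  NextMethod()
}

#' Atom coordinates as an n x 3 matrix
#' @param s a `pqr_structure`.
#' @return numeric matrix of positions (Angstrom).
#' @export
atom_coords <- function(s) as.matrix(s[, c("x", "y", "z")])

#' Net charge of a structure
#' @param s a `pqr_structure`.
#' @return sum of atomic partial charges in elementary charges.
#' @export
net_charge <- function(s) sum(s$charge)

#' Read a PQR file
#'
#' Parses whitespace-delimited ATOM/HETATM records (the PDB2PQR output
#' dialect).  An optional chain-ID column is tolerated by field counting:
#' records have 10 fields without a chain ID and 11 with one.  All other
#' record types (REMARK, TER, END, ...) are ignored.  Atoms are returned in
#' file order.
#'
#' @param path path to a PQR file.
#' @return a [pqr_structure()].
#' @export
read_pqr <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM|HETATM)", lines)
  idx <- which(rec)
  if (length(idx) == 0) stop("no ATOM/HETATM records in ", path)
  parse_one <- function(ln, lineno) {
    f <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
    if (length(f) == 11) f <- f[-5]  # drop chain ID
    if (length(f) != 10)
      stop(sprintf("line %d: expected 10 or 11 fields, got %d",
                   lineno, length(f)))
    num <- suppressWarnings(as.numeric(f[c(6, 7, 8, 9, 10)]))
    if (any(is.na(num)))
      stop(sprintf("line %d: unparseable coordinate/charge/radius field",
                   lineno))
    list(serial = suppressWarnings(as.integer(f[2])), name = f[3],
         residue_name = f[4],
         residue_number = suppressWarnings(as.integer(f[5])),
         x = num[1], y = num[2], z = num[3], charge = num[4],
         radius = num[5])
  }
  rows <- mapply(parse_one, lines[idx], idx, SIMPLIFY = FALSE)
  atoms <- do.call(rbind.data.frame, c(rows, stringsAsFactors = FALSE))
  pqr_structure(atoms, label = basename(path))
}

#' Write a PQR file
#'
#' Emits whitespace-delimited ATOM records readable by [read_pqr()].
#' Coordinates are printed with 4 decimals, charges and radii with 4 decimals,
#' so a read/write round trip is exact at that precision.
#'
#' @param s a [pqr_structure()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_pqr <- function(s, path) {
  stopifnot(inherits(s, "pqr_structure"))
  lines <- sprintf("ATOM  %6d %-4s %-4s %5d    %10.4f %10.4f %10.4f %8.4f %7.4f",
                   s$serial, s$name, s$residue_name, s$residue_number,
                   s$x, s$y, s$z, s$charge, s$radius)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Read an OpenDX scalar grid
#'
#' Reads "regular positions, regular connections" scalar datasets as written
#' by [write_dx()] and by common Poisson-Boltzmann solvers.  Data values are
#' ordered with the z index varying fastest (the OpenDX convention).
#'
#' @param path path to a .dx file.
#' @return a [scalar_grid()].
#' @export
read_dx <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  num <- function(x) as.numeric(strsplit(trimws(x), "[[:space:]]+")[[1]])
  gp <- grep("class gridpositions counts", lines, value = TRUE)
  if (length(gp) != 1) stop("not a regular-positions OpenDX grid: ", path)
  counts <- as.integer(utils::tail(num(sub(".*counts", "", gp)), 3))
  orig_line <- grep("^origin", lines, value = TRUE)
  if (length(orig_line) != 1) stop("missing origin in ", path)
  origin <- num(sub("^origin", "", orig_line))
  deltas <- grep("^delta", lines, value = TRUE)
  if (length(deltas) != 3) stop("expected 3 delta rows in ", path)
  dm <- t(vapply(deltas, function(l) num(sub("^delta", "", l)), numeric(3)))
  if (any(abs(dm - diag(diag(dm))) > 1e-12))
    stop("grid is not axis-aligned: ", path)
  spacing <- diag(dm)
  if (!any(grepl("class gridconnections", lines)))
    stop("not a regular-connections OpenDX grid: ", path)
  di <- grep("data follows", lines)
  if (length(di) != 1) stop("missing 'data follows' in ", path)
  n_items <- prod(counts)
  tail_lines <- lines[(di + 1):length(lines)]
  stop_at <- grep("^(attribute|object|component)", tail_lines)
  if (length(stop_at)) tail_lines <- tail_lines[seq_len(min(stop_at) - 1)]
  vals <- as.numeric(unlist(strsplit(trimws(tail_lines), "[[:space:]]+")))
  vals <- vals[!is.na(vals)]
  if (length(vals) != n_items)
    stop(sprintf("value count %d does not match grid shape %s in %s",
                 length(vals), paste(counts, collapse = "x"), path))
  # file order: z fastest, x slowest -> array [z,y,x], then permute to [x,y,z]
  arr <- aperm(array(vals, dim = rev(counts)), c(3, 2, 1))
  scalar_grid(arr, origin, spacing)
}

#' Write an OpenDX scalar grid
#'
#' Values are written z-fastest, three per line, in scientific notation with
#' 7 significant digits.
#'
#' @param g a [scalar_grid()].
#' @param path output path.
#' @param name dataset comment written to the header.
#' @return invisibly, `path`.
#' @export
write_dx <- function(g, path, name = "memslab grid") {
  stopifnot(inherits(g, "scalar_grid"))
  d <- dim(g$values)
  vals <- as.vector(aperm(g$values, c(3, 2, 1)))  # z fastest
  pad <- (-length(vals)) %% 3
  vtxt <- formatC(c(vals, rep(NA, pad)), format = "e", digits = 6)
  m <- matrix(vtxt, ncol = 3, byrow = TRUE)
  rows <- apply(m, 1, function(r) paste(r[!grepl("NA", r)], collapse = " "))
  header <- c(
    sprintf("# Data from memslab: %s", name),
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.6e %.6e %.6e", g$origin[1], g$origin[2], g$origin[3]),
    sprintf("delta %.6e %.6e %.6e", g$spacing[1], 0, 0),
    sprintf("delta %.6e %.6e %.6e", 0, g$spacing[2], 0),
    sprintf("delta %.6e %.6e %.6e", 0, 0, g$spacing[3]),
    sprintf("object 2 class gridconnections counts %d %d %d",
            d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(d)))
  footer <- c("attribute \"dep\" string \"positions\"",
              "object \"regular positions regular connections\" class field",
              "component \"positions\" value 1",
              "component \"connections\" value 2",
              "component \"data\" value 3")
  writeLines(c(header, rows, footer), path)
  invisible(path)
}
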