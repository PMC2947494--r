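#' Regular axis-aligned scalar grid
#'
#' A node-centered regular grid in 3-space.  Node `[i,j,k]` (1-based in R)
#' sits at `origin + (c(i,j,k) - 1) * spacing`.  Values are stored as a 3-D
#' array indexed `[ix, iy, iz]`.
#'
#' @param values 3-D numeric array of node values.
#' @param origin numeric(3), position of node `[1,1,1]` in Angstroms.
#' @param spacing numeric(3), node spacing per axis in Angstroms (all > 0).
#' @return an object of class `scalar_grid`.
#' @export
scalar_grid <- function(values, origin, spacing) {
  if (!is.array(values) || length(dim(values)) != 3)
    stop("values must be a 3-D array")
  origin <- as.numeric(origin); spacing <- as.numeric(spacing)
  stopifnot(length(origin) == 3, length(spacing) == 3,
            all(is.finite(origin)), all(is.finite(spacing)),
            all(spacing > 0), all(dim(values) >= 1))
  structure(list(values = values, origin = origin, spacing = spacing),
            class = "scalar_grid")
}

#' @export
print.scalar_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("scalar_grid %d x %d x %d, origin (%g, %g, %g), spacing (%g, %g, %g)\n",
              d[1], d[2], d[3], x$origin[1], x$origin[2], x$origin[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  values in [%g, %g]\n", min(x$values), max(x$values)))
  invisible(x)
}

grid_shape <- function(g) dim(g$values)

#' Grid specification by center, side lengths and node counts
#'
#' Mirrors the (grid dimensions, grid lengths) parameterization: spacing is
#' `lengths / (counts - 1)` and the grid is centered on `center`.
#'
#' @param center numeric(3) grid center (Angstrom).
#' @param lengths numeric(3) or numeric(1) side lengths (Angstrom).
#' @param counts integer(3) or integer(1) node counts per axis (>= 3).
#' @return a `grid_spec` list with `center`, `lengths`, `counts`, `spacing`,
#'   `origin`.
#' @export
grid_spec <- function(center = c(0, 0, 0), lengths, counts) {
  center <- rep_len(as.numeric(center), 3)
  lengths <- rep_len(as.numeric(lengths), 3)
  counts <- rep_len(as.integer(counts), 3)
  stopifnot(all(counts >= 3), all(lengths > 0), all(is.finite(center)))
  spacing <- lengths / (counts - 1)
  structure(list(center = center, lengths = lengths, counts = counts,
                 spacing = spacing, origin = center - lengths / 2),
            class = "grid_spec")
}

#' Allocate a constant-valued grid from a grid specification
#' @param spec a [grid_spec()].
#' @param value fill value (default 0).
#' @return a [scalar_grid()].
#' @export
empty_grid <- function(spec, value = 0) {
  scalar_grid(array(value, dim = spec$counts), spec$origin, spec$spacing)
}

#' Node coordinates along one axis
#' @param g a `scalar_grid`.
#' @param axis 1 (x), 2 (y) or 3 (z).
#' @return numeric vector of node positions (Angstrom).
#' @export
axis_coords <- function(g, axis) {
  g$origin[axis] + (seq_len(dim(g$values)[axis]) - 1) * g$spacing[axis]
}

grids_congruent <- function(a, b, tol = 1e-9) {
  identical(dim(a$values), dim(b$values)) &&
    all(abs(a$origin - b$origin) < tol) &&
    all(abs(a$spacing - b$spacing) < tol)
}

stop_if_not_congruent <- function(a, b) {
  if (!grids_congruent(a, b))
    stop("grids are not congruent (shape/origin/spacing differ)")
  invisible(TRUE)
}

# Fractional (0-based) grid coordinates of world points; pts is n x 3.
grid_coords <- function(g, pts) {
  sweep(sweep(pts, 2, g$origin, "-"), 2, g$spacing, "/")
}

#' Trilinear interpolation of a scalar grid at arbitrary points
#'
#' @param g a `scalar_grid`.
#' @param pts n x 3 matrix of world coordinates; all points must lie inside
#'   the grid (a point exactly on the boundary is allowed).
#' @return numeric(n) interpolated values.
#' @export
trilinear_interp <- function(g, pts) {
  pts <- rbind(pts)
  u <- grid_coords(g, pts)
  d <- dim(g$values)
  eps <- 1e-9
  if (any(u < -eps) || any(sweep(u, 2, d - 1, "-") > eps))
    stop("interpolation point outside grid")
  u <- pmin(pmax(u, 0), rep(d - 1, each = nrow(u)))
  i0 <- pmin(floor(u), rep(d - 2, each = nrow(u)))
  f <- u - i0
  v <- numeric(nrow(pts))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) f[, 1] else 1 - f[, 1]) *
         (if (dy) f[, 2] else 1 - f[, 2]) *
         (if (dz) f[, 3] else 1 - f[, 3])
    idx <- cbind(i0[, 1] + dx + 1, i0[, 2] + dy + 1, i0[, 3] + dz + 1)
    v <- v + w * g$values[idx]
  }
  v
}

# Node world coordinates as an n x 3 matrix in array order (x fastest).
all_node_coords <- function(g) {
  d <- dim(g$values)
  cbind(rep(axis_coords(g, 1), times = d[2] * d[3]),
        rep(rep(axis_coords(g, 2), each = d[1]), times = d[3]),
        rep(axis_coords(g, 3), each = d[1] * d[2]))
}

# Logical array marking the six boundary faces of a grid.
boundary_mask <- function(dims) {
  m <- array(FALSE, dims)
  m[c(1, dims[1]), , ] <- TRUE
  m[, c(1, dims[2]), ] <- TRUE
  m[, , c(1, dims[3])] <- TRUE
  m
}
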