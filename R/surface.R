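#' Hippocampal surface meshes
#'
#' A `hip_surface` is a fixed-topology triangulated mid-thickness mesh with a
#' per-vertex anterior-posterior coordinate in the unfolded space. All
#' subjects and hemispheres share the same topology, so vertex metrics are
#' exchangeable across subjects.
#'
#' @param vertices numeric matrix (n x 3), vertex coordinates in mm.
#' @param faces integer matrix (m x 3), 1-based triangle vertex indices.
#' @param ap_coord numeric vector of length n in \[0, 1\]; 0 = anterior tip,
#'   1 = posterior tip of the unfolded hippocampal sheet.
#' @param hemisphere `"left"`, `"right"` or `NA` for a side-agnostic template.
#'
#' @return An object of class `hip_surface`.
#' @export
hip_surface <- function(vertices, faces, ap_coord, hemisphere = NA_character_) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  ap_coord <- as.numeric(ap_coord)
  surf <- structure(
    list(vertices = vertices, faces = faces, ap_coord = ap_coord,
         hemisphere = hemisphere),
    class = "hip_surface"
  )
  validate_surface(surf)
  surf
}

validate_surface <- function(surface) {
  n <- nrow(surface$vertices)
  if (ncol(surface$vertices) != 3) {
    abort_aidhs("surface vertices must be an n x 3 matrix", "aidhs_format_error")
  }
  if (length(surface$ap_coord) != n) {
    abort_aidhs("ap_coord length must equal the vertex count", "aidhs_format_error")
  }
  f <- surface$faces
  if (any(f < 1L) || any(f > n)) {
    abort_aidhs("face indices out of range", "aidhs_format_error")
  }
  if (!all(seq_len(n) %in% f)) {
    abort_aidhs("every vertex must be referenced by at least one face",
                "aidhs_format_error")
  }
  if (any(surface$ap_coord < 0) || any(surface$ap_coord > 1)) {
    abort_aidhs("ap_coord must lie in [0, 1]", "aidhs_format_error")
  }
  invisible(surface)
}

#' @export
print.hip_surface <- function(x, ...) {
  cat(sprintf("<hip_surface> %d vertices, %d faces, hemisphere: %s\n",
              nrow(x$vertices), nrow(x$faces),
              ifelse(is.na(x$hemisphere), "template", x$hemisphere)))
  invisible(x)
}

#' Number of vertices of a surface
#' @param surface a [hip_surface()].
#' @return integer vertex count.
#' @export
n_vertices <- function(surface) nrow(surface$vertices)

# Unique undirected edges (2-column matrix, i < j).
surface_edges <- function(surface) {
  f <- surface$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(1, 3)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

# Sparse symmetric matrix of 1-ring edge lengths (mm); zero off-ring.
surface_edge_lengths <- function(surface) {
  e <- surface_edges(surface)
  v <- surface$vertices
  d <- sqrt(rowSums((v[e[, 1], , drop = FALSE] - v[e[, 2], , drop = FALSE])^2))
  n <- n_vertices(surface)
  Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                       x = c(d, d), dims = c(n, n))
}

# Binary 1-ring adjacency (no self loops).
surface_adjacency <- function(surface) {
  e <- surface_edges(surface)
  n <- n_vertices(surface)
  Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                       x = 1, dims = c(n, n))
}

#' Build a synthetic hippocampal surface
#'
#' Generates a fixed-topology surrogate for the unfolded hippocampal sheet: a
#' rectangular anterior-posterior x proximal-distal grid, triangulated and
#' bent into a curved tube so that mesh distances are non-trivial while edge
#' lengths stay close to the grid spacing (bending is near-isometric). The
#' anterior-posterior coordinate is the normalized row index.
#'
#' @param grid_n_ap,grid_n_pd grid dimensions (>= 4) along the
#'   anterior-posterior and proximal-distal axes.
#' @param spacing_mm grid spacing in mm.
#' @param hemisphere optional hemisphere tag.
#' @return a [hip_surface()] with `grid_n_ap * grid_n_pd` vertices and
#'   `2 * (grid_n_ap - 1) * (grid_n_pd - 1)` triangles.
#' @examples
#' surf <- make_surface(20, 10)
#' n_vertices(surf)  # 200
#' @export
make_surface <- function(grid_n_ap = 24, grid_n_pd = 12, spacing_mm = 0.5,
                         hemisphere = NA_character_) {
  if (grid_n_ap < 4 || grid_n_pd < 4) {
    abort_aidhs("grid dimensions must be at least 4 x 4", "aidhs_parameter_error")
  }
  i <- rep(seq_len(grid_n_ap), times = grid_n_pd)   # ap index
  j <- rep(seq_len(grid_n_pd), each = grid_n_ap)    # pd index

  # Roll the proximal-distal direction around a cylinder subtending ~150 deg;
  # arc length along the cylinder equals the flat pd coordinate, so edges are
  # only shortened by chord-vs-arc effects (< 3% here).
  pd_span <- (grid_n_pd - 1) * spacing_mm
  theta_max <- 5 * pi / 6
  r_pd <- pd_span / theta_max
  theta <- (j - 1) * spacing_mm / r_pd
  x <- (i - 1) * spacing_mm
  y <- r_pd * sin(theta)
  z <- r_pd * (1 - cos(theta))
  # gentle anterior-posterior arch
  ap <- (i - 1) / (grid_n_ap - 1)
  z <- z + 0.15 * (grid_n_ap - 1) * spacing_mm * sin(pi * ap) * 0.2

  vertices <- cbind(x, y, z)

  idx <- function(ii, jj) (jj - 1L) * grid_n_ap + ii
  ii <- rep(seq_len(grid_n_ap - 1), times = grid_n_pd - 1)
  jj <- rep(seq_len(grid_n_pd - 1), each = grid_n_ap - 1)
  f1 <- cbind(idx(ii, jj), idx(ii + 1L, jj), idx(ii, jj + 1L))
  f2 <- cbind(idx(ii + 1L, jj), idx(ii + 1L, jj + 1L), idx(ii, jj + 1L))
  faces <- rbind(f1, f2)

  hip_surface(vertices, faces, ap_coord = ap, hemisphere = hemisphere)
}
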