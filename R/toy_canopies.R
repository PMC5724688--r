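# Synthetic toy canopies.  These are first-class generators used both in the
# test-suite and for desk-checking the tracer against closed-form radiative
# transfer (single interaction, stacked layers, turbid-medium theory).

# assemble a canopy_mesh from raw pieces
make_mesh <- function(vertices, triangles, rank, s, ground_bounds) {
  area <- triangle_areas(vertices, triangles)
  centroid <- (vertices[triangles[, 1], , drop = FALSE] +
               vertices[triangles[, 2], , drop = FALSE] +
               vertices[triangles[, 3], , drop = FALSE]) / 3
  structure(list(vertices = vertices, triangles = triangles,
                 facet_rank = rank, facet_area = area,
                 facet_centroid = centroid, facet_s = s,
                 facet_chl = rep(NA_real_, nrow(triangles)),
                 ground_bounds = ground_bounds,
                 ground_area = (ground_bounds[2] - ground_bounds[1]) *
                   (ground_bounds[4] - ground_bounds[3])),
            class = "canopy_mesh")
}

# two triangles forming a horizontal square of side `side` centred at (cx, cy, z)
square_facet <- function(cx, cy, z, side) {
  h <- side / 2
  v <- rbind(c(cx - h, cy - h, z), c(cx + h, cy - h, z),
             c(cx + h, cy + h, z), c(cx - h, cy + h, z))
  list(vertices = v, triangles = rbind(c(1L, 2L, 3L), c(1L, 3L, 4L)))
}

#' Single horizontal square leaf on a square plot
#'
#' @param area Leaf area, m2.
#' @param height Leaf height above ground, m.
#' @param ground_side Side of the square plot, m.
#' @return A `canopy_mesh` with two triangles.
#' @export
single_facet_canopy <- function(area = 0.01, height = 0.5, ground_side = 1) {
  g <- ground_side
  sq <- square_facet(g / 2, g / 2, height, sqrt(area))
  make_mesh(sq$vertices, sq$triangles, rank = c(1L, 1L), s = c(0.5, 0.5),
            ground_bounds = c(0, g, 0, g))
}

#' Stack of horizontal square leaves
#'
#' `n` identical horizontal squares, vertically stacked and centred; leaf 1 is
#' the top (rank 1).  Useful for transmission and layer-binning checks.
#'
#' @param n Number of layers.
#' @param area Area of each square, m2.
#' @param top,bottom Heights of the top and bottom leaves, m.
#' @param ground_side Side of the square plot, m.
#' @return A `canopy_mesh` with `2 n` triangles.
#' @export
stacked_facets_canopy <- function(n = 2, area = 0.04, top = 1, bottom = 0.2,
                                  ground_side = 1) {
  g <- ground_side
  heights <- if (n == 1) top else seq(top, bottom, length.out = n)
  verts <- list(); tris <- list(); off <- 0L
  for (i in seq_len(n)) {
    sq <- square_facet(g / 2, g / 2, heights[i], sqrt(area))
    verts[[i]] <- sq$vertices
    tris[[i]] <- sq$triangles + off
    off <- off + 4L
  }
  make_mesh(do.call(rbind, verts), do.call(rbind, tris),
            rank = rep(seq_len(n), each = 2L), s = rep(0.5, 2L * n),
            ground_bounds = c(0, g, 0, g))
}

#' Random homogeneous turbid-medium-like canopy
#'
#' `n_facets` small triangles with centroids uniform in the slab
#' `[0, ground_side]^2 x [z_min, z_max]` and orientations drawn from the
#' spherical leaf-angle distribution (facet normals uniform on the sphere).
#' Total area is `lai * ground_area`.  This is the geometry for which
#' turbid-medium theory predicts a Beer's-law extinction coefficient
#' `k = G / cos(zenith)` with projection coefficient `G = 0.5`.
#'
#' @param n_facets Number of triangles.
#' @param lai Target leaf area index.
#' @param z_min,z_max Vertical extent of the slab, m.
#' @param ground_side Side of the square plot, m.
#' @param seed RNG seed.
#' @return A `canopy_mesh`.
#' @export
random_canopy <- function(n_facets = 2000, lai = 2, z_min = 0.2, z_max = 1.2,
                          ground_side = 1, seed = 1L) {
  g <- ground_side
  a_facet <- lai * g^2 / n_facets
  with_seed(seed, {
    cx <- stats::runif(n_facets, 0, g)
    cy <- stats::runif(n_facets, 0, g)
    cz <- stats::runif(n_facets, z_min, z_max)
    # normals uniform on the sphere
    u <- stats::runif(n_facets, -1, 1)
    phi <- stats::runif(n_facets, 0, 2 * pi)
    nx <- sqrt(1 - u^2) * cos(phi); ny <- sqrt(1 - u^2) * sin(phi); nz <- u
    rot <- stats::runif(n_facets, 0, 2 * pi)
  })
  # equilateral triangle of area a_facet in the plane orthogonal to n
  r_circ <- sqrt(a_facet * 4 / (3 * sqrt(3)))   # circumradius
  verts <- matrix(0, 3 * n_facets, 3)
  for (i in seq_len(n_facets)) {
    n_vec <- c(nx[i], ny[i], nz[i])
    ref <- if (abs(n_vec[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    e1 <- ref - sum(ref * n_vec) * n_vec; e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(n_vec[2] * e1[3] - n_vec[3] * e1[2],
            n_vec[3] * e1[1] - n_vec[1] * e1[3],
            n_vec[1] * e1[2] - n_vec[2] * e1[1])
    ang <- rot[i] + c(0, 2 * pi / 3, 4 * pi / 3)
    for (k in 1:3)
      verts[3 * (i - 1) + k, ] <- c(cx[i], cy[i], cz[i]) +
        r_circ * (cos(ang[k]) * e1 + sin(ang[k]) * e2)
  }
  tris <- matrix(seq_len(3 * n_facets), ncol = 3, byrow = TRUE)
  make_mesh(verts, tris, rank = rep(1L, n_facets), s = rep(0.5, n_facets),
            ground_bounds = c(0, g, 0, g))
}
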