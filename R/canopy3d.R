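# Parametric 3D cereal canopy construction.  Plants sit on a rectangular
# grid; each plant carries a set of leaf blades (optionally several tiller
# whorls); each blade is a longitudinal strip of quads following a parabolic
# droop.  The mesh is the substrate for the ray tracer: per-facet rank, area,
# centroid, along-blade position and chlorophyll all ride along with it.

#' Specification of a single leaf blade
#'
#' @param rank Leaf rank on its culm: 1 = flag leaf, increasing downward.
#' @param base_height Height of the blade base above ground, m.
#' @param base_azimuth Azimuth of the blade midrib, degrees (0 = +x).
#' @param base_inclination Inclination of the blade base above horizontal,
#'   degrees in `[0, 90]`.
#' @param length Blade length along the midrib, m.
#' @param max_width Maximum blade width, m.
#' @param curvature Dimensionless droop parameter (0 = straight blade; larger
#'   values bend the tip further downward).
#' @param segments Number of longitudinal quads (>= 2) used to mesh the blade.
#' @return Object of class `leaf_blade_spec`.
#' @export
leaf_blade_spec <- function(rank, base_height, base_azimuth, base_inclination,
                            length, max_width, curvature = 0.3, segments = 5L) {
  stopifnot(rank >= 1, base_height >= 0, length > 0, max_width > 0,
            base_inclination >= 0, base_inclination <= 90,
            curvature >= 0, segments >= 2)
  structure(list(rank = as.integer(rank), base_height = base_height,
                 base_azimuth = base_azimuth,
                 base_inclination = base_inclination, length = length,
                 max_width = max_width, curvature = curvature,
                 segments = as.integer(segments)),
            class = "leaf_blade_spec")
}

#' Specification of a canopy stand
#'
#' @param plants_x,plants_y Number of plants along the row / across rows.
#' @param row_spacing,plant_spacing Spacings, m.  The simulated plot covers
#'   `plants_x * row_spacing` by `plants_y * plant_spacing`; the ray tracer
#'   tiles it periodically, so even a small stand represents an extended field.
#' @param leaves_per_plant List of [leaf_blade_spec()] objects (one entry per
#'   blade; tillers are represented as additional whorls in this list).
#' @param angle_factor,height_factor,lai_factor Architecture multipliers
#'   applied at build time: inclinations are scaled by `angle_factor` (clamped
#'   to `[0, 90]` degrees), base heights by `height_factor`, and blade widths
#'   by `lai_factor` (preserving blade length and angles so the leaf-area
#'   effect is isolated).
#' @return Object of class `canopy_spec`.
#' @export
canopy_spec <- function(plants_x, plants_y, row_spacing, plant_spacing,
                        leaves_per_plant, angle_factor = 1, height_factor = 1,
                        lai_factor = 1) {
  stopifnot(plants_x >= 1, plants_y >= 1, row_spacing > 0, plant_spacing > 0,
            length(leaves_per_plant) >= 1,
            angle_factor > 0, height_factor > 0, lai_factor > 0)
  if (!all(vapply(leaves_per_plant, inherits, TRUE, "leaf_blade_spec")))
    stop("leaves_per_plant must be a list of leaf_blade_spec objects")
  structure(list(plants_x = as.integer(plants_x),
                 plants_y = as.integer(plants_y),
                 row_spacing = row_spacing, plant_spacing = plant_spacing,
                 leaves_per_plant = leaves_per_plant,
                 angle_factor = angle_factor, height_factor = height_factor,
                 lai_factor = lai_factor),
            class = "canopy_spec")
}

#' @export
print.canopy_spec <- function(x, ...) {
  cat(sprintf("<canopy_spec> %d x %d plants, %.2f x %.2f m spacing, %d blades/plant\n",
              x$plants_x, x$plants_y, x$row_spacing, x$plant_spacing,
              length(x$leaves_per_plant)))
  cat(sprintf("  factors: angle %.2f, height %.2f, LAI %.2f; target LAI %.2f\n",
              x$angle_factor, x$height_factor, x$lai_factor, target_lai(x)))
  invisible(x)
}

#' Scale architecture factors of a canopy specification
#'
#' Multiplies the stored angle / height / LAI factors.  The factors act at
#' build time (see [canopy_spec()]); inclination clamping to `[0, 90]` degrees
#' happens when blades are realised ([effective_blades()]).
#'
#' @param spec A [canopy_spec()].
#' @param angle_factor,height_factor,lai_factor Positive multipliers.
#' @return The modified `canopy_spec`.
#' @export
apply_architecture_factors <- function(spec, angle_factor = 1,
                                       height_factor = 1, lai_factor = 1) {
  stopifnot(inherits(spec, "canopy_spec"),
            angle_factor > 0, height_factor > 0, lai_factor > 0)
  spec$angle_factor <- spec$angle_factor * angle_factor
  spec$height_factor <- spec$height_factor * height_factor
  spec$lai_factor <- spec$lai_factor * lai_factor
  spec
}

#' Blade specifications with architecture factors folded in
#'
#' @param spec A [canopy_spec()].
#' @return List of [leaf_blade_spec()] with inclination scaled and clamped to
#'   `[0, 90]`, heights scaled, and widths scaled by the LAI factor.
#' @export
effective_blades <- function(spec) {
  lapply(spec$leaves_per_plant, function(b) {
    b$base_inclination <- min(90, max(0, b$base_inclination * spec$angle_factor))
    b$base_height <- b$base_height * spec$height_factor
    b$max_width <- b$max_width * spec$lai_factor
    b
  })
}

# One-sided blade area implied by the width profile
# w(s) = max_width * (1 - 0.96 s^2) (tip kept at 4% width so no facet is
# degenerate): integral over s in [0,1] is 1 - 0.96/3.
blade_area <- function(b) (1 - 0.96 / 3) * b$length * b$max_width

#' Target leaf area index of a specification
#'
#' Analytic one-sided leaf area per unit ground area implied by the blade
#' dimensions and the LAI factor (independent of meshing).
#'
#' @param spec A [canopy_spec()].
#' @return LAI, m2 leaf per m2 ground.
#' @export
target_lai <- function(spec) {
  per_plant <- sum(vapply(effective_blades(spec), blade_area, 0))
  n_plants <- spec$plants_x * spec$plants_y
  ground <- (spec$plants_x * spec$row_spacing) * (spec$plants_y * spec$plant_spacing)
  n_plants * per_plant / ground
}

# Evaluate RNG-dependent code under a fixed seed without disturbing the
# caller's RNG stream.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Mesh one blade; returns list(vertices, s_mid per facet).  The midrib starts
# at `origin` pointing along `azimuth` at `inclination` above horizontal and
# droops parabolically: elevation(s) = incl - curvature * 90 * s degrees,
# clamped at -80 (tips do not fold under the blade).
mesh_blade <- function(b, origin) {
  ns <- b$segments
  s_edges <- seq(0, 1, length.out = ns + 1)
  az <- b$base_azimuth * pi / 180
  dir_h <- c(cos(az), sin(az), 0)
  lat <- c(-sin(az), cos(az), 0)
  # integrate midrib positions at segment edges
  pts <- matrix(0, ns + 1, 3)
  pts[1, ] <- origin
  for (i in seq_len(ns)) {
    s_mid <- (s_edges[i] + s_edges[i + 1]) / 2
    elev <- max(-80, b$base_inclination - b$curvature * 90 * s_mid) * pi / 180
    step <- b$length / ns
    d <- dir_h * cos(elev) * step
    d[3] <- sin(elev) * step
    pts[i + 1, ] <- pts[i, ] + d
  }
  # keep blades above ground
  pts[, 3] <- pmax(pts[, 3], 0.002)
  half_w <- b$max_width * (1 - 0.96 * s_edges^2) / 2
  left <- pts + outer(half_w, lat)
  right <- pts - outer(half_w, lat)
  verts <- rbind(left, right)            # rows 1..ns+1 left, ns+2..2ns+2 right
  tri <- matrix(0L, 2 * ns, 3)
  s_mid_facet <- numeric(2 * ns)
  for (i in seq_len(ns)) {
    l0 <- i; l1 <- i + 1; r0 <- ns + 1 + i; r1 <- ns + 2 + i
    tri[2 * i - 1, ] <- c(l0, r0, l1)
    tri[2 * i, ] <- c(r0, r1, l1)
    s_mid_facet[c(2 * i - 1, 2 * i)] <- (s_edges[i] + s_edges[i + 1]) / 2
  }
  list(vertices = verts, triangles = tri, s_mid = s_mid_facet)
}

triangle_areas <- function(vertices, triangles) {
  a <- vertices[triangles[, 1], , drop = FALSE]
  b <- vertices[triangles[, 2], , drop = FALSE]
  c_ <- vertices[triangles[, 3], , drop = FALSE]
  u <- b - a; v <- c_ - a
  cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Build a triangulated canopy mesh from a specification
#'
#' Deterministic given `(spec, seed)`: the only randomness is a small
#' per-blade azimuth jitter that breaks the artificial regularity of the
#' planting grid.
#'
#' @param spec A [canopy_spec()].
#' @param seed Integer seed for the azimuth jitter.
#' @param azimuth_jitter Half-range of the uniform per-blade azimuth jitter,
#'   degrees.
#' @return Object of class `canopy_mesh`: `vertices` (n x 3, m),
#'   `triangles` (m x 3 vertex indices), per-facet `facet_rank`, `facet_area`
#'   (m2), `facet_centroid` (m x 3), `facet_s` (along-blade position, 0 base
#'   to 1 tip), `facet_chl` (umol m-2, NA until [assign_chlorophyll()]),
#'   `ground_bounds` (xmin, xmax, ymin, ymax) and `ground_area` (m2).
#' @export
build_canopy <- function(spec, seed = 1L, azimuth_jitter = 10) {
  stopifnot(inherits(spec, "canopy_spec"))
  blades <- effective_blades(spec)
  nb <- length(blades)
  vert_list <- list(); tri_list <- list()
  rank_list <- list(); s_list <- list()
  offset <- 0L
  jit <- with_seed(seed, stats::runif(spec$plants_x * spec$plants_y * nb,
                                      -azimuth_jitter, azimuth_jitter))
  k <- 0L
  for (ix in seq_len(spec$plants_x)) {
    for (iy in seq_len(spec$plants_y)) {
      base <- c((ix - 0.5) * spec$row_spacing, (iy - 0.5) * spec$plant_spacing, 0)
      for (b in blades) {
        k <- k + 1L
        b$base_azimuth <- b$base_azimuth + jit[k]
        part <- mesh_blade(b, base + c(0, 0, b$base_height))
        vert_list[[k]] <- part$vertices
        tri_list[[k]] <- part$triangles + offset
        rank_list[[k]] <- rep(b$rank, nrow(part$triangles))
        s_list[[k]] <- part$s_mid
        offset <- offset + nrow(part$vertices)
      }
    }
  }
  vertices <- do.call(rbind, vert_list)
  triangles <- do.call(rbind, tri_list)
  bounds <- c(0, spec$plants_x * spec$row_spacing,
              0, spec$plants_y * spec$plant_spacing)
  # The plot is horizontally periodic: edge-plant blades reaching past the
  # bounds are equivalent to their wrapped images.  Give each facet its own
  # vertices and translate it so its centroid lies inside the plot.
  nf <- nrow(triangles)
  vertices <- vertices[t(triangles), , drop = FALSE]   # 3 rows per facet
  triangles <- matrix(seq_len(3 * nf), ncol = 3, byrow = TRUE)
  cx <- (vertices[c(TRUE, FALSE, FALSE), 1] + vertices[c(FALSE, TRUE, FALSE), 1] +
           vertices[c(FALSE, FALSE, TRUE), 1]) / 3
  cy <- (vertices[c(TRUE, FALSE, FALSE), 2] + vertices[c(FALSE, TRUE, FALSE), 2] +
           vertices[c(FALSE, FALSE, TRUE), 2]) / 3
  wx <- bounds[2] - bounds[1]; wy <- bounds[4] - bounds[3]
  sx <- -floor((cx - bounds[1]) / wx) * wx
  sy <- -floor((cy - bounds[3]) / wy) * wy
  vertices[, 1] <- vertices[, 1] + rep(sx, each = 3)
  vertices[, 2] <- vertices[, 2] + rep(sy, each = 3)
  area <- triangle_areas(vertices, triangles)
  centroid <- (vertices[triangles[, 1], , drop = FALSE] +
               vertices[triangles[, 2], , drop = FALSE] +
               vertices[triangles[, 3], , drop = FALSE]) / 3
  structure(list(vertices = vertices, triangles = triangles,
                 facet_rank = unlist(rank_list), facet_area = area,
                 facet_centroid = centroid, facet_s = unlist(s_list),
                 facet_chl = rep(NA_real_, nrow(triangles)),
                 ground_bounds = bounds,
                 ground_area = (bounds[2] - bounds[1]) * (bounds[4] - bounds[3])),
            class = "canopy_mesh")
}

#' @export
print.canopy_mesh <- function(x, ...) {
  cat(sprintf("<canopy_mesh> %d facets, %d vertices, LAI %.3f, ground %.2f m2\n",
              nrow(x$triangles), nrow(x$vertices), mesh_lai(x), x$ground_area))
  if (!all(is.na(x$facet_chl)))
    cat(sprintf("  chlorophyll: area-weighted mean %.1f umol m-2\n",
                stats::weighted.mean(x$facet_chl, x$facet_area)))
  invisible(x)
}

#' Leaf area index of a mesh
#' @param mesh A [build_canopy()] mesh.
#' @return Total facet area per unit ground area.
#' @export
mesh_lai <- function(mesh) sum(mesh$facet_area) / mesh$ground_area

#' Assign per-facet chlorophyll
#'
#' `uniform` sets every facet to `mean_chl`.  `profiled` looks up relative
#' chlorophyll by leaf rank and along-blade position from `profile` and then
#' rescales so the area-weighted canopy mean equals `mean_chl` (the profile
#' carries shape only).
#'
#' @param mesh A `canopy_mesh`.
#' @param mode `"uniform"` or `"profiled"`.
#' @param mean_chl Target area-weighted mean chlorophyll, umol m-2.
#' @param profile For `profiled`: data frame with columns `rank`, `s`
#'   (along-blade position in `[0, 1]`) and `rel` (relative chlorophyll);
#'   values are interpolated linearly in `s` within each rank.  Every rank
#'   present in the mesh must appear.  Default: [default_chl_profile()].
#' @return The mesh with `facet_chl` filled in.
#' @export
assign_chlorophyll <- function(mesh, mode = c("uniform", "profiled"),
                               mean_chl, profile = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(mesh, "canopy_mesh"), mean_chl > 0)
  if (mode == "uniform") {
    mesh$facet_chl <- rep(mean_chl, nrow(mesh$triangles))
    return(mesh)
  }
  if (is.null(profile)) profile <- default_chl_profile(unique(mesh$facet_rank))
  missing_ranks <- setdiff(unique(mesh$facet_rank), unique(profile$rank))
  if (length(missing_ranks))
    stop("profile is missing ranks: ", paste(missing_ranks, collapse = ", "))
  rel <- numeric(nrow(mesh$triangles))
  for (r in unique(mesh$facet_rank)) {
    idx <- mesh$facet_rank == r
    p <- profile[profile$rank == r, ]
    p <- p[order(p$s), ]
    rel[idx] <- stats::approx(p$s, p$rel, xout = mesh$facet_s[idx],
                              rule = 2)$y
  }
  w_mean <- stats::weighted.mean(rel, mesh$facet_area)
  mesh$facet_chl <- rel * mean_chl / w_mean
  mesh
}

#' Default vertical chlorophyll profile
#'
#' Relative chlorophyll declining linearly with leaf rank (lower leaves hold
#' less) and from a slightly enriched blade middle toward the tip; a
#' "measured-like" stand-in for typical booting-stage cereal gradients.
#' Shape only: [assign_chlorophyll()] rescales to the requested mean.
#'
#' @param ranks Integer vector of leaf ranks to cover.
#' @return Data frame with columns `rank`, `s`, `rel`.
#' @export
default_chl_profile <- function(ranks = 1:4) {
  do.call(rbind, lapply(ranks, function(r) {
    base <- 1 - 0.08 * (r - 1)
    data.frame(rank = r, s = c(1 / 6, 1 / 2, 5 / 6),
               rel = base * c(1.05, 1.0, 0.85))
  }))
}

#' Default booting-stage cereal stand
#'
#' A synthetic rice-like stand: plants on a 0.25 x 0.20 m grid (20 plants
#' m-2), each with `tillers` whorls of four leaf ranks (flag leaf steepest),
#' parabolic droop, dimensions giving a booting-stage LAI of ~4.6 at the
#' default factors.  The architectural numbers are illustrative defaults for
#' a generic erect cereal stand, fully exposed here and through the YAML
#' config.
#'
#' @param plants_x,plants_y Plants along / across rows.
#' @param tillers Number of leaf whorls per plant.
#' @param segments Longitudinal quads per blade.
#' @return A [canopy_spec()].
#' @export
default_canopy_spec <- function(plants_x = 3, plants_y = 3, tillers = 11,
                                segments = 5L) {
  heights <- c(0.95, 0.80, 0.62, 0.45)
  lengths <- c(0.30, 0.35, 0.38, 0.33)
  incl <- c(78, 70, 60, 50)
  curv <- c(0.25, 0.35, 0.45, 0.55)
  width <- 0.023
  blades <- list()
  for (tl in seq_len(tillers)) {
    az <- (tl - 1) * 137.5
    for (r in 1:4) {
      blades[[length(blades) + 1]] <-
        leaf_blade_spec(rank = r, base_height = heights[r] * (1 - 0.04 * (tl - 1)),
                        base_azimuth = az + (r - 1) * 90,
                        base_inclination = incl[r], length = lengths[r],
                        max_width = width, curvature = curv[r],
                        segments = segments)
    }
  }
  canopy_spec(plants_x, plants_y, row_spacing = 0.25, plant_spacing = 0.20,
              leaves_per_plant = blades)
}

#' Export a canopy mesh as Wavefront OBJ plus metadata sidecar
#'
#' @param mesh A `canopy_mesh`.
#' @param obj_path Path for the OBJ file (triangles only).
#' @param sidecar_path Path for the per-facet CSV (facet id, rank, area,
#'   along-blade position, chlorophyll); default: `obj_path` with `.csv`.
#' @return Invisibly, the two paths.
#' @export
write_mesh_obj <- function(mesh, obj_path,
                           sidecar_path = sub("\\.obj$", ".csv", obj_path)) {
  v <- sprintf("v %.6f %.6f %.6f",
               mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3])
  f <- sprintf("f %d %d %d",
               mesh$triangles[, 1], mesh$triangles[, 2], mesh$triangles[, 3])
  writeLines(c("# canophot canopy mesh", v, f), obj_path)
  utils::write.csv(data.frame(facet = seq_len(nrow(mesh$triangles)),
                              rank = mesh$facet_rank, area = mesh$facet_area,
                              s = mesh$facet_s, chl = mesh$facet_chl),
                   sidecar_path, row.names = FALSE)
  invisible(c(obj_path, sidecar_path))
}

#' Read a canopy mesh written by [write_mesh_obj()]
#'
#' @param obj_path OBJ path.
#' @param sidecar_path Per-facet metadata CSV path.
#' @param ground_bounds Plot bounds `c(xmin, xmax, ymin, ymax)`, m; default:
#'   the mesh's horizontal bounding box.
#' @return A `canopy_mesh`.
#' @export
read_mesh_obj <- function(obj_path, sidecar_path = sub("\\.obj$", ".csv", obj_path),
                          ground_bounds = NULL) {
  lines <- readLines(obj_path)
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  vertices <- do.call(rbind, lapply(strsplit(vl, " +"), function(x)
    as.numeric(x[2:4])))
  triangles <- do.call(rbind, lapply(strsplit(fl, " +"), function(x)
    as.integer(x[2:4])))
  meta <- utils::read.csv(sidecar_path)
  if (nrow(meta) != nrow(triangles))
    stop("sidecar rows do not match triangle count")
  if (is.null(ground_bounds))
    ground_bounds <- c(min(vertices[, 1]), max(vertices[, 1]),
                       min(vertices[, 2]), max(vertices[, 2]))
  centroid <- (vertices[triangles[, 1], , drop = FALSE] +
               vertices[triangles[, 2], , drop = FALSE] +
               vertices[triangles[, 3], , drop = FALSE]) / 3
  structure(list(vertices = vertices, triangles = triangles,
                 facet_rank = meta$rank, facet_area = meta$area,
                 facet_centroid = centroid, facet_s = meta$s,
                 facet_chl = meta$chl, ground_bounds = ground_bounds,
                 ground_area = (ground_bounds[2] - ground_bounds[1]) *
                   (ground_bounds[4] - ground_bounds[3])),
            class = "canopy_mesh")
}
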