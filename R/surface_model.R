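# Surface model preparation: per-face soft-tissue thickness by ray casting
# from bone-face centroids along outward normals to the skin surface,
# thickness-threshold analysis-area selection, and the per-face marker
# correspondence with signed vertical distances.

#' Construct a surface model
#'
#' Bundles the (remeshed) bone mesh expressed in the patella local
#' coordinate system with its per-face soft-tissue thickness and the
#' analysis-area mask.
#'
#' @param bone a [trimesh()] in the patella LCS
#' @param epsilon per-face soft-tissue thickness, mm (`NA` where the
#'   outward ray misses the skin)
#' @param analysis_mask per-face logical; `TRUE` faces enter the mapping error
#' @return object of class `surface_model`
#' @export
surface_model <- function(bone, epsilon, analysis_mask = NULL) {
  nf <- nrow(bone$faces)
  if (length(epsilon) != nf) stop("one epsilon per face required")
  if (is.null(analysis_mask)) analysis_mask <- !is.na(epsilon)
  if (length(analysis_mask) != nf) stop("one mask entry per face required")
  if (any(analysis_mask & is.na(epsilon))) {
    stop("analysis faces must have a defined soft-tissue thickness")
  }
  fg <- face_geometry(bone)
  structure(list(bone = bone, epsilon = as.numeric(epsilon),
                 analysis_mask = as.logical(analysis_mask),
                 normals = fg$normals, centroids = fg$centroids),
            class = "surface_model")
}

#' Number of analysis faces of a surface model
#' @param model a [surface_model()]
#' @return integer count N
#' @export
n_analysis_faces <- function(model) sum(model$analysis_mask)

#' @export
print.surface_model <- function(x, ...) {
  eps <- x$epsilon[x$analysis_mask]
  cat(sprintf("surface_model: %d bone faces, %d in analysis area\n",
              nrow(x$bone$faces), n_analysis_faces(x)))
  if (length(eps)) {
    cat(sprintf("  soft-tissue thickness %.1f-%.1f mm (median %.1f)\n",
                min(eps), max(eps), stats::median(eps)))
  }
  invisible(x)
}

#' Soft-tissue thickness per bone face
#'
#' For every bone face, casts a ray from the face centroid along the
#' outward face normal and returns the distance to the first skin-surface
#' intersection (Moller-Trumbore). Faces whose ray misses the skin (for
#' example posterior faces pointing away from it) get `NA`.
#'
#' @param bone,skin [trimesh()] objects in the same (CT) frame
#' @return numeric vector of thickness, mm, `NA` where undefined
#' @export
compute_soft_tissue_thickness <- function(bone, skin) {
  if (nrow(skin$faces) == 0) stop("skin mesh is empty")
  fg <- face_geometry(bone)
  eps <- ray_mesh_distance(fg$centroids, fg$normals, skin)
  if (all(is.na(eps))) {
    stop("no bone face sees the skin surface (no coverage)")
  }
  eps
}

# First positive ray-triangle intersection distance for each (origin,
# direction) pair against all triangles of `mesh`. Vectorized over the
# mesh triangles, looped over rays.
ray_mesh_distance <- function(origins, directions, mesh, t_min = 1e-9) {
  v0 <- face_corner(mesh, 1)
  e1 <- face_corner(mesh, 2) - v0
  e2 <- face_corner(mesh, 3) - v0
  n_rays <- nrow(origins)
  out <- rep(NA_real_, n_rays)
  for (i in seq_len(n_rays)) {
    d <- directions[i, ]
    # h = d x e2
    h <- cbind(d[2] * e2[, 3] - d[3] * e2[, 2],
               d[3] * e2[, 1] - d[1] * e2[, 3],
               d[1] * e2[, 2] - d[2] * e2[, 1])
    a <- rowSums(e1 * h)
    ok <- abs(a) > 1e-12
    s <- sweep(-v0, 2, origins[i, ], "+")
    u <- rowSums(s * h) / a
    q <- cross3(s, e1)
    v <- as.numeric(q %*% d)   # q . d per triangle
    v <- v / a
    t_ <- rowSums(e2 * q) / a
    hit <- ok & u >= -1e-9 & v >= -1e-9 & (u + v) <= 1 + 1e-9 & t_ > t_min
    if (any(hit)) out[i] <- min(t_[hit])
  }
  out
}

#' Select the analysis area by soft-tissue thickness
#'
#' Marks as analysis faces exactly those with a defined thickness inside
#' `threshold = c(lo, hi)` mm. Selection is idempotent and recomputable
#' with a different threshold at any time.
#'
#' @param model a [surface_model()]
#' @param threshold length-2 numeric `c(lo, hi)`, mm, `0 <= lo < hi`
#' @return the model with an updated mask
#' @export
select_analysis_area <- function(model, threshold) {
  if (length(threshold) != 2 || threshold[1] < 0 || threshold[1] >= threshold[2]) {
    stop("threshold must be c(lo, hi) with 0 <= lo < hi")
  }
  mask <- !is.na(model$epsilon) &
    model$epsilon >= threshold[1] & model$epsilon <= threshold[2]
  if (!any(mask)) {
    stop(sprintf(
      "empty analysis area for thickness threshold %g-%g mm (area too small)",
      threshold[1], threshold[2]))
  }
  model$analysis_mask <- mask
  model
}

#' Generate virtual markers by Poisson-disk dart throwing
#'
#' Draws candidate points from the skin (its vertices by default, matching
#' the idea of using measured skin coordinate points, or uniform-by-area
#' surface samples) and accepts each candidate only if it keeps all
#' pairwise marker distances at or above `min_distance`, until the budget
#' of consecutive rejections is exhausted (saturation).
#'
#' @param skin a [trimesh()]
#' @param min_distance minimum pairwise marker distance, mm
#' @param seed RNG seed for reproducibility
#' @param on `"vertices"` or `"surface"` candidate source
#' @param max_failures consecutive rejections accepted before stopping
#' @return a [marker_set()] in the CT frame
#' @export
generate_virtual_markers <- function(skin, min_distance, seed = NULL,
                                     on = c("vertices", "surface"),
                                     max_failures = 2000) {
  if (min_distance <= 0) stop("min_distance must be positive")
  if (nrow(skin$vertices) == 0) stop("skin mesh is empty")
  on <- match.arg(on)
  with_seed(seed, {
    if (on == "vertices") {
      pool <- skin$vertices[sample.int(nrow(skin$vertices)), , drop = FALSE]
      accepted <- matrix(NA_real_, 0, 3)
      for (i in seq_len(nrow(pool))) {
        p <- pool[i, ]
        if (nrow(accepted) == 0 ||
            min(row_norms(sweep(accepted, 2, p))) >= min_distance) {
          accepted <- rbind(accepted, p)
        }
      }
    } else {
      accepted <- matrix(NA_real_, 0, 3)
      fails <- 0L
      while (fails < max_failures) {
        p <- sample_surface(skin, 1)
        if (nrow(accepted) == 0 ||
            min(row_norms(sweep(accepted, 2, drop(p)))) >= min_distance) {
          accepted <- rbind(accepted, p)
          fails <- 0L
        } else {
          fails <- fails + 1L
        }
      }
    }
    marker_set(accepted, frame = "ct")
  })
}

#' Generate grid markers on a skin patch
#'
#' Lays a square grid of the requested spacing over the x-y footprint of
#' the patch and projects each grid node onto the skin along -z (the
#' anteroposterior direction in this package's frames), emulating
#' physical markers attached in a grid pattern on the anterior knee.
#'
#' @param skin a [trimesh()] skin patch
#' @param spacing grid spacing, mm
#' @return a [marker_set()] in the CT frame
#' @export
generate_grid_markers <- function(skin, spacing) {
  if (spacing <= 0) stop("spacing must be positive")
  if (nrow(skin$faces) == 0) stop("empty skin patch")
  rng_x <- range(skin$vertices[, 1])
  rng_y <- range(skin$vertices[, 2])
  gx <- seq(rng_x[1], rng_x[2] + 1e-9, by = spacing)
  gy <- seq(rng_y[1], rng_y[2] + 1e-9, by = spacing)
  grid <- as.matrix(expand.grid(x = gx, y = gy))
  z_top <- max(skin$vertices[, 3]) + 10
  origins <- cbind(grid, z_top)
  dirs <- matrix(rep(c(0, 0, -1), each = nrow(origins)), ncol = 3)
  t_ <- ray_mesh_distance(origins, dirs, mesh = skin)
  hit <- !is.na(t_)
  if (!any(hit)) stop("no grid node projects onto the skin patch")
  pts <- origins[hit, , drop = FALSE]
  pts[, 3] <- pts[, 3] - t_[hit]
  marker_set(pts, frame = "ct")
}

#' Marker correspondence and vertical distances at a pose
#'
#' Poses the bone by `pose`, then for every analysis face selects the
#' marker closest to the outward normal ray from the posed face centroid,
#' and measures the signed projection of that marker onto the normal
#' (positive outside the bone): the face's vertical distance. Distance to
#' the half-line (not the infinite line) is used so that a marker behind
#' the bone can never be "closest" to an anterior face by lying near the
#' line's backward extension.
#'
#' @param model a [surface_model()] (bone in patella LCS)
#' @param pose a [pose6()] placing the LCS in the marker frame
#' @param markers a [marker_set()] in that same frame
#' @return list with `face` (analysis face indices), `marker` (chosen
#'   marker index per face) and `distance` (signed d_i, mm)
#' @export
correspond_and_distance <- function(model, pose, markers) {
  idx <- which(model$analysis_mask)
  if (length(idx) == 0) stop("empty analysis area")
  tr <- pose_to_transform(pose)
  cen <- apply_transform(tr, model$centroids[idx, , drop = FALSE])
  nrm <- model$normals[idx, , drop = FALSE] %*% t(tr$R)
  M <- markers$coords
  # signed projection of every marker onto every face normal line:
  # along[j, i] = (m_j - c_i) . n_i
  along <- M %*% t(nrm) - rep(1, nrow(M)) %o% rowSums(cen * nrm)
  # squared marker-to-centroid distances via the expansion |m|^2+|c|^2-2 m.c
  d2 <- outer(rowSums(M * M), rowSums(cen * cen), "+") - 2 * M %*% t(cen)
  # squared distance to the outward ray: perpendicular distance where the
  # projection is forward, full distance to the origin where it is behind
  ray2 <- pmax(d2 - pmax(along, 0)^2, 0)
  sel <- max.col(-t(ray2), ties.method = "first")
  list(face = idx,
       marker = sel,
       distance = along[cbind(sel, seq_along(idx))])
}
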