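# Triangle-mesh container and per-face geometry.
#
# A trimesh is a plain list: `vertices` (n x 3 double, mm) and `faces`
# (m x 3 integer, 1-based vertex indices, counter-clockwise winding seen
# from outside when the generator provides orientation).

#' Construct a triangle mesh
#'
#' @param vertices n x 3 numeric matrix of coordinates, mm
#' @param faces m x 3 integer matrix of 1-based vertex indices
#' @return object of class `trimesh`
#' @export
trimesh <- function(vertices, faces) {
  v <- as_matrix3(vertices, "vertices")
  f <- as.matrix(faces)
  if (ncol(f) != 3) stop("faces must have 3 columns")
  storage.mode(f) <- "integer"
  if (nrow(f) > 0) {
    if (min(f) < 1 || max(f) > nrow(v)) stop("face indices out of range")
    if (any(f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3])) {
      stop("faces with repeated vertices are not allowed")
    }
  }
  structure(list(vertices = v, faces = f), class = "trimesh")
}

#' @export
print.trimesh <- function(x, ...) {
  cat(sprintf("trimesh: %d vertices, %d faces\n", nrow(x$vertices), nrow(x$faces)))
  rng <- apply(x$vertices, 2, range)
  cat(sprintf("  bbox x [%.1f, %.1f]  y [%.1f, %.1f]  z [%.1f, %.1f] mm\n",
              rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  invisible(x)
}

face_corner <- function(mesh, k) mesh$vertices[mesh$faces[, k], , drop = FALSE]

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# Unnormalized winding normals (2 * area vectors).
face_area_vectors <- function(mesh) {
  a <- face_corner(mesh, 1)
  cross3(face_corner(mesh, 2) - a, face_corner(mesh, 3) - a)
}

face_areas <- function(mesh) 0.5 * row_norms(face_area_vectors(mesh))

#' Per-face unit normals and centroids
#'
#' Normals are taken from the face winding, then (by default) oriented
#' outward, i.e. flipped where they point towards the mesh vertex centroid.
#' The centroid orientation rule is reliable for convex-ish closed surfaces
#' such as the patella; meshes written by the phantom generator are wound
#' consistently so either rule agrees.
#'
#' @param mesh a [trimesh()]
#' @param orient `"centroid"` (flip normals pointing at the mesh centroid)
#'   or `"winding"` (trust face winding)
#' @return list with `normals` (m x 3 unit vectors), `centroids` (m x 3, mm)
#'   and `areas` (mm^2)
#' @export
face_geometry <- function(mesh, orient = c("centroid", "winding")) {
  orient <- match.arg(orient)
  if (nrow(mesh$faces) == 0) stop("mesh has no faces")
  av <- face_area_vectors(mesh)
  nrm <- row_norms(av)
  bad <- which(nrm < 1e-12)
  if (length(bad)) {
    stop(sprintf("degenerate (zero-area) face at index %d", bad[1]))
  }
  n <- av / nrm
  cen <- (face_corner(mesh, 1) + face_corner(mesh, 2) + face_corner(mesh, 3)) / 3
  if (orient == "centroid") {
    mc <- colMeans(mesh$vertices)
    inward <- rowSums(n * sweep(cen, 2, mc)) < 0
    n[inward, ] <- -n[inward, , drop = FALSE]
  }
  list(normals = n, centroids = cen, areas = 0.5 * nrm)
}

#' Transform a mesh by a rigid transform
#'
#' @param mesh a [trimesh()]
#' @param transform a [rigid_transform()]
#' @return the transformed [trimesh()]
#' @export
transform_mesh <- function(mesh, transform) {
  trimesh(apply_transform(transform, mesh$vertices), mesh$faces)
}

# Unique undirected edges with adjacent faces. Returns a data.frame with
# columns v1 < v2, f1, f2 (NA for boundary edges).
mesh_edges <- function(mesh) {
  f <- mesh$faces
  m <- nrow(f)
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  fid <- rep(seq_len(m), 3)
  lo <- pmin(e[, 1], e[, 2]); hi <- pmax(e[, 1], e[, 2])
  key <- paste(lo, hi)
  first <- !duplicated(key)
  idx <- match(key, key[first])
  nedge <- sum(first)
  f1 <- rep(NA_integer_, nedge); f2 <- rep(NA_integer_, nedge)
  ord <- order(idx)
  grp <- idx[ord]
  occ <- sequence(rle(grp)$lengths)
  f1[grp[occ == 1]] <- fid[ord][occ == 1]
  f2[grp[occ == 2]] <- fid[ord][occ == 2]
  data.frame(v1 = lo[first], v2 = hi[first], f1 = f1, f2 = f2)
}

edge_lengths <- function(mesh, edges = mesh_edges(mesh)) {
  row_norms(mesh$vertices[edges$v2, , drop = FALSE] -
            mesh$vertices[edges$v1, , drop = FALSE])
}

#' Mean edge length of a mesh
#' @param mesh a [trimesh()]
#' @return mean undirected edge length, mm
#' @export
mean_edge_length <- function(mesh) mean(edge_lengths(mesh))

# Drop zero-area faces and unreferenced vertices.
clean_mesh <- function(mesh, area_tol = 1e-10) {
  keep <- face_areas(mesh) > area_tol
  f <- mesh$faces[keep, , drop = FALSE]
  used <- sort(unique(as.vector(f)))
  remap <- integer(nrow(mesh$vertices))
  remap[used] <- seq_along(used)
  trimesh(mesh$vertices[used, , drop = FALSE],
          matrix(remap[f], ncol = 3))
}

# Symmetric Hausdorff-style distance estimated by sampling points on each
# surface and measuring distance to the nearest point of the other mesh's
# triangles (vertex-to-surface, sampled). Used to bound remeshing deviation.
mesh_deviation <- function(mesh_a, mesh_b, n_samples = 400, seed = 1) {
  da <- max(points_to_mesh_distance(sample_surface(mesh_a, n_samples, seed), mesh_b))
  db <- max(points_to_mesh_distance(sample_surface(mesh_b, n_samples, seed + 1), mesh_a))
  max(da, db)
}

# Uniform-by-area random surface samples.
sample_surface <- function(mesh, n, seed = NULL) {
  with_seed(seed, {
    ar <- face_areas(mesh)
    fi <- sample.int(nrow(mesh$faces), n, replace = TRUE, prob = ar)
    r1 <- sqrt(stats::runif(n)); r2 <- stats::runif(n)
    a <- mesh$vertices[mesh$faces[fi, 1], , drop = FALSE]
    b <- mesh$vertices[mesh$faces[fi, 2], , drop = FALSE]
    c_ <- mesh$vertices[mesh$faces[fi, 3], , drop = FALSE]
    (1 - r1) * a + r1 * (1 - r2) * b + r1 * r2 * c_
  })
}

# Distance from each query point to the nearest point on any triangle of
# `mesh` (exact closest-point-on-triangle, brute force over faces).
points_to_mesh_distance <- function(points, mesh) {
  p <- as_matrix3(points)
  a <- face_corner(mesh, 1); b <- face_corner(mesh, 2); c_ <- face_corner(mesh, 3)
  ab <- b - a; ac <- c_ - a
  out <- numeric(nrow(p))
  for (i in seq_len(nrow(p))) {
    out[i] <- sqrt(min(point_triangle_dist2(p[i, ], a, ab, ac)))
  }
  out
}

# Squared distance from one point to each triangle (a; a+ab; a+ac),
# vectorized over triangles. Ericson's closest-point-on-triangle cases.
point_triangle_dist2 <- function(p, a, ab, ac) {
  ap <- sweep(-a, 2, p, "+")
  d1 <- rowSums(ab * ap); d2 <- rowSums(ac * ap)
  bp <- ap - ab
  d3 <- rowSums(ab * bp); d4 <- rowSums(ac * bp)
  cp <- ap - ac
  d5 <- rowSums(ab * cp); d6 <- rowSums(ac * cp)
  va <- d3 * d6 - d5 * d4
  vb <- d5 * d2 - d1 * d6
  vc <- d1 * d4 - d3 * d2
  denom <- va + vb + vc
  # interior barycentric solution
  v <- vb / denom; w <- vc / denom
  cx <- a + v * ab + w * ac
  # region tests override where the projection falls outside
  inA <- d1 <= 0 & d2 <= 0
  inB <- d3 >= 0 & d4 <= d3
  inC <- d6 >= 0 & d5 <= d6
  onAB <- !inA & !inB & vc <= 0 & d1 >= 0 & d3 <= 0
  onAC <- !inA & !inC & vb <= 0 & d2 >= 0 & d6 <= 0
  onBC <- !inB & !inC & va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0
  t_ab <- ifelse(d1 - d3 != 0, d1 / (d1 - d3), 0)
  t_ac <- ifelse(d2 - d6 != 0, d2 / (d2 - d6), 0)
  t_bc <- ifelse((d4 - d3) + (d5 - d6) != 0, (d4 - d3) / ((d4 - d3) + (d5 - d6)), 0)
  cx[inA, ] <- a[inA, , drop = FALSE]
  cx[inB, ] <- a[inB, , drop = FALSE] + ab[inB, , drop = FALSE]
  cx[inC, ] <- a[inC, , drop = FALSE] + ac[inC, , drop = FALSE]
  cx[onAB, ] <- a[onAB, , drop = FALSE] + t_ab[onAB] * ab[onAB, , drop = FALSE]
  cx[onAC, ] <- a[onAC, , drop = FALSE] + t_ac[onAC] * ac[onAC, , drop = FALSE]
  cx[onBC, ] <- a[onBC, , drop = FALSE] + ab[onBC, , drop = FALSE] +
    t_bc[onBC] * (ac[onBC, , drop = FALSE] - ab[onBC, , drop = FALSE])
  d <- sweep(cx, 2, p)
  rowSums(d * d)
}
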