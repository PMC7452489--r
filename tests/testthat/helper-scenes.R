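# Shared fixtures, built lazily in code and memoized for the test run.

.fixtures <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fixtures[[name]])) assign(name, force(expr), envir = .fixtures)
  .fixtures[[name]]
}

# the default phantom scene and its prepared surface model
scene0 <- function() cached("scene0", make_phantom(knee_angle = 0, seed = 1))
model0 <- function() cached("model0", {
  sc <- scene0()
  build_surface_model(sc$bone, sc$skin, sc$true_pose, mapping_params())
})

# a coarse, fast scene for optimizer-heavy loops
small_scene <- function() cached("small_scene",
  make_phantom(knee_angle = 0, bone_subdiv = 2, seed = 3))
small_model <- function() cached("small_model", {
  sc <- small_scene()
  build_surface_model(sc$bone, sc$skin, sc$true_pose, mapping_params())
})

# markers lying exactly at epsilon along every analysis face's outward
# normal at the true pose: the constructed scene in which d_i = eps_i
# holds exactly, so S(truth) = 0 and the truth is an exact fixed point
exact_marker_scene <- function() cached("exact_scene", {
  sc <- scene0()
  model <- model0()
  tr <- pose_to_transform(sc$true_pose)
  idx <- which(model$analysis_mask)
  cen <- apply_transform(tr, model$centroids[idx, , drop = FALSE])
  nrm <- model$normals[idx, , drop = FALSE] %*% t(tr$R)
  sc$markers <- marker_set(cen + model$epsilon[idx] * nrm, frame = "ct")
  sc
})

random_pose <- function(mag_t = 20, mag_a = 60) {
  pose6(stats::runif(1, -mag_t, mag_t), stats::runif(1, -mag_t, mag_t),
        stats::runif(1, -mag_t, mag_t), stats::runif(1, -mag_a, mag_a),
        stats::runif(1, -mag_a, mag_a), stats::runif(1, -mag_a, mag_a))
}

# independent Cardan x-y-z extraction: numeric minimization of the
# Frobenius distance over the three angles, multi-started, then mapped
# to the canonical branch |thy| <= 90 (the decomposition is two-valued:
# (a, b, c) and (a + 180, 180 - b, c + 180) give the same rotation)
cardan_oracle <- function(R) {
  obj <- function(a) {
    Ra <- patmap:::rot_x(a[1]) %*% patmap:::rot_y(a[2]) %*% patmap:::rot_z(a[3])
    sum((Ra - R)^2)
  }
  best <- NULL
  for (s in list(c(0, 0, 0), c(90, 0, 0), c(0, 90, 0), c(0, 0, 90),
                 c(-90, 45, 30), c(45, -45, -45))) {
    o <- stats::optim(s, obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
    if (is.null(best) || o$value < best$value) best <- o
  }
  a <- patmap:::wrap_angle(best$par)
  if (abs(a[2]) > 90) {
    a <- patmap:::wrap_angle(c(a[1] + 180, 180 - a[2], a[3] + 180))
  }
  a
}

# independent single-ray / single-triangle intersection via a 3x3 solve
ray_tri_oracle <- function(orig, dir, v0, v1, v2) {
  A <- cbind(v1 - v0, v2 - v0, -dir)
  if (abs(det(A)) < 1e-12) return(NA_real_)
  x <- solve(A, orig - v0)
  u <- x[1]; v <- x[2]; t_ <- x[3]
  if (u >= -1e-9 && v >= -1e-9 && u + v <= 1 + 1e-9 && t_ > 1e-9) t_ else NA_real_
}

# exhaustive soft-tissue thickness: loop over every bone face and every
# skin triangle with the solve-based intersector
thickness_oracle <- function(bone, skin) {
  fg <- face_geometry(bone)
  vapply(seq_len(nrow(bone$faces)), function(i) {
    ts <- vapply(seq_len(nrow(skin$faces)), function(j) {
      ray_tri_oracle(fg$centroids[i, ], fg$normals[i, ],
                     skin$vertices[skin$faces[j, 1], ],
                     skin$vertices[skin$faces[j, 2], ],
                     skin$vertices[skin$faces[j, 3], ])
    }, numeric(1))
    if (all(is.na(ts))) NA_real_ else min(ts, na.rm = TRUE)
  }, numeric(1))
}

# exhaustive correspondence + vertical distance: plain double loop with
# explicit point-to-ray distances
correspondence_oracle <- function(model, pose, markers) {
  tr <- pose_to_transform(pose)
  idx <- which(model$analysis_mask)
  M <- markers$coords
  sel <- integer(length(idx)); dist <- numeric(length(idx))
  for (k in seq_along(idx)) {
    cen <- as.numeric(apply_transform(tr, model$centroids[idx[k], ]))
    nrm <- as.numeric(tr$R %*% model$normals[idx[k], ])
    best <- Inf; bj <- 0L; bd <- 0
    for (j in seq_len(nrow(M))) {
      w <- M[j, ] - cen
      along <- sum(w * nrm)
      d2 <- if (along >= 0) sum(w * w) - along^2 else sum(w * w)
      if (d2 < best) { best <- d2; bj <- j; bd <- along }
    }
    sel[k] <- bj; dist[k] <- bd
  }
  list(face = idx, marker = sel, distance = dist)
}

s_oracle <- function(model, pose, markers) {
  cd <- correspondence_oracle(model, pose, markers)
  sum(abs(cd$distance - model$epsilon[cd$face]))
}
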