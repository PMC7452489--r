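# Synthetic knee phantom: a patella-like superellipsoid bone, a skin
# surface in front of it, grid or Poisson-disk markers on the skin, and a
# known true pose per knee-flexion angle. Everything the estimator needs
# is generated with known ground truth, so no CT or motion-capture data
# are required to exercise and validate the pipeline.
#
# Frames: the bone is generated in its local coordinate system (LCS):
# origin at the centroid, x mediolateral (largest extent 40 mm),
# y proximodistal (45 mm), z anteroposterior (20 mm, +z anterior). The
# "CT" frame contains the bone posed by the true pose, the fixed skin
# surface and the markers.

# icosahedron subdivided `n` times, vertices on the unit sphere
icosphere <- function(subdiv = 3) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / row_norms(v)
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    nv <- nrow(v); nf <- nrow(f)
    edge_key <- new.env(hash = TRUE)
    newf <- matrix(0L, 4 * nf, 3)
    midpoint <- function(a, b) {
      k <- paste(min(a, b), max(a, b))
      id <- edge_key[[k]]
      if (is.null(id)) {
        p <- (v[a, ] + v[b, ]) / 2
        p <- p / sqrt(sum(p * p))
        v <<- rbind(v, p)
        id <- nrow(v)
        assign(k, id, envir = edge_key)
      }
      id
    }
    for (i in seq_len(nf)) {
      a <- f[i, 1]; b <- f[i, 2]; c_ <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
      newf[4 * i - 3, ] <- c(a, ab, ca)
      newf[4 * i - 2, ] <- c(b, bc, ab)
      newf[4 * i - 1, ] <- c(c_, ca, bc)
      newf[4 * i, ] <- c(ab, bc, ca)
    }
    f <- newf
  }
  trimesh(v, f)
}

# map unit-sphere directions onto a superellipsoid surface
# |x/a|^r + |y/b|^r + |z/c|^r = 1
superellipsoid_radius <- function(dirs, semiaxes, exponent) {
  s <- (abs(dirs[, 1] / semiaxes[1])^exponent +
        abs(dirs[, 2] / semiaxes[2])^exponent +
        abs(dirs[, 3] / semiaxes[3])^exponent)^(-1 / exponent)
  s
}

#' Patella-like bone mesh
#'
#' A superellipsoid (exponent slightly above 2, flatter than an
#' ellipsoid) with semi-axes matching a typical patella envelope of about
#' 40 x 45 x 20 mm, tapered along the proximodistal axis so that it is
#' wider proximally and narrows towards a distal apex, like a real
#' patella. The taper also makes rotation about the anteroposterior axis
#' identifiable, which a symmetric envelope would not be.
#'
#' @param semiaxes length-3 semi-axes, mm (mediolateral, proximodistal,
#'   anteroposterior)
#' @param exponent superellipsoid exponent (2 = ellipsoid)
#' @param taper mediolateral width change per unit of normalized
#'   proximodistal position (0 = symmetric)
#' @param ridge_amp height of the vertical anterior median ridge, mm
#' @param ridge_width Gaussian half-width of the ridge, mm
#' @param subdiv icosphere subdivisions controlling resolution
#' @return a [trimesh()] in the patella LCS
#' @export
phantom_bone <- function(semiaxes = c(20, 22.5, 10), exponent = 2.0,
                         taper = 0.45, ridge_amp = 4, ridge_width = 12,
                         subdiv = 3) {
  sph <- icosphere(subdiv)
  r <- superellipsoid_radius(sph$vertices, semiaxes, exponent)
  v <- sph$vertices * r
  v[, 1] <- v[, 1] * (1 + taper * v[, 2] / semiaxes[2])
  # vertical median ridge on the anterior face only (fades with z < 0)
  anterior <- pmax(v[, 3] / semiaxes[3], 0)
  v[, 3] <- v[, 3] + ridge_amp * exp(-(v[, 1] / ridge_width)^2) * anterior
  trimesh(v, sph$faces)
}

# Knee-skin heightfield: over an elliptical footprint, the skin follows
# the top of the posed bone plus a soft-tissue thickness profile tau,
# smoothly blended into a background dome away from the bone. This keeps
# the skin roughly parallel to the anterior bone surface (as real soft
# tissue is) while covering the whole anterior knee. tau combines a
# radial growth term with a smooth low-frequency lumpiness, emulating
# the spatial inhomogeneity of real prepatellar soft tissue; the lumps
# also give the mapping error distinct values at translated or rotated
# poses, which a perfectly radial thickness field would not.
phantom_skin <- function(bone_ct, footprint = c(50, 54), dome_depth = 22,
                         dome_z0 = -12, tau0 = 3.5, tau_slope = 0.0065,
                         bump_amp = 2, bump_wavelength = 28,
                         spacing = 2.6) {
  A <- footprint[1]; B <- footprint[2]
  gx <- seq(-A, A, by = spacing)
  gy <- seq(-B, B, by = spacing)
  nodes <- as.matrix(expand.grid(x = gx, y = gy))
  inside <- (nodes[, 1] / A)^2 + (nodes[, 2] / B)^2 <= 1
  # bone top under each node, by casting straight down
  z_top <- max(bone_ct$vertices[, 3]) + 5
  org <- cbind(nodes[inside, , drop = FALSE], z_top)
  dirs <- matrix(rep(c(0, 0, -1), each = nrow(org)), ncol = 3)
  t_hit <- ray_mesh_distance(org, dirs, bone_ct)
  z_bone <- z_top - t_hit                       # NA where the ray misses
  rho2 <- rowSums(nodes[inside, 1:2, drop = FALSE]^2)
  tau <- tau0 + tau_slope * rho2 + bump_amp *
    (1 + sin(nodes[inside, 1] * 2 * pi / bump_wavelength) *
       cos(nodes[inside, 2] * 2 * pi / (bump_wavelength * 1.23)))
  z_base <- dome_z0 + dome_depth *
    sqrt(pmax(1 - (nodes[inside, 1] / A)^2 - (nodes[inside, 2] / B)^2, 0))
  # smooth maximum of (bone + tau) and the background dome
  k <- 0.6
  zb <- ifelse(is.na(z_bone), -Inf, z_bone + tau)
  z <- pmax(zb, z_base) + log1p(exp(-k * abs(zb - z_base))) / k
  # assemble the grid mesh over cells whose four corners are in the footprint
  nxg <- length(gx)
  idx_all <- rep(NA_integer_, nrow(nodes))
  idx_all[inside] <- seq_len(sum(inside))
  verts <- cbind(nodes[inside, , drop = FALSE], z)
  faces <- list()
  for (j in seq_len(length(gy) - 1)) {
    for (i in seq_len(nxg - 1)) {
      n00 <- idx_all[(j - 1) * nxg + i]
      n10 <- idx_all[(j - 1) * nxg + i + 1]
      n01 <- idx_all[j * nxg + i]
      n11 <- idx_all[j * nxg + i + 1]
      if (anyNA(c(n00, n10, n01, n11))) next
      faces[[length(faces) + 1]] <- c(n00, n10, n11)
      faces[[length(faces) + 1]] <- c(n00, n11, n01)
    }
  }
  clean_mesh(trimesh(verts, do.call(rbind, faces)))
}

#' True patellar pose for a knee-flexion angle
#'
#' A smooth prescribed glide-and-tilt model: the patella translates a few
#' millimetres and tilts up to about ten degrees over 0-90 degrees of
#' knee flexion. The coefficients are phantom fixtures giving each angle
#' a distinct, recoverable truth; they are not claims about real
#' patellofemoral kinematics.
#'
#' @param angle knee flexion angle, degrees
#' @return a [pose6()] placing the patella LCS in the CT frame
#' @export
true_pose_for_angle <- function(angle) {
  stopifnot_finite(angle, "angle")
  pose6(px = 0.030 * angle, py = -0.080 * angle, pz = -0.020 * angle,
        thx = 0.120 * angle, thy = 0.040 * angle, thz = -0.030 * angle)
}

#' Knee-angle scenarios for a phantom
#'
#' @param angles knee flexion angles, degrees (default the four study
#'   conditions 0, 30, 60, 90)
#' @return list of `list(angle, true_pose)` entries
#' @export
pose_scenarios <- function(angles = c(0, 30, 60, 90)) {
  lapply(angles, function(a) list(angle = a, true_pose = true_pose_for_angle(a)))
}

#' Generate a synthetic knee phantom scene
#'
#' Builds the bone in its LCS, poses it in the CT frame by the true pose
#' for `knee_angle`, builds the skin (a fixed anterior dome by default, or
#' a constant-offset shell for analytic checks), places markers on the
#' skin, and synthesizes the four lower-leg markers in both the CT and a
#' motion-capture frame linked by a known transform.
#'
#' @param knee_angle knee flexion angle, degrees
#' @param grid_spacing marker grid spacing, mm (default 10, giving about
#'   79 markers on the default dome); ignored for `markers = "poisson"`
#' @param markers `"grid"` or `"poisson"`
#' @param min_marker_distance Poisson-disk minimum distance, mm
#' @param skin `"knee"` (heightfield skin following the bone top plus a
#'   radial thickness profile, blended into a background dome over the
#'   whole anterior knee) or `"offset"` (skin is the bone offset outward
#'   by `offset_thickness` everywhere, for analytic checks)
#' @param tau0 soft-tissue thickness over the bone apex, mm (knee skin)
#' @param tau_slope radial growth of the thickness profile, mm per mm^2
#'   (knee skin)
#' @param offset_thickness constant thickness for `skin = "offset"`, mm
#' @param bone_subdiv icosphere subdivisions of the bone
#' @param seed RNG seed (marker sampling)
#' @return object of class `phantom_scene`
#' @export
make_phantom <- function(knee_angle = 0, grid_spacing = 10,
                         markers = c("grid", "poisson"),
                         min_marker_distance = 10,
                         skin = c("knee", "offset"),
                         offset_thickness = 10, tau0 = 3.5,
                         tau_slope = 0.0065,
                         bone_subdiv = 3, seed = NULL) {
  markers <- match.arg(markers)
  skin <- match.arg(skin)
  bone_lcs <- phantom_bone(subdiv = bone_subdiv)
  true_pose <- true_pose_for_angle(knee_angle)
  tr <- pose_to_transform(true_pose)
  bone_ct <- transform_mesh(bone_lcs, tr)
  if (skin == "knee") {
    if (tau0 <= 0) stop("soft-tissue thickness tau0 must be positive")
    skin_mesh <- phantom_skin(bone_ct, tau0 = tau0, tau_slope = tau_slope)
    # the bone must sit strictly under the skin: compare each bone vertex
    # against the skin height at the nearest skin node
    sv <- skin_mesh$vertices
    for (i in seq_len(nrow(bone_ct$vertices))) {
      bv <- bone_ct$vertices[i, ]
      d2 <- (sv[, 1] - bv[1])^2 + (sv[, 2] - bv[2])^2
      if (sv[which.min(d2), 3] <= bv[3]) {
        stop("bone intersects the skin surface; thickness profile is infeasible")
      }
    }
  } else {
    if (offset_thickness <= 0) stop("offset_thickness must be positive")
    fgv <- face_area_vectors(bone_ct)
    vn <- rowsum_accumulate(fgv, bone_ct$faces, nrow(bone_ct$vertices))
    vn <- vn / pmax(row_norms(vn), 1e-12)
    skin_mesh <- trimesh(bone_ct$vertices + offset_thickness * vn, bone_ct$faces)
  }
  mk <- if (markers == "grid") {
    generate_grid_markers(skin_mesh, grid_spacing)
  } else {
    generate_virtual_markers(skin_mesh, min_marker_distance, seed = seed)
  }
  # four lower-leg markers (tibial condyle, fibular head, both malleoli)
  leg_ct <- marker_set(rbind(c(-40, -60, -20), c(45, -65, -25),
                             c(-35, -320, -15), c(40, -325, -20)),
                       labels = c("TIB", "FIB", "MMAL", "LMAL"), frame = "ct")
  mocap_tf <- pose_to_transform(pose6(120, 40, -30, 25, -10, 40))
  leg_mocap <- transform_markers(leg_ct, invert_transform(mocap_tf), "mocap")
  structure(list(
    bone_lcs = bone_lcs, bone = bone_ct, skin = skin_mesh, markers = mk,
    true_pose = true_pose, knee_angle = knee_angle,
    leg_ct = leg_ct, leg_mocap = leg_mocap, mocap_transform = mocap_tf,
    eps_bias = 0, seed = seed, skin_kind = skin
  ), class = "phantom_scene")
}

#' @export
print.phantom_scene <- function(x, ...) {
  cat(sprintf(
    "phantom_scene: knee %g deg, %d bone faces, %d skin faces, %d markers\n",
    x$knee_angle, nrow(x$bone$faces), nrow(x$skin$faces), n_markers(x$markers)))
  print(x$true_pose)
  invisible(x)
}

#' Add measurement noise to a phantom scene
#'
#' Displaces every marker by isotropic Gaussian jitter and/or adds a
#' constant bias to the soft-tissue thickness the scene will report,
#' emulating skin-movement and calibration artefacts.
#'
#' @param scene a [make_phantom()] scene
#' @param marker_sd isotropic jitter standard deviation, mm
#' @param eps_bias additive thickness bias, mm
#' @param seed RNG seed
#' @return the noisy `phantom_scene`
#' @export
add_noise <- function(scene, marker_sd = 0, eps_bias = 0, seed = NULL) {
  if (marker_sd < 0 || !is.finite(marker_sd)) stop("marker_sd must be >= 0")
  if (marker_sd > 0) {
    m <- scene$markers$coords
    jit <- with_seed(seed,
                     matrix(stats::rnorm(length(m), sd = marker_sd), ncol = 3))
    scene$markers <- marker_set(m + jit, scene$markers$labels,
                                scene$markers$frame)
  }
  scene$eps_bias <- scene$eps_bias + eps_bias
  scene
}
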