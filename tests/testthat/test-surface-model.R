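# Soft-tissue thickness, analysis-area selection, marker generation and
# the marker-face correspondence.

test_that("thickness between concentric spheres equals the shell gap", {
  bone <- patmap:::icosphere(3); skin <- patmap:::icosphere(3)
  bone <- trimesh(bone$vertices * 15, bone$faces)
  skin <- trimesh(skin$vertices * 25, skin$faces)
  eps <- compute_soft_tissue_thickness(bone, skin)
  expect_true(all(!is.na(eps)))
  # facet chords put centroids slightly inside the ideal spheres
  expect_equal(mean(eps), 10, tolerance = 0.02)
  expect_lt(max(abs(eps - 10)), 0.35)
})

test_that("thickness matches the exhaustive ray-triangle oracle", {
  sc <- small_scene()
  bone <- remesh_uniform(sc$bone, 4)
  idx <- seq(1, nrow(bone$faces), by = 7)   # spot-check a spread of faces
  sub <- patmap:::clean_mesh(trimesh(bone$vertices, bone$faces[idx, , drop = FALSE]))
  got <- compute_soft_tissue_thickness(sub, sc$skin)
  want <- thickness_oracle(sub, sc$skin)
  expect_equal(got, want, tolerance = 1e-9)
})

test_that("faces pointing away from the skin are undefined and posterior faces drop out", {
  sc <- scene0()
  bone <- remesh_uniform(sc$bone, 3)
  eps <- compute_soft_tissue_thickness(bone, sc$skin)
  nrm <- face_geometry(bone)$normals
  expect_gt(sum(is.na(eps)), 0)
  expect_gt(mean(is.na(eps[nrm[, 3] < -0.5])), 0.9)  # downward-facing faces miss
  expect_error(compute_soft_tissue_thickness(bone, trimesh(matrix(0, 1, 3),
                                                           matrix(0L, 0, 3))),
               "empty")
})

test_that("analysis-area selection is exactly the threshold filter and idempotent", {
  sc <- scene0()
  model <- model0()
  eps <- model$epsilon
  m1 <- select_analysis_area(model, c(0, 1e9))
  expect_equal(sum(m1$analysis_mask), sum(!is.na(eps)))
  m2 <- select_analysis_area(model, c(0, 12.5))
  expect_equal(m2$analysis_mask, !is.na(eps) & eps >= 0 & eps <= 12.5)
  expect_equal(select_analysis_area(m2, c(0, 12.5))$analysis_mask, m2$analysis_mask)
  expect_lt(n_analysis_faces(select_analysis_area(model, c(0, 5))),
            n_analysis_faces(m2))
  expect_error(select_analysis_area(model, c(0, 0.2)), "small|empty")
  expect_error(select_analysis_area(model, c(5, 2)), "lo < hi")
})

test_that("two-shell thickness splits cleanly at a 0-5 threshold", {
  # construct a model with known epsilon directly: near shell 4 mm, far 15 mm
  sph <- patmap:::icosphere(1)
  bone <- trimesh(sph$vertices * 10, sph$faces)
  eps <- rep(c(4, 15), length.out = nrow(bone$faces))
  model <- surface_model(bone, eps)
  sel <- select_analysis_area(model, c(0, 5))
  expect_equal(which(sel$analysis_mask), which(eps == 4))
})

test_that("virtual markers respect the minimum distance and the seed", {
  sc <- scene0()
  for (md in c(10, 15, 20)) {
    mk <- generate_virtual_markers(sc$skin, md, seed = 5)
    d <- as.matrix(stats::dist(mk$coords))
    diag(d) <- Inf
    expect_gte(min(d), md)       # O(m^2) pairwise oracle
  }
  mk1 <- generate_virtual_markers(sc$skin, 10, seed = 7)
  mk2 <- generate_virtual_markers(sc$skin, 10, seed = 7)
  expect_equal(mk1$coords, mk2$coords)
  # one marker only when nothing else fits
  big <- generate_virtual_markers(sc$skin, 1e4, seed = 1)
  expect_equal(n_markers(big), 1)
  # decreasing the distance never decreases achievable count
  counts <- sapply(c(20, 15, 10), function(md) {
    mean(sapply(1:3, function(s)
      n_markers(generate_virtual_markers(sc$skin, md, seed = s))))
  })
  expect_true(all(diff(counts) > 0))
})

test_that("grid markers form the expected lattice on a flat square", {
  sq <- trimesh(rbind(c(0, 0, 0), c(30, 0, 0), c(30, 30, 0), c(0, 30, 0)),
                rbind(c(1, 2, 3), c(1, 3, 4)))
  mk <- generate_grid_markers(sq, 10)
  expect_equal(n_markers(mk), 16)
  expect_equal(mk$coords[, 3], rep(0, 16))
  # nearest-neighbour spacing equals the grid spacing on a gentle curve
  sc <- scene0()
  gm <- generate_grid_markers(sc$skin, 10)
  d <- as.matrix(stats::dist(gm$coords))
  diag(d) <- Inf
  nn <- apply(d, 1, min)
  expect_gt(median(nn), 8.5)
  expect_lt(median(nn), 11.5)
})

test_that("correspondence picks the on-ray marker with a signed distance", {
  tri <- trimesh(rbind(c(-1, -1, 0), c(1, -1, 0), c(0, 1, 0)), rbind(1:3))
  model <- surface_model(tri, epsilon = 5)
  cen <- face_geometry(tri)$centroids[1, ]
  mk <- marker_set(rbind(cen + c(0, 0, 5), c(30, 30, 2)), frame = "ct")
  cd <- correspond_and_distance(model, pose6(), mk)
  expect_equal(cd$marker, 1L)
  expect_equal(cd$distance, 5)
  # marker on the negative-normal side projects negative
  mk2 <- marker_set(rbind(cen + c(0, 0, -4)), frame = "ct")
  cd2 <- correspond_and_distance(model, pose6(), mk2)
  expect_equal(cd2$distance, -4)
})

test_that("correspondence matches the exhaustive all-pairs oracle", {
  model <- small_model()
  sc <- small_scene()
  set.seed(31)
  for (k in 1:4) {
    pose <- perturb_pose(sc$true_pose, 8, seed = 40 + k)
    got <- correspond_and_distance(model, pose, sc$markers)
    want <- correspondence_oracle(model, pose, sc$markers)
    expect_equal(got$marker, want$marker)
    expect_equal(got$distance, want$distance, tolerance = 1e-9)
  }
})

test_that("epsilon is pose-invariant by construction", {
  model <- model0()
  sc <- scene0()
  e0 <- model$epsilon
  invisible(correspond_and_distance(model, perturb_pose(sc$true_pose, 5, seed = 1),
                                    sc$markers))
  expect_identical(model$epsilon, e0)
})
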