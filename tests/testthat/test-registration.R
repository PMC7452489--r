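# Surface mapping error, the fixed-step descent, perturbation, frame
# transfer and the end-to-end pipeline.

test_that("surface mapping error sums |d - eps| (hand example)", {
  # two far-apart faces, one marker over each at known heights
  v <- rbind(c(-50, 0, 0), c(-48, 0, 0), c(-49, 2, 0),
             c(50, 0, 0), c(52, 0, 0), c(51, 2, 0))
  mesh <- trimesh(v, rbind(c(1, 2, 3), c(4, 5, 6)))
  model <- surface_model(mesh, epsilon = c(1.5, 3.5))
  fg <- face_geometry(mesh, orient = "winding")
  mk <- marker_set(rbind(fg$centroids[1, ] + c(0, 0, 2),
                         fg$centroids[2, ] + c(0, 0, 3)), frame = "ct")
  # d = (2, 3), eps = (1.5, 3.5) -> S = 0.5 + 0.5 = 1
  expect_equal(surface_mapping_error(pose6(), model, mk), 1.0)
})

test_that("surface mapping error equals the from-scratch oracle at random poses", {
  model <- small_model()
  sc <- small_scene()
  for (k in 1:5) {
    pose <- perturb_pose(sc$true_pose, 10, seed = 50 + k)
    expect_equal(surface_mapping_error(pose, model, sc$markers),
                 s_oracle(model, pose, sc$markers), tolerance = 1e-9)
  }
  expect_gte(surface_mapping_error(sc$true_pose, model, sc$markers), 0)
  bad <- model; bad$analysis_mask[] <- FALSE
  expect_error(surface_mapping_error(sc$true_pose, bad, sc$markers), "empty")
})

test_that("descent sweeps move each coordinate by 0 or +-h", {
  model <- small_model()
  sc <- small_scene()
  pose <- perturb_pose(sc$true_pose, 6, seed = 2)
  for (mode in c("sequential", "simultaneous")) {
    sw <- descent_sweep(pose, model, sc$markers,
                        optimizer_settings(update = mode))
    expect_true(all(sw$steps %in% c(-0.5, 0, 0.5)))
  }
  # custom step size is respected
  sw2 <- descent_sweep(pose, model, sc$markers, optimizer_settings(h = 0.25))
  expect_true(all(sw2$steps %in% c(-0.25, 0, 0.25)))
})

test_that("a converged pose admits no improving single step", {
  model <- small_model()
  sc <- small_scene()
  res <- optimize_pose(perturb_pose(sc$true_pose, 5, seed = 9), model,
                       sc$markers, truth = sc$true_pose)
  expect_true(res$converged)
  q <- as.numeric(res$pose)
  S0 <- surface_mapping_error(res$pose, model, sc$markers)
  for (i in 1:6) for (s in c(-0.5, 0.5)) {
    q2 <- q; q2[i] <- q2[i] + s
    expect_gte(surface_mapping_error(patmap:::as_pose6(q2), model, sc$markers),
               S0 - 1e-9)
  }
})

test_that("one-DOF offsets descend to the 1-D grid-scan minimum", {
  model <- model0()
  sc <- scene0()
  q0 <- as.numeric(sc$true_pose)
  start <- q0; start[1] <- start[1] + 3
  res <- optimize_pose(patmap:::as_pose6(start), model, sc$markers,
                       truth = sc$true_pose)
  # 1-D scan oracle along x at resolution h
  grid <- seq(q0[1] - 1.5, q0[1] + 3.5, by = 0.5)
  svals <- vapply(grid, function(x) {
    q <- as.numeric(res$pose); q[1] <- x
    surface_mapping_error(patmap:::as_pose6(q), model, sc$markers)
  }, numeric(1))
  expect_equal(as.numeric(res$pose[1]), grid[which.min(svals)])
  expect_lt(abs(as.numeric(res$errors[1])), 1.01)
})

test_that("optimization from the truth is an immediate fixed point", {
  # markers exactly at eps along the normals: S(truth) = 0, so the truth
  # is the exact global minimum and no move can be accepted
  sc <- exact_marker_scene()
  model <- model0()
  expect_lt(surface_mapping_error(sc$true_pose, model, sc$markers), 1e-9)
  res <- optimize_pose(sc$true_pose, model, sc$markers, truth = sc$true_pose)
  expect_true(res$converged)
  expect_equal(res$sweeps, 1L)
  expect_equal(as.numeric(res$errors), rep(0, 6))
  # on the realistic grid-marker scene the truth start stays inside the
  # discretization band of the fixed-step optimizer
  sc0 <- scene0()
  r2 <- optimize_pose(sc0$true_pose, model0(), sc0$markers,
                      truth = sc0$true_pose)
  e <- abs(as.numeric(r2$errors))
  expect_lte(max(e[1:3]), 0.5)
  expect_lte(max(e[4:6]), 2)
})

test_that("the sequential error trace is monotone non-increasing", {
  model <- small_model()
  sc <- small_scene()
  for (k in 1:5) {
    res <- optimize_pose(perturb_pose(sc$true_pose, 10, seed = 60 + k),
                         model, sc$markers)
    expect_true(all(diff(res$trace) <= 1e-9))
    expect_lte(res$S, res$trace[1])
  }
})

test_that("perturbation is uniform, bounded and seed-reproducible", {
  p0 <- pose6(1, 2, 3, 4, 5, 6)
  expect_equal(as.numeric(perturb_pose(p0, 0)), as.numeric(p0))
  draws <- t(sapply(1:2000, function(k) {
    as.numeric(perturb_pose(p0, 10, seed = k)) - as.numeric(p0)
  }))
  expect_true(all(abs(draws) <= 10))
  # uniform moments: mean within 3 standard errors of zero per DOF
  se <- 10 / sqrt(3) / sqrt(nrow(draws))
  expect_true(all(abs(colMeans(draws)) < 3 * se))
  expect_equal(perturb_pose(p0, 10, seed = 1), perturb_pose(p0, 10, seed = 1))
})

test_that("mocap-to-CT transfer recovers the linking transform", {
  sc <- scene0()
  tf <- mocap_to_ct(sc$leg_mocap, sc$leg_ct)
  expect_lt(attr(tf, "rms"), 1e-9)
  expect_lt(max(abs(tf$R - sc$mocap_transform$R)), 1e-9)
  expect_lt(max(abs(tf$t - sc$mocap_transform$t)), 1e-9)
  ident <- mocap_to_ct(sc$leg_ct, sc$leg_ct)
  expect_lt(max(abs(ident$R - diag(3))), 1e-12)
  # 0.5 mm jitter: transform close, residual reported
  set.seed(33)
  reps <- replicate(20, {
    noisy <- sc$leg_mocap
    noisy$coords <- noisy$coords + matrix(stats::rnorm(12, sd = 0.5), 4, 3)
    tfn <- mocap_to_ct(noisy, sc$leg_ct)
    ang <- acos(pmin((sum(diag(t(tfn$R) %*% sc$mocap_transform$R)) - 1) / 2, 1)) * 180 / pi
    c(attr(tfn, "rms"), ang, sqrt(sum((tfn$t - sc$mocap_transform$t)^2)))
  })
  expect_true(all(reps[1, ] > 0))
  expect_lt(median(reps[2, ]), 1)       # within about a degree
})

test_that("registering mocap-frame markers equals registering in CT directly", {
  sc <- scene0()
  model <- model0()
  mk_mocap <- transform_markers(sc$markers,
                                invert_transform(sc$mocap_transform), "mocap")
  direct <- register_scene(sc, perturb = 5, seed = 4, model = model)
  via <- register(bone = sc$bone, truth = sc$true_pose, skin = sc$skin,
                  markers = mk_mocap, perturb = 5, seed = 4, model = model,
                  leg_mocap = sc$leg_mocap, leg_ct = sc$leg_ct)
  expect_lt(via$transfer_rms, 1e-9)
  expect_equal(as.numeric(via$pose), as.numeric(direct$pose), tolerance = 1e-6)
  expect_equal(via$S, direct$S, tolerance = 1e-6)
  expect_error(register(bone = sc$bone, truth = sc$true_pose, skin = sc$skin,
                        markers = mk_mocap, model = model),
               "frame-transfer")
})

test_that("the pipeline reports stage-named errors on bad input", {
  sc <- scene0()
  expect_error(register(bone = sc$bone, truth = sc$true_pose), "model building")
  expect_error(register(bone = sc$bone, truth = sc$true_pose,
                        model = model0()), "marker stage")
})
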