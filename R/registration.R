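# The core estimator: surface mapping error S and the fixed-step
# derivative-free coordinate-descent ("modified steepest descent")
# optimizer over the 6 pose DOFs.
#
# S(Q, M, E) = sum over analysis faces of |d_i - eps_i|, where d_i is the
# signed vertical distance of the face's corresponding marker at pose Q
# and eps_i the CT-derived soft-tissue thickness. Each descent sweep tries
# q_i, q_i + h and q_i - h for every DOF (h = 0.5 mm or degree by default)
# and keeps the best; convergence is a full sweep with no accepted move.

#' Optimizer settings for pose descent
#'
#' @param h fixed step size, mm for positions and degrees for angles
#' @param max_sweeps sweep cap before giving up
#' @param update `"sequential"` (each accepted move updates the pose before
#'   the next DOF is tried; the error trace is then provably non-increasing)
#'   or `"simultaneous"` (all six trial moves evaluated at the sweep's
#'   starting pose, then applied together)
#' @return object of class `optimizer_settings`
#' @export
optimizer_settings <- function(h = 0.5, max_sweeps = 10000,
                               update = c("sequential", "simultaneous")) {
  if (!is.numeric(h) || h <= 0) stop("h must be positive")
  if (max_sweeps < 1) stop("max_sweeps must be >= 1")
  structure(list(h = h, max_sweeps = as.integer(max_sweeps),
                 update = match.arg(update)),
            class = "optimizer_settings")
}

#' Surface mapping error at a pose
#'
#' @param pose a [pose6()]
#' @param model a [surface_model()]
#' @param markers a [marker_set()] in the frame the pose maps into
#' @return S, the sum of absolute vertical-distance residuals, mm
#' @export
surface_mapping_error <- function(pose, model, markers) {
  cd <- correspond_and_distance(model, pose, markers)
  sum(abs(cd$distance - model$epsilon[cd$face]))
}

#' One descent sweep over the six DOFs
#'
#' For each DOF in order (px, py, pz, thx, thy, thz) evaluates S at the
#' current value and one step up and down, and moves by `0`, `+h` or `-h`
#' to whichever is strictly smallest; ties keep the current value.
#'
#' @param pose the starting [pose6()]
#' @param model a [surface_model()]
#' @param markers a [marker_set()]
#' @param settings an [optimizer_settings()]
#' @return list with `pose` (after the sweep), `S` (error at the returned
#'   pose), `moved` (logical, any accepted move) and `steps` (the six
#'   signed displacements)
#' @export
descent_sweep <- function(pose, model, markers, settings = optimizer_settings()) {
  q <- as.numeric(as_pose6(pose))
  h <- settings$h
  steps <- numeric(6)
  if (settings$update == "sequential") {
    s_cur <- surface_mapping_error(as_pose6(q), model, markers)
    for (i in 1:6) {
      qp <- q; qp[i] <- qp[i] + h
      qm <- q; qm[i] <- qm[i] - h
      s1 <- s_cur
      s2 <- surface_mapping_error(as_pose6(qp), model, markers)
      s3 <- surface_mapping_error(as_pose6(qm), model, markers)
      if (s2 < s1 && s2 < s3) {
        q <- qp; s_cur <- s2; steps[i] <- h
      } else if (s3 < s1 && s3 < s2) {
        q <- qm; s_cur <- s3; steps[i] <- -h
      }
      # otherwise (including ties) the coordinate keeps its value
    }
    s_out <- s_cur
  } else {
    q0 <- q
    s1 <- surface_mapping_error(as_pose6(q0), model, markers)
    for (i in 1:6) {
      qp <- q0; qp[i] <- qp[i] + h
      qm <- q0; qm[i] <- qm[i] - h
      s2 <- surface_mapping_error(as_pose6(qp), model, markers)
      s3 <- surface_mapping_error(as_pose6(qm), model, markers)
      if (s2 < s1 && s2 < s3) steps[i] <- h
      else if (s3 < s1 && s3 < s2) steps[i] <- -h
    }
    q <- q0 + steps
    s_out <- surface_mapping_error(as_pose6(q), model, markers)
  }
  list(pose = as_pose6(q), S = s_out, moved = any(steps != 0), steps = steps)
}

#' Minimize the surface mapping error over the pose
#'
#' Repeats descent sweeps until one full sweep accepts no move
#' (convergence) or `max_sweeps` is reached. In sequential mode the
#' returned error trace is monotone non-increasing by construction.
#'
#' @inheritParams descent_sweep
#' @param initial the initial [pose6()]
#' @param truth optional true [pose6()]; when given, signed per-DOF errors
#'   of the estimate are reported
#' @return object of class `registration_result`: estimated pose, final S,
#'   per-sweep S trace, sweeps used, convergence flag and (optionally)
#'   per-DOF errors
#' @export
optimize_pose <- function(initial, model, markers,
                          settings = optimizer_settings(), truth = NULL) {
  pose <- as_pose6(initial)
  trace <- surface_mapping_error(pose, model, markers)
  converged <- FALSE
  sweeps <- 0L
  for (k in seq_len(settings$max_sweeps)) {
    sw <- descent_sweep(pose, model, markers, settings)
    sweeps <- k
    pose <- sw$pose
    trace <- c(trace, sw$S)
    if (!sw$moved) {
      converged <- TRUE
      break
    }
  }
  res <- list(pose = pose, S = trace[length(trace)], trace = trace,
              sweeps = sweeps, converged = converged, settings = settings)
  if (!is.null(truth)) {
    res$errors <- pose_error(pose_to_transform(truth), pose_to_transform(pose))
  }
  class(res) <- "registration_result"
  res
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("registration_result: S = %.3f mm after %d sweeps (%s)\n",
              x$S, x$sweeps, if (x$converged) "converged" else "sweep cap hit"))
  print(x$pose)
  if (!is.null(x$errors)) {
    cat("errors vs truth:\n")
    print(x$errors)
  }
  invisible(x)
}

#' Perturb a pose uniformly
#'
#' Adds an independent uniform draw from `[-magnitude, magnitude]` to each
#' DOF (mm for positions, degrees for angles), emulating an initial guess
#' with bounded error relative to the true coordinate system.
#'
#' @param true_pose a [pose6()]
#' @param magnitude half-width of the uniform perturbation (default 10)
#' @param seed RNG seed
#' @return a perturbed [pose6()]
#' @export
perturb_pose <- function(true_pose, magnitude = 10, seed = NULL) {
  if (magnitude < 0) stop("magnitude must be >= 0")
  q <- as.numeric(as_pose6(true_pose))
  with_seed(seed, as_pose6(q + stats::runif(6, -magnitude, magnitude)))
}

#' Motion-capture to CT frame transfer
#'
#' Least-squares rigid fit of the (four) lower-leg marker positions
#' captured in the motion-capture frame onto the same markers localized
#' in the CT scan. The residual RMS is a quality metric for the transfer.
#'
#' @param leg_mocap,leg_ct [marker_set()] objects (or n x 3 matrices) of
#'   paired lower-leg markers in the two frames, n >= 3
#' @return a [rigid_transform()] mapping mocap to CT coordinates, with
#'   attribute `rms` (mm)
#' @export
mocap_to_ct <- function(leg_mocap, leg_ct) {
  src <- if (inherits(leg_mocap, "marker_set")) leg_mocap$coords else as_matrix3(leg_mocap)
  dst <- if (inherits(leg_ct, "marker_set")) leg_ct$coords else as_matrix3(leg_ct)
  rigid_fit(src, dst)
}
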