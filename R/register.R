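# End-to-end registration pipeline: remesh -> soft-tissue thickness ->
# analysis area -> (frame transfer) -> (perturbed initialization) ->
# pose optimization, with per-DOF error reporting against a known truth.

#' Method parameters
#'
#' Defaults are the selected working condition: 3 mm target edge length,
#' 0-20 mm soft-tissue thickness threshold, 10 mm minimum marker distance
#' and a 0.5 mm/degree descent step.
#'
#' @param target_edge remeshing target edge length, mm
#' @param thickness_range analysis-area thickness threshold `c(lo, hi)`, mm
#' @param marker_min_distance minimum distance between generated virtual
#'   markers, mm
#' @param h descent step size, mm or degree
#' @param max_sweeps descent sweep cap
#' @param update descent update mode, `"sequential"` or `"simultaneous"`
#' @return object of class `mapping_params`
#' @export
mapping_params <- function(target_edge = 3, thickness_range = c(0, 20),
                           marker_min_distance = 10, h = 0.5,
                           max_sweeps = 10000, update = "sequential") {
  p <- list(target_edge = target_edge,
            thickness_range = as.numeric(thickness_range),
            marker_min_distance = marker_min_distance,
            optimizer = optimizer_settings(h, max_sweeps, update))
  if (length(p$thickness_range) != 2) stop("thickness_range must be c(lo, hi)")
  structure(p, class = "mapping_params")
}

#' Build a surface model from CT-frame meshes
#'
#' Remeshes the bone to the target edge length, measures per-face
#' soft-tissue thickness against the skin (both in the CT frame), selects
#' the analysis area by the thickness threshold, and finally expresses
#' the bone in the patella LCS given by `lcs` so that poses can move it.
#'
#' @param bone bone [trimesh()] in the CT frame
#' @param skin skin [trimesh()] in the CT frame
#' @param lcs [pose6()] or [rigid_transform()] of the patella LCS in the
#'   CT frame (from the CT segmentation)
#' @param params a [mapping_params()]
#' @param eps_bias additive thickness bias, mm (noise studies)
#' @return a [surface_model()] with bone coordinates in the patella LCS
#' @export
build_surface_model <- function(bone, skin, lcs, params = mapping_params(),
                                eps_bias = 0) {
  if (inherits(lcs, "pose6") || (is.numeric(lcs) && length(lcs) == 6)) {
    lcs <- pose_to_transform(as_pose6(lcs))
  }
  bone_r <- remesh_uniform(bone, params$target_edge)
  eps <- compute_soft_tissue_thickness(bone_r, skin) + eps_bias
  bone_in_lcs <- transform_mesh(bone_r, invert_transform(lcs))
  model <- surface_model(bone_in_lcs, eps)
  select_analysis_area(model, params$thickness_range)
}

#' Register a bone to skin markers
#'
#' The full pipeline. `truth` (the CT-derived local coordinate system)
#' anchors the bone in its LCS and provides the initial pose; setting
#' `perturb > 0` starts the optimizer from a uniformly perturbed pose
#' instead (simulation-style validation), and per-DOF errors against the
#' truth are reported either way.
#'
#' Markers can be supplied directly (CT frame, or motion-capture frame
#' together with the paired lower-leg marker sets for the frame transfer)
#' or omitted, in which case virtual markers are generated on the skin.
#'
#' @param bone bone [trimesh()] in the CT frame
#' @param truth true [pose6()] of the patella LCS in the CT frame
#' @param skin skin [trimesh()] in the CT frame (needed when `markers` is
#'   `NULL` or for building the model)
#' @param markers optional [marker_set()]
#' @param params a [mapping_params()]
#' @param perturb half-width of the uniform initial-pose perturbation
#'   (0 = start at `truth`)
#' @param seed RNG seed (marker generation and perturbation)
#' @param leg_mocap,leg_ct paired lower-leg [marker_set()]s for the
#'   motion-capture to CT transfer (required for mocap-frame markers)
#' @param model optional prebuilt [build_surface_model()] result, reused
#'   across repeated registrations of the same geometry
#' @param eps_bias additive thickness bias, mm
#' @return a `registration_result` with fields `params`, `n_faces`,
#'   `n_markers` and (if transferred) `transfer_rms` added
#' @export
register <- function(bone, truth, skin = NULL, markers = NULL,
                     params = mapping_params(), perturb = 0, seed = NULL,
                     leg_mocap = NULL, leg_ct = NULL, model = NULL,
                     eps_bias = 0) {
  truth <- as_pose6(truth)
  if (is.null(model)) {
    if (is.null(skin)) stop("model building stage: a skin mesh is required")
    model <- build_surface_model(bone, skin, truth, params, eps_bias)
  }
  transfer_rms <- NULL
  if (is.null(markers)) {
    if (is.null(skin)) stop("marker stage: need skin to generate virtual markers")
    markers <- generate_virtual_markers(skin, params$marker_min_distance,
                                        seed = derive_seed(seed, 1))
  } else if (markers$frame == "mocap") {
    if (is.null(leg_mocap) || is.null(leg_ct)) {
      stop("frame-transfer stage: mocap markers need leg_mocap and leg_ct")
    }
    tf <- mocap_to_ct(leg_mocap, leg_ct)
    transfer_rms <- attr(tf, "rms")
    markers <- transform_markers(markers, tf, "ct")
  } else if (markers$frame != "ct") {
    stop("frame-transfer stage: markers must be in the mocap or ct frame")
  }
  initial <- if (perturb > 0) {
    perturb_pose(truth, perturb, seed = derive_seed(seed, 2))
  } else {
    truth
  }
  res <- optimize_pose(initial, model, markers, params$optimizer, truth = truth)
  res$params <- params
  res$initial <- initial
  res$n_faces <- n_analysis_faces(model)
  res$n_markers <- n_markers(markers)
  res$transfer_rms <- transfer_rms
  res
}

#' Register a phantom scene
#'
#' Convenience wrapper running [register()] on a [make_phantom()] scene
#' with its own markers and true pose.
#'
#' @param scene a `phantom_scene`
#' @param params a [mapping_params()]
#' @param perturb initial-pose perturbation half-width (default 10,
#'   simulation-style)
#' @param seed RNG seed
#' @param model optional prebuilt surface model for the scene
#' @return a `registration_result`
#' @export
register_scene <- function(scene, params = mapping_params(), perturb = 10,
                           seed = NULL, model = NULL) {
  register(bone = scene$bone, truth = scene$true_pose, skin = scene$skin,
           markers = scene$markers, params = params, perturb = perturb,
           seed = seed, model = model, eps_bias = scene$eps_bias)
}
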