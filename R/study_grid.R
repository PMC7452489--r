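# Full-factorial parameter-selection machinery: enumerate all
# combinations of target edge length x thickness threshold x marker
# distance over the knee-angle scenarios with repetitions, pool mean
# absolute DOF errors per condition, rank conditions per DOF (1 = best)
# and pick the condition with the minimum total score.

#' Define a factorial condition grid
#'
#' The default grid is the full 3 x 3 x 3 design over four knee angles
#' with 10 repetitions: 27 conditions, 1080 runs.
#'
#' @param target_edges target edge lengths, mm
#' @param thickness_ranges list of `c(lo, hi)` thickness thresholds, mm
#' @param marker_distances minimum marker distances, mm
#' @param angles knee flexion angles, degrees
#' @param reps repetitions per condition and angle
#' @return object of class `condition_grid`
#' @export
condition_grid <- function(target_edges = c(2, 3, 4),
                           thickness_ranges = list(c(0, 5), c(0, 12.5), c(0, 20)),
                           marker_distances = c(10, 15, 20),
                           angles = c(0, 30, 60, 90),
                           reps = 10) {
  if (!length(target_edges) || !length(thickness_ranges) ||
      !length(marker_distances) || !length(angles)) {
    stop("all level lists must be non-empty")
  }
  if (reps < 1) stop("reps must be >= 1")
  conditions <- expand.grid(
    thickness = seq_along(thickness_ranges),
    target_edge = target_edges,
    marker_distance = marker_distances,
    KEEP.OUT.ATTRS = FALSE)
  conditions <- data.frame(
    condition = seq_len(nrow(conditions)),
    target_edge = conditions$target_edge,
    thickness_lo = vapply(thickness_ranges, `[`, numeric(1), 1)[conditions$thickness],
    thickness_hi = vapply(thickness_ranges, `[`, numeric(1), 2)[conditions$thickness],
    marker_distance = conditions$marker_distance)
  structure(list(conditions = conditions, angles = angles, reps = as.integer(reps)),
            class = "condition_grid")
}

#' @export
print.condition_grid <- function(x, ...) {
  cat(sprintf("condition_grid: %d conditions x %d angles x %d reps = %d runs\n",
              nrow(x$conditions), length(x$angles), x$reps, grid_run_count(x)))
  invisible(x)
}

#' Number of runs a grid enumerates
#' @param grid a [condition_grid()]
#' @return integer run count (conditions x angles x reps)
#' @export
grid_run_count <- function(grid) {
  nrow(grid$conditions) * length(grid$angles) * grid$reps
}

#' Run (or enumerate) the factorial simulation
#'
#' For every condition, knee angle and repetition: build the surface
#' model from the angle's phantom scene at the condition's edge length
#' and thickness threshold (models are cached per edge x angle), draw
#' virtual markers at the condition's minimum distance, register from a
#' perturbed start, and record the six absolute DOF errors. Failed
#' registrations are flagged and excluded from downstream means.
#'
#' @param grid a [condition_grid()]
#' @param scenes list of `phantom_scene`s, one per angle in the grid
#'   (matched by knee angle); ignored for `dry_run = TRUE`
#' @param seed base RNG seed; every run derives its own sub-seed
#' @param perturb initial-pose perturbation half-width, mm/degrees
#' @param dry_run if `TRUE`, return the enumerated run plan without
#'   executing any registration
#' @return data.frame with one row per run: condition columns, `angle`,
#'   `rep`, absolute errors `err_px`..`err_thz`, `converged`, `failed`
#' @export
run_factorial <- function(grid, scenes = NULL, seed = 1, perturb = 10,
                          dry_run = FALSE) {
  plan <- merge(grid$conditions,
                expand.grid(condition = grid$conditions$condition,
                            angle = grid$angles, rep = seq_len(grid$reps),
                            KEEP.OUT.ATTRS = FALSE),
                by = "condition")
  plan <- plan[order(plan$condition, plan$angle, plan$rep), ]
  rownames(plan) <- NULL
  if (dry_run) return(plan)
  if (is.null(scenes)) stop("scenes are required unless dry_run = TRUE")
  scene_angles <- vapply(scenes, function(s) s$knee_angle, numeric(1))
  if (!all(grid$angles %in% scene_angles)) {
    stop("one phantom scene per grid angle is required")
  }
  err_cols <- paste0("err_", c("px", "py", "pz", "thx", "thy", "thz"))
  for (cc in err_cols) plan[[cc]] <- NA_real_
  plan$converged <- NA
  plan$failed <- FALSE
  # cache remeshed bone + thickness per (edge, angle); thresholds re-mask
  model_cache <- new.env(hash = TRUE)
  for (r in seq_len(nrow(plan))) {
    scene <- scenes[[match(plan$angle[r], scene_angles)]]
    params <- mapping_params(
      target_edge = plan$target_edge[r],
      thickness_range = c(plan$thickness_lo[r], plan$thickness_hi[r]),
      marker_min_distance = plan$marker_distance[r])
    key <- sprintf("e%g_a%g", plan$target_edge[r], plan$angle[r])
    base <- model_cache[[key]]
    run <- tryCatch({
      if (is.null(base)) {
        bone_r <- remesh_uniform(scene$bone, params$target_edge)
        eps <- compute_soft_tissue_thickness(bone_r, scene$skin) + scene$eps_bias
        bone_in_lcs <- transform_mesh(
          bone_r, invert_transform(pose_to_transform(scene$true_pose)))
        base <- surface_model(bone_in_lcs, eps)
        model_cache[[key]] <- base
      }
      model <- select_analysis_area(base, params$thickness_range)
      run_seed <- derive_seed(seed, plan$condition[r], plan$angle[r], plan$rep[r])
      mk <- generate_virtual_markers(scene$skin, params$marker_min_distance,
                                     seed = run_seed)
      register(bone = scene$bone, truth = scene$true_pose, skin = scene$skin,
               markers = mk, params = params, perturb = perturb,
               seed = run_seed, model = model)
    }, error = function(e) e)
    if (inherits(run, "error")) {
      plan$failed[r] <- TRUE
      warning(sprintf("run %d (condition %d, angle %g, rep %d) failed: %s",
                      r, plan$condition[r], plan$angle[r], plan$rep[r],
                      conditionMessage(run)))
    } else {
      plan[r, err_cols] <- abs(as.numeric(run$errors))
      plan$converged[r] <- run$converged
    }
  }
  plan
}

#' Rank conditions and compute total scores
#'
#' Pools each condition's absolute DOF errors over angles and
#' repetitions, ranks the conditions per DOF in ascending error (1 =
#' smallest; ties share the average rank), and sums the six ranks into a
#' total score.
#'
#' @param records a [run_factorial()] result
#' @return object of class `grid_report`: data.frame of per-condition
#'   mean errors, per-DOF ranks and `total`, with the selected condition
#'   as attribute `selected`
#' @export
rank_and_score <- function(records) {
  err_cols <- paste0("err_", c("px", "py", "pz", "thx", "thy", "thz"))
  if (!all(err_cols %in% names(records))) stop("records lack error columns")
  ok <- records[!records$failed & !is.na(records$err_px), ]
  cond_cols <- c("condition", "target_edge", "thickness_lo", "thickness_hi",
                 "marker_distance")
  conds <- unique(records[, cond_cols])
  if (length(unique(ok$condition)) == 0 ||
      !all(conds$condition %in% ok$condition)) {
    stop("at least one condition has no successful run")
  }
  agg <- stats::aggregate(ok[, err_cols], by = list(condition = ok$condition), mean)
  report <- merge(conds, agg, by = "condition")
  names(report)[match(err_cols, names(report))] <- sub("err_", "mean_", err_cols)
  for (d in c("px", "py", "pz", "thx", "thy", "thz")) {
    report[[paste0("rank_", d)]] <- rank(report[[paste0("mean_", d)]],
                                         ties.method = "average")
  }
  report$total <- rowSums(report[, paste0("rank_", c("px", "py", "pz",
                                                     "thx", "thy", "thz"))])
  report <- report[order(report$condition), ]
  rownames(report) <- NULL
  class(report) <- c("grid_report", "data.frame")
  attr(report, "selected") <- select_best(report)
  report
}

#' Select the best condition from a scored report
#'
#' The condition with the minimum total score wins; ties are broken
#' deterministically by smaller target edge, then wider thickness range,
#' then smaller marker distance (and a message notes the tie).
#'
#' @param report a [rank_and_score()] report, or any data.frame with
#'   columns `target_edge`, `thickness_lo`, `thickness_hi`,
#'   `marker_distance` and `total`
#' @return one-row data.frame: the selected condition and its total
#' @export
select_best <- function(report) {
  need <- c("target_edge", "thickness_lo", "thickness_hi", "marker_distance",
            "total")
  if (!all(need %in% names(report))) {
    stop("report must carry condition columns and a total score")
  }
  if (nrow(report) == 0) stop("empty report")
  if (sum(report$total == min(report$total)) > 1) {
    message("tie on total score; broken by edge, thickness width, marker distance")
  }
  ord <- order(report$total, report$target_edge,
               -(report$thickness_hi - report$thickness_lo),
               report$marker_distance)
  out <- report[ord[1], need, drop = FALSE]
  rownames(out) <- NULL
  as.data.frame(out)
}

#' Reference total-score table
#'
#' The published 27-condition total-score table for this mapping method
#' (target edge length 2/3/4 mm x soft-tissue threshold 0-5/0-12.5/0-20
#' mm x minimum marker distance 10/15/20 mm), usable as a
#' [select_best()] input. Its minimum total (235) sits at the
#' 3 mm / 0-20 mm / 10 mm condition, the package's parameter defaults.
#'
#' @return data.frame with the condition columns and `total`
#' @export
condition_total_scores <- function() {
  path <- system.file("extdata", "condition_total_scores.csv",
                      package = "patmap", mustWork = TRUE)
  utils::read.csv(path)
}
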