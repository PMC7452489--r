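# Factorial design enumeration, rank scoring, condition selection.

test_that("the full design enumerates 3x3x3x4x10 = 1080 runs", {
  g <- condition_grid()
  expect_equal(nrow(g$conditions), 27)
  expect_equal(grid_run_count(g), 1080)
  plan <- run_factorial(g, dry_run = TRUE)
  expect_equal(nrow(plan), 1080)
  expect_equal(nrow(unique(plan[, c("condition", "angle", "rep")])), 1080)
})

test_that("degenerate and reduced designs count correctly", {
  g1 <- condition_grid(target_edges = 3, thickness_ranges = list(c(0, 20)),
                       marker_distances = 10, angles = 0, reps = 1)
  expect_equal(grid_run_count(g1), 1)
  g2 <- condition_grid(target_edges = c(3, 4),
                       thickness_ranges = list(c(0, 12.5), c(0, 20)),
                       marker_distances = c(10, 20), angles = 0, reps = 2)
  expect_equal(nrow(g2$conditions), 8)
  expect_equal(grid_run_count(g2), 16)
  expect_error(condition_grid(target_edges = numeric(0)), "non-empty")
  expect_error(condition_grid(reps = 0), "reps")
})

random_records <- function(conds, n_rep = 3, seed = 1) {
  set.seed(seed)
  plan <- merge(conds, expand.grid(condition = conds$condition,
                                   angle = 0, rep = seq_len(n_rep)),
                by = "condition")
  for (d in c("px", "py", "pz", "thx", "thy", "thz")) {
    plan[[paste0("err_", d)]] <- stats::runif(nrow(plan), 0, 5)
  }
  plan$converged <- TRUE
  plan$failed <- FALSE
  plan
}

test_that("rank scores match a sort oracle and form permutations", {
  conds <- condition_grid()$conditions
  rec <- random_records(conds)
  rep_ <- rank_and_score(rec)
  expect_s3_class(rep_, "grid_report")
  for (d in c("px", "py", "pz", "thx", "thy", "thz")) {
    means <- tapply(rec[[paste0("err_", d)]], rec$condition, mean)
    means <- means[as.character(rep_$condition)]
    expect_equal(rep_[[paste0("mean_", d)]], as.numeric(means), tolerance = 1e-12)
    # independent sort oracle
    expect_equal(rep_[[paste0("rank_", d)]],
                 as.numeric(rank(means, ties.method = "average")))
    expect_equal(sort(rep_[[paste0("rank_", d)]]), as.numeric(1:27))
  }
  expect_equal(rep_$total,
               rowSums(rep_[, paste0("rank_", c("px", "py", "pz",
                                                "thx", "thy", "thz"))]))
  expect_true(all(rep_$total >= 6 & rep_$total <= 6 * 27))
})

test_that("scoring is invariant to monotone rescaling of a DOF's mean errors", {
  # one rep per condition so the condition means are the raw errors; a
  # strictly increasing map of those cannot change rank-based scores
  conds <- condition_grid()$conditions
  rec <- random_records(conds, n_rep = 1, seed = 4)
  r1 <- rank_and_score(rec)
  rec2 <- rec
  rec2$err_px <- exp(rec2$err_px / 2)
  r2 <- rank_and_score(rec2)
  expect_equal(r2$rank_px, r1$rank_px)
  expect_equal(r2$total, r1$total)
})

test_that("identical errors tie to the average rank everywhere", {
  conds <- condition_grid()$conditions
  rec <- random_records(conds, seed = 5)
  for (d in c("px", "py", "pz", "thx", "thy", "thz")) {
    rec[[paste0("err_", d)]] <- 1.0
  }
  rep_ <- rank_and_score(rec)
  expect_true(all(rep_$rank_px == 14))
  expect_true(all(rep_$total == 84))
})

test_that("failed runs are excluded from means", {
  conds <- condition_grid(target_edges = 3,
                          thickness_ranges = list(c(0, 20)),
                          marker_distances = 10, angles = 0, reps = 4)$conditions
  rec <- random_records(conds, n_rep = 4, seed = 6)
  rec$err_px[1] <- 99
  rec$failed[1] <- TRUE
  rep_ <- rank_and_score(rec)
  expect_equal(rep_$mean_px, mean(rec$err_px[-1]))
  rec$failed[] <- TRUE
  expect_error(rank_and_score(rec), "no successful run")
})

test_that("selection on the reference score table returns the known condition", {
  tab <- condition_total_scores()
  expect_equal(nrow(tab), 27)
  sel <- select_best(tab)
  expect_equal(sel$target_edge, 3)
  expect_equal(c(sel$thickness_lo, sel$thickness_hi), c(0, 20))
  expect_equal(sel$marker_distance, 10)
  expect_equal(sel$total, 235)
})

test_that("selection handles singletons, unique minima and ties", {
  tab <- condition_total_scores()
  expect_equal(select_best(tab[16, ])$total, tab$total[16])
  set.seed(8)
  for (k in 1:10) {
    tab$total <- sample(1000, 27)
    expect_equal(select_best(tab)$total, min(tab$total))   # argmin oracle
  }
  tab$total <- 50
  tab$target_edge[5] <- 2    # tie broken towards the smaller edge
  expect_message(sel <- select_best(tab), "tie")
  expect_equal(sel$target_edge, 2)
})

test_that("a miniature live factorial produces complete records", {
  g <- condition_grid(target_edges = 4, thickness_ranges = list(c(0, 20)),
                      marker_distances = c(15, 20), angles = 0, reps = 1)
  rec <- run_factorial(g, scenes = list(small_scene()), seed = 2)
  expect_equal(nrow(rec), 2)
  expect_true(all(!rec$failed))
  expect_true(all(is.finite(as.matrix(rec[, paste0("err_", c("px", "py", "pz",
                                                             "thx", "thy", "thz"))]))))
})
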