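test_that("ROC endpoints, perfect separation, and tie conventions hold", {
  perfect <- roc_curve(c(5, 4, 3, 1, 0.5), c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$tpr[1], 0); expect_equal(perfect$fpr[1], 0)
  expect_equal(utils::tail(perfect$tpr, 1), 1)
  expect_equal(utils::tail(perfect$fpr, 1), 1)
  ties <- roc_curve(rep(2, 6), c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE))
  expect_equal(ties$auc, 0.5)
  expect_error(roc_curve(1:4, rep(TRUE, 4)), "both classes")
})

test_that("trapezoid AUC equals the exhaustive pairwise-concordance oracle", {
  scores8 <- c(3.1, 2.2, 2.2, 1.5, 0.9, 0.9, 0.1, -1)
  labels8 <- c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE)
  expect_equal(roc_curve(scores8, labels8)$auc, auc_concordance(scores8, labels8))
  withr::with_seed(21, {
    for (rep in 1:10) {
      n <- sample(8:60, 1)
      sc <- round(rnorm(n), 1)          # rounding forces ties
      lb <- runif(n) < 0.4
      if (!any(lb) || all(lb)) next
      expect_equal(roc_curve(sc, lb)$auc, auc_concordance(sc, lb))
    }
  })
})

test_that("AUC agrees with pROC on a random instance", {
  skip_if_not_installed("pROC")
  withr::with_seed(22, {
    sc <- rnorm(150); lb <- runif(150) < 0.5
  })
  ref <- as.numeric(pROC::auc(pROC::roc(response = lb, predictor = sc,
                                        quiet = TRUE, direction = "<")))
  expect_equal(roc_curve(sc, lb)$auc, ref, tolerance = 1e-12)
})

test_that("the Youden cutoff matches an exhaustive threshold scan", {
  withr::with_seed(23, {
    for (rep in 1:8) {
      sc <- round(rnorm(40), 1)
      lb <- runif(40) < 0.45
      if (!any(lb) || all(lb)) next
      got <- youden_cutoff(roc_curve(sc, lb))
      ref <- youden_brute_force(sc, lb)
      expect_equal(got$cutoff, ref$cutoff)
      expect_equal(got$sensitivity, ref$sens)
      expect_equal(got$specificity, ref$spec)
    }
  })
  perfect <- youden_cutoff(roc_curve(c(9, 8, 2, 1), c(TRUE, TRUE, FALSE, FALSE)))
  expect_equal(perfect$youden, 1)
  expect_equal(perfect$sensitivity, 1); expect_equal(perfect$specificity, 1)
  # equal Youden at two cutoffs: the higher-specificity one is returned
  tie <- youden_cutoff(roc_curve(c(10, 9, 8, 7), c(TRUE, FALSE, TRUE, FALSE)))
  expect_equal(tie$cutoff, 10)
  expect_equal(tie$specificity, 1)
})

test_that("Youden maximality holds against every distinct threshold", {
  withr::with_seed(24, {
    sc <- rnorm(100); lb <- runif(100) < 0.4
  })
  curve <- roc_curve(sc, lb)
  yj <- youden_cutoff(curve)
  expect_true(all(yj$youden >= curve$tpr - curve$fpr - 1e-12))
})

test_that("hierarchical bootstrap is seeded, grouped, and degenerate-safe", {
  withr::with_seed(25, {
    df <- data.frame(score = rnorm(60), cancer = rep(c(TRUE, FALSE), 30),
                     group = rep(sprintf("g%02d", 1:12), each = 5))
  })
  stat <- function(d) mean(d$score)
  ci1 <- bootstrap_ci(stat, df, "test", n_boot = 200, seed = 7)
  ci2 <- bootstrap_ci(stat, df, "test", n_boot = 200, seed = 7)
  expect_identical(as.numeric(ci1), as.numeric(ci2))       # bit-reproducible
  expect_identical(attr(ci1, "replicates"), attr(ci2, "replicates"))
  # constant statistic collapses to a point interval
  cc <- bootstrap_ci(function(d) 42, df, "test", n_boot = 50, seed = 1)
  expect_equal(as.numeric(cc), c(42, 42))
  # the point estimate lies inside the percentile CI for these data
  est <- stat(df)
  ci <- bootstrap_ci(stat, df, "test", n_boot = 400, seed = 3)
  expect_true(ci[1] <= est && est <= ci[2])
})

test_that("test-mode resampling keeps every WSI pair's squares together", {
  sizes <- c(g1 = 3, g2 = 5, g3 = 7, g4 = 4)
  df <- data.frame(group = rep(names(sizes), sizes), x = seq_len(sum(sizes)))
  audit <- function(d) {
    tab <- table(d$group)
    orig <- sizes[names(tab)]
    if (any(tab %% orig != 0)) return(NA_real_)  # a broken group would force a redraw
    1
  }
  reps <- bootstrap_replicates(audit, df, "test", n_boot = 100, seed = 9)
  expect_true(all(reps == 1))
  expect_equal(attr(reps, "n_redraws"), 0L)
  # train mode resamples squares within groups but keeps the group sizes
  audit_train <- function(d) if (all(table(d$group) %% sizes[names(table(d$group))] == 0)) 1 else NA_real_
  reps_tr <- bootstrap_replicates(audit_train, df, "train", n_boot = 50, seed = 9)
  expect_true(all(reps_tr == 1))
  expect_error(bootstrap_replicates(audit, df[df$group == "g1", ], "test",
                                    n_boot = 5, seed = 1), "at least two groups")
})

test_that("CI-inversion p-values match the direct percentile identity", {
  withr::with_seed(26, {
    all_pos <- runif(1000, 0.01, 1)
    expect_lte(pvalue_by_ci_inversion(all_pos), 0.002)
    sym <- c(rnorm(500), -rnorm(500))
    expect_gt(pvalue_by_ci_inversion(sym), 0.9)
    for (shift in c(0.5, 1, 2)) {
      d <- rnorm(1000, mean = shift)
      p_inv <- pvalue_by_ci_inversion(d)
      p_direct <- max(2 * min(mean(d <= 0), mean(d >= 0)), 1 / length(d))
      expect_lt(abs(p_inv - p_direct), 0.01)
    }
  })
})

test_that("paired model comparison shares bootstrap resamples", {
  withr::with_seed(27, {
    df <- data.frame(cancer = rep(c(TRUE, FALSE), 40),
                     group = rep(sprintf("g%02d", 1:8), each = 10))
    df$sa <- rnorm(80, mean = ifelse(df$cancer, 2, 0))   # strong model
    df$sb <- rnorm(80, mean = ifelse(df$cancer, 0.2, 0)) # weak model
  })
  cmp <- compare_bootstrap(function(d) roc_curve(d$sa, d$cancer)$auc,
                           function(d) roc_curve(d$sb, d$cancer)$auc,
                           df, "test", n_boot = 300, seed = 5)
  expect_lt(cmp$p, 0.05)
  expect_gt(cmp$ci[1], 0)
  expect_length(cmp$diff_replicates, 300)
})

test_that("grade-group breakdown buckets Gleason scores correctly", {
  squares <- data.frame(
    label = c(rep("cancer", 6), "benign"),
    gleason = c("3 + 3", "3 + 4", "4 + 3", "4 + 4", "4 + 5", "5 + 4", NA))
  pred <- c(10, 10, 10, 1, 10, 10, 0)
  gb <- grade_group_breakdown(pred, cutoff = 5, squares)
  low <- gb[gb$type == "GG <= 2", ]
  high <- gb[gb$type == "GG >= 3", ]
  tot <- gb[gb$type == "Totals", ]
  expect_equal(low$n_squares, 2L)        # 3+3, 3+4
  expect_equal(high$n_squares, 4L)       # 4+3, 4+4, 4+5, 5+4
  expect_equal(low$n_squares + high$n_squares, tot$n_squares)
  expect_equal(high$sensitivity, 3 / 4)  # the 4+4 square fell below the cutoff
  expect_equal(gb$sensitivity[gb$type == "4 + 4"], 0)
  # every cancer square above the cutoff gives unit sensitivity everywhere
  gb1 <- grade_group_breakdown(rep(10, 7), cutoff = 5, squares)
  expect_true(all(gb1$sensitivity == 1))
  # unknown scores are dropped from grouped rows with a message
  squares$gleason[1] <- "weird"
  expect_message(gb2 <- grade_group_breakdown(pred, 5, squares), "unknown")
  expect_equal(gb2[gb2$type == "Totals", "n_squares"], 5L)
})

test_that("prediction maps are self-consistent with the cutoff rule", {
  g <- generate_grid(300, 200, 100)
  pred <- c(0, 10, 60, 80, 0, 5)
  out <- render_prediction_map(g, pred, cutoff = 50)
  expect_equal(sum(out$mask), 2L)
  expect_equal(out$heatmap[cbind(g$row, g$col)], pmin(pmax(pred, 0), 100))
  expect_equal(out$squares$above_cutoff, pred >= 50)
  # all-zero predictions give an empty mask
  empty <- render_prediction_map(g, rep(0, 6), cutoff = 10)
  expect_false(any(empty$mask))
  # single square above cutoff: the written rasters match the square set
  dir <- withr::local_tempdir()
  one <- c(0, 0, 99, 0, 0, 0)
  res <- render_prediction_map(g, one, cutoff = 50,
                               path_prefix = file.path(dir, "map"), cell_px = 4)
  mask_png <- png::readPNG(file.path(dir, "map_mask.png"))
  expect_equal(sum(mask_png > 0.5), 16)     # one 4x4 cell
  csv <- utils::read.csv(file.path(dir, "map_squares.csv"))
  expect_equal(which(csv$above_cutoff), 3L)
})

test_that("evaluate_predictions assembles a coherent summary", {
  withr::with_seed(28, {
    truth <- rep(c(TRUE, FALSE), 50)
    scores <- rnorm(100, mean = ifelse(truth, 3, 0))
    groups <- rep(sprintf("g%02d", 1:10), each = 10)
    gleason <- ifelse(truth, "3 + 4", NA)
  })
  ev <- evaluate_predictions(scores, ifelse(truth, "cancer", "benign"),
                             groups, gleason, n_boot = 100, seed = 2)
  expect_s3_class(ev, "stainmap_eval")
  expect_true(ev$auc > 0.9)
  expect_true(ev$ci_auc[1] <= ev$ci_auc[2])
  expect_equal(ev$grade_breakdown$type[1], "3 + 4")
  expect_equal(ev$sensitivity, mean(scores[truth] >= ev$cutoff))
  expect_equal(ev$specificity, mean(scores[!truth] < ev$cutoff))
})
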