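#' ROC curve over all distinct score thresholds
#'
#' Sweeps the decision rule `score >= threshold` over all distinct scores
#' (plus an infinite endpoint), accumulating true/false positive rates. The
#' AUC is the trapezoidal area, which equals the pairwise-concordance
#' probability with ties counted one half.
#'
#' @param scores Numeric prediction scores (raw, unclipped).
#' @param labels Logical or 0/1 vector (TRUE/1 = cancer).
#' @return Object of class `roc_curve`: `thresholds` (descending), `tpr`,
#'   `fpr`, `auc`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  if (anyNA(scores) || anyNA(labels)) stop("scores/labels must not contain NA")
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    stop("ROC undefined: both classes must be present")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  # group tied scores
  last <- !duplicated(s, fromLast = TRUE)        # last index of each tie group
  cum_tp <- cumsum(l)[last]
  cum_fp <- cumsum(!l)[last]
  thresholds <- c(Inf, s[last])
  tpr <- c(0, cum_tp / n_pos)
  fpr <- c(0, cum_fp / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(thresholds = thresholds, tpr = tpr, fpr = fpr, auc = auc,
                 n_pos = n_pos, n_neg = n_neg),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d cancer / %d benign squares, AUC = %.4f\n",
              x$n_pos, x$n_neg, x$auc))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "l", xlab = "1 - specificity",
                 ylab = "sensitivity", xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Youden-index operating point of an ROC curve
#'
#' Returns the threshold maximizing `J = sensitivity + specificity - 1`
#' (equivalently `tpr - fpr`); ties are broken toward higher specificity.
#'
#' @param curve A [roc_curve()].
#' @return List `cutoff`, `sensitivity`, `specificity`, `youden`.
#' @export
youden_cutoff <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  j <- curve$tpr - curve$fpr
  best <- which(j == max(j))
  if (length(best) > 1L) best <- best[which.min(curve$fpr[best])]
  k <- best[1L]
  cutoff <- curve$thresholds[k]
  if (!is.finite(cutoff)) cutoff <- max(curve$thresholds[is.finite(curve$thresholds)])
  list(cutoff = cutoff, sensitivity = curve$tpr[k],
       specificity = 1 - curve$fpr[k], youden = j[k])
}

# one resample of a grouped data frame; returns row indices
.resample_indices <- function(data, group_col, mode) {
  gids <- unique(data[[group_col]])
  picked <- sample(gids, length(gids), replace = TRUE)
  idx <- integer(0)
  for (g in picked) {
    rows <- which(data[[group_col]] == g)
    if (mode == "train") rows <- sample(rows, length(rows), replace = TRUE)
    idx <- c(idx, rows)
  }
  idx
}

#' Bootstrap replicates of a grouped statistic
#'
#' The hierarchical resampling honors the grouping of analysis squares into
#' WSI pairs: `mode = "test"` resamples WSI pairs with replacement keeping
#' all their squares; `mode = "train"` additionally resamples squares with
#' replacement within each sampled pair (same size as the original pair).
#' Replicates on which the statistic is undefined (e.g. a single-class
#' resample for AUC) are redrawn, up to 100 redraws each.
#'
#' @param statistic Function of a data-frame subset returning a scalar.
#' @param data Data frame of per-square rows.
#' @param mode `"test"` or `"train"`.
#' @param n_boot Number of replicates.
#' @param seed RNG seed (reproducible replicate stream).
#' @param group_col Name of the WSI-pair identifier column.
#' @return Numeric vector of `n_boot` replicate statistics, with attribute
#'   `n_redraws`.
#' @export
bootstrap_replicates <- function(statistic, data, mode = c("test", "train"),
                                 n_boot = 1000L, seed = 1L, group_col = "group") {
  mode <- match.arg(mode)
  if (length(unique(data[[group_col]])) < 2L) {
    stop("hierarchical bootstrap needs at least two groups")
  }
  withr::with_seed(seed, {
    reps <- numeric(n_boot)
    redraws <- 0L
    for (b in seq_len(n_boot)) {
      val <- NA_real_
      for (try in seq_len(100L)) {
        idx <- .resample_indices(data, group_col, mode)
        val <- tryCatch(statistic(data[idx, , drop = FALSE]),
                        error = function(e) NA_real_)
        if (is.finite(val)) break
        redraws <- redraws + 1L
      }
      if (!is.finite(val)) stop("bootstrap statistic undefined on 100 consecutive redraws")
      reps[b] <- val
    }
    if (redraws > 0L) {
      message(sprintf("bootstrap: %d replicate(s) redrawn (undefined statistic)", redraws))
    }
    attr(reps, "n_redraws") <- redraws
    reps
  })
}

#' Percentile bootstrap confidence interval of a grouped statistic
#'
#' @inheritParams bootstrap_replicates
#' @param level Confidence level (default 0.95).
#' @return Length-2 vector `(lo, hi)` with attribute `replicates`.
#' @export
bootstrap_ci <- function(statistic, data, mode = c("test", "train"),
                         n_boot = 1000L, level = 0.95, seed = 1L,
                         group_col = "group") {
  reps <- bootstrap_replicates(statistic, data, mode, n_boot, seed, group_col)
  a <- (1 - level) / 2
  ci <- unname(stats::quantile(reps, c(a, 1 - a)))
  attr(ci, "replicates") <- as.numeric(reps)
  attr(ci, "n_redraws") <- attr(reps, "n_redraws")
  ci
}

#' Two-sided p-value by bootstrap CI inversion
#'
#' The p-value is the smallest `a` on a 0.001-step grid such that the
#' `(1 - a)` percentile CI of the bootstrap difference distribution excludes
#' zero, floored at `1 / n_boot` (CI inversion cannot resolve below the
#' replicate granularity).
#'
#' @param diff_replicates Bootstrap replicates of a paired statistic
#'   difference (computed on shared resamples).
#' @return p-value in `(0, 1]`.
#' @export
pvalue_by_ci_inversion <- function(diff_replicates) {
  d <- diff_replicates[is.finite(diff_replicates)]
  n <- length(d)
  if (n == 0L) stop("no finite bootstrap differences")
  alphas <- seq(0.001, 0.999, by = 0.001)
  lo <- stats::quantile(d, alphas / 2, names = FALSE)
  hi <- stats::quantile(d, 1 - alphas / 2, names = FALSE)
  excl <- lo > 0 | hi < 0
  p <- if (any(excl)) alphas[which(excl)[1L]] else 1
  max(p, 1 / n)
}

#' Compare two models' test statistics on shared bootstrap resamples
#'
#' Draws one stream of hierarchical resamples and evaluates the difference
#' `statistic_a - statistic_b` on each, yielding paired replicates for CI
#' inversion.
#'
#' @param statistic_a,statistic_b Functions of a data-frame subset.
#' @param data,mode,n_boot,seed,group_col As in [bootstrap_replicates()].
#' @return List `diff_replicates`, `p`, `ci` (95% percentile CI of the
#'   difference).
#' @export
compare_bootstrap <- function(statistic_a, statistic_b, data,
                              mode = c("test", "train"), n_boot = 1000L,
                              seed = 1L, group_col = "group") {
  both <- function(df) statistic_a(df) - statistic_b(df)
  reps <- bootstrap_replicates(both, data, mode, n_boot, seed, group_col)
  list(diff_replicates = as.numeric(reps),
       p = pvalue_by_ci_inversion(reps),
       ci = unname(stats::quantile(reps, c(0.025, 0.975))))
}

#' Sensitivity breakdown by Gleason score and grade group
#'
#' Per-score sensitivity (correctly labeled / total cancer squares with that
#' score, under the rule `score >= cutoff`), aggregated into grade groups:
#' GG <= 2 (GS 3+3, 3+4; low to intermediate grade) and GG >= 3 (GS 4+3,
#' 4+4, 4+5, 5+4; high grade), plus a totals row. Cancer squares with
#' unrecognized score strings are dropped from the grouped rows with a
#' message.
#'
#' @param predictions Numeric scores, one per square.
#' @param cutoff Operating threshold (typically the Youden cutoff).
#' @param squares Data frame with columns `label` (`"cancer"`/`"benign"`)
#'   and `gleason`.
#' @return Data frame: `type`, `n_squares`, `n_correct`, `sensitivity`.
#' @export
grade_group_breakdown <- function(predictions, cutoff, squares) {
  stopifnot(length(predictions) == nrow(squares))
  cancer <- squares$label == "cancer"
  gs <- vapply(squares$gleason, function(g)
    if (is.na(g)) NA_character_ else normalize_gleason(g), "")
  gg <- gs_grade_group(ifelse(is.na(gs), "", gs))
  correct <- predictions >= cutoff
  unknown <- cancer & is.na(gg)
  if (any(unknown)) {
    message(sprintf("%d cancer square(s) with unknown Gleason score dropped from grade-group rows",
                    sum(unknown)))
  }
  row_for <- function(sel, name) {
    data.frame(type = name, n_squares = sum(sel), n_correct = sum(sel & correct),
               sensitivity = if (sum(sel)) sum(sel & correct) / sum(sel) else NA_real_,
               stringsAsFactors = FALSE)
  }
  known <- cancer & !is.na(gg)
  per_gs <- lapply(sort(unique(gs[known])), function(g) row_for(known & gs == g, g))
  out <- rbind(do.call(rbind, per_gs),
               row_for(known & gg <= 2L, "GG <= 2"),
               row_for(known & gg >= 3L, "GG >= 3"),
               row_for(known, "Totals"))
  rownames(out) <- NULL
  out
}

#' Render per-square prediction maps
#'
#' Builds a continuous heatmap of predicted % malignant epithelium (one cell
#' per analysis square, clipped to 0-100 for display) and a binary map of
#' squares at or above the cutoff. Optionally writes both as PNG (the
#' heatmap on a white-to-red ramp) plus the per-square CSV.
#'
#' @param grid Labeled grid data frame.
#' @param predictions Numeric scores aligned with `grid` rows.
#' @param cutoff Operating threshold.
#' @param path_prefix If non-NULL, writes `<prefix>_heatmap.png`,
#'   `<prefix>_mask.png` and `<prefix>_squares.csv`.
#' @param cell_px Pixels per square in the rendered rasters (default 12).
#' @return List `heatmap` (matrix of clipped predictions, grid layout),
#'   `mask` (logical matrix), `squares` (per-square data frame).
#' @export
render_prediction_map <- function(grid, predictions, cutoff,
                                  path_prefix = NULL, cell_px = 12L) {
  stopifnot(length(predictions) == nrow(grid))
  nrows <- max(grid$row); ncols <- max(grid$col)
  heat <- matrix(NA_real_, nrows, ncols)
  heat[cbind(grid$row, grid$col)] <- pmin(pmax(predictions, 0), 100)
  mask <- !is.na(heat) & heat >= cutoff
  squares <- cbind(grid[, c("row", "col", "x0", "y0", "x1", "y1", "label")],
                   prediction = predictions, above_cutoff = predictions >= cutoff)
  if (!is.null(path_prefix)) {
    up <- function(m) m[rep(seq_len(nrow(m)), each = cell_px),
                        rep(seq_len(ncol(m)), each = cell_px), drop = FALSE]
    v <- up(heat) / 100
    v[is.na(v)] <- 0
    img <- array(1, dim = c(dim(v), 3))
    img[, , 2] <- 1 - v          # white -> red ramp
    img[, , 3] <- 1 - v
    png::writePNG(img, paste0(path_prefix, "_heatmap.png"))
    png::writePNG(up(mask) + 0, paste0(path_prefix, "_mask.png"))
    utils::write.csv(squares, paste0(path_prefix, "_squares.csv"), row.names = FALSE)
  }
  list(heatmap = heat, mask = mask, squares = squares)
}

#' Full square-level evaluation of a model's test predictions
#'
#' Computes the ROC curve and AUC against the square labels, the Youden
#' operating point, hierarchical bootstrap CIs for AUC, sensitivity and
#' specificity (sensitivity/specificity evaluated at the point-estimate
#' cutoff within each replicate), and the grade-group breakdown.
#'
#' @param scores Raw predicted % malignant epithelium.
#' @param labels `"cancer"`/`"benign"` labels (or logical).
#' @param groups WSI-pair identifiers.
#' @param gleason Gleason score strings (NA for benign squares).
#' @param mode Bootstrap mode (`"test"` resamples pairs only).
#' @param n_boot,level,seed Bootstrap settings.
#' @return List of class `stainmap_eval`: `roc`, `auc`, `cutoff`,
#'   `sensitivity`, `specificity`, `ci_auc`, `ci_sens`, `ci_spec`,
#'   `grade_breakdown`, `n_boot`, `seed`.
#' @export
evaluate_predictions <- function(scores, labels, groups, gleason = NULL,
                                 mode = "test", n_boot = 1000L, level = 0.95,
                                 seed = 1L) {
  is_cancer <- if (is.logical(labels)) labels else labels == "cancer"
  roc <- roc_curve(scores, is_cancer)
  yj <- youden_cutoff(roc)
  df <- data.frame(score = scores, cancer = is_cancer, group = groups,
                   stringsAsFactors = FALSE)
  stat_auc <- function(d) roc_curve(d$score, d$cancer)$auc
  stat_sens <- function(d) {
    if (!any(d$cancer)) return(NA_real_)
    mean(d$score[d$cancer] >= yj$cutoff)
  }
  stat_spec <- function(d) {
    if (all(d$cancer)) return(NA_real_)
    mean(d$score[!d$cancer] < yj$cutoff)
  }
  ci_auc <- bootstrap_ci(stat_auc, df, mode, n_boot, level, seed)
  ci_sens <- bootstrap_ci(stat_sens, df, mode, n_boot, level, seed + 1L)
  ci_spec <- bootstrap_ci(stat_spec, df, mode, n_boot, level, seed + 2L)
  gb <- if (!is.null(gleason)) {
    grade_group_breakdown(scores, yj$cutoff,
                          data.frame(label = ifelse(is_cancer, "cancer", "benign"),
                                     gleason = gleason, stringsAsFactors = FALSE))
  } else NULL
  structure(list(roc = roc, auc = roc$auc, cutoff = yj$cutoff,
                 sensitivity = yj$sensitivity, specificity = yj$specificity,
                 ci_auc = as.numeric(ci_auc), ci_sens = as.numeric(ci_sens),
                 ci_spec = as.numeric(ci_spec), grade_breakdown = gb,
                 n_boot = n_boot, level = level, seed = seed),
            class = "stainmap_eval")
}

#' @export
print.stainmap_eval <- function(x, ...) {
  cat(sprintf("AUC %.3f [%.3f, %.3f]  sens %.3f [%.3f, %.3f]  spec %.3f [%.3f, %.3f]  (cutoff %.3f, %d bootstrap reps)\n",
              x$auc, x$ci_auc[1], x$ci_auc[2],
              x$sensitivity, x$ci_sens[1], x$ci_sens[2],
              x$specificity, x$ci_spec[1], x$ci_spec[2],
              x$cutoff, x$n_boot))
  invisible(x)
}
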