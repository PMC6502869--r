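#' Names of the seven predictive features
#'
#' Column order is fixed: the three H&E positive-pixel-count percentages,
#' the two deconvolution OD x %Pos products, then the two co-expression
#' percentages. The named feature subsets in [feature_set_columns()] index
#' into this order.
#'
#' @return Character vector of length 7.
#' @export
feature_names <- function() {
  c("pct_nuclei", "pct_cytoplasm", "pct_stroma",
    "od_x_pctpos_brown", "od_x_pctpos_red",
    "pctpos_ce_brown", "pctpos_ce_red")
}

#' Feature columns of a named feature set
#'
#' Four model variants are trained: H&E features only, IHC features only,
#' all features except the two co-expression percentages, and all seven.
#'
#' @param set One of `"he"`, `"ihc"`, `"full_minus_ce"`, `"full"`.
#' @return Character vector of feature names.
#' @export
feature_set_columns <- function(set = c("full", "he", "ihc", "full_minus_ce")) {
  set <- match.arg(set)
  fn <- feature_names()
  switch(set,
         he = fn[1:3],
         ihc = fn[4:7],
         full_minus_ce = fn[1:5],
         full = fn)
}

#' Unstained percentage of an analysis square
#'
#' `% unstained = 100 - (% nuclei + % cytoplasm + % stroma)`, floored at 0.
#' Because the three PPC ranges are disjoint, the three percentages cannot
#' legitimately sum above 100; a sum beyond tolerance indicates an
#' inconsistent PPC configuration and is an error.
#'
#' @param pct_nuclei,pct_cytoplasm,pct_stroma Percentages in `[0, 100]`.
#' @return Percentage in `[0, 100]`.
#' @export
compute_unstained <- function(pct_nuclei, pct_cytoplasm, pct_stroma) {
  vals <- c(pct_nuclei, pct_cytoplasm, pct_stroma)
  if (any(vals < 0 | vals > 100)) stop("PPC percentages must lie in [0, 100]")
  s <- pct_nuclei + pct_cytoplasm + pct_stroma
  if (s > 100 + 1e-9) {
    stop("inconsistent PPC output: compartment percentages sum above 100 (ranges not disjoint?)")
  }
  max(0, 100 - s)
}

#' Extract the per-square feature vector
#'
#' Computes the seven predictive features for one analysis square: the three
#' H&E compartment percentages by positive pixel counting, the two
#' OD x %Pos products by color deconvolution of the IHC tile, and the two
#' single-stain co-expression percentages; plus the derived unstained
#' percentage.
#'
#' @param he_tile,ihc_tile Same-size RGB crops of one analysis square from
#'   the registered H&E and IHC frames.
#' @param ppc_config A [ppc_config()] for the tile's staining batch.
#' @param cd_config A [cd_config()].
#' @param square_id Grid reference carried through to the output.
#' @return One-row data frame: `square_id`, `batch_id`, the seven features
#'   in [feature_names()] order, and `pct_unstained`.
#' @export
extract_features <- function(he_tile, ihc_tile, ppc_config, cd_config,
                             square_id = NA_character_) {
  stopifnot(inherits(ppc_config, "ppc_config"), inherits(cd_config, "cd_config"))
  dhe <- dim(he_tile); dihc <- dim(ihc_tile)
  if (!identical(dhe[1:2], dihc[1:2])) {
    stop("H&E and IHC tiles must crop the same analysis square (dimension mismatch)")
  }
  pct_nuclei    <- positive_pixel_percent(he_tile, ppc_config$ranges$nuclei)
  pct_cytoplasm <- positive_pixel_percent(he_tile, ppc_config$ranges$cytoplasm)
  pct_stroma    <- positive_pixel_percent(he_tile, ppc_config$ranges$stroma)
  cd_brown <- cd_quantify(ihc_tile, cd_config, "brown")
  cd_red   <- cd_quantify(ihc_tile, cd_config, "red")
  ce       <- ce_quantify(ihc_tile, cd_config)
  data.frame(square_id = square_id, batch_id = ppc_config$batch_id,
             pct_nuclei = pct_nuclei, pct_cytoplasm = pct_cytoplasm,
             pct_stroma = pct_stroma,
             od_x_pctpos_brown = cd_brown$od_x_pctpos,
             od_x_pctpos_red = cd_red$od_x_pctpos,
             pctpos_ce_brown = ce$pctpos_ce_brown,
             pctpos_ce_red = ce$pctpos_ce_red,
             pct_unstained = compute_unstained(pct_nuclei, pct_cytoplasm, pct_stroma),
             stringsAsFactors = FALSE)
}

#' Apply the unstained (off-tissue) exclusion to a square
#'
#' Squares that are more than `threshold` percent unstained on H&E (strict
#' inequality) sit outside the tissue boundary and are excluded with reason
#' `"unstained"`.
#'
#' @param square One grid row (list or one-row data frame).
#' @param fv Feature vector row from [extract_features()].
#' @param threshold Percentage threshold, default 99.
#' @return The square with `excluded`/`reason` updated.
#' @export
apply_unstained_exclusion <- function(square, fv, threshold = 99) {
  if (fv$pct_unstained > threshold) {
    square$excluded <- TRUE
    square$reason <- "unstained"
  }
  square
}

#' Crop one analysis square from an image
#'
#' @param img Matrix or h x w x 3 array.
#' @param square Grid row with 0-based half-open bounds `x0`,`y0`,`x1`,`y1`.
#' @return The cropped tile.
#' @export
crop_square <- function(img, square) {
  rows <- (square$y0 + 1):square$y1
  cols <- (square$x0 + 1):square$x1
  if (is.matrix(img)) img[rows, cols, drop = FALSE] else img[rows, cols, , drop = FALSE]
}

#' Extract the feature table for a labeled grid
#'
#' Loops over grid squares, crops the H&E and registered IHC images, computes
#' the feature vector for each square, and applies the unstained exclusion.
#' Squares already excluded (negative-annotation overlap) keep their features
#' but stay excluded.
#'
#' @param he_img H&E image (h x w x 3).
#' @param ihc_reg_img IHC image already warped into the H&E frame.
#' @param grid Labeled grid data frame ([label_squares()]).
#' @param ppc_config,cd_config Colorimetry configurations.
#' @param unstained_threshold Percent-unstained exclusion threshold.
#' @return Data frame: grid columns plus the feature columns.
#' @export
extract_feature_table <- function(he_img, ihc_reg_img, grid, ppc_config, cd_config,
                                  unstained_threshold = 99) {
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    sq <- grid[i, , drop = FALSE]
    fv <- extract_features(crop_square(he_img, sq), crop_square(ihc_reg_img, sq),
                           ppc_config, cd_config,
                           square_id = sprintf("r%02dc%02d", sq$row, sq$col))
    sq <- apply_unstained_exclusion(sq, fv, unstained_threshold)
    rows[[i]] <- cbind(sq, fv[, setdiff(names(fv), "square_id"), drop = FALSE],
                       square_id = fv$square_id)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
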