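# Internal class codes for the scene raster. Codes 4-6 collapse to benign
# epithelium and 7-8 to malignant epithelium in the 5-class ground truth.
.CLS <- c(glass = 1L, stroma = 2L, lumen = 3L,
          benign_inner = 4L, benign_outer = 5L, basal = 6L,
          malig_inner = 7L, malig_outer = 8L)
.MALIG_CODES  <- c(7L, 8L)
.BENIGN_CODES <- c(4L, 5L, 6L)

# H&E palette: colors occupy disjoint HSB boxes so the default PPC ranges
# separate them (nuclei purple, cytoplasm pink, stroma pale pink).
.HE_COLORS <- rbind(
  glass        = c(255, 255, 255),
  stroma       = c(244, 210, 222),
  lumen        = c(255, 255, 255),
  benign_inner = c(115,  60, 160),   # nuclear band
  benign_outer = c(233, 150, 180),   # cytoplasmic band
  basal        = c(115,  60, 160),
  malig_inner  = c(115,  60, 160),
  malig_outer  = c(233, 150, 180)
)

# IHC stain concentrations (red = Fast Red, brown = DAB, blue = hematoxylin)
.IHC_CONC <- rbind(
  glass        = c(0,    0,    0),
  stroma       = c(0,    0,    0.55),
  lumen        = c(0,    0,    0),
  benign_inner = c(0,    0,    0.45),
  benign_outer = c(0,    0,    0.45),
  basal        = c(0,    0.85, 0.15),
  malig_inner  = c(0.90, 0,    0.15),
  malig_outer  = c(0.90, 0,    0.15)
)
.IHC_CONC_DROPOUT  <- c(0, 0, 0.45)      # AMACR-negative malignant epithelium
.IHC_CONC_ARTIFACT <- c(0.5, 0.5, 0.35)  # double-staining debris/fold
.IHC_CONC_DEBRIS   <- c(0.6, 0.6, 0.30)  # corpora-amylacea-like dots
.HE_ARTIFACT_COLOR <- c(90, 85, 85)      # dark tissue fold on H&E

#' Configure a phantom slide pair
#'
#' The phantom emulates a pair of serially-sectioned tiles: an H&E tile and
#' an IHC tile (HMWCK+p63 brown, AMACR red, hematoxylin blue) of the same
#' tissue, with a known rigid misalignment between them. Glands are ellipses
#' with an annular epithelial band and a central lumen, one gland slot per
#' analysis-square-sized cell; benign glands carry a thin brown basal ring,
#' malignant glands omit the ring and stain red (unless AMACR dropout).
#'
#' @param width_px,height_px Image dimensions in pixels; must fit at least
#'   one analysis square.
#' @param square_px Analysis-square (and gland-cell) side length in pixels.
#' @param n_glands Number of glands (default: one per cell).
#' @param malignant_fraction Probability that a gland is malignant.
#' @param gs_palette Gleason-score strings assignable to malignant regions.
#' @param amacr_dropout Fraction of malignant glands rendered AMACR-negative.
#' @param artifact_fraction Fraction of tile area covered by
#'   negative-annotation artifacts.
#' @param debris_fraction Fraction of area covered by double-stained debris
#'   dots (no negative annotation; default 0).
#' @param color_jitter_sd Per-channel additive Gaussian noise SD in OD units
#'   (stain variability is multiplicative in intensity).
#' @param rigid_offset Length-3 `(tx, ty, theta_deg)` misalignment of the
#'   IHC rendering; the stored `true_transform` maps IHC coordinates back to
#'   the H&E frame.
#' @param dilation_px Dilation radius for the coarse cancer-region outlines
#'   drawn around malignant glands (default 12% of `square_px`).
#' @param seed RNG seed; the same config and seed give bit-identical output.
#' @param i0 White reference intensity (fixed default 255).
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(width_px = 800L, height_px = 500L, square_px = 100L,
                           n_glands = NULL, malignant_fraction = 0.3,
                           gs_palette = c("3 + 3", "3 + 4", "4 + 3",
                                          "4 + 4", "4 + 5", "5 + 4"),
                           amacr_dropout = 0, artifact_fraction = 0.03,
                           debris_fraction = 0, color_jitter_sd = 0.02,
                           rigid_offset = c(0, 0, 0), dilation_px = NULL,
                           seed = 1L, i0 = 255) {
  ncols <- width_px %/% square_px
  nrows <- height_px %/% square_px
  if (ncols < 1L || nrows < 1L) {
    stop("phantom dimensions must fit at least one analysis square")
  }
  n_cells <- ncols * nrows
  if (is.null(n_glands)) n_glands <- n_cells
  fracs <- c(malignant_fraction, amacr_dropout, artifact_fraction, debris_fraction)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must lie in [0, 1]")
  if (n_glands == 0L && malignant_fraction > 0) {
    stop("invalid config: malignant_fraction > 0 requires at least one gland")
  }
  if (n_glands > n_cells) {
    stop(sprintf("n_glands (%d) exceeds the %d available gland cells", n_glands, n_cells))
  }
  if (length(rigid_offset) != 3L) stop("rigid_offset must be (tx, ty, theta)")
  if (color_jitter_sd < 0) stop("color_jitter_sd must be >= 0")
  if (is.null(dilation_px)) dilation_px <- 0.12 * square_px
  structure(list(width_px = as.integer(width_px), height_px = as.integer(height_px),
                 square_px = as.integer(square_px), n_glands = as.integer(n_glands),
                 malignant_fraction = malignant_fraction, gs_palette = gs_palette,
                 amacr_dropout = amacr_dropout, artifact_fraction = artifact_fraction,
                 debris_fraction = debris_fraction, color_jitter_sd = color_jitter_sd,
                 rigid_offset = as.numeric(rigid_offset), dilation_px = dilation_px,
                 seed = as.integer(seed), i0 = i0),
            class = "phantom_config")
}

# draw the gland layout, artifacts and debris (uses the current RNG stream)
.sample_scene <- function(config) {
  s <- config$square_px
  ncols <- config$width_px %/% s
  nrows <- config$height_px %/% s
  n_cells <- ncols * nrows
  cells <- if (config$n_glands > 0) sort(sample.int(n_cells, config$n_glands)) else integer()
  glands <- NULL
  if (length(cells)) {
    cr <- ((cells - 1L) %/% ncols) + 1L    # grid row
    cc <- ((cells - 1L) %%  ncols) + 1L    # grid col
    n <- length(cells)
    malignant <- stats::runif(n) < config$malignant_fraction
    glands <- data.frame(
      cell_row = cr, cell_col = cc,
      cx = (cc - 0.5) * s + stats::runif(n, -0.05, 0.05) * s,
      cy = (cr - 0.5) * s + stats::runif(n, -0.05, 0.05) * s,
      a = stats::runif(n, 0.40, 0.46) * s,
      b = stats::runif(n, 0.40, 0.46) * s,
      phi = stats::runif(n, 0, pi),
      ring_px = stats::runif(n, 2, 4),
      lumen_frac = stats::runif(n, 0.30, 0.40),
      malignant = malignant,
      dropout = malignant & (stats::runif(n) < config$amacr_dropout),
      gleason = ifelse(malignant,
                       sample(config$gs_palette, n, replace = TRUE),
                       NA_character_),
      stringsAsFactors = FALSE
    )
  }
  artifacts <- NULL
  if (config$artifact_fraction > 0) {
    target <- config$artifact_fraction * config$width_px * config$height_px
    acc <- 0; rects <- list()
    while (acc < target && length(rects) < 200L) {
      rw <- stats::runif(1, 0.25, 0.45) * s
      rh <- stats::runif(1, 0.25, 0.45) * s
      rx <- stats::runif(1, 0, config$width_px - rw)
      ry <- stats::runif(1, 0, config$height_px - rh)
      rects[[length(rects) + 1L]] <- c(rx, ry, rx + rw, ry + rh)
      acc <- acc + rw * rh
    }
    artifacts <- do.call(rbind, rects)
    colnames(artifacts) <- c("x0", "y0", "x1", "y1")
  }
  debris <- NULL
  if (config$debris_fraction > 0) {
    target <- config$debris_fraction * config$width_px * config$height_px
    acc <- 0; dots <- list()
    while (acc < target && length(dots) < 5000L) {
      r <- stats::runif(1, 1.5, 3)
      dots[[length(dots) + 1L]] <- c(stats::runif(1, 0, config$width_px),
                                     stats::runif(1, 0, config$height_px), r)
      acc <- acc + pi * r^2
    }
    debris <- do.call(rbind, dots)
    colnames(debris) <- c("cx", "cy", "r")
  }
  list(glands = glands, artifacts = artifacts, debris = debris,
       ncols = ncols, nrows = nrows)
}

# classify scene-frame coordinates; returns list(class codes, gland index)
.classify_points <- function(xs, ys, scene) {
  n <- length(xs)
  cls <- rep(.CLS[["stroma"]], n)
  gland_of <- rep(NA_integer_, n)
  g <- scene$glands
  if (is.null(g)) return(list(class = cls, gland = gland_of))
  for (k in seq_len(nrow(g))) {
    rmax <- max(g$a[k], g$b[k]) + 1
    sel <- which(abs(xs - g$cx[k]) <= rmax & abs(ys - g$cy[k]) <= rmax)
    if (!length(sel)) next
    dx <- xs[sel] - g$cx[k]; dy <- ys[sel] - g$cy[k]
    cs <- cos(g$phi[k]); sn <- sin(g$phi[k])
    u <- dx * cs + dy * sn
    v <- -dx * sn + dy * cs
    a <- g$a[k]; b <- g$b[k]
    q_out <- (u / a)^2 + (v / b)^2
    ins <- q_out <= 1
    if (!any(ins)) next
    sel <- sel[ins]; u <- u[ins]; v <- v[ins]
    la <- g$lumen_frac[k] * a; lb <- g$lumen_frac[k] * b
    q_lum <- (u / la)^2 + (v / lb)^2
    ma <- (la + a) / 2; mb <- (lb + b) / 2
    q_mid <- (u / ma)^2 + (v / mb)^2
    ra <- max(a - g$ring_px[k], la); rb <- max(b - g$ring_px[k], lb)
    q_ring <- (u / ra)^2 + (v / rb)^2
    code <- integer(length(sel))
    lum <- q_lum <= 1
    code[lum] <- .CLS[["lumen"]]
    if (g$malignant[k]) {
      code[!lum] <- ifelse(q_mid[!lum] <= 1, .CLS[["malig_inner"]], .CLS[["malig_outer"]])
    } else {
      ringed <- !lum & q_ring > 1
      code[ringed] <- .CLS[["basal"]]
      rest <- !lum & !ringed
      code[rest] <- ifelse(q_mid[rest] <= 1, .CLS[["benign_inner"]], .CLS[["benign_outer"]])
    }
    cls[sel] <- code
    gland_of[sel] <- k
  }
  list(class = cls, gland = gland_of)
}

.in_rects <- function(xs, ys, rects) {
  hit <- rep(FALSE, length(xs))
  if (is.null(rects)) return(hit)
  for (k in seq_len(nrow(rects))) {
    hit <- hit | (xs >= rects[k, "x0"] & xs < rects[k, "x1"] &
                    ys >= rects[k, "y0"] & ys < rects[k, "y1"])
  }
  hit
}

.in_debris <- function(xs, ys, debris) {
  hit <- rep(FALSE, length(xs))
  if (is.null(debris)) return(hit)
  for (k in seq_len(nrow(debris))) {
    hit <- hit | ((xs - debris[k, "cx"])^2 + (ys - debris[k, "cy"])^2 <=
                    debris[k, "r"]^2)
  }
  hit
}

.add_od_jitter <- function(img, sd, i0) {
  if (sd <= 0) return(img)
  od <- rgb_to_od(img, i0)
  od <- od + stats::rnorm(length(od), sd = sd)
  pmin(pmax(od_to_rgb(od, i0), 0), i0)
}

# ellipse polygon (dilated by d) used for coarse cancer-region outlines
.ellipse_polygon <- function(cx, cy, a, b, phi, d, n = 48L) {
  t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  u <- (a + d) * cos(t); v <- (b + d) * sin(t)
  cbind(cx + u * cos(phi) - v * sin(phi),
        cy + u * sin(phi) + v * cos(phi))
}

#' Render a paired synthetic H&E/IHC tile
#'
#' The IHC image is synthesized per-pixel by the forward Beer-Lambert model
#' `I_c = I0 * 10^(-sum_s conc_s * v_{s,c})` using the configured normalized
#' stain vectors, rendered directly in the misaligned IHC frame (each IHC
#' pixel samples the scene at `true_transform(pixel)`). The H&E image and all
#' ground-truth rasters are rendered in the H&E frame. Images are kept as
#' continuous intensities in `[0, i0]`; quantization to 8 bits happens only
#' on write ([write_phantom_pair()]).
#'
#' @param config A [phantom_config()].
#' @param stain_mat Optional [stain_matrix()] used for the forward rendering
#'   (default: the standard chromogen vectors).
#' @return An object of class `phantom_pair`: `he_image`, `ihc_image`
#'   (h x w x 3 arrays), `class_raster` (h x w integer scene codes),
#'   `cancer_mask`, `negative_mask` (logical matrices), `cancer_regions`,
#'   `negative_regions` (annotation lists), `true_transform`
#'   (a [rigid_transform()] mapping IHC to H&E coordinates), `glands`,
#'   `config`.
#' @export
render_phantom_pair <- function(config, stain_mat = stain_matrix()) {
  stopifnot(inherits(config, "phantom_config"))
  withr::with_seed(config$seed, {
    w <- config$width_px; h <- config$height_px; i0 <- config$i0
    scene <- .sample_scene(config)

    # --- ground truth (H&E frame, pre-noise, pre-transform) ---
    gx <- rep(seq_len(w) - 0.5, each = h)
    gy <- rep(seq_len(h) - 0.5, times = w)
    cls_he <- .classify_points(gx, gy, scene)
    class_raster <- matrix(cls_he$class, h, w)

    # --- H&E rendering ---
    he_cols <- .HE_COLORS[cls_he$class, , drop = FALSE]
    art_he <- .in_rects(gx, gy, scene$artifacts)
    he_cols[art_he, ] <- rep(.HE_ARTIFACT_COLOR, each = sum(art_he))
    he <- array(0, dim = c(h, w, 3))
    for (k in 1:3) he[, , k] <- matrix(he_cols[, k], h, w)
    he <- .add_od_jitter(he, config$color_jitter_sd, i0)

    # --- IHC rendering in the misaligned frame ---
    true_transform <- rigid_transform(config$rigid_offset[1], config$rigid_offset[2],
                                      config$rigid_offset[3], center = c(w / 2, h / 2))
    src <- apply_transform(true_transform, cbind(gx, gy))
    cls_ihc <- .classify_points(src[, 1], src[, 2], scene)
    conc <- .IHC_CONC[cls_ihc$class, , drop = FALSE]
    if (!is.null(scene$glands) && any(scene$glands$dropout)) {
      dropped <- !is.na(cls_ihc$gland) & scene$glands$dropout[cls_ihc$gland] &
        cls_ihc$class %in% .MALIG_CODES
      conc[dropped, ] <- rep(.IHC_CONC_DROPOUT, each = sum(dropped))
    }
    deb <- .in_debris(src[, 1], src[, 2], scene$debris)
    conc[deb, ] <- rep(.IHC_CONC_DEBRIS, each = sum(deb))
    art <- .in_rects(src[, 1], src[, 2], scene$artifacts)
    conc[art, ] <- rep(.IHC_CONC_ARTIFACT, each = sum(art))
    rgb <- stains_to_rgb(conc, stain_mat, i0)
    ihc <- array(0, dim = c(h, w, 3))
    for (k in 1:3) ihc[, , k] <- matrix(rgb[, k], h, w)
    ihc <- .add_od_jitter(ihc, config$color_jitter_sd, i0)

    # --- annotations (H&E frame) ---
    cancer_regions <- list()
    if (!is.null(scene$glands)) {
      g <- scene$glands
      for (k in which(g$malignant)) {
        poly <- .ellipse_polygon(g$cx[k], g$cy[k], g$a[k], g$b[k], g$phi[k],
                                 config$dilation_px)
        cancer_regions[[length(cancer_regions) + 1L]] <-
          annotation_region(poly, kind = "cancer", gleason = g$gleason[k])
      }
    }
    negative_regions <- list()
    if (!is.null(scene$artifacts)) {
      for (k in seq_len(nrow(scene$artifacts))) {
        r <- scene$artifacts[k, ]
        poly <- rbind(c(r["x0"], r["y0"]), c(r["x1"], r["y0"]),
                      c(r["x1"], r["y1"]), c(r["x0"], r["y1"]))
        negative_regions[[length(negative_regions) + 1L]] <-
          annotation_region(poly, kind = "negative")
      }
    }
    cancer_mask <- matrix(FALSE, h, w)
    for (r in cancer_regions) {
      cancer_mask <- cancer_mask | rasterize_polygon(r$geometry, w, h)
    }
    negative_mask <- matrix(.in_rects(gx, gy, scene$artifacts), h, w)

    structure(list(he_image = he, ihc_image = ihc, class_raster = class_raster,
                   cancer_mask = cancer_mask, negative_mask = negative_mask,
                   cancer_regions = cancer_regions,
                   negative_regions = negative_regions,
                   true_transform = true_transform,
                   glands = scene$glands, config = config),
              class = "phantom_pair")
  })
}

#' @export
print.phantom_pair <- function(x, ...) {
  g <- x$glands
  cat(sprintf("<phantom_pair> %d x %d px, %d glands (%d malignant), offset (%.1f, %.1f, %.2f deg)\n",
              x$config$width_px, x$config$height_px,
              if (is.null(g)) 0L else nrow(g),
              if (is.null(g)) 0L else sum(g$malignant),
              x$config$rigid_offset[1], x$config$rigid_offset[2],
              x$config$rigid_offset[3]))
  invisible(x)
}

#' Five-class ground-truth raster of a phantom pair
#'
#' Collapses the internal scene codes to the annotation vocabulary:
#' 1 = glass, 2 = stroma, 3 = lumen, 4 = benign epithelium,
#' 5 = malignant epithelium.
#'
#' @param pair A `phantom_pair`.
#' @return Integer matrix (h x w).
#' @export
epithelium_truth <- function(pair) {
  stopifnot(inherits(pair, "phantom_pair"))
  m <- pair$class_raster
  out <- m
  out[m %in% .BENIGN_CODES] <- 4L
  out[m %in% .MALIG_CODES] <- 5L
  out
}

#' Ground-truth percentage of malignant epithelium in a square
#'
#' The exact per-pixel count of malignant-epithelium pixels over the total
#' pixel count of the analysis square, as a percentage -- the regression
#' target the model is trained on.
#'
#' @param pair A `phantom_pair`.
#' @param square One grid row (list or data frame row) with 0-based
#'   half-open bounds `x0`, `y0`, `x1`, `y1`.
#' @return Percentage in `[0, 100]`.
#' @export
truth_percent_malignant <- function(pair, square) {
  stopifnot(inherits(pair, "phantom_pair"))
  x0 <- square$x0; y0 <- square$y0; x1 <- square$x1; y1 <- square$y1
  h <- nrow(pair$class_raster); w <- ncol(pair$class_raster)
  if (x0 < 0 || y0 < 0 || x1 > w || y1 > h || x1 <= x0 || y1 <= y0) {
    stop("analysis square out of raster bounds")
  }
  block <- pair$class_raster[(y0 + 1):y1, (x0 + 1):x1]
  100 * mean(block %in% .MALIG_CODES)
}

#' Write a phantom pair to disk
#'
#' Images are quantized to 8-bit PNG; masks and the class raster are written
#' as single-channel PNG; annotations as GeoJSON; the configuration and true
#' transform as a JSON sidecar; everything is listed in `manifest.json`.
#'
#' @param pair A `phantom_pair`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom_pair <- function(pair, dir) {
  stopifnot(inherits(pair, "phantom_pair"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  i0 <- pair$config$i0
  png::writePNG(pair$he_image / i0, file.path(dir, "he.png"))
  png::writePNG(pair$ihc_image / i0, file.path(dir, "ihc.png"))
  png::writePNG(pair$class_raster / 255, file.path(dir, "class_raster.png"))
  png::writePNG((pair$cancer_mask + 0) , file.path(dir, "cancer_mask.png"))
  png::writePNG((pair$negative_mask + 0), file.path(dir, "negative_mask.png"))
  write_annotations_geojson(c(pair$cancer_regions, pair$negative_regions),
                            file.path(dir, "regions.geojson"))
  meta <- list(config = unclass(pair$config),
               true_transform = unclass(pair$true_transform),
               files = c("he.png", "ihc.png", "class_raster.png",
                         "cancer_mask.png", "negative_mask.png",
                         "regions.geojson"))
  jsonlite::write_json(meta, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}

#' Read a phantom pair written by [write_phantom_pair()]
#'
#' Images come back quantized to the 8-bit grid (the on-disk precision).
#'
#' @param dir Directory written by [write_phantom_pair()].
#' @return A `phantom_pair`.
#' @export
read_phantom_pair <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  cfg <- meta$config
  config <- phantom_config(width_px = cfg$width_px, height_px = cfg$height_px,
                           square_px = cfg$square_px, n_glands = cfg$n_glands,
                           malignant_fraction = cfg$malignant_fraction,
                           gs_palette = cfg$gs_palette,
                           amacr_dropout = cfg$amacr_dropout,
                           artifact_fraction = cfg$artifact_fraction,
                           debris_fraction = cfg$debris_fraction,
                           color_jitter_sd = cfg$color_jitter_sd,
                           rigid_offset = cfg$rigid_offset,
                           dilation_px = cfg$dilation_px,
                           seed = cfg$seed, i0 = cfg$i0)
  i0 <- config$i0
  rd <- function(f) png::readPNG(file.path(dir, f))
  to_img <- function(a) {
    if (length(dim(a)) == 3L && dim(a)[3] > 3L) a <- a[, , 1:3]
    round(a * i0)
  }
  regions <- read_annotations_geojson(file.path(dir, "regions.geojson"))
  kinds <- vapply(regions, `[[`, "", "kind")
  tt <- meta$true_transform
  structure(list(he_image = to_img(rd("he.png")),
                 ihc_image = to_img(rd("ihc.png")),
                 class_raster = matrix(as.integer(round(rd("class_raster.png") * 255)),
                                       config$height_px, config$width_px),
                 cancer_mask = rd("cancer_mask.png") > 0.5,
                 negative_mask = rd("negative_mask.png") > 0.5,
                 cancer_regions = regions[kinds == "cancer"],
                 negative_regions = regions[kinds == "negative"],
                 true_transform = rigid_transform(tt$tx, tt$ty, tt$theta, tt$center),
                 glands = NULL, config = config),
            class = "phantom_pair")
}
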