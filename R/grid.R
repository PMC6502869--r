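#' Construct a rigid transform
#'
#' Maps a point `p` to `R(theta) %*% (p - center) + center + c(tx, ty)`,
#' with `theta` in degrees (counter-clockwise in pixel coordinates) and the
#' rotation taken about `center` (typically the image center). Coordinates
#' are 0-based pixels throughout.
#'
#' @param tx,ty Translation in pixels.
#' @param theta Rotation in degrees.
#' @param center Length-2 rotation center (pixels), default the origin.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(tx = 0, ty = 0, theta = 0, center = c(0, 0)) {
  stopifnot(is.numeric(tx), is.numeric(ty), is.numeric(theta),
            length(center) == 2L)
  structure(list(tx = tx, ty = ty, theta = theta, center = as.numeric(center)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> tx=%.3f px, ty=%.3f px, theta=%.3f deg, center=(%.1f, %.1f)\n",
              x$tx, x$ty, x$theta, x$center[1], x$center[2]))
  invisible(x)
}

#' Apply a rigid transform to points
#'
#' @param transform A [rigid_transform()].
#' @param points n x 2 matrix of (x, y) coordinates, or a length-2 vector.
#' @return Transformed coordinates, same shape.
#' @export
apply_transform <- function(transform, points) {
  stopifnot(inherits(transform, "rigid_transform"))
  vec_in <- is.null(dim(points))
  if (vec_in) points <- rbind(points)
  th <- transform$theta * pi / 180
  cs <- cos(th); sn <- sin(th)
  dx <- points[, 1] - transform$center[1]
  dy <- points[, 2] - transform$center[2]
  out <- cbind(cs * dx - sn * dy + transform$center[1] + transform$tx,
               sn * dx + cs * dy + transform$center[2] + transform$ty)
  if (vec_in) out[1L, ] else out
}

#' Invert a rigid transform
#'
#' @param transform A [rigid_transform()].
#' @return The inverse [rigid_transform()] (same rotation center).
#' @export
invert_transform <- function(transform) {
  th <- -transform$theta * pi / 180
  cs <- cos(th); sn <- sin(th)
  t_inv <- c(-(cs * transform$tx - sn * transform$ty),
             -(sn * transform$tx + cs * transform$ty))
  rigid_transform(t_inv[1], t_inv[2], -transform$theta, transform$center)
}

#' Resample an image through a rigid transform
#'
#' Produces `out(x) = img(T^{-1}(x))` with nearest-neighbor sampling, i.e.
#' the moving image re-expressed in the fixed frame when `transform` maps
#' moving-frame coordinates into the fixed frame. Out-of-bounds samples are
#' filled with `fill`.
#'
#' @param img Matrix (grayscale) or h x w x 3 array.
#' @param transform A [rigid_transform()] mapping moving -> fixed coordinates.
#' @param fill Fill value for unsampled pixels (default 255, brightfield
#'   white).
#' @return Warped image with the same dimensions.
#' @export
warp_image <- function(img, transform, fill = 255) {
  gray <- is.matrix(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  inv <- invert_transform(transform)
  gx <- rep(seq_len(w) - 0.5, each = h)   # pixel centers, 0-based coords
  gy <- rep(seq_len(h) - 0.5, times = w)
  src <- apply_transform(inv, cbind(gx, gy))
  sx <- floor(src[, 1]) + 1L              # back to 1-based indices
  sy <- floor(src[, 2]) + 1L
  ok <- sx >= 1L & sx <= w & sy >= 1L & sy <= h
  idx <- sy + (sx - 1L) * h
  take <- function(m) {
    v <- rep(fill, h * w)
    v[ok] <- m[idx[ok]]
    matrix(v, h, w)
  }
  if (gray) return(take(img))
  out <- array(fill, dim = dim(img))
  for (k in seq_len(dim(img)[3])) out[, , k] <- take(img[, , k])
  out
}

.luminance <- function(img) {
  if (is.matrix(img)) return(img)
  (img[, , 1] + img[, , 2] + img[, , 3]) / 3
}

.downsample <- function(m, f) {
  if (f <= 1L) return(m)
  nr <- nrow(m) %/% f; nc <- ncol(m) %/% f
  m <- m[seq_len(nr * f), seq_len(nc * f), drop = FALSE]
  g <- rowsum(m, rep(seq_len(nr), each = f))
  t(rowsum(t(g), rep(seq_len(nc), each = f))) / (f * f)
}

# NCC over integer shifts of 'mov' relative to 'fix'; returns best shift
.best_shift <- function(fix, mov, dx_range, dy_range) {
  h <- nrow(fix); w <- ncol(fix)
  best <- c(NA, NA); best_ncc <- -Inf
  for (dx in dx_range) {
    for (dy in dy_range) {
      # overlap of fix with mov shifted by (dx, dy)
      fx <- max(1, 1 + dx):min(w, w + dx)
      fy <- max(1, 1 + dy):min(h, h + dy)
      if (length(fx) < 8 || length(fy) < 8) next
      a <- fix[fy, fx]
      b <- mov[fy - dy, fx - dx]
      keep <- is.finite(a) & is.finite(b)
      if (sum(keep) < 32) next
      av <- a[keep]; bv <- b[keep]
      if (stats::sd(av) == 0 || stats::sd(bv) == 0) next
      ncc <- stats::cor(av, bv)
      if (is.finite(ncc) && ncc > best_ncc) {
        best_ncc <- ncc; best <- c(dx, dy)
      }
    }
  }
  list(shift = best, ncc = best_ncc)
}

# rotate grayscale about its center by theta degrees, NA fill
.rotate_gray <- function(m, theta) {
  if (theta == 0) return(m)
  warp_image(m, rigid_transform(0, 0, theta, center = c(ncol(m) / 2, nrow(m) / 2)),
             fill = NA_real_)
}

#' Estimate the rigid transform aligning a moving image to a fixed image
#'
#' Exhaustive normalized cross-correlation over a coarse-to-fine translation
#' grid crossed with a rotation sweep, on (optionally downsampled) luminance
#' images. The returned transform maps moving-frame coordinates into the
#' fixed frame, i.e. `warp_image(moving, transform)` aligns with `fixed`.
#'
#' @param fixed,moving Grayscale matrices or RGB arrays at the same pixel
#'   scale with at least 50% overlap.
#' @param search_bounds List with elements `tx`, `ty` (length-2 pixel
#'   ranges) and `theta` (length-2 degree range; `c(0, 0)` disables the
#'   rotation search).
#' @param theta_step Coarse rotation step in degrees (refined to
#'   `theta_step / 5` around the best candidate).
#' @param downsample Integer block-averaging factor for the coarse stage.
#' @return A [rigid_transform()] with attribute `ncc` (the peak normalized
#'   cross-correlation).
#' @export
estimate_rigid <- function(fixed, moving,
                           search_bounds = list(tx = c(-20, 20), ty = c(-20, 20),
                                                theta = c(-3, 3)),
                           theta_step = 0.5, downsample = 4L) {
  fix <- .luminance(fixed); mov <- .luminance(moving)
  if (stats::sd(fix) == 0 || stats::sd(mov) == 0) {
    stop("registration failure: constant image has no structure to align")
  }
  center <- c(ncol(fix) / 2, nrow(fix) / 2)
  f <- max(1L, as.integer(downsample))
  fix_ds <- .downsample(fix, f); mov_ds <- .downsample(mov, f)

  thetas <- if (diff(range(search_bounds$theta)) == 0) {
    search_bounds$theta[1]
  } else {
    seq(search_bounds$theta[1], search_bounds$theta[2], by = theta_step)
  }
  dx_c <- seq(floor(search_bounds$tx[1] / f), ceiling(search_bounds$tx[2] / f))
  dy_c <- seq(floor(search_bounds$ty[1] / f), ceiling(search_bounds$ty[2] / f))

  best <- NULL
  for (th in thetas) {
    rot <- .rotate_gray(mov_ds, th)
    cand <- .best_shift(fix_ds, rot, dx_c, dy_c)
    if (is.null(best) || cand$ncc > best$ncc) {
      best <- list(theta = th, shift = cand$shift, ncc = cand$ncc)
    }
  }
  if (!is.finite(best$ncc)) stop("registration failure: no valid overlap found")

  # mid stage (half the coarse downsampling): refine the rotation
  f2 <- max(1L, f %/% 2L)
  if (length(thetas) > 1L || f2 < f) {
    fix_m <- .downsample(fix, f2); mov_m <- .downsample(mov, f2)
    thetas_m <- if (length(thetas) == 1L) thetas else {
      seq(best$theta - theta_step, best$theta + theta_step, by = theta_step / 5)
    }
    sc <- f / f2
    dx_m <- seq(best$shift[1] * sc - sc - 1, best$shift[1] * sc + sc + 1)
    dy_m <- seq(best$shift[2] * sc - sc - 1, best$shift[2] * sc + sc + 1)
    mid <- NULL
    for (th in thetas_m) {
      rot <- .rotate_gray(mov_m, th)
      cand <- .best_shift(fix_m, rot, dx_m, dy_m)
      if (is.null(mid) || cand$ncc > mid$ncc) {
        mid <- list(theta = th, shift = cand$shift, ncc = cand$ncc)
      }
    }
    best <- mid
    f <- f2
  }

  # fine stage: full resolution, best rotation only, +/- f px translation
  tx0 <- best$shift[1] * f; ty0 <- best$shift[2] * f
  dx_f <- seq(max(search_bounds$tx[1], tx0 - f - 1), min(search_bounds$tx[2], tx0 + f + 1))
  dy_f <- seq(max(search_bounds$ty[1], ty0 - f - 1), min(search_bounds$ty[2], ty0 + f + 1))
  rot <- .rotate_gray(mov, best$theta)
  cand <- .best_shift(fix, rot, dx_f, dy_f)
  fine <- list(theta = best$theta, shift = cand$shift, ncc = cand$ncc)
  out <- rigid_transform(fine$shift[1], fine$shift[2], fine$theta, center = center)
  attr(out, "ncc") <- fine$ncc
  out
}

# ---- annotation regions -------------------------------------------------

#' Construct an annotation region
#'
#' @param geometry n x 2 matrix of polygon vertices in pixel coordinates
#'   (H&E frame, 0-based; the polygon is closed implicitly).
#' @param kind `"cancer"` or `"negative"` (processing artifact).
#' @param gleason Gleason score string (e.g. `"3 + 4"`); required iff
#'   `kind == "cancer"`.
#' @return An object of class `annotation_region`.
#' @export
annotation_region <- function(geometry, kind = c("cancer", "negative"),
                              gleason = NULL) {
  kind <- match.arg(kind)
  geometry <- as.matrix(geometry)
  if (ncol(geometry) != 2L || nrow(geometry) < 3L) {
    stop("geometry must be an n x 2 vertex matrix with n >= 3")
  }
  if (kind == "cancer") {
    if (is.null(gleason)) stop("cancer regions require a Gleason score")
    gleason <- normalize_gleason(gleason)
  } else {
    gleason <- NULL
  }
  structure(list(geometry = geometry, kind = kind, gleason = gleason),
            class = "annotation_region")
}

#' Normalize a Gleason score string
#'
#' Accepts `"3+4"` or `"3 + 4"` style strings and returns the canonical
#' `"3 + 4"` form; unrecognized strings are returned stripped but flagged by
#' [gs_grade_group()] as unknown.
#'
#' @param gs Gleason score string.
#' @return Canonical score string.
#' @export
normalize_gleason <- function(gs) {
  s <- gsub("\\s", "", gs)
  m <- regmatches(s, regexec("^([0-9])\\+([0-9])$", s))[[1]]
  if (length(m) == 3L) paste(m[2], "+", m[3]) else s
}

#' Gleason grade group of a score string
#'
#' Grade groups: 1 = 3+3, 2 = 3+4, 3 = 4+3, 4 = 4+4, 5 = 4+5/5+4/5+5.
#'
#' @param gs Gleason score string (any spacing).
#' @return Integer grade group, or `NA` for unknown scores.
#' @export
gs_grade_group <- function(gs) {
  key <- vapply(gs, normalize_gleason, "")
  map <- c("3 + 3" = 1L, "3 + 4" = 2L, "4 + 3" = 3L, "4 + 4" = 4L,
           "4 + 5" = 5L, "5 + 4" = 5L, "5 + 5" = 5L)
  out <- unname(map[key])
  out
}

#' Map annotation regions through a rigid transform
#'
#' Vertex coordinates are transformed; kind and Gleason score are preserved.
#'
#' @param regions List of [annotation_region()] objects.
#' @param transform A [rigid_transform()].
#' @return List of transformed regions.
#' @export
transfer_annotations <- function(regions, transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  lapply(regions, function(r) {
    stopifnot(inherits(r, "annotation_region"))
    r$geometry <- apply_transform(transform, r$geometry)
    r
  })
}

#' Point-in-polygon test (even-odd rule)
#'
#' @param px,py Point coordinate vectors.
#' @param poly n x 2 vertex matrix (implicitly closed).
#' @return Logical vector.
#' @export
point_in_polygon <- function(px, py, poly) {
  n <- length(px)
  inside <- rep(FALSE, n)
  nv <- nrow(poly)
  j <- nv
  for (i in seq_len(nv)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Rasterize a polygon onto a pixel mask
#'
#' A pixel counts as inside when its center `(x + 0.5, y + 0.5)` is inside
#' the polygon. Only the polygon's bounding box is tested.
#'
#' @param poly n x 2 vertex matrix (0-based pixel coordinates).
#' @param width,height Raster dimensions in pixels.
#' @return `height x width` logical matrix (row = y + 1, col = x + 1).
#' @export
rasterize_polygon <- function(poly, width, height) {
  mask <- matrix(FALSE, height, width)
  x0 <- max(0L, floor(min(poly[, 1]))); x1 <- min(width - 1L, ceiling(max(poly[, 1])))
  y0 <- max(0L, floor(min(poly[, 2]))); y1 <- min(height - 1L, ceiling(max(poly[, 2])))
  if (x1 < x0 || y1 < y0) return(mask)
  xs <- seq(x0, x1); ys <- seq(y0, y1)
  px <- rep(xs + 0.5, each = length(ys))
  py <- rep(ys + 0.5, times = length(xs))
  inside <- point_in_polygon(px, py, poly)
  mask[cbind(rep(ys, times = length(xs)) + 1L,
             rep(xs, each = length(ys)) + 1L)] <- inside
  mask
}

# ---- grid ---------------------------------------------------------------

#' Generate the analysis-square grid
#'
#' Axis-aligned, non-overlapping squares tiling from the origin. Partial
#' squares at the right/bottom edges are dropped rather than padded, so the
#' grid covers `floor(w/s) x floor(h/s)` squares. At the native scan
#' resolution of 0.5 um/px, the default 1,000 px square covers 0.25 mm^2.
#'
#' @param image_width,image_height Image dimensions in pixels.
#' @param square_px Square side length in pixels (default 1000).
#' @return Data frame with columns `row`, `col` (1-based grid indices) and
#'   `x0`, `y0`, `x1`, `y1` (0-based half-open pixel bounds), plus label
#'   bookkeeping columns initialized to their defaults.
#' @export
generate_grid <- function(image_width, image_height, square_px = 1000L) {
  stopifnot(square_px >= 1)
  ncols <- image_width %/% square_px
  nrows <- image_height %/% square_px
  if (ncols < 1L || nrows < 1L) {
    warning("image smaller than one analysis square: empty grid")
    return(data.frame(row = integer(), col = integer(), x0 = integer(),
                      y0 = integer(), x1 = integer(), y1 = integer(),
                      label = character(), gleason = character(),
                      cancer_overlap = numeric(), negative_overlap = numeric(),
                      excluded = logical(), reason = character(),
                      stringsAsFactors = FALSE))
  }
  g <- expand.grid(row = seq_len(nrows), col = seq_len(ncols))
  g <- g[order(g$row, g$col), , drop = FALSE]
  rownames(g) <- NULL
  g$x0 <- (g$col - 1L) * square_px
  g$y0 <- (g$row - 1L) * square_px
  g$x1 <- g$x0 + square_px
  g$y1 <- g$y0 + square_px
  g$label <- "benign"
  g$gleason <- NA_character_
  g$cancer_overlap <- 0
  g$negative_overlap <- 0
  g$excluded <- FALSE
  g$reason <- NA_character_
  g
}

# per-grid-square sums of a full-resolution mask (squares aligned at origin)
.block_fractions <- function(mask, square_px, nrows, ncols) {
  m <- mask[seq_len(nrows * square_px), seq_len(ncols * square_px), drop = FALSE]
  g <- rowsum(m + 0, rep(seq_len(nrows), each = square_px))
  t(rowsum(t(g), rep(seq_len(ncols), each = square_px))) / (square_px^2)
}

#' Label analysis squares by annotation overlap
#'
#' A square is labeled cancer when at least `cancer_thresh` (default 75%) of
#' its area lies inside the union of cancer regions, and receives the Gleason
#' score of the single region contributing the largest overlap (ties broken
#' toward the higher grade group). A square is excluded (reason
#' `"negative-overlap"`) when at least `negative_thresh` of its area lies in
#' negative regions; exclusion takes precedence over labeling. Overlaps are
#' computed on masks rasterized at full resolution.
#'
#' @param grid Data frame from [generate_grid()].
#' @param cancer_regions,negative_regions Lists of [annotation_region()].
#' @param image_width,image_height Raster dimensions.
#' @param cancer_thresh,negative_thresh Overlap thresholds (fractions).
#' @return The grid with `label`, `gleason`, `cancer_overlap`,
#'   `negative_overlap`, `excluded` and `reason` filled in.
#' @export
label_squares <- function(grid, cancer_regions = list(), negative_regions = list(),
                          image_width, image_height,
                          cancer_thresh = 0.75, negative_thresh = 0.75) {
  if (nrow(grid) == 0L) return(grid)
  square_px <- grid$x1[1] - grid$x0[1]
  nrows <- max(grid$row); ncols <- max(grid$col)
  idx <- cbind(grid$row, grid$col)

  if (length(cancer_regions)) {
    union_mask <- matrix(FALSE, image_height, image_width)
    per_region <- matrix(0, nrow(grid), length(cancer_regions))
    for (k in seq_along(cancer_regions)) {
      r <- cancer_regions[[k]]
      stopifnot(r$kind == "cancer")
      mk <- rasterize_polygon(r$geometry, image_width, image_height)
      union_mask <- union_mask | mk
      per_region[, k] <- .block_fractions(mk, square_px, nrows, ncols)[idx]
    }
    grid$cancer_overlap <- .block_fractions(union_mask, square_px, nrows, ncols)[idx]
    gg <- gs_grade_group(vapply(cancer_regions, function(r) r$gleason, ""))
    gg[is.na(gg)] <- 0L
    pick <- apply(per_region, 1L, function(v) {
      if (max(v) <= 0) return(NA_integer_)
      cand <- which(v == max(v))
      if (length(cand) > 1L) cand <- cand[which.max(gg[cand])]  # tie: higher grade
      cand[1L]
    })
    is_cancer <- grid$cancer_overlap >= cancer_thresh
    grid$label <- ifelse(is_cancer, "cancer", "benign")
    grid$gleason <- ifelse(is_cancer & !is.na(pick),
                           vapply(cancer_regions, function(r) r$gleason, "")[pick],
                           NA_character_)
    multi <- is_cancer & apply(per_region > 0, 1L, sum) > 1L
    if (any(multi)) {
      message(sprintf("%d cancer square(s) overlap multiple annotations; largest-overlap Gleason score assigned",
                      sum(multi)))
    }
  }

  if (length(negative_regions)) {
    neg_mask <- matrix(FALSE, image_height, image_width)
    for (r in negative_regions) {
      stopifnot(r$kind == "negative")
      neg_mask <- neg_mask | rasterize_polygon(r$geometry, image_width, image_height)
    }
    grid$negative_overlap <- .block_fractions(neg_mask, square_px, nrows, ncols)[idx]
    drop <- grid$negative_overlap >= negative_thresh
    grid$excluded <- grid$excluded | drop
    grid$reason[drop] <- "negative-overlap"
    grid$label[drop] <- "benign"       # exclusion takes precedence over labeling
    grid$gleason[drop] <- NA_character_
  }
  grid
}

# ---- GeoJSON / CSV I/O --------------------------------------------------

#' Write annotation regions as GeoJSON
#'
#' Polygon features with `kind` and `gleason` properties, coordinates in
#' pixel units of the H&E frame.
#'
#' @param regions List of [annotation_region()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations_geojson <- function(regions, path) {
  features <- lapply(regions, function(r) {
    ring <- rbind(r$geometry, r$geometry[1, , drop = FALSE])
    list(type = "Feature",
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(i) ring[i, ]))),
         properties = list(kind = r$kind,
                           gleason = if (is.null(r$gleason)) NA else r$gleason))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read annotation regions from GeoJSON
#'
#' @param path GeoJSON path written by [write_annotations_geojson()].
#' @return List of [annotation_region()].
#' @export
read_annotations_geojson <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(j$features, function(f) {
    ring <- f$geometry$coordinates[[1]]
    pts <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    pts <- pts[-nrow(pts), , drop = FALSE]    # drop closing vertex
    gl <- f$properties$gleason
    annotation_region(pts, kind = f$properties$kind,
                      gleason = if (is.null(gl) || is.na(gl)) NULL else gl)
  })
}

#' Write a labeled grid as CSV
#'
#' @param grid Labeled grid data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_grid_csv <- function(grid, path) {
  utils::write.csv(grid, path, row.names = FALSE)
  invisible(path)
}
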