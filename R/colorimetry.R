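#' Construct a stain optical-density vector
#'
#' A stain is characterized by its RGB optical-density (OD) absorption
#' signature, measured from a singly-stained control slide. OD is unitless:
#' `OD_c = -log10(I_c / I0)` for transmitted intensity `I_c` against the
#' white reference `I0`, and is linear in the amount of stain (Beer-Lambert).
#'
#' @param name Stain identifier (e.g. `"fast_red"`).
#' @param od Numeric length-3 vector of RGB optical densities; all components
#'   must be non-negative and not all zero.
#' @param allow_zero Permit an all-zero vector (a measured signature of an
#'   unstained control region); such a vector cannot enter a
#'   [stain_matrix()].
#' @return An object of class `stain_vector`.
#' @export
stain_vector <- function(name, od, allow_zero = FALSE) {
  stopifnot(is.character(name), length(name) == 1L)
  od <- as.numeric(od)
  if (length(od) != 3L || anyNA(od)) {
    stop("'od' must be a numeric triple of RGB optical densities")
  }
  if (any(od < 0) || (!allow_zero && all(od == 0))) {
    stop("stain OD components must be >= 0 and not all zero")
  }
  structure(list(name = name, od = od), class = "stain_vector")
}

#' @export
print.stain_vector <- function(x, ...) {
  cat(sprintf("<stain_vector> %s  OD(R,G,B) = (%.3f, %.3f, %.3f)\n",
              x$name, x$od[1], x$od[2], x$od[3]))
  invisible(x)
}

#' Default chromogen OD vectors
#'
#' The three stains of the HMWCK+p63+AMACR triple cocktail as seen in
#' brightfield: Fast Red (AMACR, malignant epithelium), DAB (basal-cell
#' markers, brown), and the hematoxylin counterstain (blue). The OD triples
#' are mean values sampled from singly-stained control slides.
#'
#' @return Named list of three [stain_vector()] objects (`red`, `brown`,
#'   `blue`).
#' @export
default_stain_vectors <- function() {
  list(
    red   = stain_vector("fast_red",    c(0.283, 0.949, 0.757)),
    brown = stain_vector("dab",         c(0.461, 0.826, 1.000)),
    blue  = stain_vector("hematoxylin", c(0.210, 0.276, 0.176))
  )
}

#' Build a 3-stain deconvolution matrix
#'
#' The raw OD vectors are scaled to unit Euclidean length, assembled as the
#' columns of the mixing basis (channels x stains), and the basis is inverted.
#' Per-pixel stain concentrations are then `inverse %*% od` and are expressed
#' in OD units along each normalized stain direction.
#'
#' @param vectors Named list of exactly three [stain_vector()] objects in the
#'   order red, brown, blue.
#' @return An object of class `stain_matrix` with elements `vectors`,
#'   `basis` (3x3, columns = normalized stains), and `inverse`.
#' @export
stain_matrix <- function(vectors = default_stain_vectors()) {
  if (length(vectors) != 3L || !all(vapply(vectors, inherits, TRUE, "stain_vector"))) {
    stop("'vectors' must be a list of exactly three stain_vector objects")
  }
  nm <- names(vectors)
  if (is.null(nm)) nm <- vapply(vectors, `[[`, "", "name")
  raw <- vapply(vectors, `[[`, numeric(3), "od")      # 3 x 3, columns = stains
  basis <- sweep(raw, 2L, sqrt(colSums(raw^2)), "/")
  colnames(basis) <- nm
  rownames(basis) <- c("R", "G", "B")
  kappa_val <- kappa(basis, exact = TRUE)
  if (!is.finite(kappa_val) || kappa_val > 1e8) {
    stop("stain vectors are collinear: deconvolution matrix is singular")
  }
  inv <- solve(basis)
  if (max(abs(inv %*% basis - diag(3))) > 1e-10) {
    stop("stain matrix inversion failed the identity check")
  }
  structure(list(vectors = vectors, basis = basis, inverse = inv,
                 condition = kappa_val),
            class = "stain_matrix")
}

#' @export
print.stain_matrix <- function(x, ...) {
  cat("<stain_matrix> normalized OD basis (columns = stains):\n")
  print(round(x$basis, 4))
  cat(sprintf("condition number: %.2f\n", x$condition))
  invisible(x)
}

#' Convert transmitted RGB intensities to optical density
#'
#' `OD_c = -log10(max(I_c, 1) / i0)` componentwise. Intensities are clamped
#' below at 1 so that a fully dark pixel maps to a finite OD. The transform is
#' monotone decreasing in intensity.
#'
#' @param rgb Numeric triple, n x 3 matrix, or h x w x 3 array of intensities
#'   in `[0, i0]`.
#' @param i0 White reference intensity (> 0), default 255.
#' @return OD values with the same shape as the input.
#' @export
rgb_to_od <- function(rgb, i0 = 255) {
  if (!is.numeric(i0) || length(i0) != 1L || i0 <= 0) {
    stop("'i0' must be a single positive white-reference intensity")
  }
  -log10(pmax(rgb, 1) / i0)
}

#' Forward Beer-Lambert transform: OD to transmitted intensity
#'
#' @param od Optical densities (any shape).
#' @param i0 White reference intensity, default 255.
#' @return Intensities `i0 * 10^(-od)`.
#' @export
od_to_rgb <- function(od, i0 = 255) {
  if (!is.numeric(i0) || length(i0) != 1L || i0 <= 0) {
    stop("'i0' must be a single positive white-reference intensity")
  }
  i0 * 10^(-od)
}

#' Mean OD signature of a singly-stained control region
#'
#' Averages the per-channel OD of a set of pixels sampled from a control slide
#' carrying a single stain, yielding the stain's OD vector.
#'
#' @param pixels n x 3 matrix (or single triple) of RGB intensities.
#' @param i0 White reference intensity.
#' @param name Name for the resulting stain vector.
#' @return A [stain_vector()].
#' @export
sample_stain_vector <- function(pixels, i0 = 255, name = "sampled") {
  if (is.null(dim(pixels))) pixels <- matrix(pixels, ncol = 3, byrow = TRUE)
  if (nrow(pixels) < 1L) stop("need at least one pixel to sample a stain vector")
  od <- rgb_to_od(pixels, i0)
  stain_vector(name, colMeans(od), allow_zero = TRUE)
}

#' Deconvolve OD values into per-stain concentrations
#'
#' Applies the inverse of the normalized stain basis; negative concentrations
#' (possible with off-basis colors) are clipped to zero, as negative stain
#' amounts are unphysical.
#'
#' @param od Length-3 OD triple or n x 3 matrix (rows = pixels).
#' @param matrix A [stain_matrix()].
#' @return Concentrations with the same shape, columns named after the stains.
#' @export
deconvolve <- function(od, matrix) {
  stopifnot(inherits(matrix, "stain_matrix"))
  vec_in <- is.null(dim(od))
  if (vec_in) od <- rbind(od)
  if (ncol(od) != 3L) stop("'od' must have three channels")
  conc <- od %*% t(matrix$inverse)
  conc[conc < 0] <- 0
  colnames(conc) <- colnames(matrix$basis)
  if (vec_in) conc[1L, ] else conc
}

#' Forward-render stain concentrations to RGB intensities
#'
#' The exact inverse of [deconvolve()] for non-negative concentrations:
#' `I = i0 * 10^(-basis %*% conc)`.
#'
#' @param conc Length-3 concentration triple or n x 3 matrix (red, brown,
#'   blue order matching the matrix columns).
#' @param matrix A [stain_matrix()].
#' @param i0 White reference intensity.
#' @return RGB intensities, same shape as `conc`.
#' @export
stains_to_rgb <- function(conc, matrix, i0 = 255) {
  stopifnot(inherits(matrix, "stain_matrix"))
  vec_in <- is.null(dim(conc))
  if (vec_in) conc <- rbind(conc)
  od <- conc %*% t(matrix$basis)
  out <- od_to_rgb(od, i0)
  if (vec_in) out[1L, ] else out
}

# ---- HSB ---------------------------------------------------------------

#' Convert RGB to hue-saturation-brightness
#'
#' Standard HSV convention: hue in degrees `[0, 360)` (achromatic pixels get
#' hue 0), saturation and brightness as fractions in `[0, 1]`.
#'
#' @param rgb Numeric triple or n x 3 matrix of 8-bit intensities.
#' @return n x 3 matrix with columns `hue`, `sat`, `bri` (or a named triple).
#' @export
rgb_to_hsb <- function(rgb) {
  vec_in <- is.null(dim(rgb))
  if (vec_in) rgb <- rbind(rgb)
  r <- rgb[, 1] / 255; g <- rgb[, 2] / 255; b <- rgb[, 3] / 255
  mx <- pmax(r, g, b); mn <- pmin(r, g, b)
  d <- mx - mn
  hue <- numeric(length(mx))
  nz <- d > 0
  i_r <- nz & mx == r
  i_g <- nz & !i_r & mx == g
  i_b <- nz & !i_r & !i_g
  hue[i_r] <- 60 * (((g[i_r] - b[i_r]) / d[i_r]) %% 6)
  hue[i_g] <- 60 * ((b[i_g] - r[i_g]) / d[i_g] + 2)
  hue[i_b] <- 60 * ((r[i_b] - g[i_b]) / d[i_b] + 4)
  hue <- hue %% 360
  sat <- ifelse(mx > 0, d / mx, 0)
  out <- cbind(hue = hue, sat = sat, bri = mx)
  if (vec_in) out[1L, ] else out
}

#' Define an HSB color range
#'
#' Hue bounds are interpreted modulo 360, so `hue_lo > hue_hi` denotes a
#' wraparound interval (e.g. 350 to 10 degrees). Saturation and brightness
#' bounds are ordinary closed intervals in `[0, 1]`.
#'
#' @param hue_lo,hue_hi Hue bounds in degrees `[0, 360)`.
#' @param sat_lo,sat_hi Saturation bounds.
#' @param bri_lo,bri_hi Brightness bounds.
#' @return An object of class `hsb_range`.
#' @export
hsb_range <- function(hue_lo, hue_hi, sat_lo, sat_hi, bri_lo, bri_hi) {
  vals <- c(hue_lo, hue_hi, sat_lo, sat_hi, bri_lo, bri_hi)
  if (!is.numeric(vals) || anyNA(vals)) stop("all HSB bounds must be numeric")
  if (hue_lo < 0 || hue_lo >= 360 || hue_hi < 0 || hue_hi >= 360) {
    stop("hue bounds must lie in [0, 360)")
  }
  if (sat_lo > sat_hi || bri_lo > bri_hi) {
    stop("saturation/brightness bounds must be ordered lo <= hi")
  }
  if (any(c(sat_lo, sat_hi, bri_lo, bri_hi) < 0) ||
      any(c(sat_lo, sat_hi, bri_lo, bri_hi) > 1)) {
    stop("saturation/brightness bounds must lie in [0, 1]")
  }
  structure(list(hue_lo = hue_lo, hue_hi = hue_hi,
                 sat_lo = sat_lo, sat_hi = sat_hi,
                 bri_lo = bri_lo, bri_hi = bri_hi),
            class = "hsb_range")
}

#' Test HSB values against a range
#'
#' @param hsb n x 3 matrix (hue, sat, bri) or a single triple.
#' @param range An [hsb_range()].
#' @return Logical vector, one entry per pixel.
#' @export
hsb_in_range <- function(hsb, range) {
  stopifnot(inherits(range, "hsb_range"))
  if (is.null(dim(hsb))) hsb <- rbind(hsb)
  h <- hsb[, 1] %% 360; s <- hsb[, 2]; b <- hsb[, 3]
  hue_ok <- if (range$hue_lo <= range$hue_hi) {
    h >= range$hue_lo & h <= range$hue_hi
  } else {
    h >= range$hue_lo | h <= range$hue_hi   # wraparound interval
  }
  hue_ok & s >= range$sat_lo & s <= range$sat_hi &
    b >= range$bri_lo & b <= range$bri_hi
}

# modular hue intervals as arcs on [0,360); returns list of lo/hi pairs
.hue_arcs <- function(r) {
  if (r$hue_lo <= r$hue_hi) list(c(r$hue_lo, r$hue_hi))
  else list(c(r$hue_lo, 360), c(0, r$hue_hi))
}

.intervals_overlap <- function(a, b) a[1] <= b[2] && b[1] <= a[2]

.hsb_ranges_overlap <- function(r1, r2) {
  hue <- any(vapply(.hue_arcs(r1), function(a)
    any(vapply(.hue_arcs(r2), function(b) .intervals_overlap(a, b), TRUE)), TRUE))
  sat <- .intervals_overlap(c(r1$sat_lo, r1$sat_hi), c(r2$sat_lo, r2$sat_hi))
  bri <- .intervals_overlap(c(r1$bri_lo, r1$bri_hi), c(r2$bri_lo, r2$bri_hi))
  hue && sat && bri
}

#' Configure positive pixel counting for one staining batch
#'
#' One HSB range per histological compartment (nuclei, cytoplasm, stroma).
#' The three ranges must be pairwise disjoint boxes in HSB space, so that no
#' pixel can count toward two compartments; overlapping ranges are rejected.
#'
#' @param nuclei,cytoplasm,stroma [hsb_range()] objects.
#' @param batch_id Label tying the configuration to an H&E staining batch.
#' @return An object of class `ppc_config`.
#' @export
ppc_config <- function(nuclei, cytoplasm, stroma, batch_id = "batch1") {
  ranges <- list(nuclei = nuclei, cytoplasm = cytoplasm, stroma = stroma)
  ok <- vapply(ranges, inherits, TRUE, "hsb_range")
  if (!all(ok)) stop("nuclei, cytoplasm and stroma must be hsb_range objects")
  pairs <- utils::combn(names(ranges), 2, simplify = FALSE)
  for (p in pairs) {
    if (.hsb_ranges_overlap(ranges[[p[1]]], ranges[[p[2]]])) {
      stop(sprintf("HSB ranges for '%s' and '%s' overlap; compartment ranges must be disjoint",
                   p[1], p[2]))
    }
  }
  structure(list(ranges = ranges, batch_id = batch_id), class = "ppc_config")
}

#' Default PPC configuration matched to the phantom H&E palette
#'
#' The ranges bracket the phantom renderer's nuclei (purple), cytoplasm
#' (pink) and stroma (pale pink) colors with margin for optical-density
#' jitter, and are pairwise disjoint.
#'
#' @param batch_id Staining-batch label.
#' @return A [ppc_config()].
#' @export
default_ppc_config <- function(batch_id = "batch1") {
  ppc_config(
    nuclei    = hsb_range(250, 300, 0.45, 0.85, 0.35, 0.85),
    cytoplasm = hsb_range(320, 355, 0.25, 0.55, 0.75, 1.00),
    stroma    = hsb_range(320, 355, 0.03, 0.22, 0.85, 1.00),
    batch_id  = batch_id
  )
}

#' Percentage of tile pixels inside an HSB range
#'
#' The positive-pixel count statistic: pixels whose HSB color falls inside
#' the configured range are positive, all others negative; the result is the
#' positive fraction as a percentage. The hue test is modular.
#'
#' @param tile h x w x 3 RGB array (or n x 3 pixel matrix), 8-bit scale.
#' @param range An [hsb_range()].
#' @return Percentage in `[0, 100]`.
#' @export
positive_pixel_percent <- function(tile, range) {
  px <- as_pixel_matrix(tile)
  if (nrow(px) == 0L) stop("tile has no pixels")
  100 * mean(hsb_in_range(rgb_to_hsb(px), range))
}

#' Flatten an image array to an n x 3 pixel matrix
#'
#' @param tile h x w x 3 array, n x 3 matrix, or length-3 vector.
#' @return n x 3 numeric matrix, one row per pixel.
#' @export
as_pixel_matrix <- function(tile) {
  if (is.null(dim(tile))) return(matrix(tile, ncol = 3, byrow = TRUE))
  if (length(dim(tile)) == 3L) {
    stopifnot(dim(tile)[3] == 3L)
    return(cbind(as.vector(tile[, , 1]), as.vector(tile[, , 2]),
                 as.vector(tile[, , 3])))
  }
  stopifnot(ncol(tile) == 3L)
  tile
}

# ---- Color deconvolution / co-expression --------------------------------

#' Configure color deconvolution positivity
#'
#' @param stain_matrix A [stain_matrix()].
#' @param positivity_threshold Named per-stain OD concentration above which a
#'   pixel counts as positively stained. Thresholds must be positive.
#' @param i0 White reference intensity.
#' @return An object of class `cd_config`.
#' @export
cd_config <- function(stain_matrix = stainmap::stain_matrix(),
                      positivity_threshold = c(red = 0.15, brown = 0.15, blue = 0.15),
                      i0 = 255) {
  stopifnot(inherits(stain_matrix, "stain_matrix"))
  if (any(positivity_threshold <= 0)) stop("positivity thresholds must be > 0")
  need <- colnames(stain_matrix$basis)
  if (!all(need %in% names(positivity_threshold))) {
    stop("positivity_threshold must name every stain in the matrix")
  }
  structure(list(stain_matrix = stain_matrix,
                 positivity_threshold = positivity_threshold, i0 = i0),
            class = "cd_config")
}

#' Quantify one deconvolved stain over a tile
#'
#' Deconvolves every pixel and reports the percentage of pixels whose
#' concentration for the requested stain exceeds its positivity threshold
#' (`pct_pos`), the mean concentration over those positive pixels (`mean_od`,
#' 0 when there are none), and their product `od_x_pctpos`, the per-square
#' predictive feature.
#'
#' @param tile RGB raster (h x w x 3 array or n x 3 matrix).
#' @param config A [cd_config()].
#' @param stain `"red"` or `"brown"`.
#' @return Named list `pct_pos`, `mean_od`, `od_x_pctpos`.
#' @export
cd_quantify <- function(tile, config, stain = c("red", "brown")) {
  stain <- match.arg(stain)
  stopifnot(inherits(config, "cd_config"))
  px <- as_pixel_matrix(tile)
  conc <- deconvolve(rgb_to_od(px, config$i0), config$stain_matrix)[, stain]
  pos <- conc > config$positivity_threshold[[stain]]
  pct_pos <- 100 * mean(pos)
  mean_od <- if (any(pos)) mean(conc[pos]) else 0
  list(pct_pos = pct_pos, mean_od = mean_od, od_x_pctpos = mean_od * pct_pos)
}

#' Co-expression percentages: singly-stained pixel fractions
#'
#' The co-expression statistic counts pixels positive for exactly one of the
#' red and brown stains. Double-stained pixels (e.g. chromogen-trapping
#' debris such as corpora amylacea) are excluded, so each co-expression
#' percentage is bounded above by the corresponding single-stain percentage.
#'
#' @param tile RGB raster.
#' @param config A [cd_config()].
#' @return Named list `pctpos_ce_red`, `pctpos_ce_brown`.
#' @export
ce_quantify <- function(tile, config) {
  stopifnot(inherits(config, "cd_config"))
  px <- as_pixel_matrix(tile)
  conc <- deconvolve(rgb_to_od(px, config$i0), config$stain_matrix)
  pos_red   <- conc[, "red"]   > config$positivity_threshold[["red"]]
  pos_brown <- conc[, "brown"] > config$positivity_threshold[["brown"]]
  list(pctpos_ce_red   = 100 * mean(pos_red & !pos_brown),
       pctpos_ce_brown = 100 * mean(pos_brown & !pos_red))
}

# ---- config (de)serialization ------------------------------------------

#' Write a colorimetry configuration to JSON
#'
#' Serializes the stain matrix (raw OD vectors), the per-stain positivity
#' thresholds, and a keyed map of per-batch PPC configurations.
#'
#' @param cd A [cd_config()].
#' @param ppc_batches Named list of [ppc_config()], keyed by batch id.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_colorimetry_config <- function(cd, ppc_batches, path) {
  stains <- lapply(cd$stain_matrix$vectors, function(v) list(name = v$name, od = v$od))
  ppc <- lapply(ppc_batches, function(p) {
    list(batch_id = p$batch_id,
         ranges = lapply(p$ranges, function(r) unclass(r)))
  })
  jsonlite::write_json(
    list(stains = stains,
         positivity_threshold = as.list(cd$positivity_threshold),
         i0 = cd$i0, ppc = ppc),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a colorimetry configuration from JSON
#'
#' @param path JSON path written by [write_colorimetry_config()].
#' @return List with elements `cd` (a [cd_config()]) and `ppc` (named list of
#'   [ppc_config()] keyed by batch id).
#' @export
read_colorimetry_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  vecs <- lapply(j$stains, function(s) stain_vector(s$name, unlist(s$od)))
  cd <- cd_config(stain_matrix(vecs),
                  positivity_threshold = unlist(j$positivity_threshold),
                  i0 = j$i0)
  ppc <- lapply(j$ppc, function(p) {
    r <- lapply(p$ranges, function(x) do.call(hsb_range, as.list(unlist(x))))
    ppc_config(r$nuclei, r$cytoplasm, r$stroma, batch_id = p$batch_id)
  })
  list(cd = cd, ppc = ppc)
}
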