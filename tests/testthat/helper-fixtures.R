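# Shared fixtures and independent oracles, built in code at test time.

# small, fast phantom (6 analysis squares)
small_phantom <- function(seed = 7, ...) {
  render_phantom_pair(phantom_config(width_px = 300, height_px = 200,
                                     square_px = 100, seed = seed, ...))
}

# a uniform tile rendered at given stain concentrations (red, brown, blue)
uniform_stain_tile <- function(conc, n = 64, sm = stain_matrix(), i0 = 255) {
  nr <- round(sqrt(n))
  stopifnot(n %% nr == 0)
  px <- stains_to_rgb(matrix(conc, n, 3, byrow = TRUE), sm, i0)
  arr <- array(0, dim = c(nr, n / nr, 3))
  for (k in 1:3) arr[, , k] <- matrix(px[, k], nr)
  arr
}

# brute-force per-pixel PPC oracle (independent of the vectorized path)
ppc_brute_force <- function(tile, range) {
  px <- as_pixel_matrix(tile)
  hits <- 0L
  for (i in seq_len(nrow(px))) {
    hsb <- rgb_to_hsb(px[i, ])
    h <- hsb[1]; s <- hsb[2]; b <- hsb[3]
    hue_ok <- if (range$hue_lo <= range$hue_hi) {
      h >= range$hue_lo && h <= range$hue_hi
    } else {
      h >= range$hue_lo || h <= range$hue_hi
    }
    if (hue_ok && s >= range$sat_lo && s <= range$sat_hi &&
        b >= range$bri_lo && b <= range$bri_hi) hits <- hits + 1L
  }
  100 * hits / nrow(px)
}

# exhaustive pairwise-concordance AUC oracle (ties counted one half)
auc_concordance <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]; neg <- scores[!labels]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# exhaustive Youden scan oracle over every distinct threshold
youden_brute_force <- function(scores, labels) {
  labels <- as.logical(labels)
  best <- NULL
  for (t in sort(unique(scores), decreasing = TRUE)) {
    sens <- mean(scores[labels] >= t)
    spec <- mean(scores[!labels] < t)
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 && spec > best$spec)) {
      best <- list(cutoff = t, sens = sens, spec = spec, j = j)
    }
  }
  best
}
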