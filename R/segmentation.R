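#' Otsu threshold of an intensity image
#'
#' Scans every cut point between consecutive distinct intensity values and
#' returns the threshold maximizing the between-class variance of the
#' resulting background/foreground partition. The returned value lies
#' strictly between the two classes; foreground is `pixel > threshold`.
#' On a constant image there is no partition: `NA` is returned (a sentinel
#' the callers treat as "empty foreground for this section").
#'
#' @param image Numeric matrix or vector of intensities.
#' @return Scalar threshold, or `NA_real_` for a constant image.
#' @export
threshold_otsu <- function(image) {
  v <- as.numeric(image)
  tab <- table(v)
  u <- as.numeric(names(tab))
  if (length(u) < 2) return(NA_real_)
  n <- as.numeric(tab)
  N <- sum(n)
  cw <- cumsum(n)                      # pixels in class {<= u[i]}
  cs <- cumsum(n * u)
  tot <- cs[length(cs)]
  i <- seq_len(length(u) - 1)
  w0 <- cw[i] / N
  w1 <- 1 - w0
  mu0 <- cs[i] / cw[i]
  mu1 <- (tot - cs[i]) / (N - cw[i])
  bcv <- w0 * w1 * (mu0 - mu1)^2
  k <- which.max(bcv)                  # first maximum: deterministic
  (u[k] + u[k + 1]) / 2
}

#' Triangle threshold of an intensity image
#'
#' Geometric threshold for unimodal histograms with a long foreground tail,
#' the standard choice for admitting dim fluorescent objects: a line is
#' drawn from the histogram peak to the far end of its longer tail, and the
#' threshold is placed at the bin farthest (perpendicular distance) below
#' that line. Foreground is `pixel > threshold`. Returns `NA` for constant
#' images.
#'
#' @param image Numeric matrix or vector of intensities.
#' @param n_bins Histogram resolution; integer-valued images with a small
#'   range use one bin per integer.
#' @return Scalar threshold, or `NA_real_`.
#' @export
threshold_triangle <- function(image, n_bins = 256) {
  v <- as.numeric(image)
  rng <- range(v)
  if (rng[1] == rng[2]) return(NA_real_)
  integerish <- all(v == round(v)) && diff(rng) <= 4 * n_bins
  if (integerish) {
    mids <- seq(rng[1], rng[2])
    h <- tabulate(v - rng[1] + 1, nbins = length(mids))
    width <- 1
  } else {
    width <- diff(rng) / n_bins
    idx <- pmin(floor((v - rng[1]) / width) + 1, n_bins)
    h <- tabulate(idx, nbins = n_bins)
    mids <- rng[1] + (seq_len(n_bins) - 0.5) * width
  }
  nz <- which(h > 0)
  p <- which.max(h)                    # peak bin
  lo <- nz[1]; hi <- nz[length(nz)]
  # walk towards the longer tail (for fluorescence, usually the bright side)
  if ((hi - p) >= (p - lo)) { a <- p; b <- hi } else { a <- p; b <- lo }
  if (a == b) return(NA_real_)
  seg <- a:b
  # perpendicular distance of (bin, count) points below the peak-to-tail line
  x1 <- a; y1 <- h[a]; x2 <- b; y2 <- h[b]
  dists <- abs((y2 - y1) * seg - (x2 - x1) * h[seg] + x2 * y1 - y2 * x1)
  k <- seg[which.max(dists)]
  # threshold just past the chosen bin, on the tail side
  if (b >= a) mids[k] + width / 2 else mids[k] - width / 2
}

#' Binarize a volume stack section by section
#'
#' Applies per-section automatic thresholding — per section, not per
#' volume, because immunostaining intensity varies from physical section to
#' section along a ribbon. Method `"combined"` takes the union of the Otsu
#' and triangle foregrounds so that both high- and low-intensity puncta
#' survive: Otsu captures the bright class, triangle the dim tail.
#' Degenerate (constant) sections contribute empty foreground. The
#' thresholds actually used are recorded per section for audit; the whole
#' operation is deterministic.
#'
#' Synaptic puncta are sparse: foreground occupies a few percent of any
#' real section. An automatic threshold applied to a section with no
#' signal at all (for example the human-tau channel of a control animal)
#' would simply split the noise distribution and mark a large share of the
#' section foreground. A section is therefore treated as signal-free for a
#' given algorithm when that algorithm's foreground would exceed
#' `max_foreground_frac` of the section — the section contributes empty
#' foreground for that algorithm, and its recorded threshold is `NA`.
#'
#' @param stack A [volume_stack()].
#' @param method `"combined"` (default), `"otsu"`, or `"triangle"`.
#' @param max_foreground_frac Largest credible per-section foreground
#'   fraction; a threshold selecting more than this is discarded as a
#'   no-signal artifact.
#' @return A `binary_mask`: list with `data` (logical array congruent with
#'   the stack), `channel`, calibration fields, `origin_um`, and
#'   `thresholds` (tibble `section`, `algorithm`, `value`).
#' @export
binarize_stack <- function(stack, method = c("combined", "otsu", "triangle"),
                           max_foreground_frac = 0.25) {
  method <- match.arg(method)
  algos <- switch(method,
                  combined = c("otsu", "triangle"),
                  otsu = "otsu",
                  triangle = "triangle")
  d <- dim(stack$data)
  mask <- array(FALSE, dim = d)
  rec <- vector("list", d[3])
  for (s in seq_len(d[3])) {
    img <- stack$data[, , s]
    fg <- matrix(FALSE, d[1], d[2])
    vals <- numeric(length(algos))
    for (j in seq_along(algos)) {
      thr <- switch(algos[j],
                    otsu = threshold_otsu(img),
                    triangle = threshold_triangle(img))
      if (!is.na(thr) && mean(img > thr) > max_foreground_frac) {
        thr <- NA_real_  # no-signal section: the cut only splits noise
      }
      vals[j] <- thr
      if (!is.na(thr)) fg <- fg | (img > thr)
    }
    mask[, , s] <- fg
    rec[[s]] <- tibble::tibble(section = s, algorithm = algos, value = vals)
  }
  structure(
    list(data = mask,
         channel = stack$channel,
         pixel_size_um = stack$pixel_size_um,
         section_thickness_um = stack$section_thickness_um,
         origin_um = stack$origin_um,
         method = method,
         thresholds = dplyr::bind_rows(rec)),
    class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<binary_mask> channel '%s' (%s): %dx%dx%d, %d foreground voxels\n",
    x$channel, x$method, d[1], d[2], d[3], sum(x$data)))
  invisible(x)
}

#' Export a binary mask as a multi-page TIFF (0/255) for inspection
#' @param mask A `binary_mask`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  d <- dim(mask$data)
  pages <- lapply(seq_len(d[3]), function(s) {
    matrix(as.numeric(mask$data[, , s]), d[1], d[2])
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}
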