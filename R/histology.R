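#' Stain image container
#'
#' An 8-bit RGB image of a stained section: Picrosirius Red (PSR, collagen
#' birefringence enhancer, fiber color tracks thickness/packing) or Alizarin
#' Red S (ARS, calcium deposits).
#'
#' @param rgb H-by-W-by-3 numeric array with values in `[0, 255]`.
#' @param stain `"PSR"` or `"ARS"`.
#' @param pixel_pitch physical pixel size, micrometres per pixel.
#' @return a `stain_image`.
#' @export
stain_image <- function(rgb, stain = c("PSR", "ARS"), pixel_pitch = 1) {
  stain <- match.arg(stain)
  stopifnot(is.array(rgb), length(dim(rgb)) == 3L, dim(rgb)[3] == 3L)
  if (anyNA(rgb) || any(rgb < 0 | rgb > 255)) stop("rgb values must be in [0, 255]")
  stopifnot(pixel_pitch > 0)
  structure(list(rgb = rgb, stain = stain, pixel_pitch = pixel_pitch),
            class = "stain_image")
}

#' Default picrosirius hue bins (degrees)
#'
#' Fiber-thickness categories by hue, following common picrosirius
#' hue-segmentation practice: thick (red), thick-intermediate (orange),
#' thin-intermediate (yellow), thin (green). Each bin is a union of
#' `[lo, hi)` intervals on the hue circle.
#' @return named list of 2-column interval matrices.
#' @export
psr_default_bins <- function() {
  list(thick              = rbind(c(0, 10), c(350, 360)),
       thick_intermediate = rbind(c(10, 40)),
       thin_intermediate  = rbind(c(40, 60)),
       thin               = rbind(c(60, 140)))
}

hue_in_bin <- function(hue, intervals) {
  hit <- rep(FALSE, length(hue))
  for (i in seq_len(nrow(intervals)))
    hit <- hit | (hue >= intervals[i, 1] & hue < intervals[i, 2])
  hit
}

#' PSR fiber-thickness composition by hue binning
#'
#' Converts the image to HSV, classifies collagen-positive pixels
#' (`saturation >= sat_floor` and `value >= val_floor` and hue inside the
#' union of the four bins) and reports, per region, the percentage of
#' collagen pixels falling in each thickness bin. Percentages sum to 100
#' whenever the region holds any collagen pixel; a region with none is
#' flagged `undefined` rather than reported as zeros.
#'
#' @param image a [stain_image()] with `stain = "PSR"`.
#' @param masks a `region_mask`.
#' @param hue_bins list of 4 hue-interval matrices, as [psr_default_bins()];
#'   bins must not overlap.
#' @param sat_floor,val_floor HSV floors in `[0, 1]` excluding unstained /
#'   background pixels.
#' @return data.frame with one row per region: percentage per bin,
#'   `collagen_pixel_count`, `undefined`.
#' @export
psr_bin <- function(image, masks, hue_bins = psr_default_bins(),
                    sat_floor = 0.25, val_floor = 0.10) {
  stopifnot(inherits(image, "stain_image"), inherits(masks, "region_mask"))
  if (image$stain != "PSR") stop("psr_bin requires a PSR stain image")
  if (length(hue_bins) != 4L) stop("exactly 4 hue bins are required")
  # reject overlapping bins on a fine hue grid
  grid <- seq(0, 359.75, by = 0.25)
  cover <- vapply(hue_bins, function(b) hue_in_bin(grid, b), logical(length(grid)))
  if (any(rowSums(cover) > 1)) stop("hue bins overlap")
  d <- dim(image$rgb)[1:2]
  if (!all(masks$shape == d)) stop("mask/image shape mismatch")
  px <- matrix(c(image$rgb[, , 1], image$rgb[, , 2], image$rgb[, , 3]),
               nrow = 3, byrow = TRUE)
  hsv <- grDevices::rgb2hsv(px, maxColorValue = 255)
  hue <- hsv[1, ] * 360
  positive <- hsv[2, ] >= sat_floor & hsv[3, ] >= val_floor
  bin_hits <- vapply(hue_bins, function(b) hue_in_bin(hue, b),
                     logical(length(hue)))
  positive <- positive & rowSums(bin_hits) > 0
  rows <- lapply(names(masks$masks), function(nm) {
    sel <- as.vector(masks$masks[[nm]]) & positive
    n <- sum(sel)
    pct <- if (n > 0L) 100 * colSums(bin_hits[sel, , drop = FALSE]) / n
           else rep(NA_real_, 4L)
    out <- data.frame(region = nm, collagen_pixel_count = n, undefined = n == 0L)
    out[paste0("pct_", names(hue_bins))] <- as.list(pct)
    out
  })
  do.call(rbind, rows)
}

# two-pass 8-connected component labelling (union-find); mask is logical
label_components <- function(mask, connectivity = 8L) {
  h <- nrow(mask); w <- ncol(mask)
  labels <- matrix(0L, h, w)
  parent <- integer(0)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  nxt <- 0L
  for (j in seq_len(w)) for (i in seq_len(h)) {
    if (!mask[i, j]) next
    nb <- integer(0)
    if (i > 1L && labels[i - 1L, j]) nb <- c(nb, labels[i - 1L, j])
    if (j > 1L) {
      if (labels[i, j - 1L]) nb <- c(nb, labels[i, j - 1L])
      if (connectivity == 8L) {
        if (i > 1L && labels[i - 1L, j - 1L]) nb <- c(nb, labels[i - 1L, j - 1L])
        if (i < h && labels[i + 1L, j - 1L]) nb <- c(nb, labels[i + 1L, j - 1L])
      }
    }
    if (length(nb) == 0L) {
      nxt <- nxt + 1L; parent[nxt] <- nxt; labels[i, j] <- nxt
    } else {
      roots <- vapply(unique(nb), find, integer(1))
      r0 <- min(roots)
      labels[i, j] <- r0
      for (r in roots) parent[r] <- r0
    }
  }
  if (nxt == 0L) return(labels)
  flat <- vapply(seq_len(nxt), find, integer(1))
  relab <- integer(nxt)
  relab[sort(unique(flat))] <- seq_along(unique(flat))
  pos <- labels > 0L
  labels[pos] <- relab[flat[labels[pos]]]
  labels
}

#' ARS percent-positive area by constant-threshold particle analysis
#'
#' Mirrors the Fiji/ImageJ workflow on Alizarin Red S sections: the RGB image
#' is converted to 8-bit grayscale (ITU-R 601 luminance weights
#' 0.299/0.587/0.114), binarized at a constant threshold (positive = pixels
#' darker than `threshold`: ARS deposits are dark red on a bright
#' background), labelled into 8-connected components, and components smaller
#' than `min_particle` pixels are discarded. Per region it reports the
#' percent positive area and the surviving particle statistics (a particle is
#' attributed to every region it touches).
#'
#' @param image a [stain_image()] with `stain = "ARS"`.
#' @param masks a `region_mask`.
#' @param threshold 8-bit grayscale threshold in `[0, 255]` (default 100).
#' @param min_particle minimum particle size in pixels, `>= 1` (default 4).
#' @return list with `per_region` (data.frame: `region`,
#'   `percent_positive_area`, `particle_count`, `n_pixels`) and `particles`
#'   (data.frame: `particle`, `area_px`, `area_um2`).
#' @export
ars_percent_area <- function(image, masks, threshold = 100, min_particle = 4L) {
  stopifnot(inherits(image, "stain_image"), inherits(masks, "region_mask"))
  if (image$stain != "ARS") stop("ars_percent_area requires an ARS stain image")
  if (threshold < 0 || threshold > 255) stop("threshold must be in [0, 255]")
  if (min_particle < 1L) stop("min_particle must be >= 1")
  d <- dim(image$rgb)[1:2]
  if (!all(masks$shape == d)) stop("mask/image shape mismatch")
  gray <- 0.299 * image$rgb[, , 1] + 0.587 * image$rgb[, , 2] +
          0.114 * image$rgb[, , 3]
  positive <- gray < threshold
  labels <- label_components(positive, 8L)
  if (max(labels) > 0L) {
    sizes <- tabulate(labels[labels > 0L])
    keep_ids <- which(sizes >= min_particle)
    keep <- labels > 0L & labels %in% keep_ids
    labels[!keep] <- 0L
  } else {
    sizes <- integer(0); keep_ids <- integer(0)
  }
  pitch2 <- image$pixel_pitch^2
  particles <- data.frame(particle = keep_ids,
                          area_px = if (length(keep_ids)) sizes[keep_ids] else integer(0))
  particles$area_um2 <- particles$area_px * pitch2
  per_region <- do.call(rbind, lapply(names(masks$masks), function(nm) {
    m <- masks$masks[[nm]]
    n <- sum(m)
    lab_in <- unique(labels[m & labels > 0L])
    data.frame(region = nm,
               percent_positive_area = if (n) 100 * sum(labels[m] > 0L) / n else NaN,
               particle_count = length(lab_in),
               n_pixels = n, empty = n == 0L)
  }))
  list(per_region = per_region, particles = particles,
       positive_mask = labels > 0L)
}
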