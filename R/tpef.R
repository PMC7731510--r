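#' Co-registered TPEF autofluorescence channel set
#'
#' Holds the four two-photon excited fluorescence intensity fields acquired
#' per tissue section, indexed by excitation/emission wavelength (nm):
#' `a755_460` (NADH-weighted), `a860_525` (FAD-weighted), and the 810-nm
#' pair `a810_460` (collagen-weighted) and `a810_525` (calcium-weighted).
#' Intensities are arbitrary units; the ratios below are gain-invariant.
#'
#' @param a755_460,a860_525,a810_460,a810_525 nonnegative numeric matrices of
#'   identical dimensions.
#' @return a `channel_set` object.
#' @export
channel_set <- function(a755_460, a860_525, a810_460, a810_525) {
  ch <- list(a755_460 = a755_460, a860_525 = a860_525,
             a810_460 = a810_460, a810_525 = a810_525)
  d <- dim(a755_460)
  for (nm in names(ch)) {
    x <- ch[[nm]]
    if (!is.matrix(x) || !is.numeric(x)) stop(nm, " must be a numeric matrix")
    if (!all(dim(x) == d)) stop("channel shapes differ (", nm, ")")
    if (anyNA(x) || any(!is.finite(x))) stop(nm, " contains non-finite values")
    if (any(x < 0)) stop(nm, " contains negative intensities")
  }
  structure(ch, class = "channel_set")
}

ratio_map_new <- function(num, den, floor, kind) {
  if (!all(dim(num) == dim(den))) stop("channel shape mismatch")
  if (!is.numeric(floor) || length(floor) != 1L || floor < 0)
    stop("floor must be a single nonnegative intensity")
  total <- num + den
  valid <- total >= floor & total > 0
  values <- matrix(NA_real_, nrow(num), ncol(num))
  values[valid] <- num[valid] / total[valid]
  structure(list(values = values, valid = valid, kind = kind, floor = floor),
            class = "ratio_map")
}

#' Per-pixel TPEF autofluorescence ratios
#'
#' `ratio_755_860` computes the 755–860 ratio
#' \deqn{A_{860/525} / (A_{755/460} + A_{860/525})}
#' a generalisation of the optical redox ratio FAD/(FAD+NADH) to tissue,
#' where autofluorescence also carries collagen, lipid and mineral signal.
#' `ratio_col_cal` computes the Collagen–Calcium (Col–Cal) ratio
#' \deqn{A_{810/525} / (A_{810/460} + A_{810/525})}
#' contrasting collagen-like (525 nm) against calcium-like (460 nm) emission
#' at 810 nm excitation. Both are evaluated at each pixel; pixels whose
#' denominator channel sum falls below `floor` are marked invalid rather than
#' returning noise-dominated ratios.
#'
#' @param channels a [channel_set()].
#' @param floor intensity floor on the channel-pair sum (same arbitrary units
#'   as the channels). See [estimate_intensity_floor()] for a data-driven
#'   default.
#' @return a `ratio_map`: list with `values` (in `[0, 1]` where valid, `NA`
#'   elsewhere), `valid`, `kind`.
#' @export
ratio_755_860 <- function(channels, floor = 0) {
  stopifnot(inherits(channels, "channel_set"))
  ratio_map_new(channels$a860_525, channels$a755_460, floor, "ratio_755_860")
}

#' @rdname ratio_755_860
#' @export
ratio_col_cal <- function(channels, floor = 0) {
  stopifnot(inherits(channels, "channel_set"))
  ratio_map_new(channels$a810_525, channels$a810_460, floor, "col_cal")
}

#' Background-based intensity floor
#'
#' Estimates the ratio validity floor as mean + 2 sd of the channel-pair sum
#' over pixels outside every annotated region (background). Falls back to 0
#' when no background pixels exist.
#'
#' @param channels a [channel_set()].
#' @param masks a `region_mask` from [rasterize()].
#' @param pair `"755_860"` or `"810"`, selecting which channel pair's sum the
#'   floor applies to.
#' @return single numeric floor.
#' @export
estimate_intensity_floor <- function(channels, masks, pair = c("755_860", "810")) {
  pair <- match.arg(pair)
  stopifnot(inherits(channels, "channel_set"), inherits(masks, "region_mask"))
  total <- if (pair == "755_860") channels$a755_460 + channels$a860_525
           else channels$a810_460 + channels$a810_525
  bg <- Reduce(`|`, masks$masks)
  bg <- !bg
  if (!any(bg)) return(0)
  mean(total[bg]) + 2 * stats::sd(total[bg])
}

#' Per-region TPEF summary
#'
#' For each region: mean of each of the four channels, mean 755–860 ratio and
#' mean Col–Cal ratio, and the valid-pixel counts. Ratio means are means of
#' per-pixel ratios (the ratios are defined pixel-wise; region figures report
#' their averages) — not ratios of channel means.
#'
#' @inheritParams ratio_755_860
#' @param masks a `region_mask` rasterized at the channel shape.
#' @return data.frame, one row per region.
#' @export
tpef_region_summary <- function(channels, masks, floor = 0) {
  stopifnot(inherits(channels, "channel_set"), inherits(masks, "region_mask"))
  r1 <- ratio_755_860(channels, floor)
  r2 <- ratio_col_cal(channels, floor)
  rows <- lapply(names(masks$masks), function(nm) {
    m <- masks$masks[[nm]]
    if (!all(dim(m) == dim(channels$a755_460))) stop("mask/channel shape mismatch")
    n <- sum(m)
    m1 <- region_mean(r1$values, m, valid = r1$valid)
    m2 <- region_mean(r2$values, m, valid = r2$valid)
    data.frame(
      region = nm,
      mean_a755_460 = if (n) mean(channels$a755_460[m]) else NaN,
      mean_a860_525 = if (n) mean(channels$a860_525[m]) else NaN,
      mean_a810_460 = if (n) mean(channels$a810_460[m]) else NaN,
      mean_a810_525 = if (n) mean(channels$a810_525[m]) else NaN,
      mean_ratio_755_860 = m1$mean,
      mean_ratio_col_cal = m2$mean,
      n_pixels = n,
      n_valid_755_860 = m1$n_pixels,
      n_valid_col_cal = m2$n_pixels,
      empty = n == 0L)
  })
  do.call(rbind, rows)
}
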