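#' Configuration for the synthetic valve phantom
#'
#' The phantom encodes the generative assumptions the analysis pipeline
#' makes about a stained/imaged valve section, with known ground truth:
#' four linearly mixed fluorophore sources (NADH-, FAD-, collagen- and
#' calcium-like) observed through four TPEF excitation/emission channels
#' with additive noise; a single-harmonic polarization forward model
#' `I(theta) = B (1 + sin(delta) sin 2(theta - phi))` parameterized by
#' per-pixel retardation and axial orientation drawn from an axial von Mises
#' field; hue-structured PSR images; disk-shaped ARS deposits of known area
#' fraction; and group/time-structured echo and rater-score tables.
#'
#' The `effect_size` is the multiplicative "pro-calcific" modifier: it
#' scales the calcium source weight directly and couples into the NADH-like
#' source (factor `1 + 0.3 (effect - 1)`), so a stronger effect raises the
#' 460-nm-emission channels and depresses both TPEF ratios — the disease
#' signature the pipeline is meant to detect.
#'
#' @param image_size `c(height, width)` pixels (default 128 x 128, a
#'   desk-scale section).
#' @param pixel_pitch micrometres per pixel.
#' @param region_layout a [region_annotation()] placing leaflet, commissure
#'   and root polygons; `NULL` for the default layout scaled to
#'   `image_size`.
#' @param fluorophore_weights regions-by-sources nonnegative matrix of
#'   source concentrations (rows `leaflet`, `commissure`, `root`; columns
#'   `nadh`, `fad`, `collagen`, `calcium`), arbitrary units.
#' @param mixing_matrix 4x4 nonnegative map from sources (columns `nadh`,
#'   `fad`, `collagen`, `calcium`) to channels (rows `a755_460`, `a860_525`,
#'   `a810_460`, `a810_525`).
#' @param noise_model list: `gaussian_sd_frac` (sd as a fraction of the
#'   maximum clean signal; default 0.02) and `poisson_scale` (photons per
#'   intensity unit for shot-like noise, `NULL` to disable).
#' @param polarizer_angles K evenly spaced polarizer angles, degrees in
#'   `[0, 180)`; `K >= 4`.
#' @param retardation_range truth/display retardation range, degrees
#'   (default 0-50).
#' @param orientation_dispersion named per-region von Mises concentration
#'   `kappa` of the axial orientation field.
#' @param region_orientation_deg named per-region mean fiber direction.
#' @param region_retardation_deg named per-region base retardation.
#' @param ars_area_fraction target calcified area fraction per region at
#'   full effect, in `[0, 1]`.
#' @param psr_bin_fractions 4-vector of thickness-bin probabilities
#'   (thick, thick-intermediate, thin-intermediate, thin); sums to 1.
#' @param effect_size pro-calcific effect multiplier (1 = control).
#' @param thickness_factor per-section collagen thickness multiplier; the
#'   orientation concentration scales with its square, coupling thickness
#'   and disorder the way remodeling couples them in tissue.
#' @param seed integer RNG seed.
#' @return a `phantom_config`.
#' @export
phantom_config <- function(image_size = c(128L, 128L),
                           pixel_pitch = 2,
                           region_layout = NULL,
                           fluorophore_weights = default_fluorophore_weights(),
                           mixing_matrix = default_mixing_matrix(),
                           noise_model = list(gaussian_sd_frac = 0.02,
                                              poisson_scale = NULL),
                           polarizer_angles = seq(0, 180 - 10, by = 10),
                           retardation_range = c(0, 50),
                           orientation_dispersion = c(leaflet = 4, commissure = 6, root = 8),
                           region_orientation_deg = c(leaflet = 0, commissure = 45, root = 90),
                           region_retardation_deg = c(leaflet = 25, commissure = 30, root = 35),
                           ars_area_fraction = 0.05,
                           psr_bin_fractions = c(0.20, 0.30, 0.30, 0.20),
                           effect_size = 1,
                           thickness_factor = 1,
                           seed = 1L) {
  image_size <- as.integer(image_size)
  stopifnot(length(image_size) == 2L, all(image_size >= 16L))
  if (is.null(region_layout)) region_layout <- default_region_layout(image_size)
  stopifnot(inherits(region_layout, "region_annotation"))
  fw <- as.matrix(fluorophore_weights)
  if (anyNA(fw) || any(!is.finite(fw)) || any(fw < 0))
    stop("fluorophore weights must be finite and nonnegative")
  mm <- as.matrix(mixing_matrix)
  stopifnot(all(dim(mm) == c(4L, 4L)))
  if (anyNA(mm) || any(!is.finite(mm)) || any(mm < 0))
    stop("mixing_matrix entries must be finite and nonnegative")
  k <- length(polarizer_angles)
  if (k < 4L) stop("at least 4 polarizer angles are required (harmonic fit is under-determined below 4)")
  if (any(diff(polarizer_angles) <= 0)) stop("polarizer angles must be strictly increasing")
  if (any(polarizer_angles < 0 | polarizer_angles >= 180))
    stop("polarizer angles must lie in [0, 180)")
  if (any(ars_area_fraction < 0 | ars_area_fraction > 1))
    stop("ars_area_fraction must be in [0, 1]")
  if (abs(sum(psr_bin_fractions) - 1) > 1e-9)
    stop("psr_bin_fractions must sum to 1")
  if (!is.finite(effect_size) || effect_size <= 0)
    stop("effect_size must be positive and finite")
  structure(list(
    image_size = image_size, pixel_pitch = pixel_pitch,
    region_layout = region_layout,
    fluorophore_weights = fw, mixing_matrix = mm,
    noise_model = noise_model,
    polarizer_angles = as.numeric(polarizer_angles),
    retardation_range = retardation_range,
    orientation_dispersion = orientation_dispersion,
    region_orientation_deg = region_orientation_deg,
    region_retardation_deg = region_retardation_deg,
    ars_area_fraction = ars_area_fraction,
    psr_bin_fractions = psr_bin_fractions,
    effect_size = effect_size, thickness_factor = thickness_factor,
    seed = as.integer(seed)), class = "phantom_config")
}

#' @rdname phantom_config
#' @export
default_fluorophore_weights <- function() {
  m <- rbind(leaflet    = c(60, 40, 30, 2),
             commissure = c(50, 35, 45, 8),
             root       = c(45, 30, 60, 3))
  colnames(m) <- c("nadh", "fad", "collagen", "calcium")
  m
}

#' @rdname phantom_config
#' @export
default_mixing_matrix <- function() {
  # rows: channels; cols: sources. Calcium loads mostly on 460-nm emission
  # (both at 755 and 810 nm excitation), so raising it depresses both the
  # 755-860 and the Col-Cal ratio.
  m <- rbind(a755_460 = c(1.0, 0.1, 0.3, 0.6),
             a860_525 = c(0.1, 1.0, 0.2, 0.2),
             a810_460 = c(0.4, 0.1, 0.7, 1.0),
             a810_525 = c(0.1, 0.5, 1.0, 0.3))
  colnames(m) <- c("nadh", "fad", "collagen", "calcium")
  m
}

#' @rdname phantom_config
#' @param image_size `c(height, width)` pixels.
#' @export
default_region_layout <- function(image_size) {
  h <- image_size[1]; w <- image_size[2]
  octagon <- function(cx, cy, rx, ry) {
    a <- seq(0, 2 * pi, length.out = 9L)[-9L]
    cbind(cx + rx * cos(a), cy + ry * sin(a))
  }
  quad <- function(cx, cy, rx, ry)
    cbind(c(cx - rx, cx + rx, cx + rx, cx - rx),
          c(cy - ry, cy - ry, cy + ry, cy + ry))
  region_annotation(list(
    list(name = "leaflet", polygon = octagon(0.50 * w, 0.38 * h, 0.20 * w, 0.16 * h)),
    list(name = "commissure", polygon = quad(0.16 * w, 0.52 * h, 0.07 * w, 0.07 * h)),
    list(name = "commissure", polygon = quad(0.84 * w, 0.52 * h, 0.07 * w, 0.07 * h)),
    list(name = "root", polygon = cbind(
      c(0.06, 0.94, 0.90, 0.10) * w, c(0.70, 0.70, 0.94, 0.94) * h))))
}

# effect-modified source weights: calcium scales with effect, NADH couples
# at 0.3 per unit of excess effect (metabolic shift raises 460-nm signal)
effective_weights <- function(config) {
  fw <- config$fluorophore_weights
  e <- config$effect_size
  fw[, "calcium"] <- fw[, "calcium"] * e
  fw[, "nadh"] <- fw[, "nadh"] * (1 + 0.3 * (e - 1))
  fw
}

# deterministic per-block seeds so skipping a component never perturbs the
# draws of another
block_seeds <- function(seed, n = 8L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

place_ars_deposits <- function(region_masks, fractions, radius, seed) {
  set.seed(seed)
  h <- region_masks$shape[1]; w <- region_masks$shape[2]
  calc <- matrix(FALSE, h, w)
  off <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  off <- off[off$dr^2 + off$dc^2 <= radius^2, ]
  for (nm in names(region_masks$masks)) {
    m <- region_masks$masks[[nm]]
    idx <- which(m)
    n_reg <- length(idx)
    target <- round(fractions[[nm]] * n_reg)
    if (target <= 0L || n_reg == 0L) next
    covered <- 0L
    guard <- 0L
    while (covered < target && guard < 10000L) {
      guard <- guard + 1L
      ctr <- idx[sample.int(n_reg, 1L)]
      ci <- (ctr - 1L) %% h + 1L
      cj <- (ctr - 1L) %/% h + 1L
      ri <- ci + off$dr; rj <- cj + off$dc
      ok <- ri >= 1L & ri <= h & rj >= 1L & rj <= w
      ri <- ri[ok]; rj <- rj[ok]
      lin <- (rj - 1L) * h + ri
      lin <- lin[m[lin] & !calc[lin]]
      if (length(lin) == 0L) next
      need <- target - covered
      if (length(lin) > need) {
        # trim the final deposit to hit the configured fraction exactly,
        # keeping pixels closest to the deposit center
        d2 <- ((lin - 1L) %% h + 1L - ci)^2 + ((lin - 1L) %/% h + 1L - cj)^2
        lin <- lin[order(d2)][seq_len(need)]
      }
      calc[lin] <- TRUE
      covered <- covered + length(lin)
    }
  }
  calc
}

#' Generate one synthetic valve-section dataset
#'
#' Draws every pipeline input for a single section from the forward models
#' described in [phantom_config()], alongside the ground truth each
#' estimator is later judged against. Deterministic for a fixed seed;
#' component blocks use independently derived sub-seeds, so skipping one
#' component never changes another's draws.
#'
#' @param config a [phantom_config()].
#' @param components which blocks to generate: any of `"channels"`,
#'   `"polarization"`, `"psr"`, `"ars"`, `"tables"`. Truth maps needed by a
#'   requested block are always generated.
#' @return a `phantom_dataset`: list with `channels` ([channel_set()]),
#'   `stack` ([polarization_stack()]), `psr`/`ars` ([stain_image()]),
#'   `annotation`, `masks`, `truth` (source maps, retardation, orientation,
#'   calcified mask, realized PSR bin fractions, per-region calcium burden),
#'   `echo_row`, `score_rows`, `effect`, `seed`.
#' @export
generate_phantom <- function(config,
                             components = c("channels", "polarization",
                                            "psr", "ars", "tables")) {
  stopifnot(inherits(config, "phantom_config"))
  components <- match.arg(components, several.ok = TRUE)
  h <- config$image_size[1]; w <- config$image_size[2]
  masks <- rasterize(config$region_layout, config$image_size)
  seeds <- block_seeds(config$seed)
  fw <- effective_weights(config)
  regions <- rownames(fw)

  # --- truth source concentration maps -----------------------------------
  sources <- array(0, dim = c(h, w, 4L),
                   dimnames = list(NULL, NULL, colnames(fw)))
  for (r in regions) {
    m <- masks$masks[[r]]
    for (s in colnames(fw)) {
      pl <- sources[, , s]; pl[m] <- fw[r, s]; sources[, , s] <- pl
    }
  }
  region_calcium <- stats::setNames(fw[, "calcium"], regions)

  truth <- list(sources = sources, region_calcium = region_calcium,
                effect = config$effect_size)
  out <- list(annotation = config$region_layout, masks = masks,
              effect = config$effect_size, seed = config$seed,
              pixel_pitch = config$pixel_pitch)

  # --- TPEF channels ------------------------------------------------------
  if ("channels" %in% components) {
    set.seed(seeds[1])
    mm <- config$mixing_matrix
    npx <- h * w
    smat <- matrix(sources, nrow = npx)           # npx x 4
    clean <- smat %*% t(mm)                       # npx x 4 channels
    sdv <- config$noise_model$gaussian_sd_frac
    noisy <- clean
    if (!is.null(config$noise_model$poisson_scale)) {
      sc <- config$noise_model$poisson_scale
      noisy <- matrix(stats::rpois(length(clean), pmax(clean, 0) * sc) / sc,
                      nrow = npx)
    }
    if (!is.null(sdv) && sdv > 0) {
      sd_abs <- sdv * max(clean)
      noisy <- noisy + matrix(stats::rnorm(length(noisy), 0, sd_abs), nrow = npx)
    }
    noisy <- pmax(noisy, 0)
    out$channels <- channel_set(
      a755_460 = matrix(noisy[, 1], h, w),
      a860_525 = matrix(noisy[, 2], h, w),
      a810_460 = matrix(noisy[, 3], h, w),
      a810_525 = matrix(noisy[, 4], h, w))
  }

  # --- retardation / orientation truth + polarization stack --------------
  need_fibers <- "polarization" %in% components
  set.seed(seeds[2])
  tf <- config$thickness_factor
  ret <- matrix(0, h, w)
  ori <- matrix(stats::runif(h * w, 0, pi), h, w)   # background: isotropic
  xnorm <- matrix(rep((seq_len(w) - 0.5) / w, each = h), h, w)
  for (r in regions) {
    m <- masks$masks[[r]]
    base <- config$region_retardation_deg[[r]] * tf
    ret[m] <- pmin(pmax(base * (0.5 + xnorm[m]), config$retardation_range[1]),
                   config$retardation_range[2])
    kap <- config$orientation_dispersion[[r]] * tf^2
    mu <- config$region_orientation_deg[[r]] * pi / 180
    ori[m] <- raxial_vonmises(sum(m), mu, kap)
  }
  truth$retardation <- ret
  truth$orientation_deg <- ori * 180 / pi
  truth$kappa <- stats::setNames(config$orientation_dispersion[regions] * tf^2, regions)
  truth$thickness_factor <- tf

  if (need_fibers) {
    set.seed(seeds[3])
    b <- 50 + sources[, , "collagen"]
    th <- config$polarizer_angles * pi / 180
    k <- length(th)
    sindelta <- sin(ret * pi / 180)
    frames <- array(0, dim = c(k, h, w))
    for (i in seq_len(k))
      frames[i, , ] <- b * (1 + sindelta * sin(2 * (th[i] - ori)))
    sdv <- config$noise_model$gaussian_sd_frac
    if (!is.null(sdv) && sdv > 0)
      frames <- frames + array(stats::rnorm(length(frames), 0, sdv * max(frames)),
                               dim = dim(frames))
    frames <- pmax(frames, 0)
    out$stack <- polarization_stack(frames, config$polarizer_angles)
  }

  # --- PSR stain image ----------------------------------------------------
  if ("psr" %in% components) {
    set.seed(seeds[4])
    bin_hues <- c(thick = 5, thick_intermediate = 25,
                  thin_intermediate = 50, thin = 100)
    rgbp <- array(0, dim = c(h, w, 3L))
    realized <- list()
    for (r in regions) {
      m <- masks$masks[[r]]
      n <- sum(m)
      bin <- sample.int(4L, n, replace = TRUE, prob = config$psr_bin_fractions)
      realized[[r]] <- tabulate(bin, 4L) / n
      cols <- grDevices::col2rgb(grDevices::hsv(bin_hues / 360, 0.85, 0.90))
      for (ch in 1:3) {
        pl <- rgbp[, , ch]; pl[m] <- cols[ch, bin]; rgbp[, , ch] <- pl
      }
    }
    out$psr <- stain_image(rgbp, "PSR", config$pixel_pitch)
    truth$psr_bin_fractions <- do.call(rbind, realized)
    colnames(truth$psr_bin_fractions) <- names(bin_hues)
  }

  # --- ARS stain image ----------------------------------------------------
  if ("ars" %in% components) {
    frac <- config$ars_area_fraction
    fractions <- if (length(frac) == 1L)
      stats::setNames(rep(frac, length(regions)), regions) else frac
    calc <- place_ars_deposits(masks, as.list(fractions),
                               radius = 2L, seed = seeds[5])
    rgba <- array(0, dim = c(h, w, 3L))
    bgcol <- c(230, 225, 220); tissue <- c(235, 200, 205); dep <- c(165, 30, 45)
    tis <- Reduce(`|`, masks$masks)
    for (ch in 1:3) {
      pl <- matrix(bgcol[ch], h, w)
      pl[tis] <- tissue[ch]
      pl[calc] <- dep[ch]
      rgba[, , ch] <- pl
    }
    out$ars <- stain_image(rgba, "ARS", config$pixel_pitch)
    truth$calcified_mask <- calc
    truth$ars_target_fraction <- fractions
  }

  # --- echo / score table fragments --------------------------------------
  if ("tables" %in% components) {
    set.seed(seeds[6])
    e <- config$effect_size
    lvidd <- stats::rnorm(1, 4.0, 0.15)
    sratio <- min(max(0.67 + 0.015 * (e - 1) + stats::rnorm(1, 0, 0.01), 0.2), 0.95)
    hr <- max(stats::rnorm(1, 500, 30), 300)
    out$echo_row <- data.frame(lvidd_mm = lvidd, lvids_mm = lvidd * sratio,
                               hr_bpm = hr)
    markers <- c(aSMA = 0.40, vimentin = 0.80, RUNX2 = 0.20, osteopontin = 0.30,
                 BMP4 = 0.30, Ki67 = 0.20, TGFb1 = 0.50)
    slopes <- c(aSMA = 0.35, vimentin = 0.10, RUNX2 = 0.50, osteopontin = 0.45,
                BMP4 = 0.30, Ki67 = 0.40, TGFb1 = 0.25)
    rows <- lapply(names(markers), function(mk) {
      lat <- markers[[mk]] + slopes[[mk]] * (e - 1) + stats::rnorm(3, 0, 0.3)
      data.frame(marker = mk, rater = 1:3,
                 score = as.integer(pmin(pmax(floor(lat + 0.5), 0), 2)))
    })
    out$score_rows <- do.call(rbind, rows)
  }

  out$truth <- truth
  structure(out, class = "phantom_dataset")
}

#' Generate a full phantom study (groups x weeks x animals)
#'
#' Emulates the study design: animals randomized to a control or
#' pro-calcific diet and followed over weeks. Pro-calcific animals at week
#' `w` receive an effect `1 + (effect_size - 1) * w / 16`, so the configured
#' `effect_size` is reached at week 16 and keeps growing to week 28;
#' controls stay at 1. Per-animal biological variability: lognormal jitter
#' (sdlog 0.05) on all source weights and a lognormal section thickness
#' factor whose log-mean decreases with effect (remodeling thins fibers and,
#' through the thickness-dispersion coupling, disorders them). ARS target
#' fractions ramp with the effect (controls keep a 0.002 baseline). All
#' per-animal seeds derive reproducibly from the master seed.
#'
#' @param config a [phantom_config()]; its `effect_size` is the week-16
#'   pro-calcific effect.
#' @param n_per_group animals per diet-by-week cell, `>= 1`.
#' @param weeks study weeks (default `c(4, 16, 28)`).
#' @param diets group labels, subset of `control`, `pro_calcific`.
#' @param components forwarded to [generate_phantom()]; drop
#'   `"polarization"`/`"psr"` for a lighter study when only TPEF/ARS
#'   analyses are needed.
#' @return a `phantom_study`: list with `datasets` (named list of
#'   `phantom_dataset`), `info` (animal, diet, week, effect, seed,
#'   thickness_factor), `echo_table`, `score_table`, `config`.
#' @export
generate_study <- function(config, n_per_group,
                           weeks = c(4, 16, 28),
                           diets = c("control", "pro_calcific"),
                           components = c("channels", "polarization",
                                          "psr", "ars", "tables")) {
  stopifnot(inherits(config, "phantom_config"))
  if (n_per_group < 1L) stop("n_per_group must be >= 1")
  if (!all(diets %in% c("control", "pro_calcific")))
    stop("unknown group label: ", paste(setdiff(diets, c("control", "pro_calcific")),
                                        collapse = ", "))
  grid <- expand.grid(diet = diets, week = weeks, animal = seq_len(n_per_group),
                      stringsAsFactors = FALSE)
  seeds <- block_seeds(config$seed, n = 2L * nrow(grid) + 1L)
  datasets <- list()
  info <- echo_rows <- score_rows <- list()
  for (i in seq_len(nrow(grid))) {
    diet <- grid$diet[i]; week <- grid$week[i]
    eff <- if (diet == "pro_calcific")
      1 + (config$effect_size - 1) * week / 16 else 1
    set.seed(seeds[2L * i - 1L])
    fw <- config$fluorophore_weights *
      matrix(stats::rlnorm(length(config$fluorophore_weights), 0, 0.05),
             nrow(config$fluorophore_weights))
    tf <- stats::rlnorm(1, -0.05 * (eff - 1), 0.15)
    ars_base <- if (length(config$ars_area_fraction) == 1L)
      config$ars_area_fraction else max(config$ars_area_fraction)
    frac <- if (diet == "pro_calcific" && config$effect_size > 1)
      min(ars_base * (eff - 1) / (config$effect_size - 1), 0.6) else 0.002
    cfg_i <- config
    cfg_i$fluorophore_weights <- fw
    cfg_i$effect_size <- eff
    cfg_i$thickness_factor <- tf
    cfg_i$ars_area_fraction <- frac
    cfg_i$seed <- seeds[2L * i]
    id <- sprintf("%s_w%02d_a%02d", diet, week, grid$animal[i])
    ds <- generate_phantom(cfg_i, components = components)
    datasets[[id]] <- ds
    info[[i]] <- data.frame(animal = id, diet = diet, week = week,
                            effect = eff, seed = cfg_i$seed,
                            thickness_factor = tf)
    if (!is.null(ds$echo_row))
      echo_rows[[i]] <- cbind(data.frame(animal = id, diet = diet, week = week),
                              ds$echo_row)
    if (!is.null(ds$score_rows))
      score_rows[[i]] <- cbind(data.frame(animal = id, diet = diet, week = week),
                               ds$score_rows)
  }
  structure(list(datasets = datasets,
                 info = do.call(rbind, info),
                 echo_table = if (length(echo_rows)) do.call(rbind, echo_rows),
                 score_table = if (length(score_rows)) do.call(rbind, score_rows),
                 config = config), class = "phantom_study")
}
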