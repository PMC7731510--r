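test_that("single-hue PSR images land entirely in one thickness bin", {
  rm <- whole_image_mask(10, 10, "leaflet")
  red <- stain_image(flat_rgb(10, 10, c(255, 0, 0)), "PSR")
  res <- psr_bin(red, rm)
  expect_equal(res$pct_thick, 100)
  expect_equal(res$pct_thick_intermediate + res$pct_thin_intermediate +
                 res$pct_thin, 0)
  expect_equal(res$collagen_pixel_count, 100L)
})

test_that("equal quarters of the four reference hues bin to 25/25/25/25", {
  hues <- c(5, 25, 50, 100) / 360
  cols <- grDevices::col2rgb(grDevices::hsv(hues, 0.9, 0.9))
  img <- array(0, c(8, 8, 3))
  quadrant <- list(1:4, 5:8)
  k <- 0
  for (qi in 1:2) for (qj in 1:2) {
    k <- k + 1
    for (ch in 1:3) img[quadrant[[qi]], quadrant[[qj]], ch] <- cols[ch, k]
  }
  res <- psr_bin(stain_image(img, "PSR"), whole_image_mask(8, 8))
  pct <- unlist(res[grep("^pct_", names(res))])
  expect_equal(unname(pct), c(25, 25, 25, 25))
  expect_equal(sum(pct), 100, tolerance = 1e-6)
})

test_that("an all-black PSR image yields an undefined composition, not zeros", {
  res <- psr_bin(stain_image(flat_rgb(6, 6, c(0, 0, 0)), "PSR"),
                 whole_image_mask(6, 6))
  expect_equal(res$collagen_pixel_count, 0L)
  expect_true(res$undefined)
  expect_true(all(is.na(unlist(res[grep("^pct_", names(res))]))))
})

test_that("PSR percentages are permutation-invariant and sum to 100 on phantoms", {
  ds <- generate_phantom(tiny_config(), components = "psr")
  res <- psr_bin(ds$psr, ds$masks)
  pct <- as.matrix(res[grep("^pct_", names(res))])
  expect_equal(unname(rowSums(pct)), rep(100, 3), tolerance = 1e-6)
  # realized truth fractions match the measured composition exactly
  expect_equal(unname(pct[match(rownames(ds$truth$psr_bin_fractions),
                                res$region), ] / 100),
               unname(ds$truth$psr_bin_fractions), tolerance = 1e-9)

  # shuffling pixel positions within the region leaves percentages unchanged
  set.seed(9)
  img <- ds$psr$rgb
  m <- ds$masks$masks$leaflet
  perm <- sample(which(m))
  for (ch in 1:3) { pl <- img[, , ch]; pl[which(m)] <- pl[perm]; img[, , ch] <- pl }
  res2 <- psr_bin(stain_image(img, "PSR"), ds$masks)
  expect_equal(res2[res2$region == "leaflet", grep("^pct_", names(res2))],
               res[res$region == "leaflet", grep("^pct_", names(res))])
})

test_that("overlapping hue bins are rejected", {
  bad <- psr_default_bins()
  bad$thin[1, 1] <- 55
  expect_error(psr_bin(stain_image(flat_rgb(4, 4, c(255, 0, 0)), "PSR"),
                       whole_image_mask(4, 4), hue_bins = bad), "overlap")
})

test_that("ARS controls: blank image gives 0 percent, saturated gives 100", {
  rm <- whole_image_mask(10, 10, "commissure")
  blank <- stain_image(flat_rgb(10, 10, c(255, 255, 255)), "ARS")
  res <- ars_percent_area(blank, rm)
  expect_equal(res$per_region$percent_positive_area, 0)
  expect_equal(res$per_region$particle_count, 0L)

  full <- stain_image(flat_rgb(10, 10, c(60, 10, 20)), "ARS")
  res2 <- ars_percent_area(full, rm)
  expect_equal(res2$per_region$percent_positive_area, 100)
})

test_that("particle analysis keeps a 500-px deposit and drops sub-threshold specks", {
  img <- flat_rgb(100, 100, c(255, 255, 255))
  dark <- function(rows, cols) {
    for (ch in 1:3) img[rows, cols, ch] <<- c(60, 10, 20)[ch]
  }
  dark(11:30, 21:45)            # 20 x 25 = 500 px deposit
  dark(60, 60); dark(70:71, 10) # 1-px and 2-px specks
  dark(90, 90:91)               # another 2-px speck
  res <- ars_percent_area(stain_image(img, "ARS", pixel_pitch = 2),
                          whole_image_mask(100, 100, "commissure"),
                          min_particle = 4)
  expect_equal(res$per_region$percent_positive_area, 5.0)
  expect_equal(res$per_region$particle_count, 1L)
  expect_equal(res$particles$area_px, 500L)
  expect_equal(res$particles$area_um2, 2000)
  expect_error(ars_percent_area(stain_image(img, "ARS"),
                                whole_image_mask(100, 100), min_particle = 0),
               "min_particle")
})

test_that("components are 8-connected and percent area is monotone in strictness", {
  # diagonal chain: one particle under 8-connectivity
  img <- flat_rgb(10, 10, c(255, 255, 255))
  for (i in 1:5) for (ch in 1:3) img[i, i, ch] <- c(60, 10, 20)[ch]
  res <- ars_percent_area(stain_image(img, "ARS"), whole_image_mask(10, 10),
                          min_particle = 5)
  expect_equal(res$per_region$particle_count, 1L)
  expect_equal(res$particles$area_px, 5L)

  ds <- generate_phantom(tiny_config(ars_area_fraction = 0.1), components = "ars")
  pct_at <- function(threshold, min_particle)
    ars_percent_area(ds$ars, ds$masks, threshold, min_particle)$
      per_region$percent_positive_area
  p_thr <- sapply(c(150, 100, 60), function(t) pct_at(t, 1))
  expect_true(all(diff(t(p_thr)) <= 0))       # stricter threshold, less area
  p_min <- sapply(c(1, 4, 20, 200), function(mp) pct_at(100, mp))
  expect_true(all(diff(t(p_min)) <= 0))       # larger size floor, less area
})

test_that("measured ARS percent recovers the configured phantom fraction", {
  # fractions chosen so every region's target deposit clears the 4-px
  # particle floor on a 64x64 section (the smallest region holds ~160 px)
  for (frac in c(0.05, 0.08, 0.15)) {
    ds <- generate_phantom(tiny_config(ars_area_fraction = frac),
                           components = "ars")
    res <- ars_percent_area(ds$ars, ds$masks)
    expect_true(all(abs(res$per_region$percent_positive_area - 100 * frac) <= 1))
    # truth mask itself is exact to pixel quantization
    for (r in names(ds$masks$masks)) {
      m <- ds$masks$masks[[r]]
      got <- sum(ds$truth$calcified_mask & m)
      expect_lte(abs(got - frac * sum(m)), 1)
    }
  }
})
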