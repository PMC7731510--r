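test_that("generation is bit-identical for a fixed seed", {
  cfg <- tiny_config()
  d1 <- generate_phantom(cfg)
  d2 <- generate_phantom(cfg)
  expect_identical(d1$channels, d2$channels)
  expect_identical(d1$stack$frames, d2$stack$frames)
  expect_identical(d1$psr$rgb, d2$psr$rgb)
  expect_identical(d1$ars$rgb, d2$ars$rgb)
  expect_identical(d1$truth, d2$truth)
  # truth shared with a lighter component selection stays identical
  d3 <- generate_phantom(cfg, components = c("channels", "ars"))
  expect_identical(d3$channels, d1$channels)
  expect_identical(d3$truth$calcified_mask, d1$truth$calcified_mask)
})

test_that("channels follow the linear forward model exactly at zero noise", {
  fw <- default_fluorophore_weights()
  fw[, "calcium"] <- 0
  cfg <- noiseless_config(fluorophore_weights = fw)
  ds <- generate_phantom(cfg, components = "channels")
  mm <- cfg$mixing_matrix
  for (r in rownames(fw)) {
    m <- ds$masks$masks[[r]]
    want <- drop(mm %*% fw[r, ])
    expect_equal(unique(ds$channels$a810_525[m]), want[["a810_525"]])
    expect_equal(unique(ds$channels$a755_460[m]), want[["a755_460"]])
  }
  expect_true(all(ds$channels$a810_525[!Reduce(`|`, ds$masks$masks)] == 0))
})

test_that("known mixing inverse recovers source concentrations at zero noise", {
  cfg <- noiseless_config()
  ds <- generate_phantom(cfg, components = "channels")
  minv <- solve(cfg$mixing_matrix)
  npx <- prod(cfg$image_size)
  a <- cbind(as.vector(ds$channels$a755_460), as.vector(ds$channels$a860_525),
             as.vector(ds$channels$a810_460), as.vector(ds$channels$a810_525))
  rec <- a %*% t(minv)
  truth <- matrix(ds$truth$sources, nrow = npx)
  expect_equal(rec, truth, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("channel images are nonnegative even under heavy noise", {
  cfg <- tiny_config(noise_model = list(gaussian_sd_frac = 0.5, poisson_scale = 2))
  ds <- generate_phantom(cfg, components = "channels")
  for (nm in c("a755_460", "a860_525", "a810_460", "a810_525"))
    expect_true(all(ds$channels[[nm]] >= 0))
})

test_that("polarization stack is constant over angles where retardation is zero", {
  cfg <- noiseless_config(region_retardation_deg = c(leaflet = 0, commissure = 0,
                                                     root = 0))
  ds <- generate_phantom(cfg, components = "polarization")
  fr <- ds$stack$frames
  spread <- apply(fr, c(2, 3), function(v) max(v) - min(v))
  expect_equal(max(spread), 0)
})

test_that("invalid configurations are rejected", {
  expect_error(phantom_config(polarizer_angles = c(0, 60, 120)), "at least 4")
  expect_error(phantom_config(polarizer_angles = c(0, 50, 40, 130)), "increasing")
  fw <- default_fluorophore_weights(); fw[1, 1] <- NA
  expect_error(phantom_config(fluorophore_weights = fw), "finite")
  fw2 <- default_fluorophore_weights(); fw2[2, 3] <- -1
  expect_error(phantom_config(fluorophore_weights = fw2), "nonnegative")
  mm <- default_mixing_matrix(); mm[1, 1] <- -0.1
  expect_error(phantom_config(mixing_matrix = mm), "nonnegative")
  expect_error(phantom_config(psr_bin_fractions = c(0.5, 0.5, 0.1, 0.1)),
               "sum to 1")
  expect_error(phantom_config(ars_area_fraction = 1.2), "\\[0, 1\\]")
  expect_error(generate_study(tiny_config(), n_per_group = 0), ">= 1")
  expect_error(generate_study(tiny_config(), n_per_group = 2,
                              diets = c("control", "high_fat")), "unknown group")
})

test_that("null studies show no systematic calcium difference; effect studies do", {
  cfg <- tiny_config(effect_size = 1, seed = 21)
  null_study <- generate_study(cfg, n_per_group = 4, weeks = c(4, 16),
                               components = "channels")
  cal <- function(study, diet, week) {
    ids <- study$info$animal[study$info$diet == diet & study$info$week == week]
    vapply(ids, function(id)
      study$datasets[[id]]$truth$region_calcium[["commissure"]], 0)
  }
  c0 <- cal(null_study, "control", 16); p0 <- cal(null_study, "pro_calcific", 16)
  expect_equal(null_study$info$effect, rep(1, nrow(null_study$info)))
  # only lognormal sampling jitter separates the groups
  expect_lt(abs(mean(p0) - mean(c0)), 3 * 0.05 * 8)

  eff_study <- generate_study(tiny_config(effect_size = 3, seed = 21),
                              n_per_group = 4, weeks = c(4, 16),
                              components = "channels")
  expect_gt(mean(cal(eff_study, "pro_calcific", 16)),
            mean(cal(eff_study, "control", 16)))
  # effect ramps with week: reaches the configured size at week 16
  info <- eff_study$info
  expect_equal(unique(info$effect[info$diet == "pro_calcific" & info$week == 16]), 3)
  expect_equal(unique(info$effect[info$diet == "pro_calcific" & info$week == 4]), 1.5)
})

test_that("phantom sections couple retardation and orientation dispersion", {
  # thickness factor scales retardation up and directional variance down
  cfg_thin <- noiseless_config(thickness_factor = 0.6)
  cfg_thick <- noiseless_config(thickness_factor = 1.4)
  thin <- generate_phantom(cfg_thin, components = "polarization")
  thick <- generate_phantom(cfg_thick, components = "polarization")
  m <- thin$masks$masks$leaflet
  expect_lt(mean(thin$truth$retardation[m]), mean(thick$truth$retardation[m]))
  expect_gt(axial_variance(thin$truth$orientation_deg[m] * pi / 180),
            axial_variance(thick$truth$orientation_deg[m] * pi / 180))
})
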