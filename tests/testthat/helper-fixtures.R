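# shared fixtures: small deterministic phantoms and hand-built images

tiny_config <- function(..., seed = 11L) {
  phantom_config(image_size = c(64L, 64L), seed = seed, ...)
}

noiseless_config <- function(..., seed = 11L) {
  phantom_config(image_size = c(64L, 64L), seed = seed,
                 noise_model = list(gaussian_sd_frac = 0, poisson_scale = NULL),
                 ...)
}

# forward-model polarization stack built independently of the package's
# generator: one explicit loop over angles
forward_stack <- function(delta_deg, phi_deg, b = 100, angles = seq(0, 170, by = 10),
                          noise_sd = 0) {
  stopifnot(all(dim(delta_deg) == dim(phi_deg)))
  k <- length(angles)
  fr <- array(0, c(k, nrow(delta_deg), ncol(delta_deg)))
  for (i in seq_len(k))
    fr[i, , ] <- b * (1 + sin(delta_deg * pi / 180) *
                        sin(2 * (angles[i] * pi / 180 - phi_deg * pi / 180)))
  if (noise_sd > 0) fr <- fr + array(stats::rnorm(length(fr), 0, noise_sd), dim(fr))
  polarization_stack(pmax(fr, 0), angles)
}

# uniform single-colour RGB stain image
flat_rgb <- function(h, w, col) {
  a <- array(0, c(h, w, 3))
  for (ch in 1:3) a[, , ch] <- col[ch]
  a
}

whole_image_mask <- function(h, w, name = "leaflet") {
  rasterize(region_annotation(list(list(
    name = name, polygon = cbind(c(0, w, w, 0), c(0, 0, h, h))))), c(h, w))
}
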