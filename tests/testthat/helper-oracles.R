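# Independent per-pixel brute-force oracles: plain double loops, no shared
# code with the implementation beyond the polygon membership convention
# (pixel center inside the half-open bounding box).

bf_in_polygon <- function(i, j, pixel_size, polygon) {
  x <- (j - 0.5) * pixel_size
  y <- (i - 0.5) * pixel_size
  xr <- range(polygon[, 1]); yr <- range(polygon[, 2])
  x >= xr[1] && x < xr[2] && y >= yr[1] && y < yr[2]
}

bf_projected_area <- function(mask, polygon, pixel_size) {
  cnt <- 0L
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    if (mask[i, j] && bf_in_polygon(i, j, pixel_size, polygon))
      cnt <- cnt + 1L
  }
  cnt * pixel_size^2
}

bf_index_mean <- function(rgb, mask, which, a = 0.635, polygon = NULL,
                          pixel_size = NULL, eps = 1e-9) {
  tot <- 0; n <- 0L
  for (i in seq_len(dim(rgb)[1])) for (j in seq_len(dim(rgb)[2])) {
    if (!mask[i, j]) next
    if (!is.null(polygon) && !bf_in_polygon(i, j, pixel_size, polygon)) next
    R <- rgb[i, j, 1]; G <- rgb[i, j, 2]; B <- rgb[i, j, 3]
    nd <- switch(which,
      GRVI = c(G - R, G + R),
      GLI  = c(2 * G - R - B, 2 * G + R + B),
      VARI = c(G - R, G + R - B),
      GSI  = c(G - (a * R + (1 - a) * B), G + (a * R + (1 - a) * B)))
    if (abs(nd[2]) < eps) next
    tot <- tot + nd[1] / nd[2]; n <- n + 1L
  }
  if (n == 0) NA_real_ else tot / n
}

bf_height_metrics <- function(dem, polygon, mask, pixel_size,
                              ground_percentile = 0.05) {
  inp <- c()
  for (i in seq_len(nrow(dem))) for (j in seq_len(ncol(dem))) {
    if (bf_in_polygon(i, j, pixel_size, polygon)) inp <- c(inp, dem[i, j])
  }
  ground <- stats::quantile(inp, ground_percentile, names = FALSE)
  hmax <- -Inf; tot <- 0; n <- 0L
  for (i in seq_len(nrow(dem))) for (j in seq_len(ncol(dem))) {
    if (!mask[i, j] || !bf_in_polygon(i, j, pixel_size, polygon)) next
    h <- max(dem[i, j] - ground, 0)
    hmax <- max(hmax, h); tot <- tot + h; n <- n + 1L
  }
  if (n == 0) c(H_max = NA_real_, H_ave = NA_real_) else
    c(H_max = hmax, H_ave = tot / n)
}

# Hand-built uniform-color patch with a given vegetation footprint.
make_uniform_patch <- function(n = 40, pixel_size = 0.03,
                               veg_rgb = c(0.2, 0.4, 0.1),
                               soil_rgb = c(0.4, 0.32, 0.22),
                               footprint = NULL, plant_id = "P1",
                               view = "COMBINED", dem = NULL) {
  if (is.null(footprint)) footprint <- matrix(TRUE, n, n)
  rgb <- array(NA_real_, c(n, n, 3))
  for (ch in 1:3)
    rgb[, , ch] <- ifelse(footprint, veg_rgb[ch], soil_rgb[ch])
  if (is.null(dem)) dem <- matrix(100, n, n)
  half <- n * pixel_size / 2
  polygon <- cbind(x = c(half - 0.5, half + 0.5, half + 0.5, half - 0.5),
                   y = c(half - 0.5, half - 0.5, half + 0.5, half + 0.5))
  structure(list(rgb = rgb, dem = dem, polygon = polygon,
                 pixel_size_m = pixel_size, view = view,
                 metadata = list(plant_id = plant_id, genotype_id = "G01",
                                 treatment = "unfertilized", year = 2024L,
                                 dap = 60), footprint = footprint),
            class = "plant_patch")
}

# deterministic simulator configuration (no view randomness, no DEM noise)
exact_sim_config <- function(bias = c(OBLIQUE60 = 0, NADIR90 = 0,
                                      COMBINED = 0),
                             dropout = c(OBLIQUE60 = 0, NADIR90 = 0,
                                         COMBINED = 0)) {
  canopy_sim_config(view_bias = bias, view_dropout = dropout,
                    view_bias_sd = c(OBLIQUE60 = 0, NADIR90 = 0, COMBINED = 0),
                    view_dropout_sd = c(OBLIQUE60 = 0, NADIR90 = 0,
                                        COMBINED = 0),
                    dem_noise_sd = 0, rgb_noise_sd = 0.01)
}

random_plant_state <- function(seed, id = paste0("P", seed)) {
  set.seed(seed)
  plant_state(id, sprintf("G%02d", sample(12, 1)),
              treatment = sample(c("fertilized", "unfertilized"), 1),
              dap = sample(c(60, 120), 1),
              latent_biomass = runif(1, 20, 300),
              canopy_height = runif(1, 0.3, 2.2),
              canopy_radius = runif(1, 0.1, 0.5),
              architecture = list(column_blend = runif(1),
                                  cover = runif(1, 0.5, 1)))
}
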