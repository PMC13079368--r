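#' Latent state of one staked yam plant
#'
#' Holds everything the raster simulator needs to render a plant: identity
#' and trial metadata plus latent biomass and a simple canopy geometry.
#' Staked yams form columnar canopies; geometry is a cylinder-cone blend
#' controlled by `architecture$column_blend` (1 = pure cylinder, 0 = pure
#' cone) with a leaf-cover fraction `architecture$cover`.
#'
#' @param plant_id,genotype_id identifiers.
#' @param treatment `"fertilized"` or `"unfertilized"`.
#' @param year integer cropping year.
#' @param dap days after transplanting at observation.
#' @param latent_biomass shoot dry weight driving the rendering (g/plant).
#' @param canopy_height canopy top height above the ridge (m).
#' @param canopy_radius canopy footprint radius (m).
#' @param architecture list with `column_blend` and `cover`, both in `[0,1]`.
#' @return an object of class `plant_state`.
#' @export
plant_state <- function(plant_id, genotype_id,
                        treatment = c("unfertilized", "fertilized"),
                        year = 2024L, dap = 60,
                        latent_biomass = 100, canopy_height = 1.5,
                        canopy_radius = 0.35,
                        architecture = list(column_blend = 0.6, cover = 0.85)) {
  treatment <- match.arg(treatment)
  if (latent_biomass < 0) stop("latent_biomass must be >= 0")
  if (canopy_height < 0 || canopy_radius < 0)
    stop("canopy geometry must be non-negative")
  cb <- architecture$column_blend %||% 0.6
  cv <- architecture$cover %||% 0.85
  if (cb < 0 || cb > 1 || cv < 0 || cv > 1)
    stop("architecture coefficients must lie in [0,1]")
  structure(list(plant_id = plant_id, genotype_id = genotype_id,
                 treatment = treatment, year = year, dap = dap,
                 latent_biomass = latent_biomass,
                 canopy_height = canopy_height, canopy_radius = canopy_radius,
                 architecture = list(column_blend = cb, cover = cv)),
            class = "plant_state")
}

#' Configuration of the canopy raster simulator
#'
#' View-dependent terms emulate how photogrammetric surface models flatten
#' tall thin canopies: each view set carries an additive height bias
#' (negative; the combined oblique+nadir reconstruction loses the least) and
#' an occlusion dropout rate that removes vegetation pixels, preferentially
#' low-canopy ones. The ridge is a constant 0.40 m lift of the ground inside
#' the patch.
#'
#' Both terms vary from patch to patch: the realized bias is drawn as
#' `Normal(view_bias, view_bias_sd)` and the realized dropout rate as
#' `Normal(view_dropout, view_dropout_sd)` truncated to `[0, 0.9]`,
#' reflecting plant-to-plant reconstruction instability (wind, matching
#' failures). Single views get the larger spreads; the combined
#' reconstruction is the most stable.
#'
#' @param view_bias named mean additive DEM bias (m) per view set.
#' @param view_dropout named mean occlusion dropout rate per view set.
#' @param view_bias_sd,view_dropout_sd patch-to-patch SDs of the two terms.
#' @param ridge_height_m ridge height added to the ground elevation (m).
#' @param ground_elev_m base ground elevation datum (m).
#' @param dem_noise_sd DEM roughness SD (m).
#' @param veg_rgb,soil_rgb mean reflectance of vegetation / soil pixels.
#' @param rgb_noise_sd per-channel reflectance SD.
#' @return a list of class `canopy_sim_config`.
#' @export
canopy_sim_config <- function(view_bias = c(OBLIQUE60 = -0.25, NADIR90 = -0.35,
                                            COMBINED = -0.10),
                              view_dropout = c(OBLIQUE60 = 0.15, NADIR90 = 0.25,
                                               COMBINED = 0.05),
                              view_bias_sd = c(OBLIQUE60 = 0.12, NADIR90 = 0.15,
                                               COMBINED = 0.04),
                              view_dropout_sd = c(OBLIQUE60 = 0.08,
                                                  NADIR90 = 0.10,
                                                  COMBINED = 0.02),
                              ridge_height_m = 0.40, ground_elev_m = 100,
                              dem_noise_sd = 0.01,
                              veg_rgb = c(0.15, 0.38, 0.12),
                              soil_rgb = c(0.40, 0.32, 0.22),
                              rgb_noise_sd = 0.03) {
  structure(list(view_bias = view_bias, view_dropout = view_dropout,
                 view_bias_sd = view_bias_sd,
                 view_dropout_sd = view_dropout_sd,
                 ridge_height_m = ridge_height_m, ground_elev_m = ground_elev_m,
                 dem_noise_sd = dem_noise_sd, veg_rgb = veg_rgb,
                 soil_rgb = soil_rgb, rgb_noise_sd = rgb_noise_sd),
            class = "canopy_sim_config")
}

#' Render a per-plant RGB + DEM raster patch
#'
#' Draws a square patch (default 1.2 m at 0.01 m pixels) containing one
#' plant centered in a 1 x 1 m analysis polygon. Vegetation pixels take
#' green-shifted reflectances and sit on a canopy surface; background pixels
#' take soil reflectances at ridge level. The surface height at distance
#' `rho` from the stem is `h * (blend + (1-blend) * (1 - rho/r))`, the
#' cylinder-cone blend. View bias and occlusion dropout are applied per the
#' simulator configuration.
#'
#' @param state a [plant_state()].
#' @param view one of `"OBLIQUE60"`, `"NADIR90"`, `"COMBINED"`.
#' @param pixel_size_m ground sampling distance (m).
#' @param seed integer seed; identical seed and inputs give identical rasters.
#' @param patch_size_m patch side length (m); must cover the 1 x 1 m polygon.
#' @param config a [canopy_sim_config()].
#' @return an object of class `plant_patch`: list with `rgb` (H x W x 3 array
#'   of reflectances in `[0,1]`), `dem` (H x W matrix, m), `polygon` (4 x 2
#'   corner matrix, metres, x right / y down from the top-left corner),
#'   `pixel_size_m`, `view`, `metadata`, and the ground-truth vegetation
#'   `footprint` mask used by oracle tests.
#' @export
simulate_canopy_patch <- function(state, view = c("OBLIQUE60", "NADIR90", "COMBINED"),
                                  pixel_size_m = 0.01, seed = 1,
                                  patch_size_m = 1.2,
                                  config = canopy_sim_config()) {
  stopifnot(inherits(state, "plant_state"))
  view <- match.arg(view)
  if (pixel_size_m <= 0) stop("pixel_size_m must be > 0")
  if (patch_size_m < 1) stop("patch must cover the 1 x 1 m analysis polygon")
  if (state$canopy_radius > patch_size_m / 2)
    yp_log("WARN", "canopy radius %.2f m exceeds half patch width; truncated",
           state$canopy_radius)
  set.seed(seed)

  n <- round(patch_size_m / pixel_size_m)
  # pixel-center coordinates, origin at top-left, x right, y down
  xs <- (seq_len(n) - 0.5) * pixel_size_m
  cx <- patch_size_m / 2
  X <- matrix(xs, n, n, byrow = TRUE)
  Y <- matrix(xs, n, n)
  rho <- sqrt((X - cx)^2 + (Y - cx)^2)

  h <- state$canopy_height
  r <- state$canopy_radius
  blend <- state$architecture$column_blend
  cover <- state$architecture$cover
  if (state$latent_biomass <= 0) cover <- 0

  footprint <- rho <= r & r > 0
  relh <- matrix(0, n, n)
  relh[footprint] <- h * (blend + (1 - blend) * (1 - rho[footprint] / r))

  # per-patch realizations of the view terms (reconstruction instability)
  drop_rate <- min(max(stats::rnorm(1, config$view_dropout[view],
                                    config$view_dropout_sd[view] %||% 0),
                       0), 0.9)
  bias <- stats::rnorm(1, config$view_bias[view],
                       config$view_bias_sd[view] %||% 0)

  # leaf cover and occlusion dropout decide which footprint pixels are seen
  # as vegetation; dropout prefers low-canopy pixels
  u_cover <- matrix(stats::runif(n * n), n, n)
  veg <- footprint & (u_cover < cover)
  if (h > 0) {
    p_drop <- drop_rate * (0.3 + 0.7 * (1 - relh / max(h, 1e-12)))
  } else p_drop <- matrix(drop_rate * 0.3, n, n)
  u_drop <- matrix(stats::runif(n * n), n, n)
  occluded <- veg & (u_drop < p_drop)
  veg <- veg & !occluded

  ground <- config$ground_elev_m + config$ridge_height_m
  dem <- matrix(ground, n, n)
  dem[veg] <- ground + pmax(relh[veg] + bias, 0)
  if (config$dem_noise_sd > 0)
    dem <- dem + matrix(stats::rnorm(n * n, 0, config$dem_noise_sd), n, n)

  rgb <- array(0, c(n, n, 3))
  for (ch in 1:3) {
    base <- matrix(config$soil_rgb[ch], n, n)
    base[veg] <- config$veg_rgb[ch]
    rgb[, , ch] <- pmin(pmax(base + matrix(
      stats::rnorm(n * n, 0, config$rgb_noise_sd), n, n), 0), 1)
  }

  half <- 0.5
  polygon <- cbind(x = c(cx - half, cx + half, cx + half, cx - half),
                   y = c(cx - half, cx - half, cx + half, cx + half))

  structure(list(
    rgb = rgb, dem = dem, polygon = polygon, pixel_size_m = pixel_size_m,
    view = view,
    metadata = list(plant_id = state$plant_id, genotype_id = state$genotype_id,
                    treatment = state$treatment, year = state$year,
                    dap = state$dap, seed = seed),
    footprint = veg
  ), class = "plant_patch")
}

#' Write a patch to disk (float TIFF rasters + JSON sidecar)
#'
#' The RGB raster goes to `<prefix>.tif`, the DEM to `<prefix>_dem.tif`
#' (both 32-bit float TIFF in local metric coordinates) and polygon,
#' pixel size, view and metadata to `<prefix>.json`, with the polygon as a
#' GeoJSON geometry.
#'
#' @param patch a `plant_patch`.
#' @param prefix file path prefix (no extension).
#' @return `prefix`, invisibly.
#' @export
write_patch <- function(patch, prefix) {
  stopifnot(inherits(patch, "plant_patch"))
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  tiff::writeTIFF(patch$rgb, paste0(prefix, ".tif"), bits.per.sample = 32L)
  # DEM is stored relative to a written offset so it fits writeTIFF's [0,1]
  off <- floor(min(patch$dem))
  scl <- max(ceiling(max(patch$dem) - off), 1)
  tiff::writeTIFF((patch$dem - off) / scl, paste0(prefix, "_dem.tif"),
                  bits.per.sample = 32L)
  side <- list(
    pixel_size_m = patch$pixel_size_m, view = patch$view,
    dem_offset = off, dem_scale = scl, metadata = patch$metadata,
    polygon_geojson = list(type = "Polygon", coordinates = list(
      lapply(c(seq_len(nrow(patch$polygon)), 1L),
             function(i) unname(patch$polygon[i, ]))))
  )
  jsonlite::write_json(side, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' Read a patch written by [write_patch()]
#' @param prefix file path prefix used at write time.
#' @return a `plant_patch` (without the ground-truth footprint).
#' @export
read_patch <- function(prefix) {
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  rgb <- tiff::readTIFF(paste0(prefix, ".tif"))
  dem <- tiff::readTIFF(paste0(prefix, "_dem.tif")) * side$dem_scale +
    side$dem_offset
  ring <- side$polygon_geojson$coordinates
  if (is.array(ring) && length(dim(ring)) == 3) {
    ring <- matrix(ring[1, , ], dim(ring)[2], dim(ring)[3])
  } else {
    if (is.list(ring)) ring <- ring[[1]]
    if (is.list(ring)) ring <- do.call(rbind, lapply(ring, unlist))
  }
  polygon <- ring[-nrow(ring), , drop = FALSE]   # drop closing vertex
  colnames(polygon) <- c("x", "y")
  structure(list(rgb = rgb, dem = dem, polygon = polygon,
                 pixel_size_m = side$pixel_size_m, view = side$view,
                 metadata = side$metadata, footprint = NULL),
            class = "plant_patch")
}
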