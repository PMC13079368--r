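#' Genotype-specific allometric shoot biomass
#'
#' Supplies the feature-to-biomass signal the regression stage learns:
#' shoot dry weight is a monotone power function of a canopy volume proxy
#' (projected leaf area times mean canopy height) plus Gaussian noise,
#' truncated at zero.
#'
#' The volume proxy is computed analytically from the plant state: projected
#' area `pi r^2 cover` and footprint-mean surface height
#' `h (blend + (1-blend)/3)` (the disc average of the cylinder-cone blend).
#'
#' @param state a [plant_state()].
#' @param genotype_coefs named numeric `c(scale=, exponent=)`, both > 0.
#' @param noise_sd Gaussian noise SD (g), >= 0.
#' @param seed integer seed for the noise draw.
#' @return shoot dry weight in g/plant.
#' @export
allometric_biomass <- function(state, genotype_coefs = c(scale = 180, exponent = 0.9),
                               noise_sd = 0, seed = 1) {
  stopifnot(inherits(state, "plant_state"))
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  sc <- unname(genotype_coefs["scale"])
  ex <- unname(genotype_coefs["exponent"])
  if (is.na(sc) || is.na(ex) || sc <= 0 || ex <= 0)
    stop("invalid coefficients: scale and exponent must be positive")
  v <- canopy_volume_proxy(state)
  mu <- sc * v^ex
  if (noise_sd == 0) return(mu)
  set.seed(seed)
  max(mu + stats::rnorm(1, 0, noise_sd), 0)
}

#' Canopy volume proxy of a plant state
#' @param state a [plant_state()].
#' @return projected area x mean height (m^3).
#' @export
canopy_volume_proxy <- function(state) {
  a <- state$architecture
  area <- pi * state$canopy_radius^2 * a$cover
  hbar <- state$canopy_height * (a$column_blend + (1 - a$column_blend) / 3)
  area * hbar
}
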