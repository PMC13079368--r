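#' Vegetation mask from an RGB reflectance raster
#'
#' Segments vegetation by thresholding the Green Leaf Index image:
#' `GLI = (2G - R - B) / (2G + R + B)`. The default method picks the
#' threshold automatically by Otsu's criterion on the GLI histogram; a
#' fixed threshold is available for audits.
#'
#' @param rgb H x W x 3 reflectance array with values in `[0,1]`.
#' @param method `"gli_otsu"` or `"gli_fixed"`.
#' @param threshold GLI cut-off used by `"gli_fixed"` (vegetation where
#'   `GLI > threshold`).
#' @return logical H x W matrix, `TRUE` on vegetation.
#' @export
vegetation_mask <- function(rgb, method = c("gli_otsu", "gli_fixed"),
                            threshold = 0.1) {
  method <- match.arg(method)
  stopifnot(length(dim(rgb)) == 3, dim(rgb)[3] == 3)
  if (min(rgb) < -1e-9 || max(rgb) > 1 + 1e-9)
    stop("reflectance must lie in [0,1]")
  gli <- index_image(rgb, "GLI")
  if (method == "gli_fixed") return(!is.na(gli) & gli > threshold)
  vals <- gli[!is.na(gli)]
  if (length(unique(round(vals, 12))) < 2)
    stop("degenerate threshold: GLI image is constant")
  th <- EBImage::otsu(matrix(vals, nrow = 1), range = c(-1, 1))
  !is.na(gli) & gli > th
}

# Per-pixel index image; pixels whose denominator magnitude falls below
# the guard epsilon become NA and are excluded from aggregation.
index_image <- function(rgb, which, gsi_a = 0.635, eps = 1e-9) {
  R <- rgb[, , 1]; G <- rgb[, , 2]; B <- rgb[, , 3]
  num_den <- switch(which,
    GRVI = list(G - R, G + R),
    GLI  = list(2 * G - R - B, 2 * G + R + B),
    VARI = list(G - R, G + R - B),
    GSI  = {
      gray <- gsi_a * R + (1 - gsi_a) * B
      list(G - gray, G + gray)
    },
    stop("unknown index: ", which))
  out <- num_den[[1]] / num_den[[2]]
  out[abs(num_den[[2]]) < eps] <- NA_real_
  out
}

# Logical matrix flagging pixel centers inside the (axis-aligned square)
# polygon; half-open membership so shared edges are not double counted.
pixels_in_polygon <- function(dim_hw, pixel_size_m, polygon) {
  xs <- (seq_len(dim_hw[2]) - 0.5) * pixel_size_m
  ys <- (seq_len(dim_hw[1]) - 0.5) * pixel_size_m
  xr <- range(polygon[, 1]); yr <- range(polygon[, 2])
  inx <- xs >= xr[1] & xs < xr[2]
  iny <- ys >= yr[1] & ys < yr[2]
  outer(iny, inx, "&")
}

#' Projected canopy area
#'
#' `A_proj` is the ground-plane area of vegetation pixels inside the
#' analysis polygon: vegetation pixel count times the pixel area.
#'
#' @param mask logical vegetation mask.
#' @param polygon 4 x 2 corner matrix in patch coordinates (m).
#' @param pixel_size_m pixel size (m).
#' @return area in m^2.
#' @export
projected_area <- function(mask, polygon, pixel_size_m) {
  inpoly <- pixels_in_polygon(dim(mask), pixel_size_m, polygon)
  if (!all(dim(inpoly) == dim(mask))) stop("mask/polygon grids differ")
  sum(mask & inpoly) * pixel_size_m^2
}

#' Mean vegetation index over the masked canopy
#'
#' Computes one of the four RGB vegetation indices per pixel and averages
#' over vegetation pixels (inside the polygon when one is supplied):
#' `GRVI = (G-R)/(G+R)`, `GLI = (2G-R-B)/(2G+R+B)`,
#' `VARI = (G-R)/(G+R-B)`, and the grayscale-contrast index
#' `GSI = (G - gray)/(G + gray)` with `gray = a R + (1-a) B`.
#'
#' @param rgb H x W x 3 reflectance array.
#' @param mask logical vegetation mask.
#' @param which `"GRVI"`, `"GLI"`, `"VARI"` or `"GSI"`.
#' @param gsi_a GSI weighting coefficient `a` in `[0,1]`.
#' @param polygon optional polygon restricting the aggregation.
#' @param pixel_size_m pixel size, required with `polygon`.
#' @return scalar index value; `NA` (with a logged warning) on empty mask.
#' @export
vegetation_index <- function(rgb, mask, which = c("GRVI", "GLI", "VARI", "GSI"),
                             gsi_a = 0.635, polygon = NULL,
                             pixel_size_m = NULL) {
  which <- match.arg(which)
  if (which == "GSI" && (gsi_a < 0 || gsi_a > 1))
    stop("gsi_a must lie in [0,1]")
  sel <- mask
  if (!is.null(polygon)) {
    if (is.null(pixel_size_m)) stop("pixel_size_m needed with polygon")
    sel <- sel & pixels_in_polygon(dim(mask), pixel_size_m, polygon)
  }
  if (!any(sel)) {
    yp_log("WARN", "empty vegetation mask: %s undefined", which)
    return(NA_real_)
  }
  img <- index_image(rgb, which, gsi_a = gsi_a)
  mean(img[sel], na.rm = TRUE)
}

#' Optimize the GSI weighting coefficient
#'
#' Scans a grid of candidate weights `a` and returns the one maximizing the
#' Pearson correlation between per-patch `GSI(a)` and projected canopy
#' area across a patch collection. Ties break toward the smaller `a`.
#'
#' @param patches list of `plant_patch` objects (>= 3).
#' @param a_grid sorted candidate weights in `[0,1]`; the default grid has
#'   step 0.005 so the reference optimum 0.635 is representable exactly.
#' @param mask_method,threshold passed to [vegetation_mask()].
#' @return list with `a` (the argmax), `correlations` (full grid scan) and
#'   `a_grid`.
#' @export
gsi_weight_optimize <- function(patches, a_grid = seq(0, 1, by = 0.005),
                                mask_method = "gli_otsu", threshold = 0.1) {
  if (length(patches) < 3) stop("need at least 3 patches")
  if (any(a_grid < 0 | a_grid > 1) || is.unsorted(a_grid))
    stop("a_grid must be sorted within [0,1]")
  masks <- lapply(patches, function(p)
    vegetation_mask(p$rgb, method = mask_method, threshold = threshold))
  aproj <- mapply(function(p, m)
    projected_area(m, p$polygon, p$pixel_size_m), patches, masks)
  if (stats::sd(aproj) < 1e-12)
    stop("undefined correlation: projected area is constant across patches")
  cors <- vapply(a_grid, function(a) {
    gsi <- mapply(function(p, m)
      vegetation_index(p$rgb, m, "GSI", gsi_a = a,
                       polygon = p$polygon, pixel_size_m = p$pixel_size_m),
      patches, masks)
    if (stats::sd(gsi, na.rm = TRUE) < 1e-12) return(-Inf)
    stats::cor(gsi, aproj, use = "complete.obs")
  }, numeric(1))
  best <- which.max(cors)          # which.max takes the first (smallest a) tie
  list(a = a_grid[best], correlations = cors, a_grid = a_grid)
}

#' Canopy height metrics from a DEM
#'
#' The local ground reference is a low percentile (default 5th) of the
#' in-polygon DEM; per-pixel heights are DEM minus ground, clipped at zero.
#' `H_max` and `H_ave` are the maximum and mean over vegetation pixels
#' inside the polygon.
#'
#' @param dem elevation matrix (m).
#' @param polygon 4 x 2 corner matrix (m).
#' @param mask logical vegetation mask.
#' @param pixel_size_m pixel size (m).
#' @param ground_percentile quantile defining local ground elevation.
#' @return named numeric `c(H_max=, H_ave=)`; `NA`s on empty mask.
#' @export
height_metrics <- function(dem, polygon, mask, pixel_size_m,
                           ground_percentile = 0.05) {
  inpoly <- pixels_in_polygon(dim(dem), pixel_size_m, polygon)
  if (!all(is.finite(dem[inpoly]))) stop("DEM must be finite inside polygon")
  sel <- mask & inpoly
  if (!any(sel)) {
    yp_log("WARN", "empty vegetation mask: heights undefined")
    return(c(H_max = NA_real_, H_ave = NA_real_))
  }
  ground <- stats::quantile(dem[inpoly], ground_percentile, names = FALSE)
  heights <- pmax(dem - ground, 0)
  c(H_max = max(heights[sel]), H_ave = mean(heights[sel]))
}

#' Extract the seven explanatory variables from one patch
#'
#' @param patch a `plant_patch`.
#' @param gsi_a GSI weighting coefficient.
#' @param mask_method,threshold passed to [vegetation_mask()].
#' @param ground_percentile passed to [height_metrics()].
#' @return one-row data frame: metadata columns, `view`, then `A_proj`,
#'   `GRVI`, `GLI`, `VARI`, `GSI`, `H_max`, `H_ave`.
#' @export
extract_features <- function(patch, gsi_a = 0.635, mask_method = "gli_otsu",
                             threshold = 0.1, ground_percentile = 0.05) {
  stopifnot(inherits(patch, "plant_patch"))
  mask <- vegetation_mask(patch$rgb, method = mask_method,
                          threshold = threshold)
  hm <- height_metrics(patch$dem, patch$polygon, mask, patch$pixel_size_m,
                       ground_percentile = ground_percentile)
  md <- patch$metadata
  data.frame(
    plant_id = md$plant_id %||% NA_character_,
    genotype_id = md$genotype_id %||% NA_character_,
    treatment = md$treatment %||% NA_character_,
    year = md$year %||% NA_integer_, dap = md$dap %||% NA_real_,
    view = patch$view,
    A_proj = projected_area(mask, patch$polygon, patch$pixel_size_m),
    GRVI = vegetation_index(patch$rgb, mask, "GRVI",
                            polygon = patch$polygon,
                            pixel_size_m = patch$pixel_size_m),
    GLI = vegetation_index(patch$rgb, mask, "GLI", polygon = patch$polygon,
                           pixel_size_m = patch$pixel_size_m),
    VARI = vegetation_index(patch$rgb, mask, "VARI", polygon = patch$polygon,
                            pixel_size_m = patch$pixel_size_m),
    GSI = vegetation_index(patch$rgb, mask, "GSI", gsi_a = gsi_a,
                           polygon = patch$polygon,
                           pixel_size_m = patch$pixel_size_m),
    H_max = unname(hm["H_max"]), H_ave = unname(hm["H_ave"]),
    stringsAsFactors = FALSE)
}

#' Build the per-plant, per-view feature table
#'
#' One row per plant per requested view set. A combined-view row always
#' comes from the COMBINED patch itself, never from averaging single-view
#' features. Plants missing a requested view produce a flagged row of
#' `NA` features; duplicated (plant, view) patches are an error.
#'
#' @param patches list of `plant_patch` objects.
#' @param views view sets to report.
#' @param gsi GSI settings: list with `a`, `optimize` and optionally `grid`.
#'   With `optimize = TRUE` the weight is tuned on this collection via
#'   [gsi_weight_optimize()] first.
#' @param ... passed to [extract_features()].
#' @return data frame with a logical `missing` column; the GSI weight used
#'   is attached as attribute `"gsi_a"`.
#' @export
build_feature_table <- function(patches,
                                views = c("OBLIQUE60", "NADIR90", "COMBINED"),
                                gsi = list(a = 0.635, optimize = FALSE), ...) {
  keys <- vapply(patches, function(p)
    paste(p$metadata$plant_id, p$view, sep = "|"), character(1))
  if (anyDuplicated(keys))
    stop("duplicate (plant, view) patch: ", keys[duplicated(keys)][1])
  a <- gsi$a %||% 0.635
  if (isTRUE(gsi$optimize)) {
    opt <- gsi_weight_optimize(patches,
                               a_grid = gsi$grid %||% seq(0, 1, by = 0.005))
    a <- opt$a
  }
  plant_ids <- unique(vapply(patches, function(p)
    as.character(p$metadata$plant_id), character(1)))
  rows <- list(); i <- 1L; n_missing <- 0L
  for (pid in plant_ids) {
    for (v in views) {
      hit <- which(keys == paste(pid, v, sep = "|"))
      if (length(hit) == 1L) {
        row <- extract_features(patches[[hit]], gsi_a = a, ...)
        row$missing <- FALSE
      } else {
        md <- patches[[which(vapply(patches, function(p)
          p$metadata$plant_id == pid, logical(1)))[1]]]$metadata
        row <- data.frame(plant_id = pid, genotype_id = md$genotype_id,
                          treatment = md$treatment, year = md$year,
                          dap = md$dap, view = v, A_proj = NA_real_,
                          GRVI = NA_real_, GLI = NA_real_, VARI = NA_real_,
                          GSI = NA_real_, H_max = NA_real_, H_ave = NA_real_,
                          missing = TRUE, stringsAsFactors = FALSE)
        n_missing <- n_missing + 1L
      }
      rows[[i]] <- row; i <- i + 1L
    }
  }
  if (n_missing > 0)
    yp_log("WARN", "%d plant x view combinations missing patches", n_missing)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "gsi_a") <- a
  out
}
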