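test_that("index values on uniform patches match hand arithmetic", {
  # R = G = B: all difference indices vanish by symmetry
  p_eq <- make_uniform_patch(veg_rgb = c(0.3, 0.3, 0.3))
  mask <- matrix(TRUE, 40, 40)
  for (w in c("GRVI", "GLI", "VARI"))
    expect_equal(vegetation_index(p_eq$rgb, mask, w), 0)

  # R = 0.2, G = 0.4, B = 0.1, evaluated by hand
  p <- make_uniform_patch(veg_rgb = c(0.2, 0.4, 0.1))
  expect_equal(vegetation_index(p$rgb, mask, "GRVI"), 0.2 / 0.6)
  expect_equal(vegetation_index(p$rgb, mask, "GLI"), 0.5 / 1.1)
  expect_equal(vegetation_index(p$rgb, mask, "VARI"), 0.2 / 0.5)
  gray <- 0.635 * 0.2 + (1 - 0.635) * 0.1
  expect_equal(vegetation_index(p$rgb, mask, "GSI", gsi_a = 0.635),
               (0.4 - gray) / (0.4 + gray))
})

test_that("vegetation masking recovers the painted footprint", {
  set.seed(10)
  fp <- matrix(FALSE, 40, 40)
  fp[10:30, 8:25] <- TRUE
  p <- make_uniform_patch(footprint = fp)
  # noiseless: Otsu separates the two populations perfectly
  m <- vegetation_mask(p$rgb)
  expect_true(all(m == fp))
  # with reflectance noise, >= 99% pixel agreement
  rgbn <- pmin(pmax(p$rgb + array(rnorm(length(p$rgb), 0, 0.02),
                                  dim(p$rgb)), 0), 1)
  m2 <- vegetation_mask(rgbn)
  expect_gte(mean(m2 == fp), 0.99)
  # fixed threshold: pure soil is all background
  soil <- make_uniform_patch(footprint = matrix(FALSE, 40, 40))
  expect_true(all(!vegetation_mask(soil$rgb, "gli_fixed", threshold = 0.1)))
  # constant image defeats the auto threshold
  expect_error(vegetation_mask(soil$rgb), "degenerate")
})

test_that("projected area equals the per-pixel count times pixel area", {
  poly <- make_uniform_patch()$polygon
  all1 <- matrix(TRUE, 100, 100)
  # 1 m^2 polygon at 0.01 m pixels -> exactly 1 m^2
  poly01 <- cbind(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))
  expect_equal(projected_area(all1, poly01, 0.01), 1.0)
  expect_equal(projected_area(!all1, poly01, 0.01), 0.0)
  set.seed(2)
  rnd <- matrix(runif(1600) < 0.4, 40, 40)
  expect_equal(projected_area(rnd, poly, 0.03),
               bf_projected_area(rnd, poly, 0.03))
})

test_that("height metrics match construction and brute force", {
  n <- 60; px <- 0.02
  poly <- cbind(x = c(0.1, 1.1, 1.1, 0.1), y = c(0.1, 0.1, 1.1, 1.1))
  flat <- matrix(50, n, n)
  hm <- height_metrics(flat, poly, matrix(TRUE, n, n), px)
  expect_equal(unname(hm), c(0, 0))

  # 2 m cylinder: ground at the 5th percentile of soil pixels
  st <- plant_state("P", "G01", canopy_height = 2, canopy_radius = 0.4,
                    architecture = list(column_blend = 1, cover = 1))
  p <- simulate_canopy_patch(st, "NADIR90", seed = 1,
                             config = exact_sim_config())
  mask <- p$footprint
  hm2 <- height_metrics(p$dem, p$polygon, mask, p$pixel_size_m)
  expect_equal(unname(hm2[1]), 2, tolerance = 1e-9)
  expect_equal(unname(hm2[2]), 2, tolerance = 1e-9)

  # 3 m cone: max matches construction, mean matches the pixel loop
  st3 <- plant_state("P", "G01", canopy_height = 3, canopy_radius = 0.45,
                     architecture = list(column_blend = 0, cover = 1))
  p3 <- simulate_canopy_patch(st3, "NADIR90", seed = 2,
                              config = exact_sim_config())
  hm3 <- height_metrics(p3$dem, p3$polygon, p3$footprint, p3$pixel_size_m)
  bf3 <- bf_height_metrics(p3$dem, p3$polygon, p3$footprint, p3$pixel_size_m)
  expect_equal(unname(hm3[1]), 3, tolerance = 0.05) # pixel discretization
  expect_equal(unname(hm3), unname(bf3), tolerance = 1e-12)
})

test_that("all extracted features agree with per-pixel brute force", {
  for (seed in 1:10) {
    st <- random_plant_state(seed)
    p <- simulate_canopy_patch(st, "OBLIQUE60", seed = seed,
                               pixel_size_m = 0.03)
    mask <- vegetation_mask(p$rgb)
    expect_equal(projected_area(mask, p$polygon, p$pixel_size_m),
                 bf_projected_area(mask, p$polygon, p$pixel_size_m),
                 tolerance = 1e-9)
    for (w in c("GRVI", "GLI", "VARI", "GSI")) {
      expect_equal(
        vegetation_index(p$rgb, mask, w, polygon = p$polygon,
                         pixel_size_m = p$pixel_size_m),
        bf_index_mean(p$rgb, mask, w, polygon = p$polygon,
                      pixel_size = p$pixel_size_m),
        tolerance = 1e-9)
    }
    expect_equal(
      unname(height_metrics(p$dem, p$polygon, mask, p$pixel_size_m)),
      unname(bf_height_metrics(p$dem, p$polygon, mask, p$pixel_size_m)),
      tolerance = 1e-9)
  }
})

test_that("enlarging the canopy footprint never decreases projected area", {
  st <- function(r) plant_state("P", "G01", canopy_height = 1.5,
                                canopy_radius = r,
                                architecture = list(column_blend = 0.7,
                                                    cover = 1))
  areas <- vapply(c(0.1, 0.2, 0.3, 0.4, 0.5), function(r) {
    p <- simulate_canopy_patch(st(r), "COMBINED", seed = 5,
                               config = exact_sim_config())
    extract_features(p)$A_proj
  }, numeric(1))
  expect_true(all(diff(areas) >= 0))
})

test_that("the GSI weight optimizer recovers a planted optimum", {
  # construction: G fixed; R + B constant per patch so that GSI(0.5) is an
  # exact monotone function of A_proj; R - B random, degrading other a
  set.seed(31)
  n <- 20
  sides <- 4 + seq_len(n)    # growing footprint -> growing A_proj
  areas <- (sides * 0.03)^2
  # target GSI(0.5) exactly linear in A_proj, so cor(GSI(0.5), A_proj) = 1
  L <- 0.30 + 0.40 * (areas - min(areas)) / (max(areas) - min(areas))
  patches <- list()
  for (i in seq_len(n)) {
    fp <- matrix(FALSE, 40, 40)
    fp[10:(9 + sides[i]), 10:(9 + sides[i])] <- TRUE
    ssum <- 2 * 0.45 * (1 - L[i]) / (1 + L[i])  # R + B giving GSI(0.5)=L_i
    sdiff <- runif(1, -0.8, 0.8) * ssum         # R - B, random
    R <- (ssum + sdiff) / 2; B <- (ssum - sdiff) / 2
    patches[[i]] <- make_uniform_patch(veg_rgb = c(R, 0.45, B),
                                       footprint = fp,
                                       plant_id = paste0("P", i))
  }
  opt <- gsi_weight_optimize(patches, mask_method = "gli_fixed",
                             threshold = 0.05)
  # independent full-grid brute-force scan
  grid <- seq(0, 1, by = 0.005)
  aproj <- vapply(patches, function(p) {
    m <- vegetation_mask(p$rgb, "gli_fixed", threshold = 0.05)
    bf_projected_area(m, p$polygon, p$pixel_size_m)
  }, numeric(1))
  cors <- vapply(grid, function(a) {
    gsi <- vapply(patches, function(p) {
      m <- vegetation_mask(p$rgb, "gli_fixed", threshold = 0.05)
      bf_index_mean(p$rgb, m, "GSI", a = a, polygon = p$polygon,
                    pixel_size = p$pixel_size_m)
    }, numeric(1))
    cor(gsi, aproj)
  }, numeric(1))
  expect_equal(opt$a, grid[which.max(cors)])
  expect_lte(abs(opt$a - 0.5), 0.005 + 1e-12)  # within one grid step
  # the argmax dominates the full scan by construction
  expect_true(all(opt$correlations[which.max(opt$correlations)] >=
                    opt$correlations))

  # duplicated identical patches: zero variance in A_proj
  expect_error(gsi_weight_optimize(list(patches[[1]], patches[[1]],
                                        patches[[1]]),
                                   mask_method = "gli_fixed",
                                   threshold = 0.05),
               "undefined correlation")
})

test_that("feature table has one row per plant x view and is consistent", {
  states <- lapply(1:4, function(s) random_plant_state(s))
  patches <- list(); i <- 1
  for (st in states) for (v in c("OBLIQUE60", "NADIR90", "COMBINED")) {
    patches[[i]] <- simulate_canopy_patch(st, v,
                                          seed = derive_seed(7, paste0(st$plant_id, v)),
                                          pixel_size_m = 0.03)
    i <- i + 1
  }
  ft <- build_feature_table(patches)
  expect_equal(nrow(ft), 12)
  expect_true(all(c("A_proj", "GRVI", "GLI", "VARI", "GSI", "H_max",
                    "H_ave") %in% names(ft)))
  # rows equal single-patch operations run independently
  one <- extract_features(patches[[1]])
  row <- ft[ft$plant_id == one$plant_id & ft$view == one$view, ]
  expect_equal(row$A_proj, one$A_proj)
  expect_equal(row$GSI, one$GSI)
  expect_equal(row$H_ave, one$H_ave)
  # H_max >= H_ave >= 0 everywhere
  ok <- !is.na(ft$H_max)
  expect_true(all(ft$H_max[ok] >= ft$H_ave[ok] & ft$H_ave[ok] >= 0))

  # missing view -> flagged row; duplicates -> error
  ft2 <- suppressMessages(build_feature_table(patches[-3]))
  expect_equal(nrow(ft2), 12)
  expect_equal(sum(ft2$missing), 1)
  expect_error(build_feature_table(c(patches, patches[1])), "duplicate")
})

test_that("feature extraction is pure", {
  p <- simulate_canopy_patch(random_plant_state(20), "COMBINED", seed = 8)
  a <- extract_features(p)
  b <- extract_features(p)
  expect_identical(a, b)
})
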