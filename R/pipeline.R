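#' Default pipeline configuration
#'
#' A desk-scale end-to-end run: a reduced field trial for the regression
#' stage (the full reference design is obtained by raising the counts to
#' 12 genotypes / 3 replicates / 4 plants sampled / 2 years), the full
#' 12-genotype monitoring series for the growth stage, and the
#' reduced-iteration MCMC profile.
#'
#' @return nested configuration list.
#' @export
default_config <- function() {
  list(
    seed = 1,
    output_dir = "results/run",
    stages = c("simulate", "extract", "train", "fit_growth", "summarize"),
    simulate = list(
      field = list(n_genotypes = 6, n_treatments = 2, n_replicates = 2,
                   plot_size_m = 3, plant_spacing_m = 1,
                   n_sampling_times = 2, plants_sampled_per_plot = 2,
                   n_years = 1),
      pixel_size_m = 0.02,
      views = c("OBLIQUE60", "NADIR90", "COMBINED"),
      biomass_noise_sd = 8,
      series = list(n_genotypes = 12, n_plants = 8, n_replicates = 3,
                    time_points = seq(14, 224, by = 21)),
      sigma_obs = 22),
    extract = list(gsi_a = 0.635, optimize_gsi = FALSE,
                   mask_method = "gli_otsu", ground_percentile = 0.05),
    train = list(algorithms = "SVR",
                 views = c("OBLIQUE60", "NADIR90", "COMBINED"),
                 train_fraction = 0.8, cv_folds = 5,
                 svr_C_grid = c(1, 5, 10, 50, 100),
                 svr_gamma_grid = c(0.01, 0.05, 0.1, 0.5, 1),
                 shap = TRUE, shap_nsim = 32, shap_background = 100),
    fit_growth = list(decay_mode = "gated", n_chains = 4,
                      n_iterations = 1000, n_warmup = 500)
  )
}

check_enum <- function(errors, value, allowed, what) {
  bad <- setdiff(value, allowed)
  if (length(bad))
    errors <- c(errors, sprintf("%s: unknown value(s) %s", what,
                                paste(bad, collapse = ", ")))
  errors
}

#' Validate and normalize a run configuration
#'
#' Accepts a YAML file path or a nested list; fills defaults, rejects
#' unknown keys and out-of-range values with an itemized error message,
#' and returns the normalized configuration. An empty file yields the
#' full default configuration.
#'
#' @param config YAML path or list.
#' @return normalized configuration list of class `run_config`.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  stopifnot(is.list(config))
  defaults <- default_config()
  errors <- character(0)
  merge_block <- function(user, def, path) {
    unknown <- setdiff(names(user), names(def))
    if (length(unknown))
      errors <<- c(errors, sprintf("unknown key(s) under %s: %s", path,
                                   paste(unknown, collapse = ", ")))
    for (nm in intersect(names(user), names(def))) {
      if (is.list(def[[nm]]) && !is.null(names(def[[nm]]))) {
        def[[nm]] <- merge_block(user[[nm]], def[[nm]],
                                 paste(path, nm, sep = "/"))
      } else def[[nm]] <- user[[nm]]
    }
    def
  }
  cfg <- merge_block(config, defaults, "config")

  errors <- check_enum(errors, cfg$stages,
                       c("simulate", "extract", "train", "fit_growth",
                         "summarize"), "stages")
  errors <- check_enum(errors, cfg$simulate$views,
                       c("OBLIQUE60", "NADIR90", "COMBINED"),
                       "simulate/views")
  errors <- check_enum(errors, cfg$train$views,
                       c("OBLIQUE60", "NADIR90", "COMBINED"), "train/views")
  errors <- check_enum(errors, cfg$train$algorithms,
                       c("SVR", "RF", "XGB", "STEPWISE"), "train/algorithms")
  errors <- check_enum(errors, cfg$fit_growth$decay_mode,
                       c("gated", "as_printed"), "fit_growth/decay_mode")
  tf <- cfg$train$train_fraction
  if (!is.numeric(tf) || tf <= 0 || tf >= 1)
    errors <- c(errors, "train/train_fraction: must lie in (0,1)")
  if (cfg$train$cv_folds < 2)
    errors <- c(errors, "train/cv_folds: must be >= 2")
  if (any(cfg$train$svr_C_grid <= 0) || any(cfg$train$svr_gamma_grid <= 0))
    errors <- c(errors, "train: SVR grids must be positive")
  if (cfg$simulate$pixel_size_m <= 0)
    errors <- c(errors, "simulate/pixel_size_m: must be > 0")
  if (cfg$fit_growth$n_warmup >= cfg$fit_growth$n_iterations)
    errors <- c(errors, "fit_growth: n_warmup must be < n_iterations")
  if (length(errors))
    stop("invalid configuration:\n  - ", paste(errors, collapse = "\n  - "))
  class(cfg) <- c("run_config", "list")
  cfg
}

#' Assign latent plant states and reference biomass to sampled plants
#'
#' Deterministic genotype/treatment/stage effects plus seeded plant-level
#' variation give each destructively sampled plant a canopy geometry;
#' reference shoot dry weight comes from the genotype allometry with
#' Gaussian noise.
#'
#' @param sampling sampling table from [simulate_field_design()].
#' @param seed integer seed.
#' @param biomass_noise_sd allometric noise SD (g).
#' @return list with `states` (list of [plant_state()]) and `biomass`
#'   (data frame `plant_id`, `biomass`).
#' @export
simulate_phenotypes <- function(sampling, seed = 1, biomass_noise_sd = 8) {
  set.seed(seed)
  genos <- sort(unique(sampling$genotype_id))
  gi <- match(sampling$genotype_id, genos)
  gfrac <- ((seq_along(genos) * 37) %% 23) / 22     # fixed genotype spread
  states <- vector("list", nrow(sampling))
  biomass <- numeric(nrow(sampling))
  for (i in seq_len(nrow(sampling))) {
    gf <- gfrac[gi[i]]
    stage_f <- if (!is.null(sampling$stage)) 0.55 + 0.45 *
      (sampling$stage[i] / max(sampling$stage)) else 1
    fert_f <- if (sampling$treatment[i] == "fertilized") 1.2 else 1
    h <- max((0.9 + 1.1 * gf) * stage_f * fert_f + stats::rnorm(1, 0, 0.15),
             0.05)
    r <- min(max(0.18 + 0.22 * gf * stage_f + stats::rnorm(1, 0, 0.04),
                 0.05), 0.55)
    cover <- min(max(0.7 + 0.2 * gf + stats::rnorm(1, 0, 0.05), 0.3), 1)
    blend <- min(max(0.45 + 0.4 * gf, 0), 1)
    st <- plant_state(
      plant_id = sampling$plant_id[i], genotype_id = sampling$genotype_id[i],
      treatment = sampling$treatment[i], year = sampling$year[i],
      dap = sampling$dap[i] %||% 60, latent_biomass = 1,
      canopy_height = h, canopy_radius = r,
      architecture = list(column_blend = blend, cover = cover))
    coefs <- c(scale = 150 + 120 * gf, exponent = 0.9)
    w <- allometric_biomass(st, coefs, noise_sd = biomass_noise_sd,
                            seed = derive_seed(seed, sampling$plant_id[i]))
    st$latent_biomass <- w
    states[[i]] <- st
    biomass[i] <- w
  }
  list(states = states,
       biomass = data.frame(plant_id = sampling$plant_id, biomass = biomass,
                            stringsAsFactors = FALSE))
}

#' Render patches and extract the feature table for a set of plants
#'
#' Convenience wrapper used by the pipeline and the regression
#' benchmarks: renders every plant under every view (independent seeds per
#' plant x view, so single views carry independent occlusion noise) and
#' extracts the seven features.
#'
#' @param states list of [plant_state()].
#' @param views view sets to render.
#' @param pixel_size_m ground sampling distance.
#' @param seed integer seed.
#' @param config a [canopy_sim_config()].
#' @param gsi_a GSI weighting coefficient.
#' @return feature table as from [build_feature_table()].
#' @export
render_and_extract <- function(states,
                               views = c("OBLIQUE60", "NADIR90", "COMBINED"),
                               pixel_size_m = 0.02, seed = 1,
                               config = canopy_sim_config(), gsi_a = 0.635) {
  patches <- list(); i <- 1L
  for (st in states) {
    for (v in views) {
      patches[[i]] <- simulate_canopy_patch(
        st, view = v, pixel_size_m = pixel_size_m,
        seed = derive_seed(seed, paste0(st$plant_id, "_", v)),
        config = config)
      i <- i + 1L
    }
  }
  build_feature_table(patches, views = views, gsi = list(a = gsi_a))
}

write_csv_ <- function(df, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full pipeline
#'
#' Executes the selected stages in dependency order
#' (simulate -> extract -> train -> fit_growth -> summarize), each seeded
#' by a stage seed derived from the global seed, and writes a JSON
#' manifest (config hash, per-stage outputs with MD5 digests, versions,
#' seeds, timestamps) last. Stages whose outputs already exist under the
#' output directory are skipped, making a run resumable; on failure the
#' manifest is not written and partial outputs are retained.
#'
#' @param config a `run_config` (or anything [validate_config()] accepts).
#' @param force character vector of stage names to re-run even if their
#'   outputs exist.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config = default_config(), force = character(0)) {
  cfg <- if (inherits(config, "run_config")) config else
    validate_config(config)
  out <- cfg$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  cfg_json <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  cfg_path <- file.path(out, "config.json")
  writeLines(cfg_json, cfg_path)
  cfg_hash <- unname(tools::md5sum(cfg_path))

  manifest <- list(config_hash = cfg_hash,
                   versions = list(r = R.version.string,
                                   yamphen = as.character(
                                     utils::packageVersion("yamphen"))),
                   global_seed = cfg$seed, stages = list())
  paths <- list(
    plants = file.path(out, "plants.csv"),
    sampling = file.path(out, "sampling.csv"),
    biomass = file.path(out, "biomass.csv"),
    series = file.path(out, "series.csv"),
    features = file.path(out, "features.csv"),
    evaluation = file.path(out, "evaluation.json"),
    shap = file.path(out, "shap.csv"),
    draws = file.path(out, "growth_draws.csv"),
    growth_summary = file.path(out, "growth_summary.csv"),
    convergence = file.path(out, "growth_convergence.csv"),
    summary = file.path(out, "run_summary.json"))

  run_stage <- function(stage, outputs, fun) {
    if (!(stage %in% cfg$stages)) return(invisible(NULL))
    t0 <- Sys.time()
    if (all(file.exists(unlist(outputs))) && !(stage %in% force)) {
      yp_log("INFO", "stage %s: outputs present, skipping", stage)
    } else {
      ok <- tryCatch({ fun(); TRUE }, error = function(e) e)
      if (inherits(ok, "error"))
        stop("stage '", stage, "' failed: ", conditionMessage(ok),
             " (partial outputs retained under ", out, ")")
    }
    manifest$stages[[stage]] <<- list(
      seed = derive_seed(cfg$seed, stage),
      outputs = as.list(tools::md5sum(unlist(outputs))),
      started = format(t0), finished = format(Sys.time()))
  }

  run_stage("simulate", paths[c("plants", "sampling", "biomass", "series")],
            function() {
    sd_ <- derive_seed(cfg$seed, "simulate")
    fd <- do.call(field_design, cfg$simulate$field)
    tabs <- simulate_field_design(fd, seed = sd_)
    ph <- simulate_phenotypes(tabs$sampling, seed = derive_seed(sd_, "pheno"),
                              biomass_noise_sd = cfg$simulate$biomass_noise_sd)
    ser <- simulate_growth_series(
      theta = default_growth_params(cfg$simulate$series$n_genotypes),
      design = do.call(series_design, cfg$simulate$series),
      sigma_obs = cfg$simulate$sigma_obs,
      decay_mode = cfg$fit_growth$decay_mode,
      seed = derive_seed(sd_, "series"))
    write_csv_(tabs$plants, paths$plants)
    write_csv_(tabs$sampling, paths$sampling)
    write_csv_(ph$biomass, paths$biomass)
    write_csv_(ser, paths$series)
    saveRDS(ph$states, file.path(out, "states.rds"))
  })

  run_stage("extract", paths["features"], function() {
    states_path <- file.path(out, "states.rds")
    if (!file.exists(states_path))
      stop("missing input from the simulate stage: ", states_path)
    states <- readRDS(states_path)
    ft <- render_and_extract(states, views = cfg$simulate$views,
                             pixel_size_m = cfg$simulate$pixel_size_m,
                             seed = derive_seed(cfg$seed, "extract"),
                             gsi_a = cfg$extract$gsi_a)
    write_csv_(ft, paths$features)
  })

  run_stage("train", paths[c("evaluation", "shap")], function() {
    sd_ <- derive_seed(cfg$seed, "train")
    ft <- utils::read.csv(paths$features, stringsAsFactors = FALSE)
    bm <- utils::read.csv(paths$biomass, stringsAsFactors = FALSE)
    ft <- merge(ft, bm, by = "plant_id")
    ft <- ft[!ft$missing & stats::complete.cases(ft[, FEATURE_COLS]), ]
    evals <- list(); shaps <- list()
    for (alg in cfg$train$algorithms) {
      for (v in cfg$train$views) {
        dat <- ft[ft$view == v, ]
        spec <- regression_spec(
          algorithm = alg, svr_C_grid = cfg$train$svr_C_grid,
          svr_gamma_grid = cfg$train$svr_gamma_grid,
          cv_folds = cfg$train$cv_folds,
          train_fraction = cfg$train$train_fraction, seed = sd_)
        sp <- split_data(dat, cfg$train$train_fraction, seed = sd_)
        std <- standardize(sp$train, sp$test)
        fit <- tune_and_train(spec, std$train, response = "biomass",
                              feature_cols = std$feature_cols)
        preds <- predict(fit, std$test)
        ev <- evaluate(fit, std$test, predictions = preds)
        sub <- subgroup_report(preds, std$test,
                               keys = intersect(c("year", "dap", "treatment",
                                                  "genotype_id"),
                                                names(std$test)))
        evals[[paste(alg, v, sep = "_")]] <-
          list(algorithm = alg, view = v, overall = ev, subgroups = sub,
               best = as.list(fit$best))
        if (isTRUE(cfg$train$shap)) {
          nbg <- min(cfg$train$shap_background, nrow(std$train))
          set.seed(derive_seed(sd_, "shapbg"))
          bg <- std$train[sample(nrow(std$train), nbg), ]
          stab <- shap_attributions(fit, bg, std$test, seed = sd_,
                                    nsim = cfg$train$shap_nsim)
          df <- as.data.frame(stab)
          df$baseline <- attr(stab, "baseline")
          df$prediction <- attr(stab, "predictions")
          df$algorithm <- alg; df$view <- v
          shaps[[paste(alg, v, sep = "_")]] <- df
        }
      }
    }
    jsonlite::write_json(evals, paths$evaluation, auto_unbox = TRUE,
                         digits = NA, force = TRUE)
    write_csv_(if (length(shaps)) do.call(rbind, shaps) else
      data.frame(), paths$shap)
  })

  run_stage("fit_growth", paths[c("draws", "growth_summary", "convergence")],
            function() {
    ser <- utils::read.csv(paths$series, stringsAsFactors = FALSE)
    mc <- mcmc_config(n_chains = cfg$fit_growth$n_chains,
                      n_iterations = cfg$fit_growth$n_iterations,
                      n_warmup = cfg$fit_growth$n_warmup,
                      seed = derive_seed(cfg$seed, "fit_growth"))
    draws <- fit_hierarchical(ser, mcmc = mc,
                              decay_mode = cfg$fit_growth$decay_mode)
    arr <- draws$draws
    long <- data.frame(
      chain = rep(seq_len(dim(arr)[1]), times = dim(arr)[2] * dim(arr)[3]),
      draw = rep(rep(seq_len(dim(arr)[2]), each = dim(arr)[1]),
                 times = dim(arr)[3]),
      parameter = rep(dimnames(arr)[[3]],
                      each = dim(arr)[1] * dim(arr)[2]),
      value = as.vector(arr), stringsAsFactors = FALSE)
    write_csv_(long, paths$draws)
    sm <- posterior_summaries(draws)
    write_csv_(sm$params, paths$growth_summary)
    cv <- convergence(draws)
    write_csv_(as.data.frame(cv), paths$convergence)
  })

  run_stage("summarize", paths["summary"], function() {
    res <- list()
    if (file.exists(paths$evaluation))
      res$evaluation <- jsonlite::read_json(paths$evaluation)
    if (file.exists(paths$convergence)) {
      cv <- utils::read.csv(paths$convergence)
      res$max_rhat <- max(cv$rhat, na.rm = TRUE)
    }
    jsonlite::write_json(res, paths$summary, auto_unbox = TRUE, digits = NA,
                         force = TRUE)
  })

  manifest_path <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}
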