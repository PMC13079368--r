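#' Construct a split-plot field design
#'
#' Describes a two-year split-plot randomized complete block trial:
#' fertilizer treatment on main plots, genotype on subplots, with destructive
#' shoot sampling at a set of growth stages. The defaults reproduce the
#' reference trial: 12 genotypes x 2 fertilizer treatments x 3 replicate
#' blocks (72 subplots), 3 x 3 m plots planted at 1 x 1 m spacing (16 plants
#' per plot), 4 plants destructively sampled per plot at each of 2 stages in
#' each of 2 years.
#'
#' @param n_genotypes number of genotypes (subplot factor).
#' @param n_treatments number of fertilizer treatments (main-plot factor).
#' @param n_replicates number of replicate blocks.
#' @param plot_size_m plot side length in metres.
#' @param plant_spacing_m within-plot plant spacing in metres.
#' @param n_sampling_times destructive sampling stages per year.
#' @param plants_sampled_per_plot plants harvested per plot per stage.
#' @param n_years number of cropping seasons.
#' @return an object of class `field_design`.
#' @export
field_design <- function(n_genotypes = 12, n_treatments = 2, n_replicates = 3,
                         plot_size_m = 3, plant_spacing_m = 1,
                         n_sampling_times = 2, plants_sampled_per_plot = 4,
                         n_years = 2) {
  counts <- c(n_genotypes, n_treatments, n_replicates, n_sampling_times,
              plants_sampled_per_plot, n_years)
  if (any(counts < 1) || any(counts != round(counts)))
    stop("all design counts must be integers >= 1")
  if (plot_size_m <= 0 || plant_spacing_m <= 0)
    stop("plot size and plant spacing must be positive")
  side <- plot_size_m / plant_spacing_m
  if (abs(side - round(side)) > 1e-9)
    stop("invalid design: plot_size_m / plant_spacing_m must be an integer, ",
         "so that plants per plot is a perfect square")
  # plants sit on a fence-post grid: a 3 x 3 m plot at 1 x 1 m spacing
  # holds a 4 x 4 arrangement of 16 plants
  ppp <- (round(side) + 1L)^2
  if (plants_sampled_per_plot * n_sampling_times > ppp)
    stop("invalid design: cannot destructively sample more plants than a plot holds")
  structure(list(
    n_genotypes = n_genotypes, n_treatments = n_treatments,
    n_replicates = n_replicates, plot_size_m = plot_size_m,
    plant_spacing_m = plant_spacing_m, plants_per_plot = ppp,
    n_sampling_times = n_sampling_times,
    plants_sampled_per_plot = plants_sampled_per_plot, n_years = n_years
  ), class = "field_design")
}

#' @export
print.field_design <- function(x, ...) {
  cat(sprintf(
    "Split-plot RCBD: %d genotypes x %d treatments x %d blocks = %d plots/year\n",
    x$n_genotypes, x$n_treatments, x$n_replicates, plot_count(x)))
  cat(sprintf("  %g x %g m plots, %d plants each; %d sampled/plot at %d stage(s), %d year(s)\n",
              x$plot_size_m, x$plot_size_m, x$plants_per_plot,
              x$plants_sampled_per_plot, x$n_sampling_times, x$n_years))
  invisible(x)
}

#' Number of subplots ("plots") in a field design
#' @param design a `field_design`.
#' @return integer plot count per year.
#' @export
plot_count <- function(design) {
  design$n_genotypes * design$n_treatments * design$n_replicates
}

#' Randomize a field design into plant and sampling tables
#'
#' Performs the split-plot randomization: within each block of each year the
#' fertilizer treatments are randomized to main plots and the genotypes to
#' subplots within each main plot. Every plant position receives a record;
#' a destructive-sampling subtable selects, without replacement across
#' stages, `plants_sampled_per_plot` plants per plot per stage per year.
#'
#' @param design a `field_design`.
#' @param seed integer seed; the randomization is reproducible from it.
#' @return a list with data frames `plants` (one row per plant position) and
#'   `sampling` (one row per destructively sampled plant, with `stage` 1..S
#'   and `dap` of the sampling date).
#' @export
simulate_field_design <- function(design, seed = 1) {
  stopifnot(inherits(design, "field_design"))
  set.seed(seed)
  d <- design
  stage_dap <- round(seq(60, by = 60, length.out = d$n_sampling_times))
  genos <- sprintf("G%02d", seq_len(d$n_genotypes))
  treatments <- c("fertilized", "unfertilized", if (d$n_treatments > 2)
    sprintf("treatment%d", 3:d$n_treatments))[seq_len(d$n_treatments)]

  plants <- list(); sampling <- list(); idx <- 1L
  for (yr in seq_len(d$n_years)) {
    year <- 2022L + yr
    for (block in seq_len(d$n_replicates)) {
      main_order <- sample(treatments)
      for (mp in seq_along(main_order)) {
        sub_order <- sample(genos)
        for (sp in seq_along(sub_order)) {
          plot_id <- sprintf("Y%d_B%d_M%d_S%02d", year, block, mp, sp)
          n <- d$plants_per_plot
          side <- sqrt(n)
          pos <- expand.grid(row = seq_len(side), col = seq_len(side))
          rec <- data.frame(
            plant_id = sprintf("%s_P%02d", plot_id, seq_len(n)),
            plot_id = plot_id, year = year, block = block,
            treatment = main_order[mp], genotype_id = sub_order[sp],
            row = pos$row, col = pos$col, stringsAsFactors = FALSE)
          plants[[idx]] <- rec
          # destructive sampling: draw all stages' plants at once so no
          # plant is harvested twice
          ns <- d$plants_sampled_per_plot * d$n_sampling_times
          picked <- sample(n, ns)
          samp <- rec[picked, c("plant_id", "plot_id", "year", "block",
                                "treatment", "genotype_id")]
          samp$stage <- rep(seq_len(d$n_sampling_times),
                            each = d$plants_sampled_per_plot)
          samp$dap <- stage_dap[samp$stage]
          sampling[[idx]] <- samp
          idx <- idx + 1L
        }
      }
    }
  }
  plants <- do.call(rbind, plants)
  sampling <- do.call(rbind, sampling)
  rownames(plants) <- rownames(sampling) <- NULL
  list(plants = plants, sampling = sampling)
}
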