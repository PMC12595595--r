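# Config-driven orchestration of the synthetic end-to-end analysis:
# simulate -> diversity -> sar -> project (affinity + countryside SAR) ->
# sdm -> change, with per-stage seeds and CSV/JSON artifacts.

PIPELINE_STAGES <- c("simulate", "diversity", "sar", "project", "sdm",
                     "change")

#' Assemble and validate a pipeline configuration
#'
#' Accepts a YAML file path or a nested list; missing entries are filled
#' with package defaults. Every stage carries its own seed so reruns with the
#' same configuration are bit-identical for the deterministic stages.
#'
#' @param x YAML path, list, or `NULL` for the packaged synthetic demo
#'   configuration.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(x = NULL) {
  defaults <- list(
    synthetic = list(
      target_z = 0.71, target_ratio = 0.84, n_sites = 9, n_natural = 2,
      pool_size = 300, n_samples = 16,
      n_species = 60, n_operational_sites = 80,
      landscape = list(nx = 12, ny = 12, human_delta = 0.1, mat_delta = 2)),
    scenarios = "SSP2-45",
    seeds = list(simulate = 11, diversity = 12, sar = 13, project = 15,
                 sdm = 14, change = 16),
    epsilon = 1e-6, min_sites = 10, train_frac = 0.7, sdm_reps = 3,
    use_point_estimates = TRUE)
  user <- if (is.null(x)) list()
  else if (is.character(x)) {
    if (!file.exists(x)) stop("no such config file: ", x)
    yaml::read_yaml(x)
  } else if (is.list(x)) x
  else stop("config must be a YAML path or a list")
  cfg <- utils::modifyList(defaults, user)
  miss <- setdiff(PIPELINE_STAGES, names(cfg$seeds))
  if (length(miss)) stop("seed missing for stage(s): ",
                         paste(miss, collapse = ", "))
  bad <- setdiff(cfg$scenarios, c("SSP2-45", "SSP5-85"))
  if (length(bad)) stop("unknown scenario(s): ", paste(bad, collapse = ", "))
  class(cfg) <- "pipeline_config"
  cfg
}

config_hash <- function(cfg) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA), f)
  unname(tools::md5sum(f))
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order, writing each stage's
#' artifacts under `out_dir` together with a `summary.json` carrying the
#' configuration hash, the seeds used and headline quantities. When a stage
#' is requested without its upstream stage, the upstream artifacts must
#' already exist in `out_dir`; otherwise the missing stage is named in the
#' error.
#'
#' @param config A [pipeline_config()], YAML path, list, or `NULL`.
#' @param stages Character vector of stages, or `"all"`.
#' @param out_dir Artifact directory (created if needed).
#' @return `out_dir`, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config = NULL, stages = "all", out_dir = tempfile()) {
  cfg <- if (inherits(config, "pipeline_config")) config
  else pipeline_config(config)
  if (identical(stages, "all")) stages <- PIPELINE_STAGES
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(...) file.path(out_dir, paste0(...))
  need_artifact <- function(file, stage) {
    if (!file.exists(pth(file)))
      stop(sprintf("stage needs artifact '%s'; run stage '%s' first",
                   file, stage))
  }
  syn <- cfg$synthetic
  summary <- list(config_hash = config_hash(cfg), seeds = cfg$seeds)

  if ("simulate" %in% stages) {
    cal <- calibrate_occupancy(syn$target_z, syn$n_samples)
    base <- occupancy_model(syn$pool_size, syn$n_samples, cal$theta,
                            seed = cfg$seeds$simulate)
    sim <- simulate_paired_plots(syn$target_ratio, base, syn$n_sites,
                                 syn$n_natural, biome = BIOMES,
                                 seed = cfg$seeds$simulate)
    write_community(sim$community, pth("community.tsv"))
    utils::write.csv(sim$meta, pth("plot_meta.csv"), row.names = FALSE)
    # pairs are reconstructible from the metadata via reclassify_and_pair()
    for (sc in cfg$scenarios) {
      grid <- simulate_landscape(
        nx = syn$landscape$nx, ny = syn$landscape$ny,
        biomes = unique(sim$meta$biome),  # only biomes with plot parameters
        human_delta = syn$landscape$human_delta,
        climate_delta = list(MAT = syn$landscape$mat_delta),
        scenario = sc, seed = cfg$seeds$simulate)
      write_grid(grid, pth("grid_", sc, ".csv"))
    }
    sites <- simulate_sites(syn$n_operational_sites,
                            seed = cfg$seeds$simulate + 1L)
    niches <- random_niches(syn$n_species, seed = cfg$seeds$simulate + 2L)
    occ <- simulate_occurrences(niches, sites, seed = cfg$seeds$simulate + 3L)
    utils::write.csv(cbind(sites, occ), pth("occurrences.csv"),
                     row.names = FALSE)
    summary$theta <- cal$theta
  }

  read_meta_pairs <- function() {
    need_artifact("plot_meta.csv", "simulate")
    need_artifact("community.tsv", "simulate")
    loaded <- load_community(pth("community.tsv"), pth("plot_meta.csv"))
    pairs <- reclassify_and_pair(loaded$meta)
    list(community = loaded$community, meta = loaded$meta, pairs = pairs)
  }

  if ("diversity" %in% stages) {
    dat <- read_meta_pairs()
    ratios <- diversity_ratios(dat$pairs, dat$community,
                               seed = cfg$seeds$diversity)
    utils::write.csv(ratios, pth("diversity_ratios.csv"), row.names = FALSE)
    long <- rbind(
      data.frame(site_id = ratios$site_id, land_system = "human_dominated",
                 gamma = ratios$S_human),
      data.frame(site_id = ratios$site_id, land_system = "natural",
                 gamma = ratios$S_natural))
    test <- landuse_effect_test(long)
    summary$diversity_ratio_mean <- mean(ratios$ratio, na.rm = TRUE)
    summary$landuse_effect <- list(ratio = test$ratio, ci = test$ci,
                                   p = test$p, fallback = test$fallback)
  }

  if ("sar" %in% stages) {
    dat <- read_meta_pairs()
    fits <- fit_plot_sars(dat$community, seed = cfg$seeds$sar)
    utils::write.csv(fits, pth("sar_fits.csv"), row.names = FALSE)
    params <- biome_guild_parameters(fits, dat$meta)
    utils::write.csv(params, pth("biome_guild_params.csv"), row.names = FALSE)
    summary$mean_z <- mean(fits$z[fits$guild == "all"])
  }

  if ("project" %in% stages) {
    need_artifact("diversity_ratios.csv", "diversity")
    need_artifact("biome_guild_params.csv", "sar")
    ratios <- utils::read.csv(pth("diversity_ratios.csv"))
    params <- utils::read.csv(pth("biome_guild_params.csv"))
    meta <- utils::read.csv(pth("plot_meta.csv"))
    biome_ratio <- stats::aggregate(
      ratio ~ guild,
      data = merge(ratios, unique(meta[, c("site_id", "biome")]),
                   by = "site_id"),
      FUN = mean)
    biome_ratio <- merge(unique(params[, c("biome", "guild")]), biome_ratio,
                         by = "guild")
    aff <- affinity_table(biome_ratio, params,
                          use_point_estimates = cfg$use_point_estimates)
    utils::write.csv(aff, pth("affinities.csv"), row.names = FALSE)
    for (sc in cfg$scenarios) {
      need_artifact(paste0("grid_", sc, ".csv"), "simulate")
      grid <- load_grid(pth("grid_", sc, ".csv"))
      for (era in c("current", "future")) {
        rm_ <- project_grid(grid_era(grid, era), params, aff)
        utils::write.csv(as.data.frame(rm_),
                         pth("sar_richness_", era, "_", sc, ".csv"),
                         row.names = FALSE)
      }
    }
  }

  if ("sdm" %in% stages) {
    need_artifact("occurrences.csv", "simulate")
    occd <- utils::read.csv(pth("occurrences.csv"))
    covn <- c("MAT", "MAP", "temp_seas", "pH", "soilC")
    spn <- setdiff(names(occd), c("site_id", covn))
    ens <- fit_ensemble(as.matrix(occd[, spn]), occd[, covn],
                        reps = cfg$sdm_reps, train_frac = cfg$train_frac,
                        min_sites = cfg$min_sites, seed = cfg$seeds$sdm)
    for (sc in cfg$scenarios) {
      need_artifact(paste0("grid_", sc, ".csv"), "simulate")
      grid <- load_grid(pth("grid_", sc, ".csv"))
      cur <- predict_and_stack(ens, grid_era(grid, "current"))
      fut <- predict_and_stack(ens, grid_era(grid, "future"))
      utils::write.csv(as.data.frame(cur), pth("richness_current.csv"),
                       row.names = FALSE)
      utils::write.csv(as.data.frame(fut),
                       pth("richness_future_", sc, ".csv"), row.names = FALSE)
    }
  }

  if ("change" %in% stages) {
    mk_map <- function(file, src, era, sc) {
      need_artifact(file, if (src == "countryside") "project" else "sdm")
      d <- utils::read.csv(pth(file))
      structure(d, class = c("richness_map", "data.frame"), source = src,
                era = era, scenario = sc)
    }
    for (sc in cfg$scenarios) {
      lu <- change_rate_map(
        mk_map(paste0("sar_richness_current_", sc, ".csv"), "countryside",
               "current", sc),
        mk_map(paste0("sar_richness_future_", sc, ".csv"), "countryside",
               "future", sc),
        driver = "landuse", epsilon = cfg$epsilon)
      cl <- change_rate_map(
        mk_map("richness_current.csv", "sdm", "current", sc),
        mk_map(paste0("richness_future_", sc, ".csv"), "sdm", "future", sc),
        driver = "climate", epsilon = cfg$epsilon)
      utils::write.csv(as.data.frame(lu), pth("change_landuse_", sc, ".csv"),
                       row.names = FALSE)
      utils::write.csv(as.data.frame(cl), pth("change_climate_", sc, ".csv"),
                       row.names = FALSE)
      ov <- classify_overlap(cl, lu)
      utils::write.csv(ov$pixels, pth("overlap_", sc, ".csv"),
                       row.names = FALSE)
      comb <- combined_change(cl, lu, epsilon = cfg$epsilon)
      utils::write.csv(as.data.frame(comb),
                       pth("change_combined_", sc, ".csv"), row.names = FALSE)
      lu_s <- mean_loss_gain(lu); cl_s <- mean_loss_gain(cl)
      summary[[paste0("change_", sc)]] <- list(
        landuse = list(net = lu_s$net,
                       proportions = as.list(lu_s$proportions)),
        climate = list(net = cl_s$net,
                       proportions = as.list(cl_s$proportions)),
        overlap_both_loss = stats::setNames(ov$by_biome$both_loss,
                                            ov$by_biome$biome))
    }
  }

  writeLines(jsonlite::toJSON(summary, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             pth("summary.json"))
  invisible(out_dir)
}
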