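#' @keywords internal
"_PACKAGE"

# Closed vocabularies used for validation throughout the package.
BIOMES <- c("broadleaf_mixed_forest", "coniferous_forest", "grassland", "dry_forest")
LAND_SYSTEMS <- c("natural", "human_dominated")
GUILDS <- c("EM", "AM", "soil_saprotroph", "plant_pathogen", "other")
LAYERS <- c("organic", "mineral", "pooled")

#' Construct a community table of soil-core observations
#'
#' A community table holds per-core (sample) counts or incidences of taxa for
#' one or more 40 x 40 m plots. It is the raw material for rarefaction, paired
#' diversity ratios and plot-scale species-area curves.
#'
#' @param counts Integer matrix, samples in rows (rownames = sample ids),
#'   taxa in columns (colnames = taxon ids). Non-negative.
#' @param samples Data frame with columns `sample_id`, `plot_id` and optionally
#'   `layer` (one of organic/mineral/pooled; defaults to "pooled").
#' @return An object of class `community_table` with elements `counts` and
#'   `samples`.
#' @examples
#' m <- matrix(c(1, 0, 2, 0, 1, 1), nrow = 2,
#'             dimnames = list(c("s1", "s2"), c("t1", "t2", "t3")))
#' ct <- community_table(m, data.frame(sample_id = c("s1", "s2"),
#'                                     plot_id = "p1"))
#' @export
community_table <- function(counts, samples) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("`counts` must carry sample ids as rownames and taxon ids as colnames")
  storage.mode(counts) <- "integer"
  if (anyNA(counts)) stop("`counts` contains missing values")
  bad <- which(counts < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("negative count at sample '%s', taxon '%s'",
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]))
  }
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (sum(counts) == 0) stop("community table has no positive count")
  samples <- as.data.frame(samples)
  if (!all(c("sample_id", "plot_id") %in% names(samples)))
    stop("`samples` needs columns sample_id and plot_id")
  if (is.null(samples$layer)) samples$layer <- "pooled"
  if (!all(samples$layer %in% LAYERS))
    stop("layer must be one of: ", paste(LAYERS, collapse = ", "))
  if (!setequal(samples$sample_id, rownames(counts)))
    stop("sample ids in `counts` and `samples` disagree")
  if (anyDuplicated(samples$sample_id))
    stop("each sample_id must map to exactly one plot")
  samples <- samples[match(rownames(counts), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  structure(list(counts = counts, samples = samples), class = "community_table")
}

#' @export
print.community_table <- function(x, ...) {
  cat(sprintf("community_table: %d samples x %d taxa, %d plot(s)\n",
              nrow(x$counts), ncol(x$counts), length(unique(x$samples$plot_id))))
  invisible(x)
}

#' Samples belonging to given plots
#' @param x A `community_table`.
#' @param plot_ids Character vector of plot ids.
#' @return Character vector of sample ids.
#' @export
plot_samples <- function(x, plot_ids) {
  stopifnot(inherits(x, "community_table"))
  x$samples$sample_id[x$samples$plot_id %in% plot_ids]
}

#' Taxon-by-sample incidence matrix for a set of samples
#'
#' @param x A `community_table`.
#' @param sample_ids Samples to include (default all).
#' @param guild_map Optional guild map (see [read_guild_map()]); with `guild`
#'   set, taxa are restricted to that guild.
#' @param guild Guild to keep, or `"all"`.
#' @return Binary integer matrix, taxa x samples.
#' @export
incidence_matrix <- function(x, sample_ids = NULL, guild_map = NULL, guild = "all") {
  stopifnot(inherits(x, "community_table"))
  if (is.null(sample_ids)) sample_ids <- x$samples$sample_id
  miss <- setdiff(sample_ids, rownames(x$counts))
  if (length(miss)) stop("unknown sample ids: ", paste(miss, collapse = ", "))
  m <- t(x$counts[sample_ids, , drop = FALSE] > 0)
  storage.mode(m) <- "integer"
  if (guild != "all") {
    if (is.null(guild_map)) stop("guild filtering requires a guild map")
    keep <- guild_map$taxon_id[guild_map$guild == guild]
    m <- m[rownames(m) %in% keep, , drop = FALSE]
  }
  m
}

#' Read a community table and plot metadata from disk
#'
#' The community file is TSV with first column `sample_id` and one integer
#' column per taxon; metadata is CSV with columns
#' `plot_id,site_id,biome,land_system,historical_land_use,raw_landuse_label`.
#'
#' @param path Community TSV path.
#' @param meta_path Plot metadata CSV path.
#' @param sample_plot Optional data frame mapping `sample_id` to `plot_id`;
#'   when absent, sample ids are expected as `<plot_id>.<k>`.
#' @return List with elements `community` (a [community_table()]) and `meta`
#'   (validated plot metadata).
#' @export
load_community <- function(path, meta_path, sample_plot = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (!file.exists(meta_path)) stop("no such file: ", meta_path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (names(tab)[1] != "sample_id") stop("first column must be `sample_id`")
  counts <- as.matrix(tab[, -1, drop = FALSE])
  rownames(counts) <- tab$sample_id
  if (is.null(sample_plot)) {
    sample_plot <- data.frame(
      sample_id = tab$sample_id,
      plot_id = sub("\\.[^.]*$", "", tab$sample_id))
  }
  meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  community <- community_table(counts, sample_plot)
  meta <- validate_plot_meta(meta, community)
  list(community = community, meta = meta)
}

#' Write a community table to TSV
#' @param x A `community_table`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_community <- function(x, path) {
  stopifnot(inherits(x, "community_table"))
  df <- data.frame(sample_id = rownames(x$counts), x$counts,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate plot metadata against a community table
#'
#' Checks the closed biome and land-system vocabularies, required columns and
#' (when a community table is supplied) that `n_samples` matches the samples
#' actually present.
#'
#' @param meta Data frame of plot metadata.
#' @param community Optional `community_table` to cross-reference.
#' @return The validated metadata with `n_samples` filled in.
#' @export
validate_plot_meta <- function(meta, community = NULL) {
  need <- c("plot_id", "site_id", "biome", "land_system", "historical_land_use")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("metadata lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(meta$plot_id)) stop("duplicate plot_id in metadata")
  bad <- setdiff(unique(meta$biome), BIOMES)
  if (length(bad)) stop("unknown biome(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(meta$land_system), LAND_SYSTEMS)
  if (length(bad)) stop("unknown land_system(s): ", paste(bad, collapse = ", "))
  if (!is.null(community)) {
    tallies <- table(community$samples$plot_id)
    meta$n_samples <- as.integer(tallies[meta$plot_id])
    meta$n_samples[is.na(meta$n_samples)] <- 0L
  }
  meta
}

#' Read a taxon-to-guild mapping
#'
#' TSV with columns `taxon_id` and `guild`. Guilds outside the closed set
#' (EM, AM, soil_saprotroph, plant_pathogen) are rejected; taxa present in
#' `taxa` but absent from the file default to "other".
#'
#' @param path Guild map TSV.
#' @param taxa Optional character vector of taxon ids to complete with "other".
#' @return Data frame with columns `taxon_id`, `guild`.
#' @export
read_guild_map <- function(path, taxa = NULL) {
  gm <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("taxon_id", "guild") %in% names(gm)))
    stop("guild map needs columns taxon_id and guild")
  if (anyDuplicated(gm$taxon_id)) stop("a taxon maps to more than one guild")
  bad <- setdiff(unique(gm$guild), GUILDS)
  if (length(bad)) stop("unknown guild(s): ", paste(bad, collapse = ", "))
  if (!is.null(taxa)) {
    extra <- setdiff(taxa, gm$taxon_id)
    if (length(extra))
      gm <- rbind(gm, data.frame(taxon_id = extra, guild = "other"))
  }
  gm
}

#' Reclassify raw land-use labels and pair plots
#'
#' Raw land-use labels are collapsed to the natural / human-dominated
#' dichotomy via `class_map`; every human-dominated plot is then paired with
#' all natural plots at the same site sharing its historical land-use type.
#' Human plots without such a partner are reported in the `unpaired`
#' attribute (with a warning), never silently dropped.
#'
#' @param meta Plot metadata including a `raw_landuse_label` column (when
#'   absent, the existing `land_system` column is used directly).
#' @param class_map Named character vector: raw label -> "natural" or
#'   "human_dominated". Must cover every raw label present.
#' @return List of `paired_plot_set` objects (fields `human_plot`,
#'   `natural_plots`, `site_id`), with attributes `meta` (reclassified
#'   metadata) and `unpaired` (data frame of unpairable human plots).
#' @export
reclassify_and_pair <- function(meta, class_map = NULL) {
  if (!is.null(class_map)) {
    if (is.null(meta$raw_landuse_label))
      stop("class_map given but metadata has no raw_landuse_label column")
    missing_labels <- setdiff(unique(meta$raw_landuse_label), names(class_map))
    if (length(missing_labels))
      stop("raw land-use label(s) absent from class_map: ",
           paste(missing_labels, collapse = ", "))
    bad <- setdiff(unique(class_map), LAND_SYSTEMS)
    if (length(bad)) stop("class_map values must be natural/human_dominated")
    meta$land_system <- unname(class_map[meta$raw_landuse_label])
  }
  humans <- meta[meta$land_system == "human_dominated", , drop = FALSE]
  pairs <- list()
  unpaired <- humans[0, , drop = FALSE]
  for (i in seq_len(nrow(humans))) {
    h <- humans[i, ]
    nat <- meta[meta$land_system == "natural" &
                  meta$site_id == h$site_id &
                  meta$historical_land_use == h$historical_land_use, ,
                drop = FALSE]
    if (nrow(nat) == 0) {
      unpaired <- rbind(unpaired, h)
    } else {
      pairs[[length(pairs) + 1L]] <- structure(
        list(human_plot = h$plot_id,
             natural_plots = sort(nat$plot_id),
             site_id = h$site_id),
        class = "paired_plot_set")
    }
  }
  if (nrow(unpaired) > 0)
    warning(sprintf("%d human-dominated plot(s) had no matching natural plot: %s",
                    nrow(unpaired), paste(unpaired$plot_id, collapse = ", ")))
  structure(pairs, meta = meta, unpaired = unpaired)
}

#' Validate a landscape grid table
#'
#' A landscape grid is a long-format table of 10 x 10 km equal-area pixels
#' with biome, land-system area fractions and climate/soil covariates for one
#' or more eras of a scenario. Fractions must sum to one per pixel and every
#' era of a scenario must carry the identical pixel set.
#'
#' @param grid Data frame with columns `pixel_id, biome, era, scenario,
#'   area_total_m2, fraction_natural, fraction_human, MAT, MAP, temp_seas,
#'   pH, soilC`.
#' @param tol Tolerance on the fraction sum (default 1e-9).
#' @return The grid with class `landscape_grid`.
#' @export
validate_grid <- function(grid, tol = 1e-9) {
  need <- c("pixel_id", "biome", "era", "scenario", "area_total_m2",
            "fraction_natural", "fraction_human", "MAT", "MAP",
            "temp_seas", "pH", "soilC")
  miss <- setdiff(need, names(grid))
  if (length(miss)) stop("grid lacks columns: ", paste(miss, collapse = ", "))
  if (any(grid$area_total_m2 <= 0)) stop("area_total_m2 must be positive")
  bad <- setdiff(unique(grid$biome), BIOMES)
  if (length(bad)) stop("unknown biome(s): ", paste(bad, collapse = ", "))
  s <- grid$fraction_natural + grid$fraction_human
  off <- abs(s - 1) > tol
  if (any(off))
    stop("land-system fractions do not sum to 1 for pixel(s): ",
         paste(utils::head(grid$pixel_id[off], 5), collapse = ", "))
  if (any(grid$fraction_natural < 0 | grid$fraction_human < 0))
    stop("fractions must be non-negative")
  for (sc in unique(grid$scenario)) {
    g <- grid[grid$scenario == sc, ]
    eras <- split(g$pixel_id, g$era)
    if (length(eras) > 1) {
      ref <- sort(eras[[1]])
      for (e in names(eras)[-1]) {
        if (!identical(sort(eras[[e]]), ref))
          stop(sprintf("pixel sets differ between eras of scenario '%s'", sc))
      }
    }
    if (anyDuplicated(paste(g$pixel_id, g$era)))
      stop("duplicate pixel_id within an era")
  }
  class(grid) <- unique(c("landscape_grid", class(grid)))
  grid
}

#' Read a landscape grid CSV
#' @param path Long-format grid CSV (see [validate_grid()] for columns).
#' @return A validated `landscape_grid`.
#' @export
load_grid <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  validate_grid(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write a landscape grid to CSV
#' @param grid A `landscape_grid`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_grid <- function(grid, path) {
  utils::write.csv(as.data.frame(grid), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Subset a landscape grid to one era (and scenario)
#' @param grid A `landscape_grid`.
#' @param era `"current"` or `"future"`.
#' @param scenario Scenario label, or `NULL` for any.
#' @return The subset, ordered by `pixel_id`, still a `landscape_grid`.
#' @export
grid_era <- function(grid, era, scenario = NULL) {
  g <- grid[grid$era == era, , drop = FALSE]
  if (!is.null(scenario)) g <- g[g$scenario %in% c(scenario, "none"), , drop = FALSE]
  if (nrow(g) == 0) stop("no pixels for era '", era, "'")
  g <- g[order(g$pixel_id), , drop = FALSE]
  rownames(g) <- NULL
  g
}
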