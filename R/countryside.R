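# Habitat affinity from paired-plot diversity ratios and countryside-SAR
# projection of landscape richness: S = c * (sum_j h_j * A_j)^z, with the
# natural land system's affinity fixed at one.

#' Relative habitat affinity from a diversity ratio
#'
#' `h = ratio^(1/z)`: the affinity whose effective-area weighting reproduces
#' the observed local diversity ratio under a SAR with slope z. By
#' construction `h^z` equals the ratio, so converting a fully natural
#' landscape entirely to the modified system changes countryside-SAR richness
#' by exactly the factor `ratio`.
#'
#' @param ratio Human/natural diversity ratio (> 0).
#' @param z SAR scaling slope (> 0).
#' @return Affinity h (> 0).
#' @export
relative_affinity <- function(ratio, z) {
  if (any(ratio <= 0)) stop("ratio must be positive")
  if (any(z <= 0)) stop("z must be positive")
  ratio^(1 / z)
}

#' Countryside-SAR richness of one landscape
#'
#' `S = c * (sum_j h_j A_j)^z`. With a single natural system (h = 1) this
#' reduces to the classic power-law SAR.
#'
#' @param c Baseline richness per unit area (> 0).
#' @param z Scaling slope.
#' @param affinities Positive affinity per land system.
#' @param areas Non-negative area (m2) per land system, matching
#'   `affinities`.
#' @return Richness S.
#' @export
countryside_richness <- function(c, z, affinities, areas) {
  if (c <= 0) stop("c must be positive")
  if (any(affinities <= 0)) stop("affinities must be positive")
  if (any(areas < 0)) stop("areas must be non-negative")
  if (length(affinities) != length(areas))
    stop("affinities and areas must align")
  c * sum(affinities * areas)^z
}

#' Build a biome x guild affinity table
#'
#' Combines per-biome (and guild) diversity ratios with the matching SAR
#' slopes into habitat affinities for the human-dominated system
#' (`h_natural` is one by definition). Ratios flagged non-significant default
#' to a neutral affinity of one unless `use_point_estimates` is set.
#'
#' @param ratios Data frame with columns `biome, guild, ratio` and optionally
#'   `significant` (logical).
#' @param params [biome_guild_parameters()] output (`biome, guild, mean_z`).
#' @param use_point_estimates Use non-significant point estimates instead of
#'   the neutral default (default FALSE).
#' @return Data frame with `biome, guild, h_human, h_natural, ratio, z`.
#' @export
affinity_table <- function(ratios, params, use_point_estimates = FALSE) {
  need <- c("biome", "guild", "ratio")
  miss <- setdiff(need, names(ratios))
  if (length(miss)) stop("ratios lack columns: ", paste(miss, collapse = ", "))
  d <- merge(ratios, params[, c("biome", "guild", "mean_z")],
             by = c("biome", "guild"))
  if (nrow(d) == 0) stop("no biome x guild overlap between ratios and params")
  use <- if (is.null(d$significant) || use_point_estimates)
    rep(TRUE, nrow(d)) else d$significant
  h <- ifelse(use, relative_affinity(d$ratio, d$mean_z), 1)
  data.frame(biome = d$biome, guild = d$guild, h_human = h, h_natural = 1,
             ratio = d$ratio, z = d$mean_z)
}

#' Project pixel richness with the countryside SAR
#'
#' For each pixel, land-system areas are `A_j = fraction_j * area_total` and
#' richness is [countryside_richness()] with the pixel biome's (c, z) and
#' affinities for the requested guild.
#'
#' @param grid Single-era `landscape_grid` (see [grid_era()]).
#' @param params [biome_guild_parameters()] output.
#' @param affinities [affinity_table()] output.
#' @param guild Guild to project (default "all").
#' @return A `richness_map` (`pixel_id`, `biome`, `richness`) with attribute
#'   `source = "countryside"`.
#' @export
project_grid <- function(grid, params, affinities, guild = "all") {
  if (length(unique(grid$era)) > 1)
    stop("grid spans several eras; subset with grid_era() first")
  p <- params[params$guild == guild, , drop = FALSE]
  a <- affinities[affinities$guild == guild, , drop = FALSE]
  need <- unique(grid$biome)
  miss <- union(setdiff(need, p$biome), setdiff(need, a$biome))
  if (length(miss))
    stop("no parameters/affinities for biome(s): ",
         paste(miss, collapse = ", "))
  ci <- p$mean_c[match(grid$biome, p$biome)]
  zi <- p$mean_z[match(grid$biome, p$biome)]
  hh <- a$h_human[match(grid$biome, a$biome)]
  area_nat <- grid$fraction_natural * grid$area_total_m2
  area_hum <- grid$fraction_human * grid$area_total_m2
  richness <- ci * (1 * area_nat + hh * area_hum)^zi
  out <- data.frame(pixel_id = grid$pixel_id, biome = grid$biome,
                    richness = richness)
  structure(out, class = c("richness_map", "data.frame"),
            source = "countryside",
            era = unique(grid$era),
            scenario = unique(grid$scenario))
}
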