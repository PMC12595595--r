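# Seeded generators producing inputs with the statistical structure the
# downstream analysis assumes: per-core occupancy within a plot, paired
# human/natural plot collections with a target diversity ratio, Gaussian
# climate niches, and paired current/future landscape grids.

# Run expr under a given seed without disturbing the caller's RNG state.
local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

#' Specify an occupancy model for one plot
#'
#' Each of `pool_size` species occupies `t` of the plot's `n_samples` soil
#' cores, with `t` drawn from a truncated geometric-like distribution on
#' `{1, ..., n_samples}` governed by `theta`: weights are proportional to
#' `r^(t-1)` with `r = theta / (1 - theta)`. As `theta -> 0` every species is
#' a singleton (steepest possible species-area slope, z -> 1); at
#' `theta = 0.5` occupancy is uniform; at `theta = 1` every species occupies
#' every core (flat curve, z = 0).
#'
#' @param pool_size Number of species in the plot's pool (>= 1).
#' @param n_samples Soil cores per plot (default 16).
#' @param theta Aggregation parameter in (0, 1].
#' @param seed Integer seed used when the model is simulated.
#' @return An object of class `occupancy_model`.
#' @export
occupancy_model <- function(pool_size, n_samples = 16, theta, seed = 1) {
  stopifnot(pool_size >= 1, n_samples >= 1)
  if (!(theta > 0 && theta <= 1)) stop("theta must lie in (0, 1]")
  structure(list(pool_size = as.integer(pool_size),
                 n_samples = as.integer(n_samples),
                 theta = theta, seed = seed),
            class = "occupancy_model")
}

#' Occupancy probability mass function
#'
#' @param theta Aggregation parameter in (0, 1].
#' @param n_samples Number of cores T.
#' @return Numeric vector of length `n_samples`; element t is P(occupy t cores).
#' @export
occupancy_pmf <- function(theta, n_samples) {
  if (!(theta > 0 && theta <= 1)) stop("theta must lie in (0, 1]")
  if (theta == 1) return(c(rep(0, n_samples - 1L), 1))
  t <- seq_len(n_samples)
  lw <- (t - 1) * (log(theta) - log1p(-theta))
  w <- exp(lw - max(lw))
  w / sum(w)
}

#' Analytic expected species-area curve under an occupancy model
#'
#' Expected rarefied richness at each subsample size m:
#' `E[S(m)] = pool * sum_t P(t) * (1 - C(T - t, m) / C(T, m))`.
#'
#' @param theta Aggregation parameter.
#' @param n_samples Cores per plot T.
#' @param pool_size Species pool size.
#' @param m_values Subsample sizes.
#' @return Numeric vector of expected richness, one per `m`.
#' @export
expected_occupancy_richness <- function(theta, n_samples, pool_size, m_values) {
  pmf <- occupancy_pmf(theta, n_samples)
  t <- seq_len(n_samples)
  vapply(m_values, function(m) {
    miss <- ifelse(n_samples - t >= m,
                   exp(lchoose(n_samples - t, m) - lchoose(n_samples, m)), 0)
    pool_size * sum(pmf * (1 - miss))
  }, numeric(1))
}

#' Calibrate the occupancy parameter to a target SAR slope
#'
#' Bisects over `theta` using the monotone map theta -> fitted z, where z is
#' obtained by fitting the linearized power law to the analytic expected
#' richness at the standard sampling scales. Larger theta (more ubiquitous
#' species) implies a flatter slope.
#'
#' @param target_z Target slope in (0, 1).
#' @param n_samples Cores per plot (default 16).
#' @param scales Data frame with columns `area` and `m` (defaults to the
#'   100/400/900/1600 m2 design with m = 1/4/9/16).
#' @param tol Convergence tolerance on z (default 0.01).
#' @return List with `theta`, the implied `z`, and `boundary` (TRUE when the
#'   target sits at the all-singleton limit).
#' @export
calibrate_occupancy <- function(target_z, n_samples = 16,
                                scales = default_scales(), tol = 0.01) {
  if (!(target_z > 0 && target_z < 1)) {
    if (identical(target_z, 1)) {
      return(list(theta = 1e-9, z = 1, boundary = TRUE))
    }
    stop("target_z must lie in (0, 1)")
  }
  z_of <- function(theta) {
    s <- expected_occupancy_richness(theta, n_samples, 1000, scales$m)
    fit_sar(data.frame(area = scales$area, richness = s))$z
  }
  lo <- 1e-9; hi <- 1 - 1e-12
  z_lo <- z_of(lo)  # ~1
  if (target_z >= z_lo - tol) return(list(theta = lo, z = z_lo, boundary = TRUE))
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    z_mid <- z_of(mid)
    if (abs(z_mid - target_z) < tol * 0.1) break
    if (z_mid > target_z) lo <- mid else hi <- mid
  }
  list(theta = mid, z = z_mid, boundary = FALSE)
}

#' Simulate one plot's core-by-taxon community
#'
#' Draws each species' core occupancy from the model's truncated
#' geometric-like distribution and places it in that many cores chosen
#' uniformly without replacement. Counts are incidences (0/1).
#'
#' @param model An [occupancy_model()].
#' @param plot_id Plot identifier used in sample ids (`<plot_id>.<k>`).
#' @param taxon_prefix Prefix for taxon ids.
#' @return A [community_table()] for the single plot.
#' @export
simulate_plot_community <- function(model, plot_id = "plot1",
                                    taxon_prefix = "t") {
  stopifnot(inherits(model, "occupancy_model"))
  T <- model$n_samples
  local_seed(model$seed, {
    pmf <- occupancy_pmf(model$theta, T)
    t_i <- sample.int(T, model$pool_size, replace = TRUE, prob = pmf)
    counts <- matrix(0L, nrow = T, ncol = model$pool_size,
                     dimnames = list(paste0(plot_id, ".", seq_len(T)),
                                     paste0(taxon_prefix, seq_len(model$pool_size))))
    for (i in seq_len(model$pool_size)) {
      counts[sample.int(T, t_i[i]), i] <- 1L
    }
    community_table(counts, data.frame(sample_id = rownames(counts),
                                       plot_id = plot_id))
  })
}

# Expected rarefied richness at m cores from a pooled collection of k
# independent plots sharing one species pool: convolve the per-plot occupancy
# pmf k times, then apply the hypergeometric rarefaction identity on k*T cores.
expected_pooled_richness <- function(theta, n_samples, k, pool_size, m) {
  pmf <- occupancy_pmf(theta, n_samples)
  poly <- c(0, pmf)  # coefficients over occupancy 0..T (0 has mass zero)
  conv <- poly
  if (k > 1) for (i in seq_len(k - 1)) conv <- convolve_poly(conv, poly)
  total <- k * n_samples
  occ <- seq_along(conv) - 1
  miss <- ifelse(total - occ >= m,
                 exp(lchoose(total - occ, m) - lchoose(total, m)), 0)
  pool_size * sum(conv * (1 - miss))
}

convolve_poly <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1)
  for (i in seq_along(a)) {
    if (a[i] != 0) {
      idx <- i + seq_along(b) - 1
      out[idx] <- out[idx] + a[i] * b
    }
  }
  out
}

#' Simulate paired human-dominated and natural plot collections
#'
#' For each site, `n_natural` natural plots are drawn from a common species
#' pool under `base_model`; the human-dominated plot is drawn from a pool
#' sized so that its observed richness has expectation `target_ratio` times
#' the expected rarefied richness of the pooled natural collection at the
#' human plot's core count.
#'
#' @param target_ratio Target human/natural gamma-diversity ratio (> 0).
#' @param base_model [occupancy_model()] shared by all plots.
#' @param n_sites Number of sites (one human plot each).
#' @param n_natural Natural plots per site (default 2).
#' @param biome Biome label(s); recycled across sites.
#' @param seed Integer seed.
#' @return List with `community` (a [community_table()]), `meta` (plot
#'   metadata), and `pairs` (list of `paired_plot_set`).
#' @export
simulate_paired_plots <- function(target_ratio, base_model, n_sites,
                                  n_natural = 2, biome = "grassland",
                                  seed = 1) {
  stopifnot(target_ratio > 0, inherits(base_model, "occupancy_model"))
  T <- base_model$n_samples
  s_nat <- expected_pooled_richness(base_model$theta, T, n_natural,
                                    base_model$pool_size, T)
  pool_h <- max(1L, as.integer(round(target_ratio * s_nat)))
  biome <- rep_len(biome, n_sites)
  tables <- list(); meta <- list(); pairs <- list()
  local_seed(seed, {
    for (s in seq_len(n_sites)) {
      site <- sprintf("site%02d", s)
      hp <- paste0(site, ".H1")
      nat_ids <- paste0(site, ".N", seq_len(n_natural))
      for (p in seq_along(nat_ids)) {
        m <- occupancy_model(base_model$pool_size, T, base_model$theta,
                             seed = NULL)
        tables[[length(tables) + 1L]] <-
          simulate_plot_community(m, nat_ids[p],
                                  taxon_prefix = paste0(site, ".tax"))
      }
      mh <- occupancy_model(pool_h, T, base_model$theta, seed = NULL)
      tables[[length(tables) + 1L]] <-
        simulate_plot_community(mh, hp, taxon_prefix = paste0(site, ".htax"))
      meta[[length(meta) + 1L]] <- data.frame(
        plot_id = c(hp, nat_ids), site_id = site, biome = biome[s],
        land_system = c("human_dominated", rep("natural", n_natural)),
        historical_land_use = "baseline")
      pairs[[length(pairs) + 1L]] <- structure(
        list(human_plot = hp, natural_plots = nat_ids, site_id = site),
        class = "paired_plot_set")
    }
  })
  community <- bind_communities(tables)
  meta <- validate_plot_meta(do.call(rbind, meta), community)
  list(community = community, meta = meta, pairs = pairs)
}

#' Combine community tables over disjoint sample sets
#' @param tables List of `community_table` objects.
#' @return One `community_table` on the union of samples and taxa.
#' @export
bind_communities <- function(tables) {
  taxa <- unique(unlist(lapply(tables, function(x) colnames(x$counts))))
  samples <- do.call(rbind, lapply(tables, function(x) x$samples))
  counts <- matrix(0L, nrow = nrow(samples), ncol = length(taxa),
                   dimnames = list(samples$sample_id, taxa))
  for (x in tables) counts[rownames(x$counts), colnames(x$counts)] <- x$counts
  community_table(counts, samples)
}

#' Specify Gaussian climate niches for a species set
#'
#' Occurrence probability at covariate vector x is
#' `pmax * exp(-0.5 * sum(((x - opt) / breadth)^2))`.
#'
#' @param optima Numeric matrix, species x covariates (named columns).
#' @param breadth Matrix of positive niche breadths, same shape as `optima`.
#' @param pmax Vector of maximum occurrence probabilities in (0, 1].
#' @return Object of class `niche_spec`.
#' @export
niche_spec <- function(optima, breadth, pmax) {
  optima <- as.matrix(optima); breadth <- as.matrix(breadth)
  stopifnot(identical(dim(optima), dim(breadth)),
            length(pmax) == nrow(optima))
  if (any(breadth <= 0)) stop("niche breadth must be positive")
  if (any(pmax <= 0 | pmax > 1)) stop("pmax must lie in (0, 1]")
  if (is.null(colnames(optima))) stop("optima must have covariate column names")
  if (is.null(rownames(optima)))
    rownames(optima) <- paste0("sp", seq_len(nrow(optima)))
  structure(list(optima = optima, breadth = breadth, pmax = pmax),
            class = "niche_spec")
}

#' True occurrence probabilities under a niche specification
#' @param niches A [niche_spec()].
#' @param covariates Data frame of site/pixel covariates containing every
#'   niche covariate column.
#' @return Matrix of probabilities, rows = sites, columns = species.
#' @export
niche_probability <- function(niches, covariates) {
  stopifnot(inherits(niches, "niche_spec"))
  vars <- colnames(niches$optima)
  miss <- setdiff(vars, names(covariates))
  if (length(miss)) stop("covariates lack: ", paste(miss, collapse = ", "))
  x <- as.matrix(covariates[, vars, drop = FALSE])
  p <- matrix(NA_real_, nrow(x), nrow(niches$optima),
              dimnames = list(NULL, rownames(niches$optima)))
  for (i in seq_len(nrow(niches$optima))) {
    d2 <- sweep(x, 2, niches$optima[i, ])^2
    d2 <- sweep(d2, 2, niches$breadth[i, ]^2, "/")
    p[, i] <- niches$pmax[i] * exp(-0.5 * rowSums(d2))
  }
  p
}

#' Simulate site-by-species presences from Gaussian niches
#' @param niches A [niche_spec()].
#' @param site_covariates Data frame of covariates (one row per site).
#' @param seed Integer seed.
#' @return Binary matrix, sites x species.
#' @export
simulate_occurrences <- function(niches, site_covariates, seed = 1) {
  p <- niche_probability(niches, site_covariates)
  local_seed(seed, {
    occ <- matrix(stats::rbinom(length(p), 1L, as.vector(p)), nrow(p), ncol(p))
    dimnames(occ) <- dimnames(p)
    occ
  })
}

#' Draw random Gaussian niches inside a covariate envelope
#'
#' Optima are placed uniformly inside `opt_range` for each covariate,
#' breadths uniformly in `breadth_range`, and `pmax` uniformly in
#' `pmax_range`. The defaults pair with [simulate_sites()]: each species'
#' response is covered by the sampled climate envelope out to about three
#' breadths on either side of the optimum, so occurrence data are informative
#' about the full response curve (the precondition for niche recovery).
#'
#' @param n_species Number of species.
#' @param opt_range Named list of c(lo, hi) per covariate.
#' @param breadth_range Named list of c(lo, hi) per covariate.
#' @param pmax_range Range of maximum occurrence probability.
#' @param seed Integer seed.
#' @return A [niche_spec()].
#' @export
random_niches <- function(n_species,
                          opt_range = list(MAT = c(6, 14),
                                           MAP = c(800, 1400)),
                          breadth_range = list(MAT = c(2.5, 3.5),
                                               MAP = c(250, 400)),
                          pmax_range = c(0.7, 0.95), seed = 1) {
  vars <- names(opt_range)
  stopifnot(!is.null(vars), setequal(vars, names(breadth_range)))
  local_seed(seed, {
    optima <- sapply(vars, function(v)
      stats::runif(n_species, opt_range[[v]][1], opt_range[[v]][2]))
    breadth <- sapply(vars, function(v)
      stats::runif(n_species, breadth_range[[v]][1], breadth_range[[v]][2]))
    pmax <- stats::runif(n_species, pmax_range[1], pmax_range[2])
    niche_spec(matrix(optima, ncol = length(vars),
                      dimnames = list(paste0("sp", seq_len(n_species)), vars)),
               matrix(breadth, ncol = length(vars),
                      dimnames = list(NULL, vars)),
               pmax)
  })
}

#' Simulate operational-site covariates
#'
#' Sites are drawn uniformly over stated covariate ranges; defaults span a
#' temperate MAT/MAP envelope with mildly varying temperature seasonality,
#' pH and soil carbon.
#'
#' @param n_sites Number of sites.
#' @param ranges Named list of c(lo, hi) covariate ranges.
#' @param seed Integer seed.
#' @return Data frame with `site_id` and covariate columns.
#' @export
simulate_sites <- function(n_sites,
                           ranges = list(MAT = c(0, 25), MAP = c(300, 2000),
                                         temp_seas = c(300, 1000),
                                         pH = c(4, 8), soilC = c(1, 12)),
                           seed = 1) {
  local_seed(seed, {
    cov <- as.data.frame(lapply(ranges, function(r)
      stats::runif(n_sites, r[1], r[2])))
    cbind(data.frame(site_id = sprintf("os%03d", seq_len(n_sites))), cov)
  })
}

#' Simulate paired current/future landscape grids
#'
#' Builds an `nx` by `ny` equal-area pixel grid with biomes laid out in
#' vertical bands, smooth climate gradients plus noise, and per-biome natural
#' area fractions. The future era shifts each pixel's human-dominated
#' fraction by `human_delta` (clamped errors are reported, not silently
#' fixed) and each climate field by `climate_delta`.
#'
#' @param nx,ny Grid dimensions.
#' @param biomes Biome bands from west to east.
#' @param natural_fraction Named per-biome current natural fraction (recycled).
#' @param human_delta Scalar or per-pixel shift in human fraction by 2100.
#' @param climate_delta Named list of additive shifts (e.g. `list(MAT = 3)`).
#' @param scenario Scenario label.
#' @param area_total_m2 Pixel area (default 1e8, a 10 x 10 km cell).
#' @param mat_range,map_range Climate gradient ranges across the grid.
#' @param seed Integer seed.
#' @return A validated two-era [validate_grid()] `landscape_grid`.
#' @export
simulate_landscape <- function(nx = 20, ny = 20,
                               biomes = BIOMES,
                               natural_fraction = 0.8,
                               human_delta = 0.1,
                               climate_delta = list(MAT = 2),
                               scenario = "SSP2-45",
                               area_total_m2 = 1e8,
                               mat_range = c(2, 24), map_range = c(350, 1900),
                               seed = 1) {
  local_seed(seed, {
    px <- expand.grid(ix = seq_len(nx), iy = seq_len(ny))
    n <- nrow(px)
    band <- if (length(biomes) == 1) rep(1L, n)
    else cut(px$ix, breaks = length(biomes), labels = FALSE)
    biome <- biomes[band]
    if (is.null(names(natural_fraction)))
      natural_fraction <- stats::setNames(rep_len(natural_fraction,
                                                  length(biomes)), biomes)
    fn <- pmin(1, pmax(0, natural_fraction[biome] +
                            stats::runif(n, -0.05, 0.05)))
    MAT <- mat_range[1] + (mat_range[2] - mat_range[1]) * (px$iy - 1) /
      max(1, ny - 1) + stats::rnorm(n, 0, 0.5)
    MAP <- map_range[1] + (map_range[2] - map_range[1]) * (px$ix - 1) /
      max(1, nx - 1) + stats::rnorm(n, 0, 30)
    temp_seas <- 400 + 300 * (px$iy - 1) / max(1, ny - 1) +
      stats::rnorm(n, 0, 20)
    pH <- 6 + stats::rnorm(n, 0, 0.4)
    soilC <- 5 + stats::rnorm(n, 0, 1)
    cur <- data.frame(
      pixel_id = sprintf("px%05d", seq_len(n)), biome = biome,
      era = "current", scenario = scenario, area_total_m2 = area_total_m2,
      fraction_natural = as.numeric(fn), fraction_human = as.numeric(1 - fn),
      MAT = MAT, MAP = MAP, temp_seas = temp_seas, pH = pH, soilC = soilC)
    fut <- cur
    fut$era <- "future"
    new_h <- cur$fraction_human + human_delta
    bad <- new_h < 0 | new_h > 1
    if (any(bad))
      stop("human_delta pushes fraction outside [0, 1] for pixel(s): ",
           paste(utils::head(cur$pixel_id[bad], 5), collapse = ", "))
    fut$fraction_human <- new_h
    fut$fraction_natural <- 1 - new_h
    for (v in names(climate_delta))
      fut[[v]] <- fut[[v]] + climate_delta[[v]]
    validate_grid(rbind(cur, fut))
  })
}

#' Simulate paired gamma-diversity counts from the Poisson site model
#'
#' Generates per-plot gamma diversity for `n_sites` sites, each with one
#' human-dominated plot and `n_natural` natural plots: site intercepts are
#' log-normal around `mu0` with standard deviation `site_sd` on the log
#' scale, and gamma ~ Poisson with the human plots' mean multiplied by
#' `ratio`. This is the generating process matched by
#' [landuse_effect_test()].
#'
#' @param n_sites Number of sites.
#' @param ratio True multiplicative effect of the human-dominated system.
#' @param n_natural Natural plots per site.
#' @param mu0 Baseline expected gamma diversity of a natural plot.
#' @param site_sd Site random-intercept SD on the log scale.
#' @param seed Integer seed.
#' @return Data frame with columns `site_id`, `land_system`, `gamma`.
#' @export
simulate_gamma_poisson <- function(n_sites, ratio, n_natural = 2,
                                   mu0 = 150, site_sd = 0.25, seed = 1) {
  stopifnot(n_sites >= 2, ratio > 0)
  local_seed(seed, {
    out <- lapply(seq_len(n_sites), function(s) {
      mu_s <- exp(log(mu0) + stats::rnorm(1, 0, site_sd))
      data.frame(
        site_id = sprintf("site%02d", s),
        land_system = c("human_dominated", rep("natural", n_natural)),
        gamma = stats::rpois(n_natural + 1L, mu_s * c(ratio, rep(1, n_natural))))
    })
    do.call(rbind, out)
  })
}
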