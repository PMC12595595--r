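# Plot-scale species-area curves from nested soil-core subsampling, the
# linearized power-law fit log(S) = log(c) + z log(A), biome/guild parameter
# aggregation, and analyses of slope variation.

#' Default nested sampling design
#'
#' Four sampling scales of 100, 400, 900 and 1600 m2, obtained by drawing
#' 1, 4, 9 and 16 soil cores respectively, so area and core count are
#' proportional (100 m2 per core).
#'
#' @return Data frame with columns `area` (m2) and `m` (cores).
#' @export
default_scales <- function() {
  data.frame(area = c(100, 400, 900, 1600), m = c(1, 4, 9, 16))
}

#' Plot-scale species-area curve
#'
#' Mean richness at each sampling scale is the expected rarefied richness of
#' the plot's cores at that scale's core count (analytic mode by default;
#' Monte-Carlo resampling is available as a cross-check).
#'
#' @param community A [community_table()].
#' @param plot_id Plot to use (default: the only plot present).
#' @param scales Sampling design, see [default_scales()].
#' @param guild_map,guild Optional guild restriction.
#' @param mode,reps,seed Passed to [expected_richness_rarefied()].
#' @return Data frame with columns `area`, `m`, `richness`.
#' @export
plot_scale_curve <- function(community, plot_id = NULL,
                             scales = default_scales(),
                             guild_map = NULL, guild = "all",
                             mode = "analytic", reps = 2000, seed = 1) {
  stopifnot(inherits(community, "community_table"))
  if (is.null(plot_id)) {
    plot_id <- unique(community$samples$plot_id)
    if (length(plot_id) > 1) stop("multiple plots present; give `plot_id`")
  }
  samp <- plot_samples(community, plot_id)
  if (length(samp) < max(scales$m))
    stop(sprintf("plot '%s' has %d samples; the design needs %d",
                 plot_id, length(samp), max(scales$m)))
  inc <- incidence_matrix(community, samp, guild_map, guild)
  richness <- vapply(scales$m, function(m)
    suppressWarnings(expected_richness_rarefied(inc, m, mode, reps, seed)),
    numeric(1))
  data.frame(area = scales$area, m = scales$m, richness = richness)
}

#' Fit the linearized power-law species-area relationship
#'
#' Ordinary least squares of log richness on log area (natural logs
#' internally): `log(S) = log(c) + z log(A)`. `c` is reported on the linear
#' scale and, with areas in m2, reads as the extrapolated richness in 1 m2.
#'
#' @param points Data frame with columns `area` and `richness` (>= 2 rows,
#'   strictly positive richness, strictly increasing areas).
#' @return Object of class `sar_fit`: list with `c`, `z`, `r_squared`,
#'   `points`, `n_scales`.
#' @export
fit_sar <- function(points) {
  if (!all(c("area", "richness") %in% names(points)))
    stop("`points` needs columns area and richness")
  if (nrow(points) < 2) stop("need at least 2 points to fit a SAR")
  if (any(points$richness <= 0))
    stop("richness must be positive (log undefined)")
  if (any(diff(points$area) <= 0)) stop("areas must be strictly increasing")
  fit <- stats::lm(log(richness) ~ log(area), data = points)
  cf <- stats::coef(fit)
  ss_tot <- sum((log(points$richness) - mean(log(points$richness)))^2)
  r2 <- if (ss_tot < 1e-20) NA_real_ else
    suppressWarnings(summary(fit)$r.squared)
  structure(list(c = exp(unname(cf[1])), z = unname(cf[2]),
                 r_squared = r2, points = points,
                 n_scales = nrow(points)),
            class = "sar_fit")
}

#' @export
print.sar_fit <- function(x, ...) {
  cat(sprintf("SAR fit: S = %.4g * A^%.4g  (R^2 = %s, %d scales)\n",
              x$c, x$z,
              ifelse(is.na(x$r_squared), "NA", sprintf("%.3f", x$r_squared)),
              x$n_scales))
  invisible(x)
}

#' Fit SARs for every plot (and optionally every guild)
#'
#' Plots with fewer cores than the largest scale requires are skipped; their
#' ids and reasons are returned in the `skipped` attribute.
#'
#' @param community A [community_table()] holding many plots.
#' @param scales Sampling design.
#' @param guild_map Optional guild map; with `guilds`, per-guild fits are
#'   added alongside the whole-community ("all") fits.
#' @param guilds Character vector of guilds to fit (default none).
#' @param mode,reps,seed Passed to [plot_scale_curve()].
#' @return Data frame with columns `plot_id, guild, c, z, r_squared,
#'   n_scales`; attribute `skipped` lists excluded plots.
#' @export
fit_plot_sars <- function(community, scales = default_scales(),
                          guild_map = NULL, guilds = character(0),
                          mode = "analytic", reps = 2000, seed = 1) {
  plots <- unique(community$samples$plot_id)
  rows <- list(); skipped <- list()
  for (p in plots) {
    if (length(plot_samples(community, p)) < max(scales$m)) {
      skipped[[p]] <- sprintf("%d < %d samples",
                              length(plot_samples(community, p)),
                              max(scales$m))
      next
    }
    for (g in c("all", guilds)) {
      curve <- plot_scale_curve(community, p, scales, guild_map, g,
                                mode, reps, seed)
      if (any(curve$richness <= 0)) {
        skipped[[paste(p, g)]] <- "zero richness at some scale"
        next
      }
      f <- fit_sar(curve)
      rows[[length(rows) + 1L]] <- data.frame(
        plot_id = p, guild = g, c = f$c, z = f$z,
        r_squared = f$r_squared, n_scales = f$n_scales)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "skipped") <- skipped
  out
}

#' Aggregate SAR parameters by biome and guild
#'
#' Arithmetic mean of `c` and of `z` across plots within the same biome (and
#' guild), with plot counts.
#'
#' @param fits Data frame from [fit_plot_sars()].
#' @param meta Plot metadata with `plot_id` and `biome`.
#' @return Data frame with `biome, guild, mean_c, mean_z, n_plots`.
#' @export
biome_guild_parameters <- function(fits, meta) {
  miss <- setdiff(unique(fits$plot_id), meta$plot_id)
  if (length(miss))
    stop("no biome metadata for plot(s): ", paste(miss, collapse = ", "))
  fits$biome <- meta$biome[match(fits$plot_id, meta$plot_id)]
  agg <- stats::aggregate(cbind(c, z) ~ biome + guild, data = fits, FUN = mean)
  n <- stats::aggregate(plot_id ~ biome + guild, data = fits,
                        FUN = function(x) length(unique(x)))
  out <- merge(agg, n, by = c("biome", "guild"))
  names(out) <- c("biome", "guild", "mean_c", "mean_z", "n_plots")
  absent <- setdiff(unique(meta$biome), unique(out$biome))
  if (length(absent))
    warning("biome(s) with no fitted plots omitted: ",
            paste(absent, collapse = ", "))
  out[order(out$biome, out$guild), , drop = FALSE]
}

#' Compare mean scaling slopes among guilds (Welch ANOVA)
#'
#' One-way unequal-variance (Welch) ANOVA on z across guilds, followed by
#' pairwise Welch t-tests with Holm adjustment. Guilds with fewer than two
#' fits are excluded with a warning.
#'
#' @param fits Data frame with columns `guild` and `z` (typically
#'   [fit_plot_sars()] output restricted to guild-level fits).
#' @return List with `F`, `df`, `p`, `pairwise` (data frame of Holm-adjusted
#'   pairwise comparisons) and `group_means`.
#' @export
guild_slope_anova <- function(fits) {
  counts <- table(fits$guild)
  small <- names(counts)[counts < 2]
  if (length(small)) {
    warning("guild(s) with < 2 fits excluded: ", paste(small, collapse = ", "))
    fits <- fits[!fits$guild %in% small, , drop = FALSE]
  }
  fits$guild <- factor(fits$guild)
  if (nlevels(fits$guild) < 2) stop("need >= 2 guilds with >= 2 fits each")
  wt <- stats::oneway.test(z ~ guild, data = fits, var.equal = FALSE)
  gl <- levels(fits$guild)
  cmb <- utils::combn(gl, 2)
  pw <- data.frame(group1 = cmb[1, ], group2 = cmb[2, ],
                   estimate = NA_real_, p_raw = NA_real_)
  for (i in seq_len(ncol(cmb))) {
    a <- fits$z[fits$guild == cmb[1, i]]
    b <- fits$z[fits$guild == cmb[2, i]]
    tt <- stats::t.test(a, b, var.equal = FALSE)
    pw$estimate[i] <- mean(a) - mean(b)
    pw$p_raw[i] <- tt$p.value
  }
  pw$p_adj <- stats::p.adjust(pw$p_raw, method = "holm")
  list(F = unname(wt$statistic), df = unname(wt$parameter),
       p = wt$p.value, pairwise = pw,
       group_means = tapply(fits$z, fits$guild, mean))
}

#' Mixed-model drivers of the scaling slope with variance partitioning
#'
#' Standardizes the covariates, fits a linear mixed model of z on all of them
#' with a site random intercept, and partitions the fixed-effect (marginal)
#' explained variance between baseline diversity (log c) and climate/soil
#' covariates via R-squared differences of nested fixed-effect sets. Only
#' covariates significant in the full model (two-sided p <= `alpha`) enter
#' the partition.
#'
#' @param data Data frame containing `z`, a site id column, the baseline
#'   column and the covariate columns.
#' @param covariate_cols Names of climate/soil covariate columns.
#' @param baseline_col Name of the baseline-diversity column (default
#'   `"log_c"`).
#' @param site_col Name of the site id column (default `"site_id"`).
#' @param alpha Significance threshold for entering the partition.
#' @return List with `effects` (standardized coefficients, SEs, p-values),
#'   `r2_marginal` (full model), and `partition` (unique_baseline,
#'   unique_climate, shared fractions of total variance explained by fixed
#'   effects, plus the significant variable sets).
#' @export
slope_driver_model <- function(data, covariate_cols, baseline_col = "log_c",
                               site_col = "site_id", alpha = 0.05) {
  vars <- c(baseline_col, covariate_cols)
  miss <- setdiff(c("z", site_col, vars), names(data))
  if (length(miss)) stop("data lacks columns: ", paste(miss, collapse = ", "))
  d <- data
  for (v in vars) {
    if (stats::sd(d[[v]]) == 0) stop("constant covariate: ", v)
    d[[v]] <- as.numeric(scale(d[[v]]))
  }
  X <- as.matrix(d[, vars, drop = FALSE])
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1) {
    drop_idx <- qrX$pivot[(qrX$rank + 1):ncol(qrX$qr)] - 1
    stop("collinear covariate column(s): ",
         paste(vars[drop_idx[drop_idx > 0]], collapse = ", "))
  }
  fml <- stats::as.formula(paste("z ~", paste(vars, collapse = " + "),
                                 "+ (1 |", site_col, ")"))
  fit <- lmerTest::lmer(fml, data = d)
  sm <- stats::coef(summary(fit))
  eff <- data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
                    se = sm[, "Std. Error"], p = sm[, "Pr(>|t|)"],
                    row.names = NULL)
  eff <- eff[eff$term != "(Intercept)", , drop = FALSE]
  sig <- eff$term[eff$p <= alpha]
  sig_base <- intersect(sig, baseline_col)
  sig_clim <- intersect(sig, covariate_cols)
  # Marginal R2: variance of the fixed-effect predictions over total variance.
  marg_r2 <- function(terms) {
    if (length(terms) == 0) return(0)
    f <- stats::as.formula(paste("z ~", paste(terms, collapse = " + "),
                                 "+ (1 |", site_col, ")"))
    m <- lme4::lmer(f, data = d)
    vf <- stats::var(as.vector(stats::model.matrix(m) %*% lme4::fixef(m)))
    vc <- as.data.frame(lme4::VarCorr(m))
    vf / (vf + sum(vc$vcov))
  }
  r2_full <- marg_r2(c(sig_base, sig_clim))
  r2_base <- marg_r2(sig_base)
  r2_clim <- marg_r2(sig_clim)
  partition <- list(
    unique_baseline = max(0, r2_full - r2_clim),
    unique_climate = max(0, r2_full - r2_base),
    shared = max(0, r2_base + r2_clim - r2_full),
    significant_baseline = sig_base, significant_climate = sig_clim)
  list(effects = eff, r2_marginal = r2_full, partition = partition,
       model = fit)
}
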