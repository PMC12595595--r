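test_that("plot-scale curves reduce correctly and match resampling", {
  # ubiquity community: flat curve
  ct <- simulate_plot_community(occupancy_model(30, 16, 1, seed = 1))
  crv <- plot_scale_curve(ct)
  expect_true(all(crv$richness == 30))
  # all-singleton community: richness proportional to m
  ct1 <- simulate_plot_community(occupancy_model(64, 16, 1e-9, seed = 1))
  crv1 <- plot_scale_curve(ct1)
  expect_equal(crv1$richness, 64 * crv1$m / 16, tolerance = 1e-9)
  # analytic and Monte-Carlo curves agree within Monte-Carlo error
  ct2 <- simulate_plot_community(occupancy_model(120, 16, 0.4, seed = 2))
  a <- plot_scale_curve(ct2)
  mc <- plot_scale_curve(ct2, mode = "montecarlo", reps = 2000, seed = 3)
  singles <- vapply(1:200, function(i)
    plot_scale_curve(ct2, mode = "montecarlo", reps = 1,
                     seed = 100 + i)$richness[2], numeric(1))
  expect_lt(abs(mc$richness[2] - a$richness[2]), 3 * sd(singles) / sqrt(2000))
  # insufficient samples is an error naming the plot
  short <- community_table(
    matrix(1L, 3, 2, dimnames = list(paste0("p.", 1:3), c("a", "b"))),
    data.frame(sample_id = paste0("p.", 1:3), plot_id = "p"))
  expect_error(plot_scale_curve(short), "3 samples")
})

test_that("linearized SAR fit recovers exact power laws", {
  areas <- c(100, 400, 900, 1600)
  f <- fit_sar(data.frame(area = areas, richness = 5 * areas^0.7))
  expect_equal(f$c, 5, tolerance = 1e-10)
  expect_equal(f$z, 0.7, tolerance = 1e-10)
  expect_equal(f$r_squared, 1, tolerance = 1e-10)
  # two-point hand solution: z = log(50/5)/log(100/1) = 0.5, c = 5
  f2 <- fit_sar(data.frame(area = c(1, 100), richness = c(5, 50)))
  expect_equal(f2$z, 0.5, tolerance = 1e-12)
  expect_equal(f2$c, 5, tolerance = 1e-12)
  # constant richness: z = 0, c = that richness
  f3 <- fit_sar(data.frame(area = areas, richness = rep(12, 4)))
  expect_equal(f3$z, 0, tolerance = 1e-12)
  expect_equal(f3$c, 12, tolerance = 1e-12)
  expect_error(fit_sar(data.frame(area = areas, richness = c(1, 2, 0, 3))),
               "positive")
  expect_error(fit_sar(data.frame(area = 1, richness = 5)), "2 points")
})

test_that("SAR fit is scale-equivariant in area units", {
  set.seed(9)
  pts <- data.frame(area = c(100, 400, 900, 1600),
                    richness = exp(log(4) + 0.6 * log(c(100, 400, 900, 1600))
                                   + rnorm(4, 0, 0.05)))
  f <- fit_sar(pts)
  for (k in c(10, 1e4)) {
    fk <- fit_sar(transform(pts, area = area * k))
    expect_equal(fk$z, f$z, tolerance = 1e-10)
    expect_equal(fk$c, f$c * k^(-f$z), tolerance = 1e-8)
  }
})

test_that("fitted z stays within [0, 1] across the occupancy range", {
  for (theta in c(0.02, 0.2, 0.5, 0.8, 0.99)) {
    ct <- simulate_plot_community(occupancy_model(150, 16, theta,
                                                  seed = round(theta * 100)))
    z <- fit_sar(plot_scale_curve(ct))$z
    expect_gte(z, 0); expect_lte(z, 1)
  }
})

test_that("biome aggregation averages parameters and tracks plot counts", {
  fits <- data.frame(plot_id = c("A", "B", "C"), guild = "all",
                     c = c(4, 6, 10), z = c(0.6, 0.8, 0.5),
                     r_squared = 1, n_scales = 4)
  meta <- data.frame(plot_id = c("A", "B", "C"), site_id = "s",
                     biome = c("grassland", "grassland", "dry_forest"),
                     land_system = "natural", historical_land_use = "x")
  bp <- biome_guild_parameters(fits, meta)
  expect_equal(bp$mean_z[bp$biome == "grassland"], 0.7)
  expect_equal(bp$mean_c[bp$biome == "grassland"], 5)
  expect_equal(bp$n_plots[bp$biome == "dry_forest"], 1)
  expect_equal(bp$mean_z[bp$biome == "dry_forest"], 0.5)
  # guild-level fits aggregate independently of whole-community fits
  fits_g <- rbind(fits, transform(fits, guild = "EM", z = z + 0.1))
  bpg <- biome_guild_parameters(fits_g, meta)
  expect_equal(bpg$mean_z[bpg$biome == "grassland" & bpg$guild == "EM"], 0.8)
  expect_equal(bpg$mean_z[bpg$biome == "grassland" & bpg$guild == "all"], 0.7)
})

test_that("Welch ANOVA on guild slopes matches the textbook statistic", {
  groups <- list(EM = c(0.70, 0.75, 0.72, 0.80, 0.68),
                 AM = c(0.60, 0.66, 0.58, 0.71),
                 soil_saprotroph = c(0.52, 0.49, 0.55, 0.50, 0.57, 0.51))
  fits <- data.frame(guild = rep(names(groups), lengths(groups)),
                     z = unlist(groups))
  res <- guild_slope_anova(fits)
  expect_equal(res$F, welch_F_oracle(groups), tolerance = 1e-10)
  expect_equal(nrow(res$pairwise), 3)
  expect_true(all(res$pairwise$p_adj >= res$pairwise$p_raw - 1e-15))
  # identical group means give F ~ 0
  same <- data.frame(guild = rep(c("EM", "AM"), each = 4),
                     z = rep(c(0.6, 0.7, 0.8, 0.5), 2))
  expect_lt(guild_slope_anova(same)$F, 1e-20)
  # guilds with one fit are excluded
  one <- rbind(fits, data.frame(guild = "plant_pathogen", z = 0.9))
  expect_warning(res2 <- guild_slope_anova(one), "plant_pathogen")
  expect_equal(res2$F, res$F)
})

test_that("two guilds with separated slopes are detected with high power", {
  hits <- vapply(1:50, function(i) {
    set.seed(3000 + i)
    fits <- data.frame(guild = rep(c("AM", "soil_saprotroph"), each = 50),
                       z = c(rnorm(50, 0.75, 0.05), rnorm(50, 0.60, 0.05)))
    guild_slope_anova(fits)$p < 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("slope-driver model attributes variance to the right sets", {
  set.seed(77)
  n <- 160
  d <- data.frame(site_id = rep(sprintf("s%02d", 1:16), each = 10),
                  MAT = rnorm(n), MAP = rnorm(n), log_c = rnorm(n))
  # z driven purely by baseline diversity
  d$z <- 0.7 + 0.1 * d$log_c + rnorm(n, 0, 0.01)
  res <- suppressMessages(
    slope_driver_model(d, covariate_cols = c("MAT", "MAP")))
  expect_gt(res$partition$unique_baseline, 0.8)
  expect_lt(res$partition$unique_climate, 0.05)
  # pure noise: nothing explained
  d$z <- rnorm(n, 0.7, 0.05)
  res0 <- suppressMessages(
    slope_driver_model(d, covariate_cols = c("MAT", "MAP")))
  expect_lt(res0$r2_marginal, 0.1)
  # collinear covariates are named
  d$MAP2 <- d$MAP
  expect_error(
    suppressMessages(slope_driver_model(d, c("MAT", "MAP", "MAP2"))),
    "collinear")
})

test_that("slope-driver model recovers known standardized effects", {
  ests <- t(vapply(1:30, function(i) {
    set.seed(5000 + i)
    n <- 120
    d <- data.frame(site_id = rep(sprintf("s%02d", 1:12), each = 10),
                    MAT = rnorm(n), MAP = rnorm(n), log_c = rnorm(n))
    d$z <- 0.5 * d$MAT + 0.3 * d$log_c + rnorm(n, 0, 0.1)
    res <- suppressMessages(slope_driver_model(d, c("MAT", "MAP")))
    c(MAT = res$effects$estimate[res$effects$term == "MAT"],
      log_c = res$effects$estimate[res$effects$term == "log_c"])
  }, numeric(2)))
  expect_lt(abs(mean(ests[, "MAT"]) - 0.5), 0.1)
  expect_lt(abs(mean(ests[, "log_c"]) - 0.3), 0.1)
})
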