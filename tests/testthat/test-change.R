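test_that("change rates and classes follow the definition", {
  cur <- mk_richness(c("p1", "p2", "p3"), "grassland", c(100, 50, 0))
  fut <- mk_richness(c("p1", "p2", "p3"), "grassland", c(80, 50, 5))
  cm <- change_rate_map(cur, fut, driver = "landuse")
  expect_equal(cm$rate[cm$pixel_id == "p1"], -0.20)
  expect_equal(cm$class[cm$pixel_id == "p1"], "loss")
  expect_equal(cm$rate[cm$pixel_id == "p2"], 0)
  expect_equal(cm$class[cm$pixel_id == "p2"], "none")
  expect_true(is.na(cm$rate[cm$pixel_id == "p3"]))
  expect_equal(cm$class[cm$pixel_id == "p3"], "undefined")
  expect_error(change_rate_map(cur, mk_richness("q1", "grassland", 1)),
               "pixel sets")
  expect_error(change_rate_map(cur, mk_richness(cur$pixel_id, "grassland",
                                                1, source = "sdm")),
               "different sources")
})

test_that("full conversion yields a change rate of ratio minus one", {
  ratio <- 0.84; z <- 0.71
  params <- data.frame(biome = "grassland", guild = "all", mean_c = 5,
                       mean_z = z, n_plots = 1)
  aff <- data.frame(biome = "grassland", guild = "all",
                    h_human = relative_affinity(ratio, z), h_natural = 1,
                    ratio = ratio, z = z)
  mk <- function(fn, era) validate_grid(data.frame(
    pixel_id = "p1", biome = "grassland", era = era, scenario = "SSP2-45",
    area_total_m2 = 1e8, fraction_natural = fn, fraction_human = 1 - fn,
    MAT = 10, MAP = 800, temp_seas = 500, pH = 6, soilC = 5))
  cur <- project_grid(mk(1, "current"), params, aff)
  fut <- project_grid(mk(0, "future"), params, aff)
  cm <- change_rate_map(cur, fut, driver = "landuse")
  expect_equal(cm$rate, ratio - 1, tolerance = 1e-12)
})

test_that("mean loss/gain estimation reduces to group means when balanced", {
  cm <- structure(
    data.frame(pixel_id = paste0("p", 1:4), biome = "grassland",
               driver = "landuse", rate = c(-0.2, -0.1, 0.1, 0.3),
               class = c("loss", "loss", "gain", "gain")),
    class = c("change_map", "data.frame"), epsilon = 1e-6)
  res <- mean_loss_gain(cm)
  expect_equal(res$loss$mean_rate[res$loss$biome == "grassland"], -0.15)
  expect_equal(res$gain$mean_rate[res$gain$biome == "grassland"], 0.2)
  expect_equal(res$net, 0.025)
  expect_equal(unname(res$proportions), c(0.5, 0.5, 0))

  zero <- structure(
    data.frame(pixel_id = paste0("p", 1:3), biome = "grassland",
               driver = "landuse", rate = 0, class = "none"),
    class = c("change_map", "data.frame"), epsilon = 1e-6)
  rz <- mean_loss_gain(zero)
  expect_null(rz$loss); expect_null(rz$gain)
  expect_equal(rz$net, 0)
  expect_equal(unname(rz$proportions), c(0, 0, 1))
})

test_that("block-model means agree with arithmetic means on balanced designs", {
  set.seed(4)
  n <- 400
  cm <- structure(
    data.frame(pixel_id = sprintf("p%03d", 1:n),
               biome = rep(c("grassland", "dry_forest"), each = n / 2),
               driver = "climate",
               rate = c(runif(n / 2, -0.3, -0.05), runif(n / 2, 0.05, 0.3))),
    class = c("change_map", "data.frame"), epsilon = 1e-6)
  cm$class <- ifelse(cm$rate < 0, "loss", "gain")
  blocks <- rep(rep(c("b1", "b2", "b3", "b4"), each = n / 8), 2)
  res <- mean_loss_gain(cm, blocks)
  direct_loss <- mean(cm$rate[cm$class == "loss"])
  est_loss <- res$loss$mean_rate[res$loss$biome == "all"]
  expect_lt(abs(est_loss - direct_loss) / abs(direct_loss), 0.01)
  direct_gain <- mean(cm$rate[cm$class == "gain"])
  est_gain <- res$gain$mean_rate[res$gain$biome == "all"]
  expect_lt(abs(est_gain - direct_gain) / abs(direct_gain), 0.01)
})

test_that("bivariate overlap classification matches manual tallies", {
  mkcm <- function(rates, biomes) structure(
    data.frame(pixel_id = sprintf("p%d", seq_along(rates)), biome = biomes,
               driver = "x", rate = rates,
               class = ifelse(rates < -1e-6, "loss",
                              ifelse(rates > 1e-6, "gain", "none"))),
    class = c("change_map", "data.frame"), epsilon = 1e-6)
  biomes <- rep(c("grassland", "dry_forest"), c(4, 2))
  clim <- mkcm(c(-0.1, -0.2, 0.1, -0.1, 0.05, -0.3), biomes)
  lu <- mkcm(c(-0.05, -0.1, -0.02, 0.2, 0.1, -0.1), biomes)
  ov <- classify_overlap(clim, lu)
  # single-pixel definition check: climate gain + land-use loss
  expect_equal(ov$pixels$overlap[ov$pixels$pixel_id == "p3"], "gain/loss")
  # manual tally: grassland pixels 1,2 are both-loss out of 4
  g <- ov$by_biome[ov$by_biome$biome == "grassland", ]
  expect_equal(g$both_loss, 0.5)
  expect_equal(g$both_gain, 0)
  d <- ov$by_biome[ov$by_biome$biome == "dry_forest", ]
  expect_equal(d$both_loss, 0.5)
  expect_equal(d$both_gain, 0.5)
  # full bivariate table matches enumeration
  expect_equal(sum(ov$table), 6)
  expect_equal(unname(ov$table["loss", "loss"]), 3)
  expect_equal(unname(ov$table["gain", "loss"]), 1)
})

test_that("both-loss proportions never exceed the marginal loss proportions", {
  set.seed(17)
  for (i in 1:20) {
    n <- 60
    biomes <- sample(c("grassland", "coniferous_forest"), n, replace = TRUE)
    mkcm <- function() structure(
      data.frame(pixel_id = sprintf("p%02d", 1:n), biome = biomes,
                 driver = "x", rate = runif(n, -0.5, 0.5)),
      class = c("change_map", "data.frame"), epsilon = 1e-6)
    a <- mkcm(); a$class <- ifelse(a$rate < -1e-6, "loss",
                                   ifelse(a$rate > 1e-6, "gain", "none"))
    b <- mkcm(); b$rate <- runif(n, -0.5, 0.5)
    b$class <- ifelse(b$rate < -1e-6, "loss",
                      ifelse(b$rate > 1e-6, "gain", "none"))
    ov <- classify_overlap(a, b)
    for (bi in unique(biomes)) {
      pa <- mean(a$class[a$biome == bi] == "loss")
      pb <- mean(b$class[b$biome == bi] == "loss")
      expect_lte(ov$by_biome$both_loss[ov$by_biome$biome == bi],
                 min(pa, pb) + 1e-12)
    }
  }
})

test_that("combined change is additive and re-classified consistently", {
  mkcm <- function(rates) structure(
    data.frame(pixel_id = c("p1", "p2"), biome = "grassland", driver = "x",
               rate = rates,
               class = ifelse(rates < -1e-6, "loss",
                              ifelse(rates > 1e-6, "gain", "none"))),
    class = c("change_map", "data.frame"), epsilon = 1e-6)
  comb <- combined_change(mkcm(c(0.1, -0.2)), mkcm(c(-0.1, -0.05)))
  expect_equal(comb$rate, c(0, -0.25))
  expect_equal(comb$class, c("none", "loss"))
  expect_equal(mean(comb$rate),
               mean(c(0.1, -0.2)) + mean(c(-0.1, -0.05)))
})

test_that("reclassification with a wider epsilon only moves the none band", {
  rates <- seq(-0.1, 0.1, length.out = 21)
  cls <- function(eps) fungalsar:::classify_rate(rates, eps)
  c1 <- cls(1e-6); c2 <- cls(0.05)
  moved <- which(c1 != c2)
  expect_true(all(abs(rates[moved]) <= 0.05 + 1e-12))
  expect_true(all(c2[moved] == "none"))
})
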