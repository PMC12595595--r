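test_that("species filter applies the inclusive site threshold", {
  occ <- cbind(a = c(rep(1, 10), rep(0, 10)),
               b = c(rep(1, 9), rep(0, 11)),
               c = rep(1, 20))
  expect_setequal(filter_species(occ, 10), c("a", "c"))
  expect_equal(filter_species(matrix(0, 0, 0)), character(0))
  expect_error(filter_species(matrix(2, 2, 2)), "binary")
})

test_that("threshold choice maximizes sensitivity plus specificity", {
  res <- optimal_threshold(c(0.1, 0.4, 0.6, 0.9), c(0, 0, 1, 1))
  expect_equal(res$threshold, 0.5)
  expect_equal(res$sensitivity + res$specificity, 2)
  # perfectly inverted scores still reach the trivial classifier's J = 1
  inv <- optimal_threshold(c(0.9, 0.6, 0.4, 0.1), c(0, 0, 1, 1))
  expect_gte(inv$sensitivity + inv$specificity, 1)
  # all scores equal: smallest candidate wins the tie, J = 1
  tie <- optimal_threshold(rep(0.5, 6), c(0, 1, 0, 1, 0, 1))
  expect_equal(tie$threshold, 0)
  expect_equal(tie$sensitivity + tie$specificity, 1)
  expect_error(optimal_threshold(c(0.2, 0.8), c(1, 1)), "both classes")
})

test_that("threshold equals exhaustive scan on random instances", {
  set.seed(99)
  for (i in 1:200) {
    n <- sample(5:40, 1)
    scores <- round(runif(n), sample(1:3, 1))
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    res <- optimal_threshold(scores, labels)
    # oracle: evaluate J over a dense candidate set covering every
    # achievable classification
    cand <- sort(unique(c(0, 1, scores, scores - 1e-9, scores + 1e-9)))
    J <- vapply(cand, function(thr) {
      pred <- scores >= thr
      sum(pred & labels == 1) / sum(labels == 1) +
        sum(!pred & labels == 0) / sum(labels == 0)
    }, numeric(1))
    expect_equal(res$sensitivity + res$specificity, max(J),
                 tolerance = 1e-12)
  }
})

test_that("ensemble fitting is deterministic and saturates wide niches", {
  sites <- simulate_sites(60, seed = 41)
  niches <- random_niches(6, seed = 42)
  occ <- simulate_occurrences(niches, sites, seed = 43)
  keep <- filter_species(occ, 6)
  expect_gte(length(keep), 2)  # deterministic given the fixture seeds
  occ <- occ[, keep, drop = FALSE]
  e1 <- fit_ensemble(occ, sites, reps = 2, min_sites = 6, seed = 7)
  e2 <- fit_ensemble(occ, sites, reps = 2, min_sites = 6, seed = 7)
  thr <- function(e) unlist(lapply(e$models, vapply, `[[`, numeric(1),
                                   "threshold"))
  expect_identical(thr(e1), thr(e2))
  grid <- simulate_landscape(nx = 5, ny = 5, seed = 44)
  s1 <- predict_and_stack(e1, grid_era(grid, "current"))
  s2 <- predict_and_stack(e2, grid_era(grid, "current"))
  expect_identical(s1$richness, s2$richness)

  # a species present everywhere except the coldest margin is predicted
  # present across the warm covariate range (absences keep both classes
  # available and sit on a learnable climate edge); the full ensemble vote
  # buffers the degenerate thresholds a perfectly separated GLM can produce
  wide <- cbind(occ, ubiq = 1L)
  wide[order(sites$MAT)[1:4], "ubiq"] <- 0L
  e3 <- fit_ensemble(wide, sites, reps = 2, min_sites = 6, seed = 8)
  s3 <- predict_and_stack(e3, grid_era(grid, "current"), subset = "ubiq")
  warm <- grid_era(grid, "current")$MAT > 8  # beyond the absence margin
  expect_gte(mean(s3$richness[warm]), 0.9)
})

test_that("stacking is order-invariant, additive, and respects subsets", {
  ens <- mk_manual_ensemble(list(
    west = function(x) as.numeric(x$MAP < 1100),
    east = function(x) as.numeric(x$MAP >= 1100),
    north = function(x) as.numeric(x$MAT < 13)))
  grid <- simulate_landscape(nx = 8, ny = 8, seed = 51)
  cur <- grid_era(grid, "current")
  s_all <- predict_and_stack(ens, cur)
  # two species on disjoint halves cover every pixel exactly once
  s_we <- predict_and_stack(ens, cur, subset = c("west", "east"))
  expect_true(all(s_we$richness == 1))
  # single-species subset equals that species' binary map
  s_w <- predict_and_stack(ens, cur, subset = "west")
  expect_equal(s_w$richness, as.numeric(cur$MAP < 1100))
  # order invariance and additivity over disjoint subsets
  s_perm <- predict_and_stack(ens, cur, subset = c("north", "east", "west"))
  expect_equal(s_perm$richness, s_all$richness)
  s_n <- predict_and_stack(ens, cur, subset = "north")
  expect_equal(s_we$richness + s_n$richness, s_all$richness)
  expect_error(predict_and_stack(ens, cur, subset = "nope"), "unknown species")
  # per-species occupancy attribute counts presence pixels
  expect_equal(unname(attr(s_all, "occupancy")["west"]),
               sum(cur$MAP < 1100))
})

test_that("grids spanning several eras are rejected before prediction", {
  ens <- mk_manual_ensemble(list(sp = function(x) rep(1, nrow(x))))
  grid <- simulate_landscape(nx = 3, ny = 3, seed = 52)
  expect_error(predict_and_stack(ens, grid), "several eras")
})
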