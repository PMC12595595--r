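# Fixtures and independent oracles shared across the suite.

# Deterministic two-plot community: plot A has 4 samples, plot B has 4.
toy_community <- function() {
  counts <- rbind(
    A.1 = c(1, 1, 0, 0, 1),
    A.2 = c(1, 0, 1, 0, 0),
    A.3 = c(1, 0, 0, 1, 0),
    A.4 = c(1, 1, 1, 0, 0),
    B.1 = c(0, 1, 1, 1, 1),
    B.2 = c(0, 0, 1, 1, 0),
    B.3 = c(0, 1, 0, 1, 1),
    B.4 = c(1, 0, 0, 1, 1))
  colnames(counts) <- paste0("t", 1:5)
  community_table(counts, data.frame(
    sample_id = rownames(counts),
    plot_id = rep(c("A", "B"), each = 4)))
}

rand_incidence <- function(n_taxa, n_samples, p = 0.4) {
  m <- matrix(rbinom(n_taxa * n_samples, 1, p), n_taxa, n_samples)
  # guarantee every taxon occurs somewhere
  empty <- rowSums(m) == 0
  m[cbind(which(empty), sample.int(n_samples, sum(empty), replace = TRUE))] <- 1
  m
}

# Exhaustive-subset oracle for expected rarefied richness.
enum_rarefied <- function(inc, m) {
  subsets <- utils::combn(ncol(inc), m)
  mean(apply(subsets, 2, function(j)
    sum(rowSums(inc[, j, drop = FALSE]) > 0)))
}

# Textbook Welch one-way F statistic.
welch_F_oracle <- function(groups) {
  k <- length(groups)
  n <- vapply(groups, length, numeric(1))
  mu <- vapply(groups, mean, numeric(1))
  v <- vapply(groups, var, numeric(1))
  w <- n / v
  mw <- sum(w * mu) / sum(w)
  A <- sum(w * (mu - mw)^2) / (k - 1)
  B <- 1 + 2 * (k - 2) / (k^2 - 1) * sum((1 - w / sum(w))^2 / (n - 1))
  A / B
}

# Minimal richness_map construction for change-module tests.
mk_richness <- function(pixel_id, biome, richness, source = "countryside",
                        era = "current", scenario = "SSP2-45") {
  structure(data.frame(pixel_id = pixel_id, biome = biome,
                       richness = richness),
            class = c("richness_map", "data.frame"),
            source = source, era = era, scenario = scenario)
}

# Hand-built ensemble honoring the opaque scorer contract (predict closure +
# threshold), for stacking tests that need exact presence geometry.
mk_manual_ensemble <- function(rules) {
  models <- lapply(rules, function(f)
    list(list(algorithm = "manual", rep = 1, predict = f, threshold = 0.5,
              sensitivity = 1, specificity = 1)))
  structure(list(models = models, algorithms = "manual", reps = 1,
                 predictors = c("MAT", "MAT2", "MAP", "MAP2", "temp_seas",
                                "pH", "soilC")),
            class = "sdm_ensemble")
}
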