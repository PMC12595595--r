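# Per-species climate-suitability models (GLM, random forest, regularized
# exponential-family classifier), conversion to binary presence by maximizing
# sensitivity + specificity on a 30% holdout, and stacking presence calls to
# pixel richness.

SDM_PREDICTORS <- c("MAT", "MAT2", "MAP", "MAP2", "temp_seas", "pH", "soilC")

#' Build the seven-predictor design table
#'
#' Adds the quadratic MAT and MAP terms to a covariate table and returns the
#' standard predictor set `MAT, MAT2, MAP, MAP2, temp_seas, pH, soilC`.
#'
#' @param covariates Data frame with columns `MAT, MAP, temp_seas, pH, soilC`.
#' @return Data frame of the seven predictors.
#' @export
sdm_design <- function(covariates) {
  need <- c("MAT", "MAP", "temp_seas", "pH", "soilC")
  miss <- setdiff(need, names(covariates))
  if (length(miss)) stop("covariates lack column(s): ",
                         paste(miss, collapse = ", "))
  out <- covariates[, need, drop = FALSE]
  out$MAT2 <- out$MAT^2
  out$MAP2 <- out$MAP^2
  out[, SDM_PREDICTORS]
}

#' Retain species present in enough operational sites
#'
#' @param occurrence Binary matrix, sites x species.
#' @param min_sites Minimum presence-site count (default 10; the boundary is
#'   inclusive).
#' @return Character vector of retained species (column names).
#' @export
filter_species <- function(occurrence, min_sites = 10) {
  if (length(occurrence) == 0) return(character(0))
  occurrence <- as.matrix(occurrence)
  if (any(!occurrence %in% c(0, 1))) stop("occurrence must be binary")
  colnames(occurrence)[colSums(occurrence) >= min_sites]
}

#' Presence threshold maximizing sensitivity plus specificity
#'
#' Candidate thresholds are the midpoints between consecutive sorted unique
#' scores, plus 0 and 1; a score is called presence when it is >= the
#' threshold. Among maximizers of sensitivity + specificity the smallest
#' candidate is returned.
#'
#' @param scores Predicted probabilities in [0, 1].
#' @param labels Binary observed presences.
#' @return List with `threshold`, `sensitivity`, `specificity`.
#' @export
optimal_threshold <- function(scores, labels) {
  labels <- as.integer(labels > 0)
  if (length(scores) != length(labels)) stop("length mismatch")
  if (length(unique(labels)) < 2)
    stop("both classes must be present to choose a threshold")
  u <- sort(unique(scores))
  cand <- sort(unique(c(0, 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2)))
  np <- sum(labels == 1); nn <- sum(labels == 0)
  best <- NULL
  for (thr in cand) {
    pred <- scores >= thr
    sens <- sum(pred & labels == 1) / np
    spec <- sum(!pred & labels == 0) / nn
    if (is.null(best) || sens + spec > best$sensitivity + best$specificity +
        1e-12) {
      best <- list(threshold = thr, sensitivity = sens, specificity = spec)
    }
  }
  best
}

# Fit one scorer and return a self-contained predictor closure plus metadata.
fit_one_scorer <- function(algorithm, x_train, y_train, seed) {
  if (algorithm == "glm") {
    d <- cbind(y = y_train, x_train)
    fit <- suppressWarnings(stats::glm(y ~ ., data = d,
                                       family = stats::binomial()))
    list(algorithm = algorithm,
         predict = function(newx)
           as.numeric(stats::predict(fit, newdata = newx,
                                     type = "response")))
  } else if (algorithm == "rf") {
    fit <- ranger::ranger(x = x_train, y = factor(y_train, levels = c(0, 1)),
                          probability = TRUE, num.trees = 150,
                          num.threads = 1, seed = seed)
    list(algorithm = algorithm,
         predict = function(newx)
           as.numeric(stats::predict(fit, data = newx,
                                     num.threads = 1)$predictions[, "1"]))
  } else if (algorithm == "maxent") {
    # Regularized exponential-family (ridge logistic) classifier behind the
    # same probability contract as a maximum-entropy model. Folds are
    # stratified so every cross-validation fit keeps both classes.
    xm <- as.matrix(x_train)
    n1 <- sum(y_train == 1); n0 <- sum(y_train == 0)
    if (min(n1, n0) >= 3) {
      k <- min(4L, n1, n0)
      foldid <- integer(length(y_train))
      foldid[y_train == 1] <- sample(rep_len(seq_len(k), n1))
      foldid[y_train == 0] <- sample(rep_len(seq_len(k), n0))
      cv <- suppressWarnings(
        glmnet::cv.glmnet(xm, y_train, family = "binomial", alpha = 0,
                          foldid = foldid, standardize = TRUE))
      lam <- cv$lambda.min
      fit <- cv$glmnet.fit
    } else {
      fit <- suppressWarnings(
        glmnet::glmnet(xm, y_train, family = "binomial", alpha = 0,
                       standardize = TRUE))
      lam <- min(fit$lambda)
    }
    list(algorithm = algorithm,
         predict = function(newx)
           as.numeric(stats::predict(fit, newx = as.matrix(newx),
                                     s = lam, type = "response")))
  } else stop("unknown algorithm: ", algorithm)
}

# Stratified train/validation split keeping both classes on both sides.
stratified_split <- function(y, train_frac) {
  pres <- which(y == 1); abs_ <- which(y == 0)
  n_tp <- max(1L, min(length(pres) - 1L, round(train_frac * length(pres))))
  n_ta <- max(1L, min(length(abs_) - 1L, round(train_frac * length(abs_))))
  train <- c(sample(pres, n_tp), sample(abs_, n_ta))
  list(train = sort(train), valid = sort(setdiff(seq_along(y), train)))
}

#' Fit the per-species SDM ensemble
#'
#' For each retained species and each algorithm x repetition, the occurrence
#' data are split 70/30 (stratified holdout), the scorer is fitted on the
#' training portion, and the presence threshold is chosen on the validation
#' portion by maximizing sensitivity + specificity. Algorithms: logistic
#' regression on the seven predictors (`glm`), a random-forest probability
#' classifier (`rf`), and a ridge-regularized exponential-family classifier
#' standing behind the same probability contract as maximum entropy
#' (`maxent`).
#'
#' @param occurrence Binary matrix, sites x species.
#' @param site_covariates Data frame (one row per site) with `MAT, MAP,
#'   temp_seas, pH, soilC`.
#' @param algorithms Subset of `c("glm", "rf", "maxent")`.
#' @param reps Repetitions per algorithm (default 10).
#' @param train_frac Training fraction of the holdout split (default 0.7).
#' @param min_sites Presence-site filter passed to [filter_species()].
#' @param seed Integer seed; results are deterministic given it.
#' @return Object of class `sdm_ensemble`: per-species lists of fitted
#'   scorers with thresholds and validation sensitivity/specificity.
#' @export
fit_ensemble <- function(occurrence, site_covariates,
                         algorithms = c("glm", "rf", "maxent"),
                         reps = 10, train_frac = 0.7, min_sites = 10,
                         seed = 1) {
  occurrence <- as.matrix(occurrence)
  if (nrow(occurrence) != nrow(site_covariates))
    stop("occurrence and covariates disagree on site count")
  keep <- filter_species(occurrence, min_sites)
  if (length(keep) == 0) stop("no species pass the presence-site filter")
  x <- sdm_design(site_covariates)
  models <- vector("list", length(keep))
  names(models) <- keep
  local_seed(seed, {
    for (sp in keep) {
      y <- occurrence[, sp]
      scorers <- list()
      for (alg in algorithms) {
        for (r in seq_len(reps)) {
          ok <- FALSE
          for (attempt in 1:10) {
            spl <- stratified_split(y, train_frac)
            if (length(unique(y[spl$train])) == 2 &&
                length(unique(y[spl$valid])) == 2) { ok <- TRUE; break }
          }
          if (!ok) {
            warning(sprintf("%s/%s rep %d: split kept losing a class; skipped",
                            sp, alg, r))
            next
          }
          sc <- fit_one_scorer(alg, x[spl$train, , drop = FALSE],
                               y[spl$train],
                               seed = sample.int(.Machine$integer.max, 1))
          val_scores <- sc$predict(x[spl$valid, , drop = FALSE])
          thr <- optimal_threshold(val_scores, y[spl$valid])
          sc$rep <- r
          sc$threshold <- thr$threshold
          sc$sensitivity <- thr$sensitivity
          sc$specificity <- thr$specificity
          scorers[[length(scorers) + 1L]] <- sc
        }
      }
      models[[sp]] <- scorers
    }
  })
  structure(list(models = models, algorithms = algorithms, reps = reps,
                 predictors = SDM_PREDICTORS),
            class = "sdm_ensemble")
}

#' @export
print.sdm_ensemble <- function(x, ...) {
  cat(sprintf("sdm_ensemble: %d species, %d scorers each (%s x %d reps)\n",
              length(x$models), length(x$models[[1]]),
              paste(x$algorithms, collapse = "/"), x$reps))
  invisible(x)
}

#' Stack per-species presence predictions to pixel richness
#'
#' A species is called present in a pixel when a strict majority of its
#' algorithm x repetition binary predictions (probability >= that scorer's
#' threshold) are presences; pixel richness is the count of present species,
#' optionally restricted to a subset (e.g. a guild or genus).
#'
#' @param ensemble An [fit_ensemble()] result.
#' @param grid Single-era `landscape_grid` (see [grid_era()]) or any data
#'   frame with `pixel_id`, `biome` and the climate/soil covariates.
#' @param subset Optional character vector of species to stack.
#' @return A `richness_map` data frame (`pixel_id`, `biome`, `richness`) with
#'   attributes `source = "sdm"`, `era`, `scenario` and `occupancy` (named
#'   per-species count of presence pixels).
#' @export
predict_and_stack <- function(ensemble, grid, subset = NULL) {
  stopifnot(inherits(ensemble, "sdm_ensemble"))
  if (length(unique(grid$era)) > 1)
    stop("grid spans several eras; subset with grid_era() first")
  x <- sdm_design(grid)
  species <- names(ensemble$models)
  if (!is.null(subset)) {
    miss <- setdiff(subset, species)
    if (length(miss)) stop("unknown species: ", paste(miss, collapse = ", "))
    species <- subset
  }
  presence <- matrix(0L, nrow = nrow(grid), ncol = length(species),
                     dimnames = list(grid$pixel_id, species))
  for (sp in species) {
    scorers <- ensemble$models[[sp]]
    votes <- numeric(nrow(grid))
    for (sc in scorers) votes <- votes + (sc$predict(x) >= sc$threshold)
    presence[, sp] <- as.integer(votes > length(scorers) / 2)
  }
  out <- data.frame(pixel_id = grid$pixel_id, biome = grid$biome,
                    richness = as.numeric(rowSums(presence)))
  structure(out, class = c("richness_map", "data.frame"),
            source = "sdm",
            era = unique(grid$era),
            scenario = unique(grid$scenario),
            occupancy = colSums(presence))
}
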