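# Per-pixel diversity change rates, model-based mean loss/gain estimation,
# bivariate climate x land-use overlap classification, and the additive
# combined-effect map.

#' Per-pixel diversity change rates between eras
#'
#' `rate = (S_future - S_current) / S_current`; pixels are classed as loss
#' when rate < -epsilon, gain when rate > epsilon, otherwise none. Pixels
#' with zero current richness get `NA` rates (class "undefined") and are
#' excluded from summaries.
#'
#' @param current,future `richness_map` objects on the same pixel set and
#'   from the same source.
#' @param driver Label for the driver behind the comparison ("climate",
#'   "landuse" or "combined").
#' @param epsilon Half-width of the no-change band (default 1e-6).
#' @return A `change_map` data frame: `pixel_id, biome, driver, rate, class`.
#' @export
change_rate_map <- function(current, future, driver = "climate",
                            epsilon = 1e-6) {
  if (!setequal(current$pixel_id, future$pixel_id))
    stop("current and future pixel sets differ")
  src_c <- attr(current, "source"); src_f <- attr(future, "source")
  if (!is.null(src_c) && !is.null(src_f) && !identical(src_c, src_f))
    stop("current and future maps come from different sources")
  cur <- current[order(current$pixel_id), ]
  fut <- future[match(cur$pixel_id, future$pixel_id), ]
  rate <- ifelse(cur$richness > 0,
                 (fut$richness - cur$richness) / cur$richness, NA_real_)
  out <- data.frame(pixel_id = cur$pixel_id, biome = cur$biome,
                    driver = driver, rate = rate,
                    class = classify_rate(rate, epsilon))
  structure(out, class = c("change_map", "data.frame"), epsilon = epsilon)
}

classify_rate <- function(rate, epsilon) {
  ifelse(is.na(rate), "undefined",
         ifelse(rate < -epsilon, "loss",
                ifelse(rate > epsilon, "gain", "none")))
}

#' Model-based mean diversity loss and gain rates
#'
#' Fits separate linear mixed models to the loss-class and gain-class pixels
#' (`rate ~ 0 + biome` fixed effects, coarse spatial block random intercept)
#' and reports per-biome and cross-biome means with 95% Wald CIs, the net
#' change rate (arithmetic mean of all defined rates, i.e. determined with
#' the raw data), and the loss/gain/none pixel proportions. When the random
#' effect cannot be estimated (e.g. a single block) the model degrades to
#' ordinary least squares, flagged in the output.
#'
#' @param changes A [change_rate_map()] result.
#' @param block_ids Coarse spatial block id per pixel (same order as
#'   `changes`); defaults to a single block.
#' @return List with `loss` and `gain` (data frames of per-biome and "all"
#'   estimates with CIs; biomes with no pixels in a class are absent, not
#'   zero), `net`, `proportions` (loss/gain/none over defined pixels),
#'   `n_undefined` and `fallback`.
#' @export
mean_loss_gain <- function(changes, block_ids = NULL) {
  if (is.null(block_ids)) block_ids <- rep("b1", nrow(changes))
  if (length(block_ids) != nrow(changes))
    stop("block_ids must have one entry per pixel")
  d <- data.frame(rate = changes$rate, biome = changes$biome,
                  class = changes$class, block = block_ids)
  defined <- d[d$class != "undefined", , drop = FALSE]
  fallback <- FALSE
  fit_class <- function(sub) {
    if (nrow(sub) == 0) return(NULL)
    sub$biome <- factor(sub$biome)
    biome_fml <- if (nlevels(sub$biome) > 1) "0 + biome" else "1"
    use_lmm <- length(unique(sub$block)) > 1 &&
      nrow(sub) > nlevels(sub$biome) + 2
    fit <- NULL
    if (use_lmm)
      fit <- tryCatch(
        suppressMessages(lme4::lmer(
          stats::as.formula(paste("rate ~", biome_fml, "+ (1 | block)")),
          data = sub)),
        error = function(e) NULL)
    if (is.null(fit)) {
      fallback <<- TRUE
      fit <- stats::lm(stats::as.formula(paste("rate ~", biome_fml)),
                       data = sub)
      sm <- summary(fit)$coefficients
    } else {
      sm <- stats::coef(summary(fit))
    }
    if (nlevels(sub$biome) == 1)
      rownames(sm) <- paste0("biome", levels(sub$biome))
    est <- data.frame(
      biome = sub("^biome", "", rownames(sm)),
      mean_rate = sm[, "Estimate"],
      ci_lo = sm[, "Estimate"] - stats::qnorm(0.975) * sm[, "Std. Error"],
      ci_hi = sm[, "Estimate"] + stats::qnorm(0.975) * sm[, "Std. Error"],
      n = as.integer(table(sub$biome)[sub("^biome", "", rownames(sm))]),
      row.names = NULL)
    # Cross-biome mean: intercept-only model on the same subset.
    all_fit <- if (length(unique(sub$block)) > 1)
      tryCatch(suppressMessages(lme4::lmer(rate ~ 1 + (1 | block),
                                           data = sub)),
               error = function(e) stats::lm(rate ~ 1, data = sub))
    else stats::lm(rate ~ 1, data = sub)
    sma <- if (inherits(all_fit, "lm")) summary(all_fit)$coefficients else
      stats::coef(summary(all_fit))
    rbind(est, data.frame(
      biome = "all", mean_rate = sma[1, "Estimate"],
      ci_lo = sma[1, "Estimate"] - stats::qnorm(0.975) * sma[1, "Std. Error"],
      ci_hi = sma[1, "Estimate"] + stats::qnorm(0.975) * sma[1, "Std. Error"],
      n = nrow(sub)))
  }
  loss <- fit_class(defined[defined$class == "loss", , drop = FALSE])
  gain <- fit_class(defined[defined$class == "gain", , drop = FALSE])
  n_def <- nrow(defined)
  props <- if (n_def > 0)
    c(loss = sum(defined$class == "loss") / n_def,
      gain = sum(defined$class == "gain") / n_def,
      none = sum(defined$class == "none") / n_def)
  else c(loss = NA_real_, gain = NA_real_, none = NA_real_)
  list(loss = loss, gain = gain,
       net = if (n_def > 0) mean(defined$rate) else NA_real_,
       proportions = props,
       n_undefined = sum(d$class == "undefined"),
       fallback = fallback)
}

#' Bivariate overlap of climate- and land-use-driven change
#'
#' Labels each pixel with the pair (climate class, land-use class) and
#' reports, per biome, the proportion of pixels where both drivers cause
#' losses and where both cause gains.
#'
#' @param climate,landuse [change_rate_map()] results on the same pixel set.
#' @return List with `pixels` (per-pixel bivariate labels), `table`
#'   (cross-tabulation of the two classes) and `by_biome` (per-biome
#'   both-loss / both-gain proportions over pixels defined in both maps).
#' @export
classify_overlap <- function(climate, landuse) {
  if (!setequal(climate$pixel_id, landuse$pixel_id))
    stop("climate and land-use pixel sets differ")
  cl <- climate[order(climate$pixel_id), ]
  lu <- landuse[match(cl$pixel_id, landuse$pixel_id), ]
  px <- data.frame(pixel_id = cl$pixel_id, biome = cl$biome,
                   climate_class = cl$class, landuse_class = lu$class)
  px$overlap <- paste(px$climate_class, px$landuse_class, sep = "/")
  def <- px[px$climate_class != "undefined" & px$landuse_class != "undefined",
            , drop = FALSE]
  by_biome <- do.call(rbind, lapply(split(def, def$biome), function(g) {
    data.frame(biome = g$biome[1], n = nrow(g),
               both_loss = mean(g$climate_class == "loss" &
                                  g$landuse_class == "loss"),
               both_gain = mean(g$climate_class == "gain" &
                                  g$landuse_class == "gain"))
  }))
  rownames(by_biome) <- NULL
  list(pixels = px,
       table = table(climate = def$climate_class,
                     landuse = def$landuse_class),
       by_biome = by_biome)
}

#' Additive combined climate + land-use change map
#'
#' Under the simple-additivity assumption the combined per-pixel rate is the
#' sum of the climate-driven and land-use-driven rates, re-classified with
#' the same no-change band.
#'
#' @param climate,landuse [change_rate_map()] results on the same pixel set.
#' @param epsilon No-change band half-width.
#' @return A `change_map` with `driver = "combined"`.
#' @export
combined_change <- function(climate, landuse, epsilon = 1e-6) {
  if (!setequal(climate$pixel_id, landuse$pixel_id))
    stop("climate and land-use pixel sets differ")
  cl <- climate[order(climate$pixel_id), ]
  lu <- landuse[match(cl$pixel_id, landuse$pixel_id), ]
  rate <- cl$rate + lu$rate
  out <- data.frame(pixel_id = cl$pixel_id, biome = cl$biome,
                    driver = "combined", rate = rate,
                    class = classify_rate(rate, epsilon))
  structure(out, class = c("change_map", "data.frame"), epsilon = epsilon)
}
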