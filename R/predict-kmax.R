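## Trait-based prediction of Kmax with extreme gradient boosting:
## feature assembly with taxonomic fallback, two-step hyperparameter
## tuning under a gamma loss, holdout evaluation, and bootstrap
## prediction intervals.

## fixed categorical vocabularies so train/test matrices always align
.waterPositions <- c("benthic", "demersal", "pelagic")

## Fill species-level trait gaps from genus then family means.
.fallbackTrait <- function(values, genus, family) {
  lvl <- rep("species", length(values))
  na <- is.na(values)
  if (any(na)) {
    gmean <- tapply(values, genus, mean, na.rm = TRUE)
    values[na] <- gmean[genus[na]]
    lvl[na & !is.na(values)] <- "genus"
    na <- is.na(values)
  }
  if (any(na)) {
    fmean <- tapply(values, family, mean, na.rm = TRUE)
    values[na] <- fmean[family[na]]
    lvl[na & !is.na(values)] <- "family"
  }
  list(values = values, level = lvl)
}

#' Assemble the Kmax modelling table from growth records and traits
#'
#' Standardizes each record's asymptotic length to total length, computes
#' the target Kmax against the species maximum length, and attaches the six
#' predictors: maximum body size (TL cm), trophic level, maximum depth (m),
#' water-column position, SST (deg C), and aging method. Numeric traits
#' missing at the species level are imputed from the genus mean, then the
#' family mean; the \code{fallback_level} column records the deepest level
#' used per record. An unresolvable trait is an error.
#'
#' @param records growth-record table (columns \code{species_id},
#'   \code{l_inf_reported}, \code{length_type}, \code{k}, \code{sst},
#'   \code{aging_method})
#' @param traits species trait table (columns \code{species_id},
#'   \code{genus}, \code{family}, \code{lmax_cm}, \code{trophic_level},
#'   \code{max_depth_m}, \code{water_position})
#' @param conversions length-length conversion table for
#'   \code{\link{standardizeLength}} (only needed when non-TL records exist)
#' @return data.frame with \code{kmax}, the six predictors,
#'   \code{species_id} and \code{fallback_level}
#' @export
assembleFeatures <- function(records, traits, conversions = NULL) {
  assertColumns(records, c("species_id", "l_inf_reported", "length_type",
                           "k", "sst", "aging_method"), "record table")
  assertColumns(traits, c("species_id", "genus", "family", "lmax_cm",
                          "trophic_level", "max_depth_m", "water_position"),
                "trait table")
  pos <- match(records$species_id, traits$species_id)
  if (anyNA(pos))
    stop("records for species missing from the trait table: ",
         paste(unique(records$species_id[is.na(pos)]), collapse = ", "))
  genus <- traits$genus[pos]; family <- traits$family[pos]
  lmax <- .fallbackTrait(traits$lmax_cm[pos], genus, family)
  trop <- .fallbackTrait(traits$trophic_level[pos], genus, family)
  dep <- .fallbackTrait(traits$max_depth_m[pos], genus, family)
  lvl <- c("species", "genus", "family")
  fallback <- lvl[pmax(match(lmax$level, lvl), match(trop$level, lvl),
                       match(dep$level, lvl))]
  unresolved <- is.na(lmax$values) | is.na(trop$values) | is.na(dep$values)
  if (any(unresolved))
    stop("traits unresolved after family fallback for: ",
         paste(unique(records$species_id[unresolved]), collapse = ", "))
  l_inf_tl <- standardizeLength(records$l_inf_reported, records$length_type,
                                records$species_id, conversions)
  kmax <- computeKmax(l_inf_tl, records$k, lmax$values)
  data.frame(
    kmax = kmax,
    lmax_cm = lmax$values,
    trophic_level = trop$values,
    max_depth_m = dep$values,
    water_position = factor(traits$water_position[pos],
                            levels = .waterPositions),
    sst = records$sst,
    aging_method = factor(records$aging_method, levels = agingMethods()),
    species_id = records$species_id,
    fallback_level = fallback,
    stringsAsFactors = FALSE)
}

## One-hot model matrix with fixed levels; shared by train and predict.
.featureMatrix <- function(df) {
  num <- cbind(lmax_cm = df$lmax_cm, trophic_level = df$trophic_level,
               max_depth_m = df$max_depth_m, sst = df$sst)
  wp <- outer(as.character(df$water_position), .waterPositions, `==`) * 1
  colnames(wp) <- paste0("water_position.", .waterPositions)
  am <- outer(as.character(df$aging_method), agingMethods(), `==`) * 1
  colnames(am) <- paste0("aging_method.", agingMethods())
  cbind(num, wp, am)
}

.randomGrid <- function(n, seed) {
  set.seed(seed)
  data.frame(eta = stats::runif(n, 0.1, 0.9),
             gamma = stats::runif(n, 0.1, 0.9),
             max_depth = sample(c(5L, 10L, 15L), n, replace = TRUE),
             subsample = stats::runif(n, 0.1, 0.9))
}

.refineGrid <- function(best, n, seed) {
  set.seed(seed)
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  data.frame(
    eta = clamp(best$eta + stats::runif(n, -0.08, 0.08), 0.01, 1),
    gamma = clamp(best$gamma + stats::runif(n, -0.08, 0.08), 0.01, 1),
    max_depth = sample(c(5L, 10L, 15L), n, replace = TRUE,
                       prob = 0.1 + 0.8 * (c(5L, 10L, 15L) == best$max_depth)),
    subsample = clamp(best$subsample + stats::runif(n, -0.08, 0.08), 0.05, 1))
}

.fitOne <- function(xtr, ytr, xva, yva, par, nrounds, esr) {
  dtr <- xgboost::xgb.DMatrix(xtr, label = ytr)
  dva <- xgboost::xgb.DMatrix(xva, label = yva)
  m <- xgboost::xgb.train(
    params = list(objective = "reg:gamma", eval_metric = "gamma-nloglik",
                  eta = par$eta, gamma = par$gamma,
                  max_depth = par$max_depth, subsample = par$subsample,
                  nthread = 1),
    data = dtr, nrounds = nrounds, evals = list(valid = dva),
    early_stopping_rounds = esr, verbose = 0)
  log <- attributes(m)$evaluation_log
  list(model = m, loss = min(log$valid_gamma_nloglik))
}

#' Tune and fit the Kmax boosting model
#'
#' Two-step hyperparameter search under a gamma loss: step 1 draws a coarse
#' random grid over the learning rate eta (0.1-0.9), the regularising
#' parameter gamma (0.1-0.9), maximum tree depth (5, 10 or 15) and the
#' subsample rate (0.1-0.9); step 2 refines locally around the step-1
#' optimum. The data are split 80/20 into build and test sets; tuning
#' minimizes the gamma negative log-likelihood on a validation fifth of the
#' build set, and the winning model is refit on the full build set.
#'
#' @param features table from \code{\link{assembleFeatures}} (a constant
#'   \code{kmax} target triggers a warning but fitting proceeds)
#' @param grid_size number of candidates per tuning step
#' @param nrounds maximum boosting rounds (early stopping after 20
#'   stagnant rounds)
#' @param seed integer seed controlling the split and both grids
#' @return list of class \code{"kmax_model"}: \code{model} (the booster),
#'   \code{params} (chosen hyperparameters), \code{grids} (both logged
#'   grids with losses), \code{test} (the held-out 20\%), \code{features}
#'   (column names), \code{seed}
#' @export
tuneAndFit <- function(features, grid_size = 12, nrounds = 200, seed = 1L) {
  if (stats::sd(features$kmax) == 0)
    warning("kmax target is constant; fit proceeds but is degenerate")
  if (any(features$kmax <= 0)) stop("kmax must be positive for a gamma loss")
  set.seed(deriveSeed(seed, "split"))
  n <- nrow(features)
  test_idx <- sample(n, max(1, round(0.2 * n)))
  build <- features[-test_idx, , drop = FALSE]
  test <- features[test_idx, , drop = FALSE]
  nb <- nrow(build)
  val_idx <- sample(nb, max(1, round(0.2 * nb)))
  xb <- .featureMatrix(build); yb <- build$kmax
  xtr <- xb[-val_idx, , drop = FALSE]; ytr <- yb[-val_idx]
  xva <- xb[val_idx, , drop = FALSE]; yva <- yb[val_idx]
  g1 <- .randomGrid(grid_size, deriveSeed(seed, "grid1"))
  g1$loss <- vapply(seq_len(nrow(g1)), function(i)
    .fitOne(xtr, ytr, xva, yva, g1[i, ], nrounds, 20)$loss, numeric(1))
  best1 <- g1[which.min(g1$loss), ]
  g2 <- .refineGrid(best1, grid_size, deriveSeed(seed, "grid2"))
  g2$loss <- vapply(seq_len(nrow(g2)), function(i)
    .fitOne(xtr, ytr, xva, yva, g2[i, ], nrounds, 20)$loss, numeric(1))
  cand <- rbind(g1, g2)
  best <- cand[which.min(cand$loss), ]
  fit <- .fitOne(xb, yb, xva, yva, best, nrounds, 20)
  structure(list(model = fit$model, params = best[, 1:4],
                 grids = list(step1 = g1, step2 = g2),
                 test = test, features = colnames(xb), seed = seed),
            class = "kmax_model")
}

#' Predict Kmax for new feature rows
#' @param object a \code{"kmax_model"}
#' @param newdata feature data.frame (same columns as the training table)
#' @param ... unused
#' @return predicted Kmax (yr^-1), clipped below at 1e-4
#' @export
predict.kmax_model <- function(object, newdata, ...) {
  p <- stats::predict(object$model, .featureMatrix(newdata))
  pmax(p, 1e-4)
}

#' Holdout evaluation of a Kmax model
#'
#' Bias is the mean of (predicted - observed) on the held-out test set;
#' precision is the R^2 of the least-squares line of log(predicted) against
#' log(observed).
#'
#' @param object a \code{"kmax_model"}
#' @param test test table; defaults to the 20\% held out at fitting time
#' @param predictions optional precomputed predictions for \code{test}
#'   (bypasses the model; useful for checking the metric definitions)
#' @return list with \code{bias} and \code{r2_loglog}
#' @export
evaluateHoldout <- function(object, test = object$test, predictions = NULL) {
  if (is.null(test) || !nrow(test)) stop("empty test set")
  pred <- if (is.null(predictions)) predict(object, test) else predictions
  obs <- test$kmax
  r2 <- if (stats::sd(log(obs)) == 0 || stats::sd(log(pred)) == 0) NA_real_
        else summary(stats::lm(log(pred) ~ log(obs)))$r.squared
  list(bias = mean(pred - obs), r2_loglog = r2)
}

#' Bootstrap the fit-and-predict process into prediction intervals
#'
#' Repeats the whole process \code{n_boot} times: resample the modelling
#' table with replacement, re-split 80/20, refit at hyperparameters drawn
#' from the step-2 neighbourhood of the reference fit (re-tuning is
#' restricted to that neighbourhood to keep the bootstrap tractable), and
#' predict the targets. Per target the empirical 5\%, 50\% and 95\%
#' quantiles across bootstraps form the 90\% predicted quantile range;
#' per-iteration holdout bias/R^2 and variable importances are retained.
#'
#' @param features modelling table from \code{\link{assembleFeatures}}
#' @param targets data.frame of prediction targets with the six predictor
#'   columns plus \code{species_id}
#' @param n_boot number of bootstrap iterations (>= 2)
#' @param reference a fitted \code{"kmax_model"} supplying the tuning
#'   neighbourhood; fitted on the fly when NULL
#' @param nrounds maximum boosting rounds per refit
#' @param seed integer seed
#' @return a \code{\link{KmaxPredictions}}; attributes \code{"metrics"}
#'   (per-iteration bias and r2) and \code{"importance"} (per-iteration
#'   gain shares)
#' @export
bootstrapPredictIntervals <- function(features, targets, n_boot = 1000,
                                      reference = NULL, nrounds = 100,
                                      seed = 1L) {
  if (n_boot < 2) stop("n_boot must be >= 2")
  if (is.null(reference))
    reference <- tuneAndFit(features, grid_size = 8, nrounds = nrounds,
                            seed = seed)
  xt <- .featureMatrix(targets)
  n <- nrow(features)
  pred_mat <- matrix(NA_real_, n_boot, nrow(targets))
  bias <- numeric(n_boot); r2 <- numeric(n_boot)
  imp <- vector("list", n_boot)
  for (bt in seq_len(n_boot)) {
    set.seed(deriveSeed(seed, paste0("boot", bt)))
    rows <- sample(n, n, replace = TRUE)
    bf <- features[rows, , drop = FALSE]
    test_idx <- sample(n, max(1, round(0.2 * n)))
    build <- bf[-test_idx, , drop = FALSE]
    test <- bf[test_idx, , drop = FALSE]
    par <- .refineGrid(reference$params, 1, deriveSeed(seed, paste0("par", bt)))
    xb <- .featureMatrix(build)
    nb <- nrow(build)
    val_idx <- sample(nb, max(1, round(0.2 * nb)))
    fit <- .fitOne(xb[-val_idx, , drop = FALSE], build$kmax[-val_idx],
                   xb[val_idx, , drop = FALSE], build$kmax[val_idx],
                   par, nrounds, 15)
    p_test <- pmax(stats::predict(fit$model, .featureMatrix(test)), 1e-4)
    bias[bt] <- mean(p_test - test$kmax)
    r2[bt] <- if (stats::sd(log(test$kmax)) > 0 && stats::sd(log(p_test)) > 0)
      summary(stats::lm(log(p_test) ~ log(test$kmax)))$r.squared else NA_real_
    pred_mat[bt, ] <- pmax(stats::predict(fit$model, xt), 1e-4)
    it <- xgboost::xgb.importance(model = fit$model)
    gain <- it$Gain
    names(gain) <- it$Feature
    imp[[bt]] <- gain
  }
  qs <- apply(pred_mat, 2, stats::quantile, probs = c(0.05, 0.5, 0.95))
  out <- data.frame(species_id = targets$species_id,
                    sst = if ("sst" %in% names(targets)) targets$sst else NA,
                    q05 = qs[1, ], median = qs[2, ], q95 = qs[3, ],
                    n_boot = n_boot, stringsAsFactors = FALSE)
  pred <- new("KmaxPredictions", predictions = out)
  attr(pred, "metrics") <- data.frame(bias = bias, r2_loglog = r2)
  attr(pred, "importance") <- imp
  pred
}

#' Variable importance aggregated across bootstrap models
#'
#' Collapses one-hot columns back to their parent predictor, expresses gain
#' as percentages summing to 100 per model, and reports the median across
#' models.
#'
#' @param importances list of named gain vectors (one per fitted model),
#'   e.g. the \code{"importance"} attribute of
#'   \code{\link{bootstrapPredictIntervals}}
#' @return data.frame with \code{predictor} and \code{importance_pct},
#'   ordered decreasing
#' @export
variableImportance <- function(importances) {
  if (!length(importances)) stop("need at least one fitted model")
  preds <- c("lmax_cm", "sst", "max_depth_m", "trophic_level",
             "aging_method", "water_position")
  per_model <- vapply(importances, function(g) {
    parent <- sub("\\..*$", "", names(g))
    agg <- tapply(g, parent, sum)
    v <- stats::setNames(numeric(length(preds)), preds)
    v[names(agg)] <- agg
    100 * v / sum(v)
  }, numeric(length(preds)))
  med <- apply(as.matrix(per_model), 1, stats::median)
  out <- data.frame(predictor = preds, importance_pct = med)
  out[order(-out$importance_pct), ]
}
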