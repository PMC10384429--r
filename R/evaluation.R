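## Model-comparison metrics and the report harness: squared Pearson
## correlation (the headline "R^2"), 1 - SSE/SST alongside, and the signed
## mean residual.

#' Squared Pearson correlation between observed and predicted values
#'
#' Affine-invariant in the predictions and bounded by 1. The coefficient of
#' determination 1 - SSE/SST is available via \code{rSquaredSSE}.
#'
#' @param obs numeric vector of observed values.
#' @param pred numeric vector of predictions, same length (>= 2).
#' @return numeric(1) in [0, 1].
#' @export
rSquared <- function(obs, pred) {
  obs <- as.numeric(obs); pred <- as.numeric(pred)
  stopifnot(length(obs) == length(pred), length(obs) >= 2L)
  if (sd(obs) == 0) stop("undefined correlation: observed values are constant")
  if (sd(pred) == 0) stop("undefined correlation: predictions are constant")
  cor(obs, pred)^2
}

#' @rdname rSquared
#' @export
rSquaredSSE <- function(obs, pred) {
  obs <- as.numeric(obs); pred <- as.numeric(pred)
  stopifnot(length(obs) == length(pred), length(obs) >= 2L)
  sst <- sum((obs - mean(obs))^2)
  if (sst == 0) stop("undefined: observed values are constant")
  1 - sum((obs - pred)^2) / sst
}

#' Signed mean residual
#'
#' mean(pred - obs): positive when the model over-predicts on average.
#'
#' @param obs,pred numeric vectors of equal, nonzero length.
#' @return numeric(1).
#' @export
meanError <- function(obs, pred) {
  obs <- as.numeric(obs); pred <- as.numeric(pred)
  if (!length(obs) || length(obs) != length(pred))
    stop("obs and pred must be nonempty vectors of equal length")
  mean(pred - obs)
}

#' Specify one model for the comparison harness
#'
#' @param name row label in the report.
#' @param technique "LR" (linear a/b regression), "MNNR" (network) or
#'   "MNFR" (fuzzy).
#' @param inputs character vector of feature-table columns the model reads:
#'   one column for LR, any set for MNNR, the three fuzzy inputs
#'   (default L_feat, a_feat, b_feat) for MNFR.
#' @param ... technique hyperparameters: \code{hiddenUnits}/\code{epochs}
#'   for MNNR, \code{order}/\code{tnorm} for MNFR.
#' @return a list of class "modelSpec".
#' @export
modelSpec <- function(name, technique = c("LR", "MNNR", "MNFR"),
                      inputs, ...) {
  technique <- match.arg(technique)
  structure(list(name = name, technique = technique, inputs = inputs,
                 hyper = list(...)), class = "modelSpec")
}

#' Default model roster: the fuzzy estimator plus both baselines
#' @return list of \code{modelSpec}s.
#' @export
defaultModelSpecs <- function() {
  list(
    modelSpec("fuzzy_Lab", "MNFR", c("L_feat", "a_feat", "b_feat")),
    modelSpec("ann_Lab", "MNNR", c("L_feat", "a_feat", "b_feat")),
    modelSpec("lr_ab", "LR", "ratio_ab"))
}

## fit one spec on a feature table; returns the fitted model object
fitSpec <- function(spec, ds, seed = 1L) {
  y <- ds$lycopene_ppm
  switch(spec$technique,
    LR = {
      stopifnot(length(spec$inputs) == 1L)
      m <- fitLinearAB(ds[[spec$inputs]], y)
      m@inputNames <- spec$inputs
      m
    },
    MNNR = {
      hy <- spec$hyper
      trainMLP(ds[, spec$inputs, drop = FALSE], y,
               hiddenUnits = hy$hiddenUnits %||% 10L,
               epochs = hy$epochs %||% 10L, seed = seed)
    },
    MNFR = {
      hy <- spec$hyper
      m <- buildDefaultModel(order = hy$order %||% "one",
                             tnorm = hy$tnorm %||% "product")
      m@inputNames <- spec$inputs
      fitConsequents(m, as.matrix(ds[, spec$inputs, drop = FALSE]), y)
    },
    stop("unknown technique: ", spec$technique))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit and compare a roster of models on a labeled feature table
#'
#' Each spec is fitted on the full table and evaluated on it (training-set
#' metrics, the study protocol for small HPLC-labeled sets); leave-one-out
#' cross-validated metrics can be reported alongside. The report is sorted
#' by decreasing headline R^2.
#'
#' @param ds data.frame in the feature-table dialect with a
#'   \code{lycopene_ppm} column.
#' @param specs list of \code{\link{modelSpec}}s (default
#'   \code{defaultModelSpecs()}).
#' @param seed RNG seed recorded in the report and passed to trainable
#'   models.
#' @param loo if TRUE, add leave-one-out columns r_squared_loo /
#'   error_mean_loo.
#' @return a data.frame (one row per spec) with columns name, technique,
#'   input, r_squared (squared Pearson), r_squared_sse, error_mean; the
#'   fitted models are attached as \code{attr(, "models")} and the
#'   evaluation policy as \code{attr(, "policy")}.
#' @export
compareModels <- function(ds, specs = defaultModelSpecs(), seed = 1L,
                          loo = FALSE) {
  stopifnot(is.data.frame(ds), "lycopene_ppm" %in% names(ds))
  y <- ds$lycopene_ppm
  models <- list()
  rows <- lapply(specs, function(spec) {
    m <- fitSpec(spec, ds, seed = seed)
    models[[spec$name]] <<- m
    pred <- predict(m, ds)
    row <- data.frame(
      name = spec$name, technique = spec$technique,
      input = paste(spec$inputs, collapse = "+"),
      r_squared = rSquared(y, pred), r_squared_sse = rSquaredSSE(y, pred),
      error_mean = meanError(y, pred))
    if (loo) {
      cvPred <- vapply(seq_len(nrow(ds)), function(i) {
        mi <- fitSpec(spec, ds[-i, , drop = FALSE], seed = seed)
        predict(mi, ds[i, , drop = FALSE])
      }, 0)
      row$r_squared_loo <- rSquared(y, cvPred)
      row$error_mean_loo <- meanError(y, cvPred)
    }
    row
  })
  rep <- do.call(rbind, rows)
  rep <- rep[order(-rep$r_squared), , drop = FALSE]
  rownames(rep) <- NULL
  attr(rep, "models") <- models
  attr(rep, "policy") <- list(split = "training-set metrics (full table)",
                              loo = loo, seed = seed)
  rep
}

#' Pretty-print an evaluation report
#'
#' @param rep report from \code{\link{compareModels}}.
#' @param path optional CSV path; when given the table is also written there.
#' @return \code{rep}, invisibly.
#' @export
printReport <- function(rep, path = NULL) {
  cat(sprintf("%-12s %-9s %-22s %-10s %-12s\n",
              "Model", "Technique", "Input", "R^2", "Error Mean"))
  for (i in seq_len(nrow(rep)))
    cat(sprintf("%-12s %-9s %-22s %-10.4f %-12.4g\n",
                rep$name[i], rep$technique[i], rep$input[i],
                rep$r_squared[i], rep$error_mean[i]))
  if (!is.null(path))
    utils::write.csv(rep, path, row.names = FALSE)
  invisible(rep)
}
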