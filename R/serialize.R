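## JSON model serialization. Numbers are written with 17 significant digits
## (the IEEE-754 double round-trip precision) so a write/read cycle
## reproduces every coefficient bit-exactly.

.mfAsList <- function(mf) {
  list(name = mf@name, left = mf@left, peak = mf@peak, right = mf@right,
       domain = mf@domain)
}

.modelAsList <- function(model) {
  if (is(model, "TakagiSugenoModel")) {
    list(type = "TakagiSugenoModel",
         variables = lapply(model@variables, function(v)
           list(name = v@name, domain = v@domain,
                mfs = lapply(v@mfs, .mfAsList))),
         antecedents = model@antecedents,
         coefficients = model@coefficients,
         tnorm = model@tnorm, order = model@order,
         inputNames = model@inputNames)
  } else if (is(model, "MLPModel")) {
    list(type = "MLPModel", W1 = model@W1, b1 = model@b1, W2 = model@W2,
         b2 = model@b2, center = model@center, scale = model@scale,
         lossTrace = model@lossTrace, inputNames = model@inputNames,
         seed = model@seed)
  } else if (is(model, "LinearABModel")) {
    list(type = "LinearABModel", slope = model@slope,
         intercept = model@intercept, inputNames = model@inputNames)
  } else stop("cannot serialize object of class ", class(model))
}

#' @describeIn writeModel JSON serialization of the three model kinds
#' @export
setMethod("writeModel", "ANY", function(model, path) {
  jsonlite::write_json(.modelAsList(model), path, auto_unbox = TRUE,
                       digits = I(17), pretty = TRUE)
  invisible(path)
})

#' Read a model serialized by \code{writeModel}
#'
#' @param path JSON file path.
#' @return a \code{TakagiSugenoModel}, \code{MLPModel} or
#'   \code{LinearABModel}, identical to the object written.
#' @export
readModel <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  num <- function(v) as.numeric(unlist(v))
  chr <- function(v) as.character(unlist(v))
  mat <- function(v) do.call(rbind, lapply(v, num))  # row-lists -> matrix
  switch(x$type,
    TakagiSugenoModel = {
      vars <- lapply(x$variables, function(v) {
        mfs <- lapply(v$mfs, function(m)
          TriangularMF(m$name, m$left, m$peak, m$right, num(m$domain)))
        FuzzyVariable(v$name, mfs, num(v$domain))
      })
      ant <- mat(x$antecedents)
      storage.mode(ant) <- "integer"
      dimnames(ant) <- list(NULL, vapply(vars, function(v) v@name, ""))
      new("TakagiSugenoModel", variables = vars, antecedents = ant,
          coefficients = mat(x$coefficients), tnorm = x$tnorm,
          order = x$order, inputNames = chr(x$inputNames))
    },
    MLPModel = new("MLPModel", W1 = mat(x$W1), b1 = num(x$b1),
                   W2 = mat(x$W2), b2 = num(x$b2), center = num(x$center),
                   scale = num(x$scale), lossTrace = num(x$lossTrace),
                   inputNames = chr(x$inputNames), seed = as.integer(x$seed)),
    LinearABModel = new("LinearABModel", slope = num(x$slope),
                        intercept = num(x$intercept),
                        inputNames = chr(x$inputNames)),
    stop("unknown model type in ", path, ": ", x$type))
}
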