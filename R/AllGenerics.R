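#' Evaluate a membership function
#'
#' @param mf a \code{TriangularMF}.
#' @param x numeric vector of input values.
#' @return numeric vector of degrees in [0, 1]; 0 outside the domain.
#' @export
setGeneric("membershipDegree", function(mf, x) standardGeneric("membershipDegree"))

#' Rule firing strengths
#'
#' @param model a \code{TakagiSugenoModel}.
#' @param x numeric vector with one value per model variable.
#' @return numeric vector of weights w, one per rule, each in [0, 1].
#' @export
setGeneric("ruleStrengths", function(model, x) standardGeneric("ruleStrengths"))

#' Fit Sugeno consequents by linear least squares (the ANFIS LSE step)
#'
#' @param model a \code{TakagiSugenoModel} with fixed premise MFs.
#' @param X numeric matrix of inputs, one row per sample.
#' @param y numeric vector of lycopene values (ppm).
#' @return the model with fitted \code{coefficients} and a \code{fitInfo}
#'   list (residual norm, design rank, rejected samples).
#' @export
setGeneric("fitConsequents", function(model, X, y) standardGeneric("fitConsequents"))

#' Number of rules in a fuzzy model
#' @param model a \code{TakagiSugenoModel}.
#' @return integer(1).
#' @export
setGeneric("nRules", function(model) standardGeneric("nRules"))

#' Total number of membership functions across all variables
#' @param model a \code{TakagiSugenoModel}.
#' @return integer(1).
#' @export
setGeneric("nMemberships", function(model) standardGeneric("nMemberships"))

#' Number of connected foreground components
#' @param x a \code{FruitMask}.
#' @return integer(1).
#' @export
setGeneric("nComponents", function(x) standardGeneric("nComponents"))

#' Component pixel areas
#' @param x a \code{FruitMask}.
#' @return integer vector, one area per component.
#' @export
setGeneric("componentAreas", function(x) standardGeneric("componentAreas"))

#' Serialize a fitted model to JSON
#'
#' Writes a JSON document that round-trips bit-exactly through
#' \code{readModel}.
#'
#' @param model a \code{TakagiSugenoModel}, \code{MLPModel} or
#'   \code{LinearABModel}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
setGeneric("writeModel", function(model, path) standardGeneric("writeModel"))
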