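## Takagi-Sugeno fuzzy inference for lycopene estimation. Three linguistic
## input variables over non-standard Lab-derived domains, eight triangular
## membership functions in total, and a full-grid rule base of 18 rules whose
## linear consequents are fitted by least squares (the ANFIS hybrid step).
##
## Membership breakpoints (all configurable through TriangularMF):
##   L on (0, 2558.3]: Low  = shoulder falling 1 -> 0 over [0, 1285]
##                     Medium = triangle (10.7, 1285, 2558.3)
##                     High = shoulder rising 0 -> 1 over [1285, 2558.3]
##   a on (0, 1736]:   Low  = shoulder falling over [0, 753]
##                     Medium = triangle (0, 753, 1736)
##                     High = shoulder rising over [753, 1736]
##   b on (-210, 358]: Low  = shoulder falling over [210, 358] (1 below 210,
##                     where the raw line (358-b)/148 exceeds 1 and is clipped)
##                     High = shoulder rising over [210, 358]

#' Construct a triangular membership function
#'
#' @param name label, e.g. "Low_a".
#' @param left,peak,right breakpoints with left <= peak <= right;
#'   \code{left == peak} makes a left shoulder (degree 1 for x <= peak),
#'   \code{peak == right} a right shoulder.
#' @param domain numeric(2): the half-open variable domain (lo, hi]. Degrees
#'   are 0 outside it.
#' @return a \code{TriangularMF}.
#' @export
TriangularMF <- function(name, left, peak, right, domain) {
  new("TriangularMF", name = name, left = as.numeric(left),
      peak = as.numeric(peak), right = as.numeric(right),
      domain = as.numeric(domain))
}

#' @describeIn membershipDegree clipped piecewise-linear evaluation
#' @export
setMethod("membershipDegree", "TriangularMF", function(mf, x) {
  deg <- numeric(length(x))
  ok <- x > mf@domain[1] & x <= mf@domain[2] & is.finite(x)
  xi <- x[ok]
  up <- if (mf@peak > mf@left) (xi - mf@left) / (mf@peak - mf@left) else 1
  dn <- if (mf@right > mf@peak) (mf@right - xi) / (mf@right - mf@peak) else 1
  d <- ifelse(xi <= mf@peak, up, dn)
  deg[ok] <- pmin(1, pmax(0, d))
  deg
})

setMethod("show", "TriangularMF", function(object) {
  cat(sprintf("TriangularMF %s: (%g, %g, %g) on (%g, %g]\n", object@name,
              object@left, object@peak, object@right, object@domain[1],
              object@domain[2]))
})

#' Construct a fuzzy input variable
#'
#' @param name variable name ("L", "a" or "b" in the default model).
#' @param mfs ordered list of \code{TriangularMF}.
#' @param domain numeric(2), the half-open input domain (lo, hi].
#' @return a \code{FuzzyVariable}.
#' @export
FuzzyVariable <- function(name, mfs, domain) {
  new("FuzzyVariable", name = name, mfs = mfs, domain = as.numeric(domain))
}

#' Build the default three-input lycopene fuzzy model
#'
#' Variables L (Low/Medium/High), a (Low/Medium/High) and b (Low/High) with
#' the breakpoints listed above: 8 membership functions in total. The rule
#' base is the full Cartesian grid over MF combinations (3 x 3 x 2 = 18
#' rules); consequents are initialized to zero and are meant to be fitted by
#' \code{\link{fitConsequents}}.
#'
#' @param order "one" (default, linear consequents Z = p.x + r) or "zero"
#'   (constant consequents).
#' @param tnorm "product" (default) or "min" antecedent conjunction.
#' @return an unfitted \code{TakagiSugenoModel}.
#' @export
buildDefaultModel <- function(order = c("one", "zero"),
                              tnorm = c("product", "min")) {
  order <- match.arg(order)
  tnorm <- match.arg(tnorm)
  dL <- c(0, 2558.3); da <- c(0, 1736); db <- c(-210, 358)
  vars <- list(
    FuzzyVariable("L", list(
      TriangularMF("Low_L", 0, 0, 1285, dL),
      TriangularMF("Medium_L", 10.7, 1285, 2558.3, dL),
      TriangularMF("High_L", 1285, 2558.3, 2558.3, dL)), dL),
    FuzzyVariable("a", list(
      TriangularMF("Low_a", 0, 0, 753, da),
      TriangularMF("Medium_a", 0, 753, 1736, da),
      TriangularMF("High_a", 753, 1736, 1736, da)), da),
    FuzzyVariable("b", list(
      TriangularMF("Low_b", 210, 210, 358, db),
      TriangularMF("High_b", 210, 358, 358, db)), db))
  ant <- as.matrix(expand.grid(lapply(vars, function(v) seq_along(v@mfs)),
                               KEEP.OUT.ATTRS = FALSE))
  dimnames(ant) <- list(NULL, vapply(vars, function(v) v@name, ""))
  storage.mode(ant) <- "integer"
  ncoef <- if (order == "one") length(vars) + 1L else 1L
  new("TakagiSugenoModel", variables = vars, antecedents = ant,
      coefficients = matrix(0, nrow(ant), ncoef), tnorm = tnorm,
      order = order, inputNames = c("L_feat", "a_feat", "b_feat"))
}

#' @describeIn nRules rule count
#' @export
setMethod("nRules", "TakagiSugenoModel", function(model) nrow(model@antecedents))

#' @describeIn nMemberships total MF count across variables
#' @export
setMethod("nMemberships", "TakagiSugenoModel", function(model)
  sum(vapply(model@variables, function(v) length(v@mfs), 1L)))

setMethod("show", "TakagiSugenoModel", function(object) {
  cat(sprintf(
    "TakagiSugenoModel: %d input(s), %d membership function(s), %d rule(s)\n",
    length(object@variables), nMemberships(object), nRules(object)))
  cat(sprintf("  t-norm: %s; consequent order: %s; fitted: %s\n",
              object@tnorm, object@order,
              if (length(object@fitInfo)) "yes" else "no"))
})

## degrees of every MF of every variable at x: list of numeric vectors
.allDegrees <- function(model, x) {
  lapply(seq_along(model@variables), function(j) {
    vapply(model@variables[[j]]@mfs,
           function(mf) membershipDegree(mf, x[j]), 0)
  })
}

#' @describeIn ruleStrengths t-norm of antecedent degrees, one weight per
#'   rule
#' @export
setMethod("ruleStrengths", "TakagiSugenoModel", function(model, x) {
  stopifnot(length(x) == length(model@variables))
  deg <- .allDegrees(model, x)
  w <- rep(1, nRules(model))
  for (j in seq_along(deg)) {
    dj <- deg[[j]][model@antecedents[, j]]
    w <- if (model@tnorm == "product") w * dj else pmin(w, dj)
  }
  w
})

## rule output levels Z_i(x)
.ruleOutputs <- function(model, x) {
  if (model@order == "one")
    as.vector(model@coefficients %*% c(x, 1))
  else
    model@coefficients[, 1]
}

#' Predict lycopene content with a Takagi-Sugeno model
#'
#' The crisp output is the firing-strength-weighted average of the rule
#' output levels, sum(w_i Z_i) / sum(w_i). Inputs firing no rule raise an
#' explicit error rather than returning NaN.
#'
#' @param object a fitted \code{TakagiSugenoModel}.
#' @param newdata numeric vector (one value per variable) or a matrix /
#'   data.frame with one row per sample; data.frames may carry the model's
#'   \code{inputNames} columns.
#' @param ... ignored.
#' @return numeric vector of lycopene estimates (ppm scale of the training
#'   labels).
#' @export
setMethod("predict", "TakagiSugenoModel", function(object, newdata, ...) {
  X <- .asInputMatrix(object, newdata)
  apply(X, 1L, function(x) {
    w <- ruleStrengths(object, x)
    sw <- sum(w)
    if (sw <= 0)
      stop("input outside rule coverage: (",
           paste(sprintf("%s=%g", vapply(object@variables, function(v) v@name, ""), x),
                 collapse = ", "), ") fires no rule")
    sum(w * .ruleOutputs(object, x)) / sw
  })
})

.asInputMatrix <- function(model, newdata) {
  p <- length(model@variables)
  if (is.data.frame(newdata)) {
    nm <- model@inputNames
    if (all(nm %in% names(newdata))) newdata <- newdata[, nm, drop = FALSE]
    newdata <- as.matrix(newdata)
  }
  if (is.null(dim(newdata))) newdata <- matrix(newdata, ncol = p, byrow = TRUE)
  if (ncol(newdata) != p)
    stop("expected ", p, " input columns, got ", ncol(newdata))
  storage.mode(newdata) <- "double"
  newdata
}

#' @describeIn fitConsequents hybrid least-squares consequent estimation
#'
#' Premise membership functions are held fixed; for each sample the
#' normalized firing strengths multiply the (x, 1) regressors of every rule,
#' and the stacked linear system is solved by minimum-norm least squares
#' (Moore-Penrose pseudoinverse). Samples firing no rule are dropped with a
#' warning; a rank-deficient design is solved minimum-norm with a warning.
#' @export
setMethod("fitConsequents", "TakagiSugenoModel", function(model, X, y) {
  X <- .asInputMatrix(model, X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y))
  R <- nRules(model)
  p <- length(model@variables)
  q <- if (model@order == "one") p + 1L else 1L

  W <- t(apply(X, 1L, function(x) ruleStrengths(model, x)))
  sw <- rowSums(W)
  dead <- sw <= 0
  if (any(dead)) {
    warning(sum(dead), " sample(s) fire no rule and were rejected")
    X <- X[!dead, , drop = FALSE]
    y <- y[!dead]
    W <- W[!dead, , drop = FALSE]
    sw <- sw[!dead]
    if (!nrow(X)) stop("no usable training samples: all fire no rule")
  }
  Wbar <- W / sw
  n <- nrow(X)
  reg <- if (model@order == "one") cbind(X, 1) else matrix(1, n, 1L)
  # design: columns grouped by rule, within rule the (x, 1) regressors
  A <- matrix(0, n, R * q)
  for (i in seq_len(R))
    A[, ((i - 1L) * q + 1L):(i * q)] <- Wbar[, i] * reg
  rnk <- qr(A)$rank
  if (rnk < ncol(A))
    warning("rank-deficient consequent design (rank ", rnk, " of ",
            ncol(A), "); returning the minimum-norm solution")
  theta <- as.vector(MASS::ginv(A) %*% y)
  model@coefficients <- matrix(theta, nrow = R, ncol = q, byrow = TRUE)
  res <- y - as.vector(A %*% theta)
  model@fitInfo <- list(nTrain = n, nRejected = sum(dead),
                        residualNorm = sqrt(sum(res^2)), designRank = rnk,
                        nParameters = ncol(A))
  model
})
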