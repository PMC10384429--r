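mdl <- buildDefaultModel()
varL <- mdl@variables[[1]]; varA <- mdl@variables[[2]]; varB <- mdl@variables[[3]]
mfsOf <- function(v) stats::setNames(v@mfs, vapply(v@mfs, function(m) m@name, ""))

test_that("the default model has the printed structure", {
  expect_identical(nRules(mdl), 18L)
  expect_identical(nMemberships(mdl), 8L)
  expect_identical(vapply(mdl@variables, function(v) v@name, ""), c("L", "a", "b"))
  expect_identical(vapply(mdl@variables, function(v) length(v@mfs), 1L),
                   c(3L, 3L, 2L))
  # full-grid rule base: all antecedent combinations, each exactly once
  expect_identical(nrow(unique(as.data.frame(mdl@antecedents))), 18L)
})

test_that("membership functions evaluate the printed line segments", {
  a <- mfsOf(varA)
  expect_equal(membershipDegree(a$Low_a, 1e-12), 1, tolerance = 1e-9)
  expect_equal(membershipDegree(a$Low_a, 376.5), 0.5)
  expect_equal(membershipDegree(a$Medium_a, 753), 1)
  expect_equal(membershipDegree(a$High_a, 753), 0)
  expect_equal(membershipDegree(a$High_a, 1736), 1)
  b <- mfsOf(varB)
  # raw line (358 - b)/148 = 3.838 at b = -210: clipped to 1
  expect_gt((358 + 210) / 148, 1)
  expect_equal(membershipDegree(b$Low_b, -210 + 1e-9), 1)
  expect_equal(membershipDegree(b$Low_b, 284), 0.5)
  expect_equal(membershipDegree(b$High_b, 358), 1)
  L <- mfsOf(varL)
  expect_equal(membershipDegree(L$Low_L, 642.5), 0.5)
  expect_equal(membershipDegree(L$Low_L, 1285 + 1), 0)
  expect_equal(membershipDegree(L$Medium_L, 1285), 1)
  expect_equal(membershipDegree(L$Medium_L, 10.7), 0)
  expect_equal(membershipDegree(L$High_L, 2558.3), 1)
  expect_equal(membershipDegree(L$High_L, 1285), 0)
})

test_that("degrees stay in [0, 1] over dense domain grids and vanish outside", {
  for (v in mdl@variables) {
    g <- seq(v@domain[1] + 1e-9, v@domain[2], length.out = 2000)
    for (mf in v@mfs) {
      d <- membershipDegree(mf, g)
      expect_true(all(d >= 0 & d <= 1))
    }
    expect_identical(membershipDegree(v@mfs[[1]], v@domain[2] + 1), 0)
    expect_identical(membershipDegree(v@mfs[[1]], v@domain[1] - 1), 0)
  }
})

test_that("partition-of-unity identities hold to 1e-12", {
  a <- mfsOf(varA); b <- mfsOf(varB)
  g1 <- seq(1e-6, 753, length.out = 1e4)
  expect_lt(max(abs(membershipDegree(a$Low_a, g1) +
                    membershipDegree(a$Medium_a, g1) - 1)), 1e-12)
  g2 <- seq(753 + 1e-6, 1736, length.out = 1e4)
  expect_lt(max(abs(membershipDegree(a$Medium_a, g2) +
                    membershipDegree(a$High_a, g2) - 1)), 1e-12)
  g3 <- seq(210, 358, length.out = 1e4)
  expect_lt(max(abs(membershipDegree(b$Low_b, g3) +
                    membershipDegree(b$High_b, g3) - 1)), 1e-12)
})

test_that("rule strengths match brute-force enumeration", {
  set.seed(31)
  for (rep in 1:20) {
    x <- c(runif(1, 1, 2558.3), runif(1, 1, 1736), runif(1, -209, 358))
    w <- ruleStrengths(mdl, x)
    expect_true(all(w >= 0 & w <= 1))
    for (i in seq_len(nRules(mdl))) {
      prod <- 1
      for (j in 1:3) {
        mf <- mdl@variables[[j]]@mfs[[mdl@antecedents[i, j]]]
        prod <- prod * membershipDegree(mf, x[j])
      }
      expect_equal(w[i], prod, tolerance = 1e-12)
    }
  }
})

test_that("a crisp corner fires exactly one rule at weight 1", {
  # L = 1285 (Medium only), a = 753 (Medium only), b = 358 (High only)
  w <- ruleStrengths(mdl, c(1285, 753, 358))
  expect_identical(sum(w == 1), 1L)
  expect_identical(sum(w == 0), 17L)
  fired <- which(w == 1)
  expect_identical(unname(mdl@antecedents[fired, ]), c(2L, 2L, 2L))
})

test_that("inputs outside every support fire nothing and predict errors", {
  x <- c(3000, 2000, 500)   # beyond all three domains
  expect_identical(max(ruleStrengths(mdl, x)), 0)
  fit <- mdl; fit@coefficients[] <- 1
  expect_error(predict(fit, x), "outside rule coverage")
})

test_that("the defuzzifier is the firing-strength-weighted average", {
  m <- buildDefaultModel(order = "zero")
  m@coefficients[, 1] <- 42
  # single-rule firing at a crisp corner: output is that rule's level
  expect_equal(predict(m, c(1285, 753, 358)), 42)
  # two equally-weighted levels average symmetrically
  m2 <- buildDefaultModel(order = "zero")
  x <- c(1285, 753, 284)   # b = 284: Low_b = High_b = 0.5
  w <- ruleStrengths(m2, x)
  expect_equal(sort(w[w > 0]), c(0.5, 0.5))
  m2@coefficients[w > 0, 1] <- c(0, 10)
  expect_equal(predict(m2, x), 5)
})

test_that("zero-order defuzzification is convex and continuous", {
  set.seed(17)
  m <- buildDefaultModel(order = "zero")
  m@coefficients[, 1] <- rnorm(18, 50, 30)
  X <- cbind(runif(200, 1, 2558.3), runif(200, 1, 1736), runif(200, -209, 358))
  out <- predict(m, X)
  expect_true(all(out >= min(m@coefficients) - 1e-9))
  expect_true(all(out <= max(m@coefficients) + 1e-9))
  # continuity spot-check away from domain edges
  base <- cbind(runif(50, 100, 2400), runif(50, 100, 1600), runif(50, -150, 300))
  d <- abs(predict(m, base + 1e-4) - predict(m, base))
  expect_lt(max(d), 1e-2)
})

test_that("noiseless planted-model data is recovered to 1e-8", {
  set.seed(42)
  planted <- buildDefaultModel()
  planted@coefficients <- matrix(rnorm(18 * 4, 0, 0.05), 18, 4)
  tab <- generateFeatureTable(100, seed = 7, model = planted, noiseSd = 0)
  X <- as.matrix(tab[, c("L_feat", "a_feat", "b_feat")])
  fit <- suppressWarnings(fitConsequents(buildDefaultModel(), X,
                                         tab$lycopene_ppm))
  expect_lt(max(abs(predict(fit, X) - tab$lycopene_ppm)), 1e-8)
  expect_lte(fit@fitInfo$residualNorm, 1e-8)
})

test_that("constant targets are reproduced exactly on the training points", {
  set.seed(19)
  X <- cbind(runif(40, 1, 2558.3), runif(40, 1, 1736), runif(40, -209, 358))
  fit <- suppressWarnings(fitConsequents(buildDefaultModel(), X, rep(7, 40)))
  expect_equal(unname(predict(fit, X)), rep(7, 40), tolerance = 1e-8)
})

test_that("underdetermined fits return the minimum-norm zero-residual solution", {
  set.seed(23)
  X <- cbind(runif(10, 1, 2558.3), runif(10, 1, 1736), runif(10, -209, 358))
  y <- runif(10, 0, 90)
  expect_warning(fit <- fitConsequents(buildDefaultModel(), X, y),
                 "rank-deficient")
  expect_lt(max(abs(predict(fit, X) - y)), 1e-7)
  # cross-check coefficients against an explicit SVD pseudoinverse oracle
  W <- t(apply(X, 1, function(x) ruleStrengths(buildDefaultModel(), x)))
  Wbar <- W / rowSums(W)
  A <- matrix(0, 10, 18 * 4)
  for (i in 1:18) A[, (i - 1) * 4 + 1:4] <- Wbar[, i] * cbind(X, 1)
  theta <- oraclePinvSolve(A, y)
  expect_equal(as.vector(t(fit@coefficients)), as.vector(theta),
               tolerance = 1e-6)
})

test_that("training residual never exceeds the best constant predictor's", {
  set.seed(29)
  tab <- generateFeatureTable(60, seed = 3)   # default smooth law + noise
  X <- as.matrix(tab[, c("L_feat", "a_feat", "b_feat")])
  fit <- suppressWarnings(fitConsequents(buildDefaultModel(), X,
                                         tab$lycopene_ppm))
  rssModel <- sum((predict(fit, X) - tab$lycopene_ppm)^2)
  rssConst <- sum((mean(tab$lycopene_ppm) - tab$lycopene_ppm)^2)
  expect_lte(rssModel, rssConst + 1e-8)
})

test_that("min t-norm and first-order consequents are configurable", {
  m <- buildDefaultModel(tnorm = "min")
  x <- c(642.5, 376.5, 284)
  w <- ruleStrengths(m, x)
  deg <- lycosense:::.allDegrees(m, x)
  for (i in seq_len(nRules(m)))
    expect_equal(w[i], min(vapply(1:3, function(j)
      deg[[j]][m@antecedents[i, j]], 0)))
  expect_identical(ncol(buildDefaultModel(order = "zero")@coefficients), 1L)
})

test_that("models serialize to JSON and back bit-exactly", {
  set.seed(37)
  tab <- generateFeatureTable(50, seed = 5)
  X <- as.matrix(tab[, c("L_feat", "a_feat", "b_feat")])
  fit <- suppressWarnings(fitConsequents(buildDefaultModel(), X,
                                         tab$lycopene_ppm))
  p <- withr::local_tempfile(fileext = ".json")
  writeModel(fit, p)
  back <- readModel(p)
  expect_identical(back@coefficients, fit@coefficients)
  expect_identical(back@antecedents, fit@antecedents)
  expect_identical(back@tnorm, fit@tnorm)
  expect_identical(back@order, fit@order)
  for (j in 1:3) {
    mfs1 <- fit@variables[[j]]@mfs; mfs2 <- back@variables[[j]]@mfs
    for (k in seq_along(mfs1)) {
      expect_identical(mfs2[[k]]@left, mfs1[[k]]@left)
      expect_identical(mfs2[[k]]@peak, mfs1[[k]]@peak)
      expect_identical(mfs2[[k]]@right, mfs1[[k]]@right)
    }
  }
  expect_identical(predict(back, X), predict(fit, X))
})
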