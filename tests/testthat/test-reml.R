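# Dense, independent evaluation of the restricted likelihood used as the
# oracle for remlLogLik: builds V and P explicitly with solve().
denseREML <- function(y, X, V) {
  n <- length(y)
  p <- ncol(X)
  Vi <- solve(V)
  if (p > 0) {
    C <- t(X) %*% Vi %*% X
    P <- Vi - Vi %*% X %*% solve(C) %*% t(X) %*% Vi
    ldC <- determinant(C)$modulus
  } else {
    P <- Vi
    ldC <- 0
  }
  -0.5 * (determinant(V)$modulus + ldC + t(y) %*% P %*% y)[1] -
    (n - p) / 2 * log(2 * pi)
}

test_that("remlLogLik matches a dense projection-matrix evaluation", {
  gr <- randomGRM(6, seed = 11)
  ph <- data.frame(iid = individualIds(gr), pop = as.character(populations(gr)),
                   y = c(0.3, -1, 2, 0.5, -0.2, 1.1))
  spec <- modelSpec(list(gr), ph, traits = 2)
  vc <- makeVC(list(matrix(c(0.7, 0.2, 0.2, 0.9), 2)), c(0.5, 0.8))
  t1 <- as.integer(ph$pop == "pop1")
  V <- grmValues(gr) * (0.7 * outer(t1, t1) + 0.9 * outer(1 - t1, 1 - t1) +
                          0.2 * (outer(t1, 1 - t1) + outer(1 - t1, t1))) +
    diag(ifelse(t1 == 1, 0.5, 0.8))
  X <- cbind(t1, 1 - t1)
  expect_equal(remlLogLik(spec, vc), denseREML(ph$y, X, V),
               tolerance = 1e-10)
})

test_that("zero-covariance likelihood factorizes over populations", {
  sc <- smallScenario(seed = 12, nPerPop = 40)
  gr <- makeGRM(centerGenotypes(sc$g))
  spec <- modelSpec(list(gr), sc$pheno, traits = 2)
  vc <- makeVC(list(matrix(c(0.5, 0, 0, 0.4), 2)), c(0.6, 0.7))
  lls <- sapply(1:2, function(p) {
    pop <- paste0("pop", p)
    inPop <- which(as.character(populations(gr)) == pop)
    sub <- makeToyGRM(grmValues(gr)[inPop, inPop], pop = rep(pop, length(inPop)))
    sub@iid <- individualIds(gr)[inPop]
    ph <- sc$pheno[sc$pheno$pop == pop, ]
    sspec <- modelSpec(list(sub), ph, traits = 1)
    remlLogLik(sspec, makeVC(list(c(0.5, 0.4)[p]), c(0.6, 0.7)[p]))
  })
  expect_equal(remlLogLik(spec, vc), sum(lls), tolerance = 1e-8)
})

test_that("fitREML recovers a grid-search optimum on a small instance", {
  gr <- randomGRM(20, seed = 13, pop = rep("pop1", 20))
  L <- chol(grmValues(gr))
  set.seed(14)
  y <- as.numeric(t(L) %*% rnorm(20)) * sqrt(0.7) + rnorm(20, 0, sqrt(0.3))
  ph <- data.frame(iid = individualIds(gr), pop = "pop1", y = y)
  spec <- modelSpec(list(gr), ph, traits = 1)
  fit <- fitREML(spec)
  grid <- expand.grid(va = seq(0.02, 3, by = 0.02),
                      ve = seq(0.02, 3, by = 0.02))
  lls <- mapply(function(va, ve)
    remlLogLik(spec, list(M = list(matrix(va, 1, 1)), residual = ve)),
    grid$va, grid$ve)
  best <- grid[which.max(lls), ]
  expect_lt(abs(fit@M[[1]][1, 1] - best$va), 0.021)
  expect_lt(abs(fit@residual - best$ve), 0.021)
  expect_gte(fit@loglik, max(lls) - 1e-6)
})

test_that("response scaling rescales components, leaving h2 and rg fixed", {
  sc <- smallScenario(seed = 15, nPerPop = 50)
  gr <- makeGRM(centerGenotypes(sc$g))
  spec1 <- modelSpec(list(gr), sc$pheno, traits = 2)
  fit1 <- fitREML(spec1)
  ph2 <- sc$pheno; ph2$y <- 3 * ph2$y
  fit2 <- fitREML(modelSpec(list(gr), ph2, traits = 2))
  expect_equal(fit2@M[[1]], 9 * fit1@M[[1]], tolerance = 1e-3)
  expect_equal(fit2@residual, 9 * fit1@residual, tolerance = 1e-3)
  d1 <- deriveParams(fit1); d2 <- deriveParams(fit2)
  expect_equal(d2$h2$h2, d1$h2$h2, tolerance = 1e-4)
  expect_equal(d2$rg$rg, d1$rg$rg, tolerance = 1e-4)
})

test_that("fit is invariant to individual reordering", {
  sc <- smallScenario(seed = 16, nPerPop = 40)
  gr <- makeGRM(centerGenotypes(sc$g))
  fit1 <- fitREML(modelSpec(list(gr), sc$pheno, traits = 2))
  set.seed(17)
  perm <- sample(nrow(sc$pheno))
  fit2 <- fitREML(modelSpec(list(gr), sc$pheno[perm, ], traits = 2))
  expect_equal(fit2@M[[1]], fit1@M[[1]], tolerance = 1e-5)
  expect_equal(fit2@loglik, fit1@loglik, tolerance = 1e-6)
})

test_that("derived parameters follow their defining formulas", {
  # h2 = 0.5 when genetic and residual variances are equal
  vc <- makeVC(list(matrix(c(1, 0, 0, 1), 2)), c(1, 1))
  dp <- deriveParams(vc)
  expect_equal(dp$h2$h2, c(0.5, 0.5))
  expect_equal(dp$rg$rg, 0)
  # forced arithmetic: (4, -1, 1) -> rg = -0.5
  vc2 <- makeVC(list(matrix(c(4, -1, -1, 1), 2)), c(1, 2))
  dp2 <- deriveParams(vc2)
  expect_equal(dp2$rg$rg, -0.5)
  expect_equal(dp2$h2$h2, c(4 / 5, 1 / 3))
  # zero genetic variance: correlation undefined
  vc3 <- makeVC(list(matrix(0, 2, 2)), c(1, 1))
  expect_true(is.na(deriveParams(vc3)$rg$rg))
  # multi-kernel heritability sums kernels
  vc4 <- makeVC(list(matrix(c(1, 0, 0, 1), 2), matrix(c(2, 0, 0, 1), 2)),
                c(3, 2))
  expect_equal(deriveParams(vc4)$h2$h2, c(3 / 6, 2 / 4))
})

test_that("likelihood-ratio test is exact in its chi-square mapping", {
  sc <- smallScenario(seed = 18, nPerPop = 40, rLgc = 0)
  gr <- makeGRM(centerGenotypes(sc$g))
  spec <- modelSpec(list(gr), sc$pheno, traits = 2)
  lrt <- lrtZeroCovariance(spec, 1)
  expect_gte(lrt$statistic, 0)
  expect_equal(lrt$p, pchisq(lrt$statistic, 1, lower.tail = FALSE))
  expect_gte(lrt$full@loglik, lrt$null@loglik - 1e-6)
  # statistic 3.841 corresponds to p ~ 0.05 in the mapping used
  expect_equal(pchisq(3.841459, 1, lower.tail = FALSE), 0.05,
               tolerance = 1e-6)
})

test_that("fit report carries components, correlation and convergence", {
  sc <- smallScenario(seed = 19, nPerPop = 40)
  gr <- makeGRM(centerGenotypes(sc$g))
  fit <- fitREML(modelSpec(list(gr), sc$pheno, traits = 2))
  rep_ <- fitReport(fit)
  expect_named(rep_, c("kernel", "s2_a1", "s_a12", "s2_a2", "rg", "rg_se",
                       "loglik", "converged"))
  expect_equal(rep_$rg, rep_$s_a12 / sqrt(rep_$s2_a1 * rep_$s2_a2))
  expect_true(rep_$converged)
})
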