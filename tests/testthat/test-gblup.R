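test_that("the two-individual conditional expectation is exact", {
  gr <- makeToyGRM(matrix(c(1, 0.5, 0.5, 1), 2), pop = rep("pop1", 2))
  ph <- data.frame(iid = individualIds(gr), pop = "pop1", y = c(1, NA))
  vc <- makeVC(list(1), 1)
  pr <- gblupSolve(list(gr), ph, vc, predictIds = individualIds(gr),
                   intercept = FALSE)
  expect_equal(gebv(pr)$total, c(0.5, 0.25))
})

test_that("zero genetic variance shrinks every GEBV to zero", {
  gr <- randomGRM(8, seed = 31, pop = rep("pop1", 8))
  ph <- data.frame(iid = individualIds(gr), pop = "pop1", y = rnorm(8))
  vc <- makeVC(list(0), 1)
  pr <- gblupSolve(list(gr), ph, vc)
  expect_true(all(gebv(pr)$total == 0))
})

test_that("GLS and Henderson MME paths agree on random instances", {
  for (seed in 31:33) {
    gr <- randomGRM(10, seed = seed)
    set.seed(seed)
    ph <- data.frame(iid = individualIds(gr),
                     pop = as.character(populations(gr)), y = rnorm(10))
    ph$y[9:10] <- NA  # two unobserved individuals
    vc <- makeVC(list(matrix(c(0.8, 0.3, 0.3, 0.6), 2)), c(0.5, 0.7))
    a <- gebv(gblupSolve(list(gr), ph, vc, method = "gls"))
    b <- gebv(gblupSolve(list(gr), ph, vc, method = "mme"))
    expect_lt(max(abs(a$total - b$total)), 1e-8)
    # single-trait path too
    vs <- makeVC(list(0.9), 0.4)
    ph1 <- ph; ph1$pop <- "pop1"
    gr1 <- gr; gr1@pop <- factor(rep("pop1", 10))
    a1 <- gebv(gblupSolve(list(gr1), ph1, vs, method = "gls"))
    b1 <- gebv(gblupSolve(list(gr1), ph1, vs, method = "mme"))
    expect_lt(max(abs(a1$total - b1$total)), 1e-8)
  }
})

test_that("prediction refuses individuals missing from the GRM", {
  gr <- randomGRM(6, seed = 34)
  ph <- data.frame(iid = individualIds(gr),
                   pop = as.character(populations(gr)), y = rnorm(6))
  vc <- makeVC(list(matrix(c(1, 0, 0, 1), 2)), c(1, 1))
  expect_error(gblupSolve(list(gr), ph, vc, predictIds = "ghost"),
               "missing from the GRM")
})

test_that("single-population runner matches the generic solver", {
  sc <- smallScenario(seed = 35, nPerPop = 40)
  gr <- makeGRM(centerGenotypes(sc$g))
  pr <- runSTGBLUP(gr, sc$pheno, "pop1")
  inPop <- which(as.character(populations(gr)) == "pop1")
  sub <- new("GRM", values = grmValues(gr)[inPop, inPop],
             iid = individualIds(gr)[inPop],
             pop = factor(populations(gr)[inPop]), snpSet = "ALL",
             nSnps = gr@nSnps, denom = gr@denom)
  ph <- sc$pheno[sc$pheno$pop == "pop1", ]
  vc <- fitREML(modelSpec(list(sub), ph, traits = 1))
  pr2 <- gblupSolve(list(sub), ph, vc, individualIds(sub))
  expect_equal(gebv(pr)$total, gebv(pr2)$total, tolerance = 1e-10)
  expect_error(runSTGBLUP(gr, sc$pheno, "pop9"), "unknown population")
  expect_error(runSTGBLUP(gr, sc$pheno[0, ], "pop1"), "empty training")
})

test_that("combined-reference model pools populations under one variance", {
  sc <- smallScenario(seed = 36, nPerPop = 40, rLgc = 1)
  gr <- makeGRM(centerGenotypes(sc$g))
  pr <- runSTGBLUPCombined(gr, sc$pheno)
  expect_equal(pr@vc@nTraits, 1L)
  expect_length(pr@vc@M, 1)       # a single genetic variance, not per-pop
  expect_equal(nrow(gebv(pr)), nInd(sc$g))
  expect_error(runSTGBLUPCombined(gr, sc$pheno, commensurable = FALSE),
               "not applicable")
})

test_that("multi-trait model with zero covariance decouples to STGBLUP", {
  sc <- smallScenario(seed = 37, nPerPop = 50)
  gr <- makeGRM(centerGenotypes(sc$g))
  mt <- runMTGBLUP(gr, sc$pheno, constrainZeroCov = TRUE, tol = 1e-12)
  g1 <- runSTGBLUP(gr, sc$pheno, "pop1", tol = 1e-12)
  g2 <- runSTGBLUP(gr, sc$pheno, "pop2", tol = 1e-12)
  st <- rbind(gebv(g1), gebv(g2))
  m <- gebv(mt)
  expect_lt(max(abs(m$total - st$total[match(m$iid, st$iid)])), 1e-6)
})

test_that("multi-trait model requires two populations", {
  sc <- smallScenario(seed = 38, nPerPop = 30)
  gr <- makeGRM(centerGenotypes(sc$g))
  expect_error(runMTGBLUP(gr, sc$pheno[sc$pheno$pop == "pop1", ]),
               "two populations")
})

test_that("partitioned models produce exact component sums", {
  sc <- smallScenario(seed = 39, nPerPop = 50, rLgc = c(0.9, -0.9, 0, 0))
  rec <- suppressWarnings(estimateLGC(sc$g, sc$pheno, sc$partition))
  cls <- classifyModel2(rec, 0.5, sc$partition)
  pr <- suppressWarnings(runLGCModel2(sc$g, sc$pheno, cls))
  gdf <- gebv(pr)
  comp <- grep("^gebv_", names(gdf))
  expect_equal(rowSums(gdf[, comp, drop = FALSE]), gdf$total)
  expect_error(runLGCModel2(sc$g, sc$pheno,
                            classifyModel1(rec, 1, sc$partition)),
               "MODEL2")
})
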