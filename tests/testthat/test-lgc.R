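fakeRecords <- function(p, r = NULL) {
  n <- length(p)
  data.frame(block_id = seq_len(n), chrom = "chr1",
             start_bp = seq_len(n) * 1000, end_bp = seq_len(n) * 1000 + 999,
             n_snps = 10L, r_lgc = if (is.null(r)) runif(n, -1, 1) else r,
             p_value = p, var1 = 0.1, var2 = 0.1, converged = TRUE,
             stringsAsFactors = FALSE)
}

fakePartition <- function(n, snpsPer = 10) {
  b <- data.frame(block_id = seq_len(n), chrom = "chr1",
                  start_index = (seq_len(n) - 1) * snpsPer + 1L,
                  end_index = seq_len(n) * snpsPer,
                  start_bp = (seq_len(n) - 1) * snpsPer * 100 + 100,
                  end_bp = seq_len(n) * snpsPer * 100,
                  n_snps = snpsPer)
  new("GenomePartition", blocks = b)
}

test_that("significance classification takes the top-k smallest p-values", {
  set.seed(21)
  p <- sample(seq(0.001, 0.9, length.out = 30))
  part <- fakePartition(30)
  cls <- classifyModel1(fakeRecords(p), topK = 10, partition = part)
  sig <- names(classAssignment(cls))[classAssignment(cls) == "SIG"]
  expect_setequal(as.integer(sig), order(p)[1:10])
  expect_equal(sum(classAssignment(cls) == "NON"), 20L)
  # top 20 alternative
  cls20 <- classifyModel1(fakeRecords(p), topK = 20, partition = part)
  expect_equal(sum(classAssignment(cls20) == "SIG"), 20L)
  # SNP sets partition all SNPs
  expect_equal(sort(unname(unlist(classSnpSets(cls)))), 1:300)
})

test_that("exact p-value ties at the boundary go to the earlier block", {
  p <- c(0.5, 0.2, 0.2, 0.8)
  cls <- classifyModel1(fakeRecords(p), topK = 1, partition = fakePartition(4))
  expect_equal(unname(classAssignment(cls)[2]), "SIG")
  expect_equal(unname(classAssignment(cls)[3]), "NON")
})

test_that("failed blocks are NON and top-k bounds are enforced", {
  p <- c(0.01, NA, 0.5, NA, 0.3)
  rec <- fakeRecords(p)
  cls <- classifyModel1(rec, topK = 2, partition = fakePartition(5))
  expect_equal(unname(classAssignment(cls)[c(2, 4)]), c("NON", "NON"))
  expect_error(classifyModel1(rec, topK = 5, partition = fakePartition(5)),
               "smaller than the number of blocks")
  expect_error(classifyModel1(rec, topK = 4, partition = fakePartition(5)),
               "fewer blocks with defined p-values")
})

test_that("magnitude classification applies the inclusive threshold rule", {
  r <- c(0.55, -0.7, 0.3, 0.5, -0.5, NA, 0)
  cls <- classifyModel2(fakeRecords(rep(0.5, 7), r = r), threshold = 0.5,
                        partition = fakePartition(7))
  expect_equal(unname(classAssignment(cls)),
               c("POS", "NEG", "RES", "POS", "NEG", "RES", "RES"))
  # all-zero estimates: everything RES
  cls0 <- classifyModel2(fakeRecords(rep(0.5, 7), r = rep(0, 7)),
                         threshold = 0.5, partition = fakePartition(7))
  expect_true(all(classAssignment(cls0) == "RES"))
  # 0.6 variant
  cls6 <- classifyModel2(fakeRecords(rep(0.5, 7), r = r), threshold = 0.6,
                         partition = fakePartition(7))
  expect_equal(unname(classAssignment(cls6))[1], "RES")
  expect_error(classifyModel2(fakeRecords(0.5, r = 0), threshold = 1.2,
                              partition = fakePartition(1)), "threshold")
  # SNP sets disjoint and exhaustive
  expect_equal(sort(unname(unlist(classSnpSets(cls)))), 1:70)
})

test_that("a single-block partition reproduces the global correlation", {
  sc <- smallScenario(seed = 22, nPerPop = 60)
  onePart <- fakePartition(1, snpsPer = nSnps(sc$g))
  rec <- estimateLGC(sc$g, sc$pheno, onePart)
  gr <- makeGRM(centerGenotypes(sc$g))
  vc <- fitREML(modelSpec(list(gr), sc$pheno, traits = 2))
  globalRg <- deriveParams(vc)$rg$rg[1]
  expect_equal(rec$r_lgc[1], globalRg, tolerance = 1e-4)
})

test_that("local correlation is recovered in a strong-signal block", {
  # one block carries all genetic variance with r_lgc = +0.9
  ests <- sapply(1:6, function(seed) {
    cfg <- simConfig(nPerPop = 120, nChrom = 1, blocksPerChrom = 2,
                     snpsPerBlock = 40, rho = 0.8,
                     rLgcBlocks = c(0.9, 0), varShareBlocks = c(0.9, 0.1),
                     h2 = c(0.5, 0.5), seed = seed)
    sc <- simulateScenario(cfg)
    rec <- suppressWarnings(estimateLGC(sc$g, sc$pheno, sc$partition))
    rec$r_lgc[1]
  })
  expect_equal(mean(ests, na.rm = TRUE), 0.9, tolerance = 0.15)
})

test_that("LGC report joins class labels under both schemes", {
  part <- fakePartition(25)
  rec <- fakeRecords(seq(0.01, 0.97, length.out = 25),
                     r = seq(-1, 1, length.out = 25))
  out <- lgcReport(rec, part, topK = 10, threshold = 0.5)
  expect_true(all(out$class_model1 %in% c("SIG", "NON")))
  expect_true(all(out$class_model2 %in% c("POS", "NEG", "RES")))
  expect_equal(sum(out$class_model1 == "SIG"), 10L)
})
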