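test_that("pairwise r2 behaves as squared correlation", {
  sc <- smallScenario(seed = 1, nPerPop = 40)
  w <- centerGenotypes(sc$g)
  expect_equal(pairwiseR2(w, 5, 5), 1)
  # sign-invariance: a column against its negation
  w2 <- w
  w2@W[, 2] <- -w2@W[, 1]
  expect_equal(pairwiseR2(w2, 1, 2), 1)
  wc <- w
  wc@W[, 3] <- 0
  expect_error(pairwiseR2(wc, 3, 4), "constant")
  # independent columns stay near zero at large n
  g0 <- simulateGenotypes(simConfig(nPerPop = 5000, nChrom = 1,
                                    blocksPerChrom = 1, snpsPerBlock = 2,
                                    rho = 0, seed = 2))
  expect_lt(pairwiseR2(centerGenotypes(g0), 1, 2), 0.01)
})

test_that("a clean two-cluster chromosome splits exactly at the boundary", {
  g <- simulateGenotypes(simConfig(nPerPop = 150, nChrom = 1,
                                   blocksPerChrom = 2, snpsPerBlock = 20,
                                   rho = 0.97, seed = 3))
  w <- centerGenotypes(g)
  part <- partitionChromosome(w, g, "chr1", maxBlockSnps = 30,
                              minSnps = 10, window = 10)
  b <- blocks(part)
  expect_equal(nrow(b), 2L)
  expect_equal(b$end_index[1], 20L)
})

test_that("splitter agrees with the exhaustive enumeration oracle", {
  for (seed in 1:3) {
    g <- simulateGenotypes(simConfig(nPerPop = 120, nChrom = 1,
                                     blocksPerChrom = 5, snpsPerBlock = 10,
                                     rho = 0.8, seed = seed))
    w <- centerGenotypes(g)
    part <- partitionChromosome(w, g, "chr1", maxBlockSnps = 30,
                                minSnps = 10, window = 5)
    Wnum <- w@W
    ob <- oraclePartition(Wnum, maxBlockSnps = 30, minSnps = 10, window = 5)
    ob <- ob[order(ob[, 1]), , drop = FALSE]
    expect_equal(blocks(part)$start_index, unname(ob[, 1]))
    expect_equal(blocks(part)$end_index, unname(ob[, 2]))
  }
})

test_that("no split happens when the cap is not exceeded; determinism", {
  sc <- smallScenario(seed = 4, nPerPop = 40)
  w <- centerGenotypes(sc$g)
  p1 <- partitionChromosome(w, sc$g, "chr1", maxBlockSnps = nSnps(sc$g))
  expect_equal(nrow(blocks(p1)), 1L)
  pa <- partitionGenome(w, sc$g, maxBlockSnps = 60, minSnps = 20,
                        window = 10)
  pb <- partitionGenome(w, sc$g, maxBlockSnps = 60, minSnps = 20,
                        window = 10)
  expect_identical(blocks(pa), blocks(pb))
})

test_that("genome partition respects chromosomes, min sizes and coverage", {
  g <- simulateGenotypes(simConfig(nPerPop = 60, nChrom = 2,
                                   blocksPerChrom = 3, snpsPerBlock = 25,
                                   rho = 0.9, seed = 5))
  w <- centerGenotypes(g)
  part <- partitionGenome(w, g, maxBlockSnps = 40, minSnps = 12,
                          window = 10)
  b <- blocks(part)
  # blocks never span chromosomes
  for (i in seq_len(nrow(b)))
    expect_equal(length(unique(snpMap(g)$chrom[b$start_index[i]:b$end_index[i]])), 1L)
  expect_true(all(b$n_snps >= 12))
  expect_equal(sum(b$n_snps), nSnps(g))
  expect_equal(b$block_id, seq_len(nrow(b)))
  expect_error(partitionChromosome(w, g, "chr1", maxBlockSnps = 20,
                                   minSnps = 15), "2\\*minSnps")
})

test_that("partition is invariant to individual relabeling", {
  sc <- smallScenario(seed = 6, nPerPop = 50)
  w <- centerGenotypes(sc$g)
  set.seed(8)
  perm <- sample(nInd(sc$g))
  gp <- sc$g[perm, ]
  wp <- centerGenotypes(gp)
  p1 <- partitionChromosome(w, sc$g, "chr1", maxBlockSnps = 60,
                            minSnps = 20, window = 10)
  p2 <- partitionChromosome(wp, gp, "chr1", maxBlockSnps = 60,
                            minSnps = 20, window = 10)
  expect_equal(blocks(p1)$start_index, blocks(p2)$start_index)
})

test_that("an undersized chromosome becomes one block with a warning", {
  g <- simulateGenotypes(simConfig(nPerPop = 30, nChrom = 2,
                                   blocksPerChrom = 1, snpsPerBlock = 10,
                                   seed = 7))
  w <- centerGenotypes(g)
  expect_warning(part <- partitionGenome(w, g, maxBlockSnps = 50,
                                         minSnps = 12),
                 "fewer than minSnps")
  expect_equal(nrow(blocks(part)), 2L)
})
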