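# PLINK 1.9 binary codec. The expected .bed bytes below were derived by
# hand from the published format: magic 6c 1b 01, SNP-major, two bits per
# genotype with the first sample in the lowest-order bits, and codes
# 00 = hom allele-1 (2 copies), 10 = het, 11 = hom allele-2, 01 = missing.

writeToyBed <- function(dir) {
  # 3 individuals x 2 SNPs: snp1 = (2, 1, 0), snp2 = (0, 1, NA)
  # snp1: bits 00, 10, 11, pad 00 -> 0 + 2*4 + 3*16 = 0x38
  # snp2: bits 11, 10, 01, pad 00 -> 3 + 2*4 + 1*16 = 0x1b
  prefix <- file.path(dir, "toy")
  con <- file(paste0(prefix, ".bed"), "wb")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 0x38, 0x1b)), con)
  close(con)
  writeLines(c("chr1\tsnp1\t0\t100\tA\tB", "chr1\tsnp2\t0\t200\tA\tB"),
             paste0(prefix, ".bim"))
  writeLines(c("pop1\tind1\t0\t0\t0\t-9", "pop1\tind2\t0\t0\t0\t-9",
               "pop2\tind3\t0\t0\t0\t-9"), paste0(prefix, ".fam"))
  prefix
}

test_that("readPlink decodes a hand-constructed .bed exactly", {
  prefix <- writeToyBed(withr::local_tempdir())
  g <- readPlink(prefix)
  expect_identical(unname(genotypeCodes(g)),
                   matrix(c(2L, 1L, 0L, 0L, 1L, NA), 3, 2))
  expect_identical(individualIds(g), c("ind1", "ind2", "ind3"))
  expect_identical(as.character(populations(g)), c("pop1", "pop1", "pop2"))
  expect_equal(alleleFreq(g), c(0.5, 0.25))
})

test_that("write-read round trip is lossless and byte-identical", {
  prefix <- writeToyBed(withr::local_tempdir())
  g <- readPlink(prefix)
  out <- file.path(withr::local_tempdir(), "rt")
  writePlink(g, out)
  expect_identical(readBin(paste0(out, ".bed"), "raw", 10),
                   readBin(paste0(prefix, ".bed"), "raw", 10))
  g2 <- readPlink(out)
  expect_identical(genotypeCodes(g2), genotypeCodes(g))
  expect_identical(snpMap(g2)$snp_id, snpMap(g)$snp_id)
  expect_identical(individualIds(g2), individualIds(g))
})

test_that("round trip preserves a larger simulated panel with missing calls", {
  g <- simulateGenotypes(simConfig(nPerPop = 9, nChrom = 2,
                                   blocksPerChrom = 2, snpsPerBlock = 13,
                                   seed = 4))
  codes <- genotypeCodes(g)
  codes[cbind(c(1, 5, 18), c(3, 40, 52))] <- NA  # sprinkle missing
  g <- genotypeData(codes, snpMap(g), individualIds(g), populations(g))
  prefix <- file.path(withr::local_tempdir(), "sim")
  writePlink(g, prefix)
  g2 <- readPlink(prefix)
  expect_identical(genotypeCodes(g2), genotypeCodes(g))
  expect_equal(snpMap(g2)$pos_bp, snpMap(g)$pos_bp)
})

test_that("malformed magic bytes and dimension mismatches are rejected", {
  prefix <- writeToyBed(withr::local_tempdir())
  bad <- readBin(paste0(prefix, ".bed"), "raw", 10)
  bad[2] <- as.raw(0)
  writeBin(bad, paste0(prefix, ".bed"))
  expect_error(readPlink(prefix), "magic")
  writeToyBed(dirname(prefix))
  writeBin(readBin(paste0(prefix, ".bed"), "raw", 4),
           paste0(prefix, ".bed"))  # truncated body
  expect_error(readPlink(prefix), "inconsistent")
})

test_that("empty .fam and all-missing columns are handled", {
  prefix <- writeToyBed(withr::local_tempdir())
  writeLines(character(0), paste0(prefix, ".fam"))
  expect_error(readPlink(prefix), "empty")
  # all-missing SNP: frequency undefined
  g <- makeToyGenotypes(matrix(c(0L, 1L, NA, NA), 2, 2))
  expect_true(is.na(alleleFreq(g)[2]))
  expect_equal(alleleFreq(g)[1], 0.25)
})

test_that("phenotype and block TSV interfaces round-trip", {
  d <- withr::local_tempdir()
  ph <- data.frame(iid = c("a", "b"), pop = c("pop1", "pop2"),
                   y = c(1.5, NA))
  writePhenotypes(ph, file.path(d, "p.tsv"))
  ph2 <- readPhenotypes(file.path(d, "p.tsv"))
  expect_equal(ph2$y, c(1.5, NA))
  expect_error(readPhenotypes(file.path(d, "nope.tsv")), "input missing")

  g <- simulateGenotypes(simConfig(nPerPop = 5, nChrom = 2,
                                   blocksPerChrom = 2, snpsPerBlock = 10,
                                   seed = 1))
  part <- truePartition(simConfig(nPerPop = 5, nChrom = 2,
                                  blocksPerChrom = 2, snpsPerBlock = 10,
                                  seed = 1), g)
  writeBlocks(part, file.path(d, "b.tsv"))
  part2 <- readBlocks(file.path(d, "b.tsv"), g)
  expect_equal(blocks(part2)$start_index, blocks(part)$start_index)
  expect_equal(blocks(part2)$end_index, blocks(part)$end_index)
})
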