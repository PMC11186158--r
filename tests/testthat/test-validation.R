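# Junction depth checks, the k-mer QV estimator, and the
# homozygous-variant error rate.

test_that("junction checks pass on constant depth and fail on zero-depth bases", {
  depth <- list(c1 = rep(30L, 1000L))
  j <- data.frame(chrom = "c1", pos = 500L)
  chk <- junctionCoverage(depth, j, window = 50, minDepth = 1)
  expect_true(chk$pass)
  depth$c1[520] <- 0L
  expect_false(junctionCoverage(depth, j, window = 50, minDepth = 1)$pass)
  expect_error(junctionCoverage(depth, data.frame(chrom = "zz", pos = 1L)),
               "unknown chromosome")
})

test_that("junction windows are clipped at chromosome ends", {
  depth <- list(c1 = c(rep(7L, 60), rep(0L, 940)))
  j <- data.frame(chrom = "c1", pos = 10L)
  chk <- junctionCoverage(depth, j, window = 50, minDepth = 1)
  expect_equal(chk$window_start, 0L)
  expect_equal(chk$window_end, 60L)
  expect_equal(chk$min_depth, min(depth$c1[1:60]))  # oracle: direct slice
  expect_true(chk$pass)
})

test_that("QV follows the shared-fraction closed form, with cap and oracle value", {
  expect_equal(kmerQV(letters, letters, k = 21)$qv, 99)         # error 0
  expect_equal(kmerQV(paste0("x", 1:10), paste0("x", 1:9), k = 1)$qv, 10,
               tolerance = 1e-12)                                # 1 - 0.9
  # shared fraction 0.5 at k = 21; expected value frozen from an
  # arbitrary-precision evaluation of -10*log10(1 - 0.5^(1/21))
  q <- kmerQV(sprintf("k%04d", 1:1000), sprintf("k%04d", 1:500), k = 21)
  expect_equal(q$qv, 14.8854150023, tolerance = 1e-9)
  expect_equal(q$per_base_error, 0.0324682214761, tolerance = 1e-11)
  expect_error(kmerQV(character(0), letters, k = 21), "no k-mers")
})

test_that("QV strictly decreases as assembly-only k-mers are added", {
  set.seed(41)
  reads <- unique(replicate(400, paste(sample(c("A", "C", "G", "T"), 21,
                                              replace = TRUE), collapse = "")))
  shared <- sample(reads, 200)
  qvs <- sapply(0:5 * 30, function(extra)
    kmerQV(c(shared, sprintf("zz%03d", seq_len(extra))), reads, k = 21)$qv)
  expect_true(all(diff(qvs) < 0))
})

test_that("planted assembly errors are recovered by the k-mer QV estimate", {
  # m single-base errors in the assembly, error-free read k-mers from truth:
  # per_base_error should approximate m / genome_size (each error erases
  # up to k k-mers)
  cfg <- smallSimConfig(seed = 42, nChroms = 1L, chromLen = 150000L)
  tr <- simulateGenome(cfg)
  truth <- genomeSeqs(tr)
  k <- 21L
  reads <- makeDepthAndKmers(truth, k = k, seed = 42)
  m <- 12L
  set.seed(43)
  s <- truth[[1]]
  # plant errors in unique (non-repetitive) core sequence, well separated
  pos <- 2000L + (seq_len(m) - 1L) * 2000L   # unique core, clear of arrays
  ch <- strsplit(s, "")[[1]]
  for (p in pos) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  asm <- c(chr01 = paste(ch, collapse = ""))
  q <- kmerQV(kmerSet(asm, k = k), reads$kmers, k = k)
  rate <- m / nchar(s)
  expect_gt(q$per_base_error, rate * 0.8)
  expect_lt(q$per_base_error, rate * 1.2)
})

test_that("error-free reads over the genome give the QV cap and passing junctions", {
  cfg <- smallSimConfig(seed = 44, nChroms = 2L)
  tr <- simulateGenome(cfg)
  deg <- degradeToScaffold(tr, cfg)
  don <- makeDonor(tr, cfg, gaps = deg$gaps)
  res <- fillGaps(deg$assembly, don$assembly, don$alignments)
  rk <- makeDepthAndKmers(genomeSeqs(tr), coverage = 30, k = 21, seed = 44)
  q <- kmerQV(kmerSet(patchedAssembly(res), k = 21), rk$kmers, k = 21)
  expect_equal(q$qv, 99)
  chk <- junctionCoverage(rk$depth, junctionSites(res))
  expect_true(all(chk$pass))
  # a planted zero-depth hole under a junction fails its check
  hole <- junctionSites(res)[1, ]
  rk2 <- makeDepthAndKmers(genomeSeqs(tr), coverage = 30, seed = 44,
                           holes = data.frame(chrom = hole$chrom,
                                              start = hole$pos,
                                              end = hole$pos + 5L))
  chk2 <- junctionCoverage(rk2$depth, junctionSites(res))
  expect_false(all(chk2$pass))
})

test_that("depth tracks read back from samtools-depth TSV and bedgraph", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("c1\t1\t5", "c1\t2\t7", "c1\t10\t3"), f)
  d <- readDepth(f, c(c1 = 10L))
  expect_equal(d$c1, c(5L, 7L, rep(0L, 7), 3L))
  writeLines(c("c1\t0\t3\t9", "c1\t5\t6\t2"), f)
  d2 <- readDepth(f, c(c1 = 8L), format = "bedgraph")
  expect_equal(d2$c1, c(9L, 9L, 9L, 0L, 0L, 2L, 0L, 0L))
})

test_that("homozygous-alternate records are counted under the filters", {
  counts <- homozygousErrorRate(
    data.frame(gt = c("1/1", "0/1"), qual = c(50, 50), dp = c(10, 10)),
    assemblySize = 1e6)
  expect_equal(counts$homozygous_variants, 1)
  expect_equal(counts$rate, 1e-6)
  hetOnly <- homozygousErrorRate(
    data.frame(gt = rep("0/1", 4), qual = 50, dp = 10), assemblySize = 1e6)
  expect_equal(hetOnly$rate, 0)
  # QUAL/DP filters apply
  f <- homozygousErrorRate(
    data.frame(gt = rep("1/1", 3), qual = c(50, 10, 50), dp = c(10, 10, 2)),
    assemblySize = 1e6)
  expect_equal(f$homozygous_variants, 1)
})

test_that("a hand-built VCF fixture yields the hand-counted rate", {
  skip_if_not_installed("VariantAnnotation")
  f <- withr::local_tempfile(fileext = ".vcf")
  hdr <- c("##fileformat=VCFv4.2",
           "##contig=<ID=chr01,length=1000000>",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Depth">',
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1")
  rec <- function(pos, gt, qual = 60, dp = 20)
    sprintf("chr01\t%d\t.\tA\tG\t%d\tPASS\t.\tGT:DP\t%s:%d", pos, qual, gt, dp)
  # 5 passing hom-alt, 3 het, 1 hom-alt failing QUAL, 1 hom-alt failing DP
  writeLines(c(hdr,
               rec(100, "1/1"), rec(200, "1|1"), rec(300, "1/1"),
               rec(400, "1/1"), rec(500, "1/1"),
               rec(600, "0/1"), rec(700, "0|1"), rec(800, "0/1"),
               rec(900, "1/1", qual = 5), rec(950, "1/1", dp = 2)), f)
  est <- homozygousErrorRate(f, assemblySize = 1e6)
  expect_equal(est$homozygous_variants, 5)
  expect_equal(est$rate, 5e-6)
})
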