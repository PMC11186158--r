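# Anchor discovery, patch planning and splicing. The central property is
# the synthetic round trip: degrade a truth genome, patch it from a
# divergence-0 donor, and recover the truth byte-for-byte.

gapAt <- function(chrom, start, end) {
  data.frame(chrom = chrom, start = start, end = end, length = end - start)
}

test_that("anchors obey the flank window on each side of the gap", {
  gap <- gapAt("t", 50, 60)
  a <- rbind(alnRow("d", 0, 50, "+", "t", 0, 50),
             alnRow("d", 200, 300, "+", "t", 200, 300))
  an <- findAnchors(gap, a, flankWindow = 150, minAnchorLen = 10)
  expect_equal(nrow(an$left), 1)
  expect_equal(an$left$distance_to_gap, 0)
  expect_equal(nrow(an$right), 1)
  expect_equal(an$right$distance_to_gap, 140)   # 200 - 60

  an2 <- findAnchors(gap, a, flankWindow = 100, minAnchorLen = 10)
  expect_equal(nrow(an2$right), 0)              # 140 > window

  far <- alnRow("d", 0, 100, "+", "t", 0, 100)  # ends 150 bp before gap
  an3 <- findAnchors(gapAt("t", 250, 260), far, flankWindow = 100,
                     minAnchorLen = 10)
  expect_equal(nrow(an3$left), 0)
})

test_that("a spanning alignment appears in both anchor lists and is preferred", {
  gap <- gapAt("t", 50, 60)
  a <- alnRow("d", 0, 110, "+", "t", 0, 110)
  an <- findAnchors(gap, a, flankWindow = 100, minAnchorLen = 10)
  expect_equal(an$left$.aid, an$right$.aid)
  plan <- planPatch(gap, an)
  expect_equal(plan$status, "planned")
  expect_equal(plan$mode, "spanning")
  expect_equal(plan$donor_start, 50)
  expect_equal(plan$donor_end, 60)
})

test_that("paired-anchor planning projects the gap through flanking alignments", {
  # truth G = A(50) + X(10) + B(50); target has X replaced by Ns; donor = G
  set.seed(5)
  A <- randDna(50); X <- randDna(10); B <- randDna(50)
  truth <- paste0(A, X, B)
  target <- c(t = paste0(A, strrep("N", 10), B))
  donor <- c(d = truth)
  a <- rbind(alnRow("d", 0, 50, "+", "t", 0, 50),
             alnRow("d", 60, 110, "+", "t", 60, 110))
  gap <- findGaps(target)
  plan <- planPatches(gap, a, flankWindow = 100, minAnchorLen = 10)
  expect_equal(plan$status, "planned")
  expect_equal(plan$mode, "paired")
  expect_equal(plan$donor_start, 50)
  expect_equal(plan$donor_end, 60)
  res <- applyPatches(target, donor, plan)
  expect_identical(unname(patchedAssembly(res)), truth)
  expect_equal(patchReport(res)$totals$filled, 1)
})

test_that("every failure mode is a status, not an error", {
  gap <- gapAt("t", 50, 60)
  onlyLeft <- alnRow("d", 0, 50, "+", "t", 0, 50)
  expect_equal(planPatch(gap, findAnchors(gap, onlyLeft, 100, 10))$status,
               "no_right_anchor")
  onlyRight <- alnRow("d", 60, 110, "+", "t", 60, 110)
  expect_equal(planPatch(gap, findAnchors(gap, onlyRight, 100, 10))$status,
               "no_left_anchor")
  twoDonors <- rbind(alnRow("d1", 0, 50, "+", "t", 0, 50),
                     alnRow("d2", 60, 110, "+", "t", 60, 110))
  expect_equal(planPatch(gap, findAnchors(gap, twoDonors, 100, 10))$status,
               "discordant_anchors")
  strandClash <- rbind(alnRow("d", 0, 50, "+", "t", 0, 50),
                       alnRow("d", 60, 110, "-", "t", 60, 110))
  expect_equal(planPatch(gap, findAnchors(gap, strandClash, 100, 10))$status,
               "discordant_anchors")
  big <- alnRow("d", 0, 2000, "+", "t", 0, 2000)
  expect_equal(planPatch(gapAt("t", 500, 1500),
                         findAnchors(gapAt("t", 500, 1500), big, 100, 10),
                         maxPatchLen = 100)$status, "span_too_long")
})

test_that("a donor-implied flank overlap is trimmed up to the cap", {
  # donor is missing the gap: left and right donor coordinates cross by 20
  gap <- gapAt("t", 100, 200)
  a <- rbind(alnRow("d", 0, 100, "+", "t", 0, 100),
             alnRow("d", 80, 180, "+", "t", 200, 300))
  plan <- planPatch(gap, findAnchors(gap, a, 100, 10), trimCap = 50)
  expect_equal(plan$status, "planned")
  expect_equal(plan$left_trim, 20)
  expect_equal(plan$patch_len, 0)
  plan2 <- planPatch(gap, findAnchors(gap, a, 100, 10), trimCap = 5)
  expect_equal(plan2$status, "donor_overlap_unresolvable")
})

test_that("negative-orientation patches splice the reverse complement", {
  set.seed(6)
  A <- randDna(60); X <- randDna(20); B <- randDna(60)
  truth <- paste0(A, X, B)
  target <- c(t = paste0(A, strrep("N", 20), B))
  donor <- c(d = gapmend::revComp(truth))       # donor contig is flipped
  a <- rbind(alnRow("d", 80, 130, "-", "t", 10, 60),
             alnRow("d", 10, 50, "-", "t", 90, 130))
  res <- fillGaps(target, donor, a, minAlnLen = 10, minAnchorLen = 10,
                  flankWindow = 100)
  expect_identical(unname(patchedAssembly(res)), truth)
})

test_that("empty plans leave the assembly untouched with an identity liftover", {
  target <- c(t = "AANNNNAA")
  plans <- planPatches(findGaps(target)[0, ], alnRow("d", 0, 1, "+", "t", 0, 1))
  res <- applyPatches(target, c(d = "ACGT"), plans)
  expect_identical(patchedAssembly(res), target)
  expect_equal(liftover("t", 0:7, liftoverMap(res)), 0:7)
})

test_that("liftover shifts, deletes and stays monotone", {
  # 10-N gap at [50,60) replaced by a 25 bp patch
  set.seed(8)
  flank <- randDna(50); tail <- randDna(40)
  target <- c(t = paste0(flank, strrep("N", 10), tail))
  donor <- c(d = paste0(flank, randDna(25), tail))
  a <- rbind(alnRow("d", 0, 50, "+", "t", 0, 50),
             alnRow("d", 75, 115, "+", "t", 60, 100))
  res <- fillGaps(target, donor, a, minAlnLen = 10, minAnchorLen = 10,
                  flankWindow = 100)
  map <- liftoverMap(res)
  expect_equal(liftover("t", 10L, map), 10L)          # before the edit
  expect_equal(liftover("t", 60L, map), 75L)          # after: shifted +15
  expect_true(is.na(liftover("t", 55L, map)))         # inside the removed Ns
  expect_error(liftover("nope", 1L, map), "unknown")
  # monotonicity over random retained positions
  pos <- sort(sample(c(0:49, 60:99), 30))
  lifted <- liftover("t", pos, map)
  expect_true(all(diff(lifted[!is.na(lifted)]) > 0))
})

test_that("liftover is monotone on random multi-edit scripts", {
  set.seed(13)
  for (rep in 1:20) {
    cfg <- smallSimConfig(seed = rep, nChroms = 1L)
    tr <- simulateGenome(cfg)
    deg <- degradeToScaffold(tr, cfg)
    don <- makeDonor(tr, cfg, gaps = deg$gaps)
    res <- fillGaps(deg$assembly, don$assembly, don$alignments)
    map <- liftoverMap(res)
    nm <- names(deg$assembly)[1]
    pos <- sort(sample.int(nchar(deg$assembly[[nm]]), 200) - 1L)
    lifted <- liftover(nm, pos, map)
    kept <- !is.na(lifted)
    expect_true(all(diff(lifted[kept]) > 0))
    # length bookkeeping: new length = old - removed + inserted
    plans <- patchReport(res)$perGap
    p <- plans[plans$chrom == nm & plans$status == "planned", ]
    expect_equal(nchar(patchedAssembly(res)[[nm]]),
                 nchar(deg$assembly[[nm]]) -
                   sum(p$gap_len + p$left_trim + p$right_trim) +
                   sum(p$patch_len))
  }
})

test_that("round-trip reconstruction is exact and patching is idempotent", {
  cfg <- smallSimConfig(seed = 21)
  tr <- simulateGenome(cfg)
  deg <- degradeToScaffold(tr, cfg)
  don <- makeDonor(tr, cfg, gaps = deg$gaps)
  res <- fillGaps(deg$assembly, don$assembly, don$alignments)
  expect_identical(patchedAssembly(res), genomeSeqs(tr))
  expect_equal(sum(patchReport(res)$residualGaps$n_gaps), 0)
  # second pass over the gap-free result plans nothing
  res2 <- fillGaps(patchedAssembly(res), don$assembly, don$alignments)
  expect_equal(patchReport(res2)$totals$found, 0)
  expect_identical(patchedAssembly(res2), patchedAssembly(res))
})

test_that("overlapping patch intervals on one chromosome are rejected loudly", {
  target <- c(t = paste0(strrep("A", 10), "NNNN", strrep("C", 2), "NNNN",
                         strrep("G", 10)))
  plans <- rbind(
    data.frame(chrom = "t", gap_start = 10L, gap_end = 14L, gap_len = 4L,
               mode = "spanning", donor_name = "d", donor_start = 0L,
               donor_end = 4L, orientation = "+", left_trim = 0L,
               right_trim = 4L, patch_len = 4L, left_identity = 100,
               right_identity = 100, score = 1, status = "planned"),
    data.frame(chrom = "t", gap_start = 16L, gap_end = 20L, gap_len = 4L,
               mode = "spanning", donor_name = "d", donor_start = 0L,
               donor_end = 4L, orientation = "+", left_trim = 4L,
               right_trim = 0L, patch_len = 4L, left_identity = 100,
               right_identity = 100, score = 1, status = "planned"))
  expect_error(applyPatches(target, c(d = "ACGT"), plans), "overlapping")
})

test_that("patched bases are uppercase while surrounding case is preserved", {
  target <- c(t = paste0("acgtacgtac", strrep("N", 4), "ttggccaatt"))
  donor <- c(d = paste0("acgtacgtac", "nnga", "ttggccaatt"))
  a <- alnRow("d", 0, 24, "+", "t", 0, 24)
  res <- fillGaps(target, donor, a, minAlnLen = 5, minAnchorLen = 5,
                  flankWindow = 50)
  expect_identical(unname(patchedAssembly(res)),
                   paste0("acgtacgtac", "NNGA", "ttggccaatt"))
})
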