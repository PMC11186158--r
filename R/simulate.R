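# Seeded generators for every input the toolkit consumes: truth genomes
# with telomere/centromere structure, gapped scaffolds, divergent donor
# assemblies, rearranged companion genomes, depth tracks and read k-mer
# sets. Every output is a pure function of (config, seed); each generator
# draws from its own RNG substream so adding one never perturbs another.

#' Simulation configuration
#'
#' Defaults emulate the study conditions the package targets: a
#' chromosome-level mammalian-like genome at GC 0.42 with 3-kb terminal
#' telomere arrays (500 hexamer copies), a 50-kb centromeric tandem array
#' of a 171-bp monomer (1% per-copy substitution), five 1-Mb chromosomes
#' with five N-gaps each, and a donor assembly from a second individual
#' (fragmented contigs, some reverse-complemented).
#'
#' @param seed integer master seed.
#' @param nChroms number of chromosomes.
#' @param chromLen chromosome length (bp).
#' @param gc GC fraction of the random core sequence.
#' @param telomereCopies hexamer copies per telomere array.
#' @param centromereMonomerLen centromeric monomer length (bp).
#' @param centromereArrayLen centromeric array length (bp).
#' @param nGapsPerChrom planted N-gaps per chromosome.
#' @param gapLenRange gap length range (bp).
#' @param donorDivergence donor per-base substitution probability.
#' @param donorFragLenRange donor contig length range (bp).
#' @param donorRevcompProb probability a donor contig is
#'   reverse-complemented.
#' @param readErrorRate per-base rate of error k-mers in the read set.
#' @param fusionEvents list of 2-vectors of chromosome names to fuse in
#'   the companion genome.
#' @return a validated list of class "SimConfig".
#' @export
simConfig <- function(seed = 1L, nChroms = 5L, chromLen = 1e6L, gc = 0.42,
                      telomereCopies = 500L, centromereMonomerLen = 171L,
                      centromereArrayLen = 50000L, nGapsPerChrom = 5L,
                      gapLenRange = c(200L, 2000L), donorDivergence = 0,
                      donorFragLenRange = c(150000L, 400000L),
                      donorRevcompProb = 0.3, readErrorRate = 0,
                      fusionEvents = list()) {
  cfg <- list(seed = as.integer(seed), nChroms = as.integer(nChroms),
              chromLen = as.integer(chromLen), gc = gc,
              telomereCopies = as.integer(telomereCopies),
              centromereMonomerLen = as.integer(centromereMonomerLen),
              centromereArrayLen = as.integer(centromereArrayLen),
              nGapsPerChrom = as.integer(nGapsPerChrom),
              gapLenRange = as.integer(gapLenRange),
              donorDivergence = donorDivergence,
              donorFragLenRange = as.integer(donorFragLenRange),
              donorRevcompProb = donorRevcompProb,
              readErrorRate = readErrorRate, fusionEvents = fusionEvents)
  stopifnot(cfg$gc >= 0, cfg$gc <= 1, cfg$donorDivergence >= 0,
            cfg$donorDivergence <= 1, cfg$donorRevcompProb >= 0,
            cfg$donorRevcompProb <= 1, cfg$readErrorRate >= 0,
            cfg$gapLenRange[1] <= cfg$gapLenRange[2])
  telLen <- 6L * cfg$telomereCopies
  if (2L * telLen + cfg$centromereArrayLen >= cfg$chromLen)
    stop("telomere/centromere arrays longer than chromosome")
  class(cfg) <- "SimConfig"
  cfg
}

#' Simulate a truth genome with planted telomeres and centromeres
#'
#' Each chromosome is CCCTAA-array + random core + centromeric tandem
#' array + random core + TTAGGG-array (the C-rich motif leads the 5' end,
#' the G-rich motif ends the 3' end, as on a real forward strand). The
#' centromeric array repeats a random monomer with 1% per-copy
#' substitution. Fully deterministic given the config seed.
#'
#' @param cfg a [simConfig()] object.
#' @return a [SimulatedGenome-class].
#' @export
simulateGenome <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(.substream(cfg$seed, "genome"))
  telLen <- 6L * cfg$telomereCopies
  tel5 <- strrep("CCCTAA", cfg$telomereCopies)
  tel3 <- strrep("TTAGGG", cfg$telomereCopies)
  genome <- character(0)
  telomeres <- NULL; centromeres <- NULL
  for (ci in seq_len(cfg$nChroms)) {
    nm <- sprintf("chr%02d", ci)
    coreTotal <- cfg$chromLen - 2L * telLen - cfg$centromereArrayLen
    coreA <- coreTotal %/% 2L
    coreB <- coreTotal - coreA
    monomer <- .randSeq(cfg$centromereMonomerLen, gc = 0.5)
    nCopies <- ceiling(cfg$centromereArrayLen / cfg$centromereMonomerLen)
    copies <- vapply(seq_len(nCopies), function(i)
      .mutateSeq(monomer, 0.01)$seq, character(1))
    array <- substr(paste(copies, collapse = ""), 1L, cfg$centromereArrayLen)
    s <- paste0(tel5, .randSeq(coreA, cfg$gc), array,
                .randSeq(coreB, cfg$gc), tel3)
    genome[[nm]] <- s
    centStart <- telLen + coreA
    telomeres <- rbind(telomeres,
      data.frame(chrom = nm, start = c(0L, cfg$chromLen - telLen),
                 end = c(telLen, cfg$chromLen),
                 end_label = c("5prime", "3prime"), stringsAsFactors = FALSE))
    centromeres <- rbind(centromeres,
      data.frame(chrom = nm, start = centStart,
                 end = centStart + cfg$centromereArrayLen,
                 monomer = monomer, monomer_len = cfg$centromereMonomerLen,
                 stringsAsFactors = FALSE))
  }
  methods::new("SimulatedGenome", genome = genome, telomeres = telomeres,
               centromeres = centromeres, config = unclass(cfg))
}

#' Degrade a truth genome into a gapped scaffold
#'
#' Replaces `nGapsPerChrom` random non-terminal intervals per chromosome
#' with N-runs, avoiding the planted telomere and centromere arrays by
#' `margin` bp and keeping gaps at least `minSpacing` apart so their
#' anchor flanks stay disjoint. The removed sequence is recorded.
#'
#' @param truth a [SimulatedGenome-class].
#' @param cfg the [simConfig()] used (gap count/length ranges, seed).
#' @param margin exclusion margin around planted arrays (bp).
#' @param minSpacing minimum distance between planted gaps (bp).
#' @return list(assembly = named character vector, gaps = data.frame with
#'   chrom, start, end, length, removed_seq).
#' @export
degradeToScaffold <- function(truth, cfg, margin = 10000L,
                              minSpacing = 15000L) {
  set.seed(.substream(cfg$seed, "degrade"))
  genome <- genomeSeqs(truth)
  tel <- telomereIntervals(truth); cen <- centromereIntervals(truth)
  gaps <- NULL
  for (nm in names(genome)) {
    len <- nchar(genome[[nm]])
    t5 <- tel[tel$chrom == nm & tel$end_label == "5prime", ]
    t3 <- tel[tel$chrom == nm & tel$end_label == "3prime", ]
    cc <- cen[cen$chrom == nm, ]
    zones <- rbind(
      data.frame(lo = t5$end + margin, hi = cc$start - margin),
      data.frame(lo = cc$end + margin, hi = t3$start - margin))
    placed <- NULL
    tries <- 0L
    while ((is.null(placed) || nrow(placed) < cfg$nGapsPerChrom) &&
           tries < 1000L) {
      tries <- tries + 1L
      glen <- sample(cfg$gapLenRange[1]:cfg$gapLenRange[2], 1L)
      z <- zones[sample.int(nrow(zones), 1L), ]
      if (z$hi - z$lo <= glen) next
      start <- z$lo + sample.int(z$hi - z$lo - glen, 1L) - 1L
      if (!is.null(placed) &&
          any(pmax(placed$start, start - minSpacing) <
              pmin(placed$end, start + glen + minSpacing))) next
      placed <- rbind(placed, data.frame(start = start, end = start + glen))
    }
    if (is.null(placed) || nrow(placed) < cfg$nGapsPerChrom)
      stop("could not place ", cfg$nGapsPerChrom, " gaps on ", nm)
    placed <- placed[order(placed$start), ]
    s <- genome[[nm]]
    removed <- substring(s, placed$start + 1L, placed$end)
    for (i in rev(seq_len(nrow(placed)))) {
      s <- paste0(substr(s, 1L, placed$start[i]),
                  strrep("N", placed$end[i] - placed$start[i]),
                  substr(s, placed$end[i] + 1L, nchar(s)))
    }
    genome[[nm]] <- s
    gaps <- rbind(gaps, data.frame(chrom = nm, start = placed$start,
                                   end = placed$end,
                                   length = placed$end - placed$start,
                                   removed_seq = removed,
                                   stringsAsFactors = FALSE))
  }
  list(assembly = genome, gaps = gaps)
}

#' Fabricate a donor assembly from a second "individual"
#'
#' Applies substitutions at `cfg$donorDivergence`, fragments each
#' chromosome into contigs with lengths drawn from
#' `cfg$donorFragLenRange`, and reverse-complements contigs with
#' probability `cfg$donorRevcompProb`. Breakpoints are pushed at least
#' `gapMargin` bp away from planted gap edges (when `gaps` is given) so
#' every gap is spannable by one contig. The true alignment of each
#' contig to the truth genome is emitted in PAF form.
#'
#' @param truth a [SimulatedGenome-class].
#' @param cfg the [simConfig()] used.
#' @param gaps optional planted-gap data.frame from [degradeToScaffold()].
#' @param gapMargin minimum breakpoint distance from a gap edge (bp).
#' @return list(assembly, provenance data.frame, alignments data.frame in
#'   the [parsePaf()] schema).
#' @export
makeDonor <- function(truth, cfg, gaps = NULL, gapMargin = 10000L) {
  set.seed(.substream(cfg$seed, "donor"))
  genome <- genomeSeqs(truth)
  contigs <- character(0)
  prov <- NULL; aln <- NULL
  for (nm in names(genome)) {
    mut <- .mutateSeq(genome[[nm]], cfg$donorDivergence)
    s <- mut$seq
    len <- nchar(s)
    # breakpoints, shifted out of gap-edge exclusion zones
    g <- if (is.null(gaps)) NULL else gaps[gaps$chrom == nm, , drop = FALSE]
    bps <- integer(0)
    pos <- 0L
    repeat {
      step <- sample(cfg$donorFragLenRange[1]:cfg$donorFragLenRange[2], 1L)
      pos <- pos + step
      if (pos >= len) break
      if (!is.null(g) && nrow(g) > 0L) {
        near <- which(pos > g$start - gapMargin & pos < g$end + gapMargin)
        if (length(near)) pos <- g$end[near[1]] + gapMargin
        if (pos >= len) break
      }
      bps <- c(bps, pos)
    }
    bounds <- c(0L, bps, len)
    for (i in seq_len(length(bounds) - 1L)) {
      cs <- bounds[i]; ce <- bounds[i + 1L]
      cname <- sprintf("ctg_%s_%03d", nm, i)
      sub <- substr(s, cs + 1L, ce)
      strand <- "+"
      if (stats::runif(1) < cfg$donorRevcompProb) {
        sub <- revComp(sub); strand <- "-"
      }
      contigs[[cname]] <- sub
      nsub <- sum(mut$positions >= cs & mut$positions < ce)
      prov <- rbind(prov, data.frame(contig = cname, chrom = nm, start = cs,
                                     end = ce, strand = strand, n_subs = nsub,
                                     stringsAsFactors = FALSE))
      aln <- rbind(aln, data.frame(qname = cname, qlen = ce - cs, qstart = 0L,
                                   qend = ce - cs, strand = strand,
                                   tname = nm, tlen = len, tstart = cs,
                                   tend = ce, matches = ce - cs - nsub,
                                   block_len = ce - cs,
                                   stringsAsFactors = FALSE))
    }
  }
  aln$identity <- 100 * aln$matches / aln$block_len
  aln$score <- as.numeric(aln$matches)
  list(assembly = contigs, provenance = prov, alignments = aln)
}

#' Build a rearranged companion-species genome
#'
#' Concatenates the specified chromosome pairs into single fused
#' chromosomes (optionally with divergence) and copies the rest — the
#' evolutionary fusion pattern seen between related karyotypes. The true
#' alignments of the companion genome (target) back to the source genome
#' (query) are emitted in chunks of `chunkLen` so block chaining has
#' something to chain.
#'
#' @param truth a [SimulatedGenome-class] (the unfused source genome).
#' @param fusionEvents list of 2-vectors of source chromosome names.
#' @param seed integer seed for the divergence stream.
#' @param divergence per-base substitution probability applied to the
#'   companion genome.
#' @param chunkLen alignment chunk length (bp).
#' @return list(assembly, alignments, events data.frame with fused, part1,
#'   part2).
#' @export
makeRearrangedGenome <- function(truth, fusionEvents = list(), seed = 1L,
                                 divergence = 0, chunkLen = 50000L) {
  set.seed(.substream(seed, "rearrange"))
  genome <- genomeSeqs(truth)
  used <- unlist(fusionEvents)
  if (any(!used %in% names(genome)))
    stop("unknown chromosome in fusion event: ",
         setdiff(used, names(genome))[1])
  if (anyDuplicated(used)) stop("chromosome used in more than one fusion")
  out <- character(0)
  events <- NULL
  aln <- NULL
  emitChunks <- function(tname, toff, qname, qseqlen) {
    starts <- seq(0L, qseqlen - 1L, by = chunkLen)
    ends <- pmin(starts + chunkLen, qseqlen)
    data.frame(qname = qname, qlen = qseqlen, qstart = starts, qend = ends,
               strand = "+", tname = tname, tlen = NA_integer_,
               tstart = toff + starts, tend = toff + ends,
               stringsAsFactors = FALSE)
  }
  for (ev in fusionEvents) {
    fname <- paste0("fused_", ev[1], "_", ev[2])
    s <- paste0(genome[[ev[1]]], genome[[ev[2]]])
    if (divergence > 0) s <- .mutateSeq(s, divergence)$seq
    out[[fname]] <- s
    aln <- rbind(aln,
                 emitChunks(fname, 0L, ev[1], nchar(genome[[ev[1]]])),
                 emitChunks(fname, nchar(genome[[ev[1]]]), ev[2],
                            nchar(genome[[ev[2]]])))
    events <- rbind(events, data.frame(fused = fname, part1 = ev[1],
                                       part2 = ev[2], stringsAsFactors = FALSE))
  }
  for (nm in setdiff(names(genome), used)) {
    s <- genome[[nm]]
    if (divergence > 0) s <- .mutateSeq(s, divergence)$seq
    out[[nm]] <- s
    aln <- rbind(aln, emitChunks(nm, 0L, nm, nchar(s)))
  }
  aln$tlen <- nchar(out)[aln$tname]
  bl <- aln$qend - aln$qstart
  # expected matches under the divergence rate (deterministic bookkeeping)
  aln$matches <- as.integer(round(bl * (1 - divergence)))
  aln$block_len <- bl
  aln$identity <- 100 * aln$matches / aln$block_len
  aln$score <- as.numeric(aln$matches)
  list(assembly = out, alignments = aln, events = events)
}

#' Simulated depth track and read k-mer set
#'
#' Uniform depth equal to `coverage` everywhere, with optional zero-depth
#' holes for negative tests; the read k-mer set is the genome's canonical
#' k-mer set, augmented with novel error k-mers at `readErrorRate` per
#' genome base.
#'
#' @param genome assembly (named character vector or XStringSet).
#' @param coverage constant read depth.
#' @param readErrorRate per-base error k-mer rate.
#' @param k k-mer size.
#' @param seed integer seed.
#' @param holes optional data.frame (chrom, start, end) of zero-depth
#'   intervals.
#' @return list(depth, kmers).
#' @export
makeDepthAndKmers <- function(genome, coverage = 30L, readErrorRate = 0,
                              k = 21L, seed = 1L, holes = NULL) {
  set.seed(.substream(seed, "reads"))
  genome <- .asSeqs(genome)
  depth <- uniformDepth(genome, coverage = coverage, holes = holes)
  kmers <- kmerSet(genome, k = k)
  nErr <- round(readErrorRate * sum(nchar(genome)))
  if (nErr > 0) {
    bases <- c("A", "C", "G", "T")
    err <- vapply(seq_len(nErr), function(i)
      paste(bases[sample.int(4L, k, replace = TRUE)], collapse = ""),
      character(1))
    rc <- revComp(err)
    canon <- ifelse(err <= rc, err, rc)
    kmers <- unique(c(kmers, canon))
  }
  list(depth = depth, kmers = kmers)
}
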