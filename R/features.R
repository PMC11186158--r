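# Telomere and centromere annotation. The vertebrate telomeric repeat is
# TTAGGG; its reverse complement CCCTAA appears at the opposite chromosome
# end, so both orientations are counted at both ends.

.TEL_MOTIFS <- c("TTAGGG", "CCCTAA")

# positions (1-based starts) of non-overlapping exact motif matches
.motifStarts <- function(s) {
  unlist(lapply(.TEL_MOTIFS, function(m) {
    hits <- gregexpr(m, s, fixed = TRUE, useBytes = TRUE)[[1]]
    if (hits[1] == -1L) integer(0) else as.integer(hits)
  }), use.names = FALSE)
}

# Best sliding-window motif-coverage density in a terminal region. Windows
# touching the chromosome boundary (`side`: "left" for a 5' region, "right"
# for 3') may be clipped down to half the scan window, so a dense terminal
# array shorter than one full window still scores its true density.
.bestWindowDensity <- function(s, scanWindow, side = "left") {
  n <- nchar(s)
  cov <- integer(n)
  st <- .motifStarts(s)
  for (p in st) cov[p:min(p + 5L, n)] <- 1L
  cs <- cumsum(c(0L, cov))
  if (n < scanWindow) return(list(density = sum(cov) / max(n, 1L),
                                  win = c(0L, n)))
  starts <- seq_len(n - scanWindow + 1L)
  dens <- (cs[starts + scanWindow] - cs[starts]) / scanWindow
  b <- which.max(dens)
  best <- list(density = dens[b],
               win = c(starts[b] - 1L, starts[b] - 1L + scanWindow))
  lens <- seq.int(max(6L, scanWindow %/% 2L), scanWindow)
  if (side == "left") {
    cdens <- cs[lens + 1L] / lens
    cb <- which.max(cdens)
    if (cdens[cb] > best$density)
      best <- list(density = cdens[cb], win = c(0L, lens[cb]))
  } else {
    cdens <- (cs[n + 1L] - cs[n + 1L - lens]) / lens
    cb <- which.max(cdens)
    if (cdens[cb] > best$density)
      best <- list(density = cdens[cb], win = c(n - lens[cb], n))
  }
  best
}

#' Scan a chromosome's ends for telomeric repeat arrays
#'
#' Counts non-overlapping exact TTAGGG and CCCTAA occurrences in the first
#' and last `endWindow` bases, and reports the densest `scanWindow` as the
#' fraction of window bases covered by motif copies; windows touching the
#' chromosome boundary may be clipped down to half the scan window so a
#' dense terminal array shorter than one window still scores fully. A
#' telomere is called present when that density reaches
#' `densityThreshold`.
#'
#' @param x a single sequence (string) or a named character vector of
#'   length 1; for whole assemblies loop or see [t2tClassify()].
#' @param chrom sequence name for the output (default from names).
#' @param endWindow terminal region examined at each end (bp).
#' @param scanWindow sliding window for the density (bp).
#' @param densityThreshold presence threshold on best-window density.
#' @return data.frame with two rows (end = "5prime"/"3prime"): chrom, end,
#'   present, motif_copies, best_window_density, window_start, window_end
#'   (0-based, in full-sequence coordinates).
#' @export
telomereScan <- function(x, chrom = NULL, endWindow = 10000L,
                         scanWindow = 1000L, densityThreshold = 0.4) {
  stopifnot(endWindow >= scanWindow, scanWindow >= 6L)
  if (is.null(chrom)) chrom <- if (!is.null(names(x))) names(x)[1] else "seq"
  s <- toupper(unname(x)[1])
  n <- nchar(s)
  ew <- min(endWindow, n)
  head5 <- substr(s, 1L, ew)
  tail3 <- substr(s, n - ew + 1L, n)
  short <- n < scanWindow
  mk <- function(region, end, off) {
    bw <- .bestWindowDensity(region, scanWindow,
                             side = if (end == "5prime") "left" else "right")
    copies <- length(.motifStarts(region))
    data.frame(chrom = chrom, end = end,
               present = !short && bw$density >= densityThreshold,
               motif_copies = copies, best_window_density = bw$density,
               window_start = bw$win[1] + off, window_end = bw$win[2] + off,
               stringsAsFactors = FALSE)
  }
  rbind(mk(head5, "5prime", 0L), mk(tail3, "3prime", n - ew))
}

#' Telomere calls for every sequence of an assembly
#'
#' @param x assembly (named character vector or XStringSet).
#' @inheritParams telomereScan
#' @return data.frame of [telomereScan()] rows for all chromosomes.
#' @export
telomereScanAll <- function(x, endWindow = 10000L, scanWindow = 1000L,
                            densityThreshold = 0.4) {
  seqs <- .asSeqs(x)
  do.call(rbind, lapply(names(seqs), function(nm)
    telomereScan(seqs[[nm]], chrom = nm, endWindow = endWindow,
                 scanWindow = scanWindow,
                 densityThreshold = densityThreshold)))
}

#' Classify chromosomes as telomere-to-telomere (T2T)
#'
#' A chromosome is T2T when it is gap-free and carries a telomere call at
#' both ends.
#'
#' @param gaps gap data.frame ([findGaps()]); chromosomes absent from it
#'   are gap-free.
#' @param calls telomere call data.frame ([telomereScanAll()]).
#' @return data.frame: chrom, gap_free, telomere_5p, telomere_3p, t2t.
#' @export
t2tClassify <- function(gaps, calls) {
  chroms <- unique(calls$chrom)
  rows <- lapply(chroms, function(nm) {
    c5 <- calls[calls$chrom == nm & calls$end == "5prime", ]
    c3 <- calls[calls$chrom == nm & calls$end == "3prime", ]
    if (nrow(c5) == 0L || nrow(c3) == 0L)
      stop("missing telomere call for chromosome ", nm)
    gf <- !nm %in% gaps$chrom
    data.frame(chrom = nm, gap_free = gf, telomere_5p = c5$present[1],
               telomere_3p = c3$present[1],
               t2t = gf && c5$present[1] && c3$present[1],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Centromere candidate scan by k-mer recurrence periodicity
#'
#' A deliberately simple tandem-array detector: a position is "tandem"
#' when its k-mer recurs downstream at a spacing inside `periodRange`.
#' The per-position indicator is smoothed with a centered running mean of
#' `window` bp; the longest maximal run at or above `threshold` becomes
#' the candidate when it is at least `minLen` long. The monomer period is
#' the modal recurrence spacing inside the candidate.
#'
#' @param x a single sequence (string, optionally named).
#' @param chrom sequence name for the output.
#' @param window smoothing window (bp).
#' @param kmer k-mer size.
#' @param periodRange allowed monomer period range (bp), within
#'   \[50, 10000\].
#' @param threshold tandemness threshold in \[0,1\].
#' @param minLen minimum candidate length (bp).
#' @return one-row data.frame: chrom, start, end, monomer_period,
#'   tandem_density, status ("candidate"/"none").
#' @export
centromereCandidates <- function(x, chrom = NULL, window = 10000L, kmer = 21L,
                                 periodRange = c(100L, 2000L), threshold = 0.5,
                                 minLen = 10000L) {
  stopifnot(periodRange[1] >= 50L, periodRange[2] <= 10000L)
  if (is.null(chrom)) chrom <- if (!is.null(names(x))) names(x)[1] else "seq"
  s <- toupper(unname(x)[1])
  n <- nchar(s)
  none <- data.frame(chrom = chrom, start = NA_integer_, end = NA_integer_,
                     monomer_period = NA_integer_, tandem_density = NA_real_,
                     status = "none", stringsAsFactors = FALSE)
  if (n < kmer + periodRange[1]) return(none)
  starts <- seq_len(n - kmer + 1L)
  km <- substring(s, starts, starts + kmer - 1L)
  valid <- !grepl("[^ACGT]", km)
  spacing <- rep(NA_integer_, length(km))
  o <- order(km, method = "radix")     # group identical k-mers together
  so <- km[o]
  same <- c(so[-1] == so[-length(so)], FALSE)
  pos_o <- o
  nxt <- c(pos_o[-1], NA_integer_)
  spacing[pos_o[same]] <- nxt[same] - pos_o[same]
  tandem <- !is.na(spacing) & spacing >= periodRange[1] &
    spacing <= periodRange[2] & valid
  dens <- .runMean(as.numeric(tandem), window)
  above <- dens >= threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts_r <- ends - r$lengths + 1L
  runs <- which(r$values & r$lengths >= minLen)
  if (length(runs) == 0L) return(none)
  best <- runs[which.max(r$lengths[runs])]
  lo <- starts_r[best]; hi <- ends[best]
  sp <- spacing[lo:hi]
  sp <- sp[tandem[lo:hi]]
  period <- as.integer(names(sort(table(sp), decreasing = TRUE))[1])
  data.frame(chrom = chrom, start = lo - 1L, end = hi - 1L + kmer,
             monomer_period = period,
             tandem_density = mean(tandem[lo:hi]),
             status = "candidate", stringsAsFactors = FALSE)
}

#' Centromere candidates for every sequence of an assembly
#'
#' @param x assembly.
#' @inheritParams centromereCandidates
#' @return data.frame of per-chromosome calls.
#' @export
centromereCandidatesAll <- function(x, window = 10000L, kmer = 21L,
                                    periodRange = c(100L, 2000L),
                                    threshold = 0.5, minLen = 10000L) {
  seqs <- .asSeqs(x)
  do.call(rbind, lapply(names(seqs), function(nm)
    centromereCandidates(seqs[[nm]], chrom = nm, window = window,
                         kmer = kmer, periodRange = periodRange,
                         threshold = threshold, minLen = minLen)))
}
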