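# Internal helpers shared across modules. All coordinates in this package are
# 0-based half-open unless a serialization format dictates otherwise.

# Accept a named character vector or an XStringSet; return named character.
.asSeqs <- function(x) {
  if (methods::is(x, "XStringSet")) {
    out <- as.character(x)
    names(out) <- sub("\\s.*$", "", names(x))
    return(out)
  }
  if (!is.character(x)) stop("assembly must be a named character vector or XStringSet")
  if (is.null(names(x)) || any(!nzchar(names(x)))) stop("assembly sequences must be named")
  x
}

#' Reverse complement of DNA strings
#'
#' IUPAC-aware, case-preserving reverse complement. Operates on plain
#' character vectors so it can be applied to multi-megabase chromosome
#' strings without copying through an external container.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @examples
#' revComp(c("ACGTn", "TTAGGG"))
#' @export
revComp <- function(x) {
  comp <- chartr("ACGTUNRYSWKMBDHVacgtunryswkmbdhv",
                 "TGCAANYRSWMKVHDBtgcaanyrswmkvhdb", x)
  vapply(comp, function(s) intToUtf8(rev(utf8ToInt(s))), character(1),
         USE.NAMES = FALSE)
}

# k-mers of one sequence, canonical (lexicographic min of k-mer and its
# reverse complement), k-mers containing non-ACGT characters dropped.
.kmersOne <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  up <- toupper(s)
  starts <- seq_len(n - k + 1L)
  fwd <- substring(up, starts, starts + k - 1L)
  rc <- revComp(up)
  rev_aln <- rev(substring(rc, starts, starts + k - 1L))
  canon <- ifelse(fwd <= rev_aln, fwd, rev_aln)
  canon[!grepl("[^ACGT]", canon)]
}

#' Canonical k-mer set of an assembly
#'
#' Distinct canonical k-mers (presence/absence, not multiplicity) over all
#' sequences. The canonical form of a k-mer is the lexicographic minimum of
#' the k-mer and its reverse complement; k-mers touching an ambiguous base
#' (anything outside ACGT, including N) are skipped.
#'
#' @param x assembly: named character vector or XStringSet.
#' @param k k-mer size (default 21).
#' @return character vector of distinct canonical k-mers.
#' @export
kmerSet <- function(x, k = 21L) {
  seqs <- .asSeqs(x)
  unique(unlist(lapply(seqs, .kmersOne, k = as.integer(k)), use.names = FALSE))
}

# Centered running mean of a 0/1 vector over a window of `w` positions,
# computed with cumulative sums; edges use the truncated window.
.runMean <- function(v, w) {
  n <- length(v)
  if (n == 0L) return(numeric(0))
  half <- max(1L, as.integer(w) %/% 2L)
  cs <- cumsum(c(0, v))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Total length of the union of half-open intervals given as a 2-column
# matrix/data.frame (start, end).
.unionLen <- function(starts, ends) {
  if (length(starts) == 0L) return(0)
  o <- order(starts, ends)
  s <- starts[o]; e <- ends[o]
  tot <- 0; cs <- s[1]; ce <- e[1]
  for (i in seq_along(s)[-1]) {
    if (s[i] > ce) { tot <- tot + (ce - cs); cs <- s[i]; ce <- e[i] }
    else ce <- max(ce, e[i])
  }
  tot + (ce - cs)
}

# Overlap (in bp) of interval [s,e) with the union of intervals in (ss,ee).
.overlapWithUnion <- function(s, e, ss, ee) {
  if (length(ss) == 0L) return(0)
  is <- pmax(s, ss); ie <- pmin(e, ee)
  keep <- ie > is
  if (!any(keep)) return(0)
  .unionLen(is[keep], ie[keep])
}

# Deterministic per-component RNG substream: maps (seed, tag) to a seed in
# [0, 2^31). Adding a new tag never perturbs the stream of an existing one.
.substream <- function(seed, tag) {
  b <- utf8ToInt(tag)
  h <- sum(b * seq_along(b)) %% 100003L
  ((as.integer(seed) %% 1000003L) * 2099L + h * 31L) %% 2147483647L
}

# Random DNA string of length n at a given GC fraction.
.randSeq <- function(n, gc = 0.5) {
  if (n <= 0L) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(c("A", "C", "G", "T")[sample.int(4L, n, replace = TRUE, prob = p)],
        collapse = "")
}

# Apply substitutions to a DNA string at per-base probability `rate`;
# returns list(seq, positions) with 0-based substituted positions.
.mutateSeq <- function(s, rate) {
  n <- nchar(s)
  if (rate <= 0 || n == 0L) return(list(seq = s, positions = integer(0)))
  idx <- which(stats::runif(n) < rate)
  if (length(idx) == 0L) return(list(seq = s, positions = integer(0)))
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  for (i in idx) {
    cur <- toupper(ch[i])
    if (!cur %in% bases) next
    ch[i] <- sample(setdiff(bases, cur), 1L)
  }
  list(seq = paste(ch, collapse = ""), positions = idx - 1L)
}

# Positions (0-based) where two equal-length strings differ (byte compare).
.diffPositions <- function(a, b) {
  ra <- charToRaw(a); rb <- charToRaw(b)
  if (length(ra) != length(rb)) stop("sequences differ in length")
  which(ra != rb) - 1L
}
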