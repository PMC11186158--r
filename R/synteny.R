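# Synteny block chaining and chromosome fusion detection.

#' Chain filtered alignments into synteny blocks
#'
#' Within each (tname, qname, strand) group, alignments sorted by target
#' start are merged into one chain while both the target gap and the query
#' gap to the previous member are at most `maxChainGap` and the query order
#' is consistent with the strand (query coordinates increase with target
#' coordinates on "+", decrease on "-"). Blocks whose target span is
#' shorter than `minBlockLen` are discarded.
#'
#' @param aln filtered alignment data.frame.
#' @param maxChainGap maximum allowed gap (bp) on either genome.
#' @param minBlockLen minimum block target span (bp).
#' @return data.frame: tname, tstart, tend, qname, qstart, qend, strand,
#'   n_alignments, length, identity (block-length-weighted mean).
#' @export
chainBlocks <- function(aln, maxChainGap = 1e5, minBlockLen = 1e4) {
  empty <- data.frame(tname = character(0), tstart = integer(0),
                      tend = integer(0), qname = character(0),
                      qstart = integer(0), qend = integer(0),
                      strand = character(0), n_alignments = integer(0),
                      length = integer(0), identity = numeric(0))
  if (nrow(aln) == 0L) return(empty)
  key <- paste(aln$tname, aln$qname, aln$strand, sep = "\r")
  out <- list()
  for (k in unique(key)) {
    g <- aln[key == k, , drop = FALSE]
    g <- g[order(g$tstart), , drop = FALSE]
    chainId <- integer(nrow(g))
    cid <- 1L
    chainId[1] <- cid
    for (i in seq_len(nrow(g))[-1]) {
      tgap <- g$tstart[i] - g$tend[i - 1]
      if (g$strand[i] == "+") {
        qgap <- g$qstart[i] - g$qend[i - 1]
        ordered <- g$qstart[i] >= g$qstart[i - 1]
      } else {
        qgap <- g$qstart[i - 1] - g$qend[i]
        ordered <- g$qend[i] <= g$qend[i - 1]
      }
      if (tgap > maxChainGap || qgap > maxChainGap || !ordered) cid <- cid + 1L
      chainId[i] <- cid
    }
    for (cc in unique(chainId)) {
      m <- g[chainId == cc, , drop = FALSE]
      len <- max(m$tend) - min(m$tstart)
      out[[length(out) + 1L]] <- data.frame(
        tname = m$tname[1], tstart = min(m$tstart), tend = max(m$tend),
        qname = m$qname[1], qstart = min(m$qstart), qend = max(m$qend),
        strand = m$strand[1], n_alignments = nrow(m), length = len,
        identity = sum(m$identity * m$block_len) / sum(m$block_len),
        stringsAsFactors = FALSE)
    }
  }
  blocks <- do.call(rbind, out)
  blocks <- blocks[blocks$length >= minBlockLen, , drop = FALSE]
  if (nrow(blocks) == 0L) return(empty)
  blocks <- blocks[order(blocks$tname, blocks$tstart), , drop = FALSE]
  rownames(blocks) <- NULL
  blocks
}

#' Summarize colinear coverage and identity
#'
#' @param blocks synteny blocks from [chainBlocks()].
#' @param targetLens optional named target chromosome lengths, enabling
#'   the genome-fraction figure.
#' @return list: colinear_bp (union of block target intervals),
#'   colinear_fraction (or NA), mean_identity (block-length weighted),
#'   pairs (per chromosome-pair union coverage data.frame).
#' @export
syntenySummary <- function(blocks, targetLens = NULL) {
  if (nrow(blocks) == 0L)
    return(list(colinear_bp = 0, colinear_fraction = NA_real_,
                mean_identity = NA_real_,
                pairs = data.frame(tname = character(0), qname = character(0),
                                   covered_bp = numeric(0))))
  colinear <- sum(vapply(unique(blocks$tname), function(nm) {
    b <- blocks[blocks$tname == nm, ]
    .unionLen(b$tstart, b$tend)
  }, numeric(1)))
  key <- paste(blocks$tname, blocks$qname, sep = "\r")
  pairs <- do.call(rbind, lapply(unique(key), function(k) {
    b <- blocks[key == k, , drop = FALSE]
    data.frame(tname = b$tname[1], qname = b$qname[1],
               covered_bp = .unionLen(b$tstart, b$tend),
               stringsAsFactors = FALSE)
  }))
  list(colinear_bp = colinear,
       colinear_fraction = if (is.null(targetLens)) NA_real_ else
         colinear / sum(targetLens),
       mean_identity = sum(blocks$identity * blocks$length) /
         sum(blocks$length),
       pairs = pairs)
}

#' Detect chromosome fusion events
#'
#' A target chromosome supported as a fusion is one whose synteny blocks
#' map to at least two query chromosomes, each covering at least
#' `minFracEach` of the target length (interval unions, so overlapping
#' blocks are not double-counted).
#'
#' @param blocks synteny blocks from [chainBlocks()].
#' @param targetLens named target chromosome lengths.
#' @param minFracEach minimum covered fraction per partner.
#' @return data.frame: target_chrom, query_chrom, covered_bp,
#'   covered_frac, supported — partners sorted by covered_bp descending
#'   within each target; `supported` is TRUE on every row of a fused
#'   target.
#' @export
detectFusions <- function(blocks, targetLens, minFracEach = 0.2) {
  empty <- data.frame(target_chrom = character(0), query_chrom = character(0),
                      covered_bp = numeric(0), covered_frac = numeric(0),
                      supported = logical(0))
  if (nrow(blocks) == 0L) return(empty)
  if (any(!blocks$tname %in% names(targetLens)))
    stop("unknown target length for: ",
         setdiff(blocks$tname, names(targetLens))[1])
  out <- list()
  for (t in unique(blocks$tname)) {
    bt <- blocks[blocks$tname == t, , drop = FALSE]
    part <- do.call(rbind, lapply(unique(bt$qname), function(q) {
      b <- bt[bt$qname == q, , drop = FALSE]
      cov <- .unionLen(b$tstart, b$tend)
      data.frame(target_chrom = t, query_chrom = q, covered_bp = cov,
                 covered_frac = cov / targetLens[[t]],
                 stringsAsFactors = FALSE)
    }))
    part <- part[order(-part$covered_bp), , drop = FALSE]
    part$supported <- sum(part$covered_frac >= minFracEach) >= 2L
    out[[t]] <- part
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Supported fusion targets
#'
#' @param fusions output of [detectFusions()].
#' @return character vector of fused target chromosome names.
#' @export
supportedFusions <- function(fusions) {
  unique(fusions$target_chrom[fusions$supported])
}
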