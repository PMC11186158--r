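# Pairwise whole-genome alignment records are plain data.frames with the
# columns below; all coordinates 0-based half-open on the forward strand of
# both sequences (PAF convention):
#   qname qlen qstart qend strand tname tlen tstart tend matches block_len
#   identity score

.alnDf <- function(qname = character(0), qlen = integer(0), qstart = integer(0),
                   qend = integer(0), strand = character(0),
                   tname = character(0), tlen = integer(0),
                   tstart = integer(0), tend = integer(0),
                   matches = integer(0), block_len = integer(0),
                   score = NULL) {
  df <- data.frame(qname = qname, qlen = qlen, qstart = qstart, qend = qend,
                   strand = strand, tname = tname, tlen = tlen,
                   tstart = tstart, tend = tend, matches = matches,
                   block_len = block_len, stringsAsFactors = FALSE)
  df$identity <- ifelse(df$block_len > 0, 100 * df$matches / df$block_len, NA_real_)
  df$score <- if (is.null(score)) as.numeric(df$matches) else score
  df
}

#' Parse a PAF alignment file
#'
#' Standard 12+ column PAF (minimap2 dialect). Coordinates are kept as-is
#' (0-based half-open, query coordinates on the forward strand regardless
#' of orientation). `matches` is column 10, `block_len` column 11; an
#' `AS:i:` tag, when present, overrides the default score (= matches).
#'
#' @param path PAF path.
#' @return alignment data.frame (see [filterAlignments()]).
#' @export
parsePaf <- function(path) {
  lns <- readLines(path)
  lns <- lns[nzchar(lns)]
  if (length(lns) == 0L) return(.alnDf())
  f <- strsplit(lns, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 12L))
    stop("PAF line ", which(nf < 12L)[1], ": fewer than 12 columns")
  gi <- function(i) as.integer(vapply(f, `[`, "", i))
  gc_ <- function(i) vapply(f, `[`, "", i)
  qstart <- gi(3L); qend <- gi(4L)
  if (any(qend <= qstart))
    stop("PAF line ", which(qend <= qstart)[1], ": qend <= qstart")
  score <- as.numeric(gi(10L))
  as_tag <- vapply(f, function(v) {
    hit <- grep("^AS:i:", v[-(1:12)], value = TRUE)
    if (length(hit)) as.numeric(sub("^AS:i:", "", hit[1])) else NA_real_
  }, numeric(1))
  score[!is.na(as_tag)] <- as_tag[!is.na(as_tag)]
  .alnDf(qname = gc_(1L), qlen = gi(2L), qstart = qstart, qend = qend,
         strand = gc_(5L), tname = gc_(6L), tlen = gi(7L),
         tstart = gi(8L), tend = gi(9L), matches = gi(10L),
         block_len = gi(11L), score = score)
}

#' Write alignments as PAF
#'
#' @param aln alignment data.frame.
#' @param path output path.
#' @return `path` invisibly.
#' @export
writePaf <- function(aln, path) {
  qlen <- ifelse(is.na(aln$qlen), aln$qend, aln$qlen)
  tlen <- ifelse(is.na(aln$tlen), aln$tend, aln$tlen)
  lines <- paste(aln$qname, qlen, aln$qstart, aln$qend, aln$strand,
                 aln$tname, tlen, aln$tstart, aln$tend, aln$matches,
                 aln$block_len, 60L, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Parse MUMmer `show-coords -rTH` output
#'
#' Tab-delimited headerless dialect with columns S1 E1 S2 E2 LEN1 LEN2
#' %IDY REF QRY. Reference coordinates (1-based inclusive) are converted
#' to 0-based half-open; S2 > E2 encodes a reverse-strand hit and is
#' normalized to forward-strand qstart < qend with strand "-". The format
#' carries no raw match count, so matches are back-computed as
#' round(%IDY/100 * max(LEN1, LEN2)).
#'
#' @param path file path.
#' @return alignment data.frame.
#' @export
parseCoords <- function(path) {
  lns <- readLines(path)
  lns <- lns[nzchar(trimws(lns))]
  if (length(lns) == 0L) return(.alnDf())
  f <- strsplit(lns, "\t", fixed = TRUE)
  if (any(lengths(f) < 9L))
    stop("coords line ", which(lengths(f) < 9L)[1], ": fewer than 9 columns")
  num <- function(i) {
    v <- suppressWarnings(as.numeric(vapply(f, `[`, "", i)))
    if (anyNA(v)) stop("coords line ", which(is.na(v))[1],
                       ": non-numeric field in column ", i)
    v
  }
  s1 <- num(1L); e1 <- num(2L); s2 <- num(3L); e2 <- num(4L)
  len1 <- num(5L); len2 <- num(6L); idy <- num(7L)
  rev <- s2 > e2
  qstart <- ifelse(rev, e2, s2) - 1L
  qend <- ifelse(rev, s2, e2)
  block <- pmax(len1, len2)
  .alnDf(qname = vapply(f, `[`, "", 9L), qlen = NA_integer_,
         qstart = as.integer(qstart), qend = as.integer(qend),
         strand = ifelse(rev, "-", "+"),
         tname = vapply(f, `[`, "", 8L), tlen = NA_integer_,
         tstart = as.integer(s1 - 1L), tend = as.integer(e1),
         matches = as.integer(round(idy / 100 * block)),
         block_len = as.integer(block))
}

#' Write alignments in show-coords -rTH dialect
#'
#' @param aln alignment data.frame.
#' @param path output path.
#' @return `path` invisibly.
#' @export
writeCoords <- function(aln, path) {
  s2 <- ifelse(aln$strand == "-", aln$qend, aln$qstart + 1L)
  e2 <- ifelse(aln$strand == "-", aln$qstart + 1L, aln$qend)
  len1 <- aln$tend - aln$tstart
  len2 <- aln$qend - aln$qstart
  lines <- paste(aln$tstart + 1L, aln$tend, s2, e2, len1, len2,
                 sprintf("%.2f", aln$identity), aln$tname, aln$qname,
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

# Union-find for conflict components.
.ufFind <- function(parent, i) { while (parent[i] != i) i <- parent[i]; i }

# Exact maximum-score feasible subset of a small conflict component, by
# branch-and-bound over records in greedy order (include branch first, so
# score ties resolve toward the greedy choice).
.exactSelect <- function(df, maxOverlapFrac) {
  n <- nrow(df)
  best <- list(score = -1, sel = logical(n))
  ord <- seq_len(n)                      # df comes pre-sorted in greedy order
  feasible <- function(sel) {
    idx <- which(sel)
    for (i in idx) {
      oth <- setdiff(idx, i)
      same_t <- oth[df$tname[oth] == df$tname[i]]
      same_q <- oth[df$qname[oth] == df$qname[i]]
      tov <- .overlapWithUnion(df$tstart[i], df$tend[i],
                               df$tstart[same_t], df$tend[same_t])
      qov <- .overlapWithUnion(df$qstart[i], df$qend[i],
                               df$qstart[same_q], df$qend[same_q])
      if (tov > maxOverlapFrac * (df$tend[i] - df$tstart[i]) + 1e-9 ||
          qov > maxOverlapFrac * (df$qend[i] - df$qstart[i]) + 1e-9)
        return(FALSE)
    }
    TRUE
  }
  rec <- function(k, sel, score, remaining) {
    if (score + remaining <= best$score) return()
    if (k > n) {
      if (score > best$score) best <<- list(score = score, sel = sel)
      return()
    }
    selIn <- sel; selIn[ord[k]] <- TRUE
    if (feasible(selIn))
      rec(k + 1L, selIn, score + df$score[ord[k]],
          remaining - df$score[ord[k]])
    rec(k + 1L, sel, score, remaining - df$score[ord[k]])
  }
  rec(1L, logical(n), 0, sum(df$score))
  best$sel
}

# Greedy score-ordered selection within one component (records pre-sorted).
.greedySelect <- function(df, maxOverlapFrac) {
  n <- nrow(df)
  sel <- logical(n)
  for (i in seq_len(n)) {
    idx <- which(sel)
    same_t <- idx[df$tname[idx] == df$tname[i]]
    same_q <- idx[df$qname[idx] == df$qname[i]]
    tov <- .overlapWithUnion(df$tstart[i], df$tend[i],
                             df$tstart[same_t], df$tend[same_t])
    qov <- .overlapWithUnion(df$qstart[i], df$qend[i],
                             df$qstart[same_q], df$qend[same_q])
    if (tov <= maxOverlapFrac * (df$tend[i] - df$tstart[i]) + 1e-9 &&
        qov <= maxOverlapFrac * (df$qend[i] - df$qstart[i]) + 1e-9)
      sel[i] <- TRUE
  }
  sel
}

#' Filter whole-genome alignments
#'
#' Drops records shorter than `minLen` or below `minIdentity`, then
#' optionally enforces a one-to-one tiling: no accepted record may overlap
#' the other accepted records on its target interval or its query interval
#' by more than `maxOverlapFrac` of its own length. Selection maximizes
#' total score exactly within small conflict components (branch-and-bound,
#' components of up to `exactLimit` records) and falls back to greedy
#' score-ordered acceptance inside larger components. Ties are broken by
#' longer block, then (tname, tstart).
#'
#' @param aln alignment data.frame ([parsePaf()]/[parseCoords()] output).
#' @param minLen minimum block length in bp (cf. MUMmer delta-filter -l).
#' @param minIdentity minimum percent identity.
#' @param oneToOne enforce the one-to-one constraint.
#' @param maxOverlapFrac maximum allowed overlap fraction (default 0.5).
#' @param exactLimit largest conflict component solved exactly.
#' @return filtered alignment data.frame sorted by (tname, tstart).
#' @export
filterAlignments <- function(aln, minLen = 0L, minIdentity = 0,
                             oneToOne = FALSE, maxOverlapFrac = 0.5,
                             exactLimit = 20L) {
  keep <- aln$block_len >= minLen & aln$identity >= minIdentity
  df <- aln[keep, , drop = FALSE]
  if (oneToOne && nrow(df) > 1L) {
    ord <- order(-df$score, -df$block_len, df$tname, df$tstart)
    df <- df[ord, , drop = FALSE]
    n <- nrow(df)
    parent <- seq_len(n)
    for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
      tHit <- df$tname[i] == df$tname[j] &&
        min(df$tend[i], df$tend[j]) > max(df$tstart[i], df$tstart[j])
      qHit <- df$qname[i] == df$qname[j] &&
        min(df$qend[i], df$qend[j]) > max(df$qstart[i], df$qstart[j])
      if (tHit || qHit) {
        ri <- .ufFind(parent, i); rj <- .ufFind(parent, j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
    roots <- vapply(seq_len(n), function(i) .ufFind(parent, i), integer(1))
    sel <- logical(n)
    for (r in unique(roots)) {
      idx <- which(roots == r)
      comp <- df[idx, , drop = FALSE]
      sel[idx] <- if (length(idx) <= exactLimit)
        .exactSelect(comp, maxOverlapFrac)
      else .greedySelect(comp, maxOverlapFrac)
    }
    df <- df[sel, , drop = FALSE]
  }
  df <- df[order(df$tname, df$tstart), , drop = FALSE]
  rownames(df) <- NULL
  df
}
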