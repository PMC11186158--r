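#' Read a FASTA file into a named character vector
#'
#' Sequence names are the header token up to the first whitespace; file
#' order is preserved, soft-masking (lowercase) and IUPAC codes are kept
#' verbatim. Parsing is delegated to Biostrings.
#'
#' @param path path to a FASTA file (plain or gzipped).
#' @return named character vector of sequences.
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  magic <- readBin(path, "raw", 2L)
  gzipped <- length(magic) == 2L && magic[1] == as.raw(0x1f) &&
    magic[2] == as.raw(0x8b)
  if (!gzipped && (length(magic) == 0L || magic[1] != charToRaw(">")))
    stop("not a FASTA file (first byte is not '>'): ", path)
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate sequence id: ", dup[1])
  if (any(Biostrings::width(ss) == 0L))
    stop("empty sequence under header: ", ids[Biostrings::width(ss) == 0L][1])
  out <- as.character(ss)
  names(out) <- ids
  out
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector or XStringSet.
#' @param path output path.
#' @param width line width (default 60 columns).
#' @return `path`, invisibly.
#' @export
writeFasta <- function(seqs, path, width = 60L) {
  seqs <- .asSeqs(seqs)
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, filepath = path, width = as.integer(width))
  invisible(path)
}

#' Locate N-gaps in sequences
#'
#' A gap is a maximal run of N/n of length >= `minGapLen`. Coordinates are
#' 0-based half-open.
#'
#' @param x assembly (named character vector / XStringSet) or a single
#'   unnamed string (then `chrom` must be given).
#' @param minGapLen minimum N-run length counted as a gap (default 1).
#' @param chrom sequence name when `x` is a bare string.
#' @return data.frame: chrom, start, end, length; sorted by (chrom, start).
#' @examples
#' findGaps(c(chr1 = "AANNNNAA"))
#' @export
findGaps <- function(x, minGapLen = 1L, chrom = NULL) {
  if (is.character(x) && is.null(names(x)) && length(x) == 1L) {
    names(x) <- if (is.null(chrom)) "seq" else chrom
  }
  seqs <- .asSeqs(x)
  stopifnot(minGapLen >= 1L)
  res <- lapply(names(seqs), function(nm) {
    m <- gregexpr("[Nn]+", seqs[[nm]], useBytes = TRUE)[[1]]
    if (m[1] == -1L) return(NULL)
    len <- attr(m, "match.length")
    keep <- len >= minGapLen
    if (!any(keep)) return(NULL)
    data.frame(chrom = nm, start = as.integer(m[keep]) - 1L,
               end = as.integer(m[keep]) - 1L + len[keep],
               length = len[keep], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), length = integer(0))
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Assembly summary statistics
#'
#' Contigs are the N-free segments obtained by splitting each sequence at
#' gaps of length >= `minGapLen`. N50 is the length at which the cumulative
#' sum of descending-sorted contig lengths first reaches half the summed
#' contig length; L50 is the number of contigs needed to reach it. GC is
#' computed over unambiguous A/C/G/T bases only.
#'
#' @param x assembly (named character vector or XStringSet).
#' @param minGapLen minimum N-run length treated as a gap.
#' @return list with n_sequences, total_len, n_gaps, gap_bp, n_contigs,
#'   contig_N50, contig_L50, max_contig, gc_fraction, gap_free_chrom_count.
#' @export
assemblyStats <- function(x, minGapLen = 1L) {
  seqs <- .asSeqs(x)
  if (length(seqs) == 0L) stop("empty assembly")
  gaps <- findGaps(seqs, minGapLen = minGapLen)
  lens <- nchar(seqs)
  contigLens <- unlist(lapply(names(seqs), function(nm) {
    g <- gaps[gaps$chrom == nm, , drop = FALSE]
    bounds <- c(0L, rbind(g$start, g$end), lens[[nm]])
    starts <- bounds[seq(1, length(bounds), by = 2)]
    ends <- bounds[seq(2, length(bounds), by = 2)]
    (ends - starts)[ends > starts]
  }), use.names = FALSE)
  if (length(contigLens) == 0L) stop("no contig sequence")
  sorted <- sort(contigLens, decreasing = TRUE)
  half <- sum(sorted) / 2
  l50 <- which(cumsum(sorted) >= half)[1]
  gcb <- charToRaw("CcGg"); atb <- charToRaw("AaTt")
  gc <- 0; at <- 0
  for (s in seqs) {
    r <- charToRaw(s)
    gc <- gc + sum(r %in% gcb)
    at <- at + sum(r %in% atb)
  }
  list(
    n_sequences = length(seqs),
    total_len = sum(lens),
    n_gaps = nrow(gaps),
    gap_bp = sum(gaps$length),
    n_contigs = length(contigLens),
    contig_N50 = sorted[l50],
    contig_L50 = l50,
    max_contig = sorted[1],
    gc_fraction = if (gc + at > 0) gc / (gc + at) else NA_real_,
    gap_free_chrom_count = sum(!names(seqs) %in% gaps$chrom)
  )
}

#' Write / read BED intervals (0-based half-open)
#'
#' @param intervals data.frame with chrom, start, end (extra columns
#'   appended verbatim).
#' @param path file path.
#' @param chromLens optional named lengths; when given, intervals outside
#'   chromosome bounds raise an error.
#' @return `path` invisibly (write); data.frame (read).
#' @export
writeBed <- function(intervals, path, chromLens = NULL) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  if (!is.null(chromLens)) {
    bad <- intervals$start < 0 | intervals$end > chromLens[intervals$chrom]
    if (any(bad, na.rm = TRUE) || any(is.na(chromLens[intervals$chrom])))
      stop("interval outside chromosome bounds: ",
           intervals$chrom[which(bad | is.na(chromLens[intervals$chrom]))[1]])
  }
  extra <- setdiff(names(intervals), c("chrom", "start", "end"))
  df <- intervals[, c("chrom", "start", "end", extra), drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeBed
#' @export
readBed <- function(path) {
  if (file.size(path) == 0)
    return(data.frame(chrom = character(0), start = integer(0), end = integer(0)))
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  df
}

#' Write an AGP v2.1 description of an assembly
#'
#' Each sequence becomes one AGP object whose W (contig) and N (gap)
#' component lines tile it exactly; coordinates are 1-based inclusive as
#' the format requires.
#'
#' @param x assembly (named character vector or XStringSet).
#' @param path output path.
#' @param minGapLen minimum N-run emitted as an N line.
#' @return `path`, invisibly.
#' @export
writeAgp <- function(x, path, minGapLen = 1L) {
  seqs <- .asSeqs(x)
  gaps <- findGaps(seqs, minGapLen = minGapLen)
  lines <- c("##agp-version\t2.1")
  for (nm in names(seqs)) {
    g <- gaps[gaps$chrom == nm, , drop = FALSE]
    len <- nchar(seqs[[nm]])
    bounds <- c(0L, rbind(g$start, g$end), len)
    part <- 0L; ctg <- 0L
    for (i in seq(1, length(bounds) - 1)) {
      s <- bounds[i]; e <- bounds[i + 1]
      if (e <= s) next
      part <- part + 1L
      isGap <- i %% 2 == 0
      if (isGap) {
        lines <- c(lines, paste(nm, s + 1L, e, part, "N", e - s,
                                "scaffold", "yes", "align_genus", sep = "\t"))
      } else {
        ctg <- ctg + 1L
        lines <- c(lines, paste(nm, s + 1L, e, part, "W",
                                paste0(nm, "_ctg", ctg), 1L, e - s, "+",
                                sep = "\t"))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read an AGP file
#'
#' @param path AGP path.
#' @return data.frame with object, object_beg, object_end (1-based
#'   inclusive), part_number, component_type and the remaining AGP columns.
#' @export
readAgp <- function(path) {
  lns <- readLines(path)
  lns <- lns[!grepl("^#", lns) & nzchar(lns)]
  f <- strsplit(lns, "\t", fixed = TRUE)
  data.frame(
    object = vapply(f, `[`, "", 1L),
    object_beg = as.integer(vapply(f, `[`, "", 2L)),
    object_end = as.integer(vapply(f, `[`, "", 3L)),
    part_number = as.integer(vapply(f, `[`, "", 4L)),
    component_type = vapply(f, `[`, "", 5L),
    col6 = vapply(f, `[`, "", 6L),
    col7 = vapply(f, `[`, "", 7L),
    col8 = vapply(f, `[`, "", 8L),
    col9 = vapply(f, `[`, "", 9L),
    stringsAsFactors = FALSE)
}
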