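# Post-patch quality control: junction read-depth checks, k-mer QV, and the
# homozygous-variant error rate.

#' Read a per-base depth track
#'
#' Accepts samtools-depth-style TSV (chrom, 1-based pos, depth) or
#' per-base BEDGRAPH (chrom, 0-based start, end, depth). Positions absent
#' from the file get depth 0.
#'
#' @param path file path.
#' @param chromLens named chromosome lengths (required to size the arrays).
#' @param format "depth" (samtools depth) or "bedgraph".
#' @return named list of integer depth vectors (one per chromosome,
#'   index i = position i-1).
#' @export
readDepth <- function(path, chromLens, format = c("depth", "bedgraph")) {
  format <- match.arg(format)
  track <- lapply(chromLens, function(n) integer(n))
  if (file.size(path) > 0) {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE)
    for (nm in unique(df[[1]])) {
      if (!nm %in% names(track)) stop("depth track names unknown chromosome: ", nm)
      sub <- df[df[[1]] == nm, , drop = FALSE]
      if (format == "depth") {
        track[[nm]][sub[[2]]] <- sub[[3]]
      } else {
        for (i in seq_len(nrow(sub)))
          track[[nm]][(sub[[2]][i] + 1L):sub[[3]][i]] <- sub[[4]][i]
      }
    }
  }
  track
}

#' Uniform depth track with optional zero-coverage holes
#'
#' @param x assembly (named character vector or XStringSet).
#' @param coverage constant depth value.
#' @param holes optional data.frame (chrom, start, end; 0-based half-open)
#'   of zero-depth intervals.
#' @return named list of integer depth vectors.
#' @export
uniformDepth <- function(x, coverage = 30L, holes = NULL) {
  seqs <- .asSeqs(x)
  track <- lapply(seqs, function(s) rep(as.integer(coverage), nchar(s)))
  if (!is.null(holes)) for (i in seq_len(nrow(holes))) {
    nm <- holes$chrom[i]
    track[[nm]][(holes$start[i] + 1L):holes$end[i]] <- 0L
  }
  track
}

#' Check read depth around patch junctions
#'
#' One check per junction: pass when the minimum depth over
#' \[pos - window, pos + window\] (clipped at chromosome ends) is at least
#' `minDepth`.
#'
#' @param depth named list of per-base integer depth vectors (patched
#'   coordinates).
#' @param junctions data.frame (chrom, pos), e.g. [junctionSites()].
#' @param window half-window in bp.
#' @param minDepth required minimum depth.
#' @return data.frame: chrom, pos, window_start, window_end, min_depth,
#'   pass; with attribute `summary` = list(n, n_pass, n_fail).
#' @export
junctionCoverage <- function(depth, junctions, window = 50L, minDepth = 1L) {
  rows <- lapply(seq_len(nrow(junctions)), function(i) {
    nm <- junctions$chrom[i]; pos <- junctions$pos[i]
    d <- depth[[nm]]
    if (is.null(d)) stop("junction on unknown chromosome: ", nm)
    lo <- max(0L, pos - window)
    hi <- min(length(d), pos + window)
    md <- if (hi > lo) min(d[(lo + 1L):hi]) else NA_integer_
    data.frame(chrom = nm, pos = pos, window_start = lo, window_end = hi,
               min_depth = md, pass = !is.na(md) && md >= minDepth,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(chrom = character(0), pos = integer(0),
                      window_start = integer(0), window_end = integer(0),
                      min_depth = integer(0), pass = logical(0))
  attr(out, "summary") <- list(n = nrow(out), n_pass = sum(out$pass),
                               n_fail = sum(!out$pass))
  out
}

#' k-mer based assembly quality value (QV)
#'
#' Reference-free QV from the fraction of distinct canonical assembly
#' k-mers found in the read k-mer set: the per-base error rate is
#' estimated as 1 - (shared/total)^(1/k) and QV = -10 log10(error),
#' capped at `qvCap` (error 0 reports the cap).
#'
#' @param assemblyKmers character vector of canonical assembly k-mers
#'   (see [kmerSet()]).
#' @param readKmers character vector of canonical read k-mers.
#' @param k the k-mer size both sets were built with.
#' @param qvCap upper bound reported when the error estimate is 0.
#' @return list: k, assembly_kmer_total, assembly_kmer_shared,
#'   per_base_error, qv.
#' @export
kmerQV <- function(assemblyKmers, readKmers, k = 21L, qvCap = 99) {
  total <- length(assemblyKmers)
  if (total == 0L) stop("no k-mers")
  shared <- sum(assemblyKmers %in% readKmers)
  err <- 1 - (shared / total)^(1 / k)
  qv <- if (err > 0) min(-10 * log10(err), qvCap) else qvCap
  list(k = as.integer(k), assembly_kmer_total = total,
       assembly_kmer_shared = shared, per_base_error = err, qv = qv)
}

#' Read a k-mer list (one k-mer per line)
#'
#' @param path file path.
#' @return character vector.
#' @export
readKmerList <- function(path) {
  x <- readLines(path)
  x[nzchar(x)]
}

#' Homozygous-variant error rate of an assembly
#'
#' Counts VCF records with a homozygous-alternate genotype (1/1 or 1|1)
#' passing QUAL and depth filters, divided by the assembly size — the
#' base-level error proxy used alongside the k-mer QV. Records without a
#' GT field are skipped and counted.
#'
#' @param vcf path to a VCF file (read with VariantAnnotation), or a
#'   data.frame with columns gt, qual, dp.
#' @param assemblySize assembly length in bp.
#' @param minQual minimum QUAL.
#' @param minDepth minimum sample depth (ignored when no DP is available).
#' @return list: homozygous_variants, assembly_size, rate, n_skipped.
#' @export
homozygousErrorRate <- function(vcf, assemblySize, minQual = 30,
                                minDepth = 5) {
  stopifnot(assemblySize > 0)
  if (is.character(vcf)) {
    if (!requireNamespace("VariantAnnotation", quietly = TRUE))
      stop("reading VCF files requires the VariantAnnotation package")
    v <- VariantAnnotation::readVcf(vcf)
    g <- VariantAnnotation::geno(v)
    gt <- if ("GT" %in% names(g)) as.character(g$GT[, 1]) else
      rep(NA_character_, nrow(v))
    dp <- if ("DP" %in% names(g)) suppressWarnings(as.numeric(g$DP[, 1])) else
      rep(NA_real_, nrow(v))
    qual <- VariantAnnotation::qual(v)
    vcf <- data.frame(gt = gt, qual = qual, dp = dp,
                      stringsAsFactors = FALSE)
  }
  skipped <- is.na(vcf$gt) | vcf$gt %in% c(".", "./.", ".|.")
  if (any(skipped))
    warning(sum(skipped), " record(s) without GT skipped")
  ok <- !skipped &
    vcf$gt %in% c("1/1", "1|1") &
    (is.na(vcf$qual) | vcf$qual >= minQual) &
    (is.na(vcf$dp) | vcf$dp >= minDepth)
  n <- sum(ok)
  list(homozygous_variants = n, assembly_size = assemblySize,
       rate = n / assemblySize, n_skipped = sum(skipped))
}
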