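# Shared fixture builders. Small genomes keep unit tests fast; the
# acceptance tests use the full-size defaults of simConfig().

smallSimConfig <- function(seed = 1L, ...) {
  defaults <- list(seed = seed, nChroms = 3L, chromLen = 200000L,
                   telomereCopies = 100L, centromereArrayLen = 20000L,
                   nGapsPerChrom = 3L, gapLenRange = c(100L, 500L),
                   donorFragLenRange = c(60000L, 120000L))
  args <- utils::modifyList(defaults, list(...))
  do.call(simConfig, args)
}

# random DNA for ad-hoc fixtures (test-local, independent of the package's
# internal generator)
randDna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

# one alignment data.frame row in the internal schema
alnRow <- function(qname, qstart, qend, strand, tname, tstart, tend,
                   matches = NULL, block_len = NULL, score = NULL) {
  if (is.null(block_len)) block_len <- max(qend - qstart, tend - tstart)
  if (is.null(matches)) matches <- block_len
  df <- data.frame(qname = qname, qlen = NA_integer_, qstart = qstart,
                   qend = qend, strand = strand, tname = tname,
                   tlen = NA_integer_, tstart = tstart, tend = tend,
                   matches = matches, block_len = block_len,
                   stringsAsFactors = FALSE)
  df$identity <- 100 * df$matches / df$block_len
  df$score <- if (is.null(score)) as.numeric(df$matches) else score
  df
}
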