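#' @import methods
NULL

#' SimulatedGenome: a truth genome with planted annotation
#'
#' Container returned by [simulateGenome()]. Holds the truth chromosome
#' sequences together with the coordinates of every planted feature
#' (telomere arrays, centromeric tandem array) and the configuration that
#' produced them, so downstream detectors can be scored against ground
#' truth.
#'
#' @slot genome named character vector of chromosome sequences.
#' @slot telomeres data.frame: chrom, start, end, end_label (5prime/3prime).
#' @slot centromeres data.frame: chrom, start, end, monomer (sequence),
#'   monomer_len.
#' @slot config the `SimConfig` list used to build the object.
#' @export
setClass("SimulatedGenome",
  representation(genome = "character", telomeres = "data.frame",
                 centromeres = "data.frame", config = "list"))

setValidity("SimulatedGenome", function(object) {
  msg <- character(0)
  if (is.null(names(object@genome)) || anyDuplicated(names(object@genome)))
    msg <- c(msg, "genome must be a uniquely named character vector")
  lens <- nchar(object@genome)
  for (df in list(object@telomeres, object@centromeres)) {
    if (nrow(df) == 0) next
    bad <- df$start < 0 | df$end > lens[df$chrom] | df$start >= df$end
    if (any(bad)) msg <- c(msg, "annotation interval outside chromosome bounds")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn SimulatedGenome chromosome sequences (named character vector)
#' @param x a `SimulatedGenome`
#' @export
genomeSeqs <- function(x) x@genome

#' @describeIn SimulatedGenome planted telomere intervals
#' @export
telomereIntervals <- function(x) x@telomeres

#' @describeIn SimulatedGenome planted centromere intervals
#' @export
centromereIntervals <- function(x) x@centromeres

setMethod("show", "SimulatedGenome", function(object) {
  cat(sprintf("SimulatedGenome: %d chromosome(s), %s bp total\n",
              length(object@genome),
              format(sum(nchar(object@genome)), big.mark = ",")))
  cat(sprintf("  telomere arrays: %d   centromere arrays: %d   seed: %s\n",
              nrow(object@telomeres), nrow(object@centromeres),
              object@config$seed))
})

#' GapFillResult: a patched assembly with liftover and report
#'
#' Returned by [applyPatches()] (and [fillGaps()]). Bundles the patched
#' sequences, the old-to-new coordinate liftover, the junction positions of
#' every applied patch (new coordinates), the plan table, and a per-gap /
#' per-chromosome report.
#'
#' @slot assembly named character vector: the patched sequences.
#' @slot liftover list with `segments` (per-chromosome data.frame of
#'   old_start, old_end, new_start) and `patches` (chrom, new_start,
#'   new_end in new coordinates).
#' @slot plans the plan data.frame that was applied (all statuses).
#' @slot junctions data.frame: chrom, pos (new coordinates) — both ends of
#'   every applied patch.
#' @slot report list: `perGap` data.frame, `totals` (found, filled,
#'   unfilled), `residualGaps` per-chromosome residual gap counts.
#' @export
setClass("GapFillResult",
  representation(assembly = "character", liftover = "list",
                 plans = "data.frame", junctions = "data.frame",
                 report = "list"))

setValidity("GapFillResult", function(object) {
  t <- object@report$totals
  if (!is.null(t) && t$filled + t$unfilled != t$found)
    return("report totals inconsistent: filled + unfilled != found")
  if (is.null(names(object@assembly)))
    return("assembly must be named")
  TRUE
})

#' @describeIn GapFillResult the patched assembly (named character vector)
#' @param x a `GapFillResult`
#' @export
patchedAssembly <- function(x) x@assembly

#' @describeIn GapFillResult the coordinate liftover map
#' @export
liftoverMap <- function(x) x@liftover

#' @describeIn GapFillResult per-gap report and totals
#' @export
patchReport <- function(x) x@report

#' @describeIn GapFillResult patch junction positions in new coordinates
#' @export
junctionSites <- function(x) x@junctions

setMethod("show", "GapFillResult", function(object) {
  t <- object@report$totals
  cat(sprintf("GapFillResult: %d sequence(s); gaps found %d, filled %d, unfilled %d\n",
              length(object@assembly), t$found, t$filled, t$unfilled))
  res <- object@report$residualGaps
  cat(sprintf("  residual gaps: %d\n", sum(res$n_gaps)))
})
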