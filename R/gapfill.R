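# Gap patching: choose donor sequence for each N-gap from flank-anchored or
# gap-spanning alignments, splice it in, and keep the books (liftover,
# junctions, per-gap report).

# Project a target coordinate through one alignment onto donor forward-strand
# coordinates by linear interpolation between the alignment endpoints
# (extrapolates when t falls outside the aligned target interval).
.projectToDonor <- function(aln, t) {
  f <- (t - aln$tstart) / (aln$tend - aln$tstart)
  if (aln$strand == "+") round(aln$qstart + f * (aln$qend - aln$qstart))
  else round(aln$qend - f * (aln$qend - aln$qstart))
}

#' Find anchor alignments flanking a gap
#'
#' Left anchors are alignments that start before the gap and whose target
#' end reaches within `flankWindow` of the gap start (or extends past it);
#' right anchors are symmetric about the gap end. An alignment whose target
#' interval contains the whole gap appears in both lists (a spanning
#' anchor). `donor_inner` is the donor forward-strand coordinate of the
#' alignment endpoint nearest the gap, respecting strand.
#'
#' @param gap one-row data.frame (chrom, start, end) — a [findGaps()] row.
#' @param aln filtered alignment data.frame, any chromosomes (subset
#'   internally).
#' @param flankWindow maximum distance (bp) from alignment end to gap edge.
#' @param minAnchorLen minimum anchor block length (bp).
#' @return list(left = data.frame, right = data.frame); each row adds
#'   `.aid` (alignment row id), `target_inner`, `donor_inner`,
#'   `distance_to_gap`.
#' @export
findAnchors <- function(gap, aln, flankWindow = 5000L, minAnchorLen = 1000L) {
  a <- aln[aln$tname == gap$chrom & aln$block_len >= minAnchorLen, , drop = FALSE]
  a$.aid <- seq_len(nrow(aln))[aln$tname == gap$chrom &
                                 aln$block_len >= minAnchorLen]
  mk <- function(rows, side) {
    if (nrow(rows) == 0L) {
      rows$target_inner <- integer(0); rows$donor_inner <- integer(0)
      rows$distance_to_gap <- integer(0); rows$side <- character(0)
      return(rows)
    }
    rows$side <- side
    if (side == "left") {
      rows$target_inner <- pmin(rows$tend, gap$start)
      rows$distance_to_gap <- pmax(0L, gap$start - rows$tend)
    } else {
      rows$target_inner <- pmax(rows$tstart, gap$end)
      rows$distance_to_gap <- pmax(0L, rows$tstart - gap$end)
    }
    rows$donor_inner <- vapply(seq_len(nrow(rows)), function(i)
      .projectToDonor(rows[i, ], rows$target_inner[i]), numeric(1))
    rows
  }
  left <- a[a$tstart < gap$start & a$tend >= gap$start - flankWindow, , drop = FALSE]
  right <- a[a$tend > gap$end & a$tstart <= gap$end + flankWindow, , drop = FALSE]
  list(left = mk(left, "left"), right = mk(right, "right"))
}

.planRow <- function(gap, status, mode = NA_character_, donor = NA_character_,
                     dstart = NA_integer_, dend = NA_integer_,
                     orientation = NA_character_, left_trim = 0L,
                     right_trim = 0L, left_identity = NA_real_,
                     right_identity = NA_real_, score = NA_real_) {
  data.frame(chrom = gap$chrom, gap_start = gap$start, gap_end = gap$end,
             gap_len = gap$end - gap$start, mode = mode, donor_name = donor,
             donor_start = dstart, donor_end = dend,
             orientation = orientation, left_trim = left_trim,
             right_trim = right_trim,
             patch_len = if (is.na(dstart)) NA_integer_ else dend - dstart,
             left_identity = left_identity, right_identity = right_identity,
             score = score, status = status, stringsAsFactors = FALSE)
}

#' Plan the patch for one gap
#'
#' A gap-spanning alignment is preferred: the gap edges are projected
#' through it onto the donor and the projected interval becomes the patch.
#' Otherwise the best concordant (left, right) anchor pair — same donor
#' contig, same strand, donor-colinear, maximal summed score — defines the
#' patch between the projections of the two gap edges. When the projected
#' donor span is negative the donor indicates the flanks overlap; an
#' overlap up to `trimCap` is resolved by trimming the left target flank,
#' larger overlaps get status `donor_overlap_unresolvable`. Every failure
#' mode is a status, never an error.
#'
#' @param gap one-row gap data.frame.
#' @param anchors output of [findAnchors()].
#' @param maxPatchLen maximum allowed donor patch length (bp).
#' @param trimCap maximum flank trim (bp).
#' @param donorLens optional named donor sequence lengths, used to clamp
#'   projected intervals to contig bounds.
#' @return one-row plan data.frame; `status` is one of planned,
#'   no_left_anchor, no_right_anchor, discordant_anchors, span_too_long,
#'   donor_overlap_unresolvable.
#' @export
planPatch <- function(gap, anchors, maxPatchLen = 5e6, trimCap = 1000L,
                      donorLens = NULL) {
  left <- anchors$left; right <- anchors$right
  if (nrow(left) == 0L) return(.planRow(gap, "no_left_anchor"))
  if (nrow(right) == 0L) return(.planRow(gap, "no_right_anchor"))

  clamp <- function(v, donor) {
    if (is.null(donorLens)) return(as.integer(v))
    as.integer(pmin(pmax(v, 0), donorLens[[donor]]))
  }

  span_ids <- intersect(left$.aid, right$.aid)
  if (length(span_ids)) {
    cand <- left[left$.aid %in% span_ids, , drop = FALSE]
    cand <- cand[order(-cand$score, -cand$block_len, cand$qname), , drop = FALSE]
    a <- cand[1, ]
    d1 <- .projectToDonor(a, gap$start)
    d2 <- .projectToDonor(a, gap$end)
    lo <- clamp(min(d1, d2), a$qname); hi <- clamp(max(d1, d2), a$qname)
    if (hi - lo > maxPatchLen)
      return(.planRow(gap, "span_too_long", mode = "spanning",
                      donor = a$qname, score = a$score))
    return(.planRow(gap, "planned", mode = "spanning", donor = a$qname,
                    dstart = lo, dend = hi, orientation = a$strand,
                    left_identity = a$identity, right_identity = a$identity,
                    score = a$score))
  }

  # paired anchors: all concordant (left i, right j) combinations
  bestRow <- NULL; bestKey <- NULL
  for (i in seq_len(nrow(left))) for (j in seq_len(nrow(right))) {
    li <- left[i, ]; rj <- right[j, ]
    if (li$qname != rj$qname || li$strand != rj$strand) next
    d1 <- .projectToDonor(li, gap$start)   # donor coord of gap start
    d2 <- .projectToDonor(rj, gap$end)     # donor coord of gap end
    span <- if (li$strand == "+") d2 - d1 else d1 - d2
    if (span < -trimCap) next              # donor-discordant beyond trimming
    key <- c(li$score + rj$score, -abs(span))
    better <- is.null(bestKey) ||
      key[1] > bestKey[1] + 1e-9 ||
      (abs(key[1] - bestKey[1]) <= 1e-9 && key[2] > bestKey[2]) ||
      (abs(key[1] - bestKey[1]) <= 1e-9 && key[2] == bestKey[2] &&
         li$qname < bestRow$donor_name)
    if (!better) next
    if (span > maxPatchLen) {
      bestRow <- .planRow(gap, "span_too_long", mode = "paired",
                          donor = li$qname, score = li$score + rj$score)
    } else if (span >= 0) {
      lo <- if (li$strand == "+") d1 else d2
      bestRow <- .planRow(gap, "planned", mode = "paired", donor = li$qname,
                          dstart = clamp(lo, li$qname),
                          dend = clamp(lo + span, li$qname),
                          orientation = li$strand,
                          left_identity = li$identity,
                          right_identity = rj$identity,
                          score = li$score + rj$score)
    } else {
      # negative span within trimCap: flanks overlap by -span in the donor;
      # trim the left target flank and insert nothing
      pos <- if (li$strand == "+") d2 else d1
      bestRow <- .planRow(gap, "planned", mode = "paired", donor = li$qname,
                          dstart = clamp(pos, li$qname),
                          dend = clamp(pos, li$qname),
                          orientation = li$strand, left_trim = -span,
                          left_identity = li$identity,
                          right_identity = rj$identity,
                          score = li$score + rj$score)
    }
    bestKey <- key
  }
  if (is.null(bestRow)) {
    # any pair at all (same donor/strand) whose span was hopelessly negative?
    anyPair <- any(outer(seq_len(nrow(left)), seq_len(nrow(right)),
                         Vectorize(function(i, j)
                           left$qname[i] == right$qname[j] &&
                             left$strand[i] == right$strand[j])))
    return(.planRow(gap, if (anyPair) "donor_overlap_unresolvable"
                    else "discordant_anchors"))
  }
  bestRow
}

#' Plan patches for every gap of a target assembly
#'
#' @param gaps gap data.frame from [findGaps()].
#' @param aln filtered alignment data.frame (donor vs target).
#' @param flankWindow,minAnchorLen passed to [findAnchors()].
#' @param maxPatchLen,trimCap passed to [planPatch()].
#' @param donorLens optional named donor lengths.
#' @return plan data.frame, one row per gap.
#' @export
planPatches <- function(gaps, aln, flankWindow = 5000L, minAnchorLen = 1000L,
                        maxPatchLen = 5e6, trimCap = 1000L, donorLens = NULL) {
  rows <- lapply(seq_len(nrow(gaps)), function(i) {
    g <- gaps[i, ]
    planPatch(g, findAnchors(g, aln, flankWindow, minAnchorLen),
              maxPatchLen, trimCap, donorLens)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- .planRow(data.frame(chrom = "x", start = 0L, end = 1L), "planned")[0, ]
  rownames(out) <- NULL
  out
}

#' Apply planned patches to the target assembly
#'
#' Planned gaps (plus any trimmed flank bases) are replaced by the donor
#' subsequence, reverse-complemented for orientation "-". Patched bases are
#' emitted uppercase; all other bases keep their case. Edits on one
#' chromosome are applied right-to-left so earlier coordinates stay valid.
#' Unplanned gaps are left untouched.
#'
#' @param target assembly to patch (named character vector or XStringSet).
#' @param donor donor assembly.
#' @param plans plan data.frame from [planPatches()].
#' @return a [GapFillResult-class] object.
#' @export
applyPatches <- function(target, donor, plans) {
  target <- .asSeqs(target); donor <- .asSeqs(donor)
  ap <- plans[plans$status == "planned", , drop = FALSE]
  missing <- setdiff(ap$donor_name, names(donor))
  if (length(missing)) stop("donor sequence not found: ", missing[1])

  out <- target
  segments <- list(); patchIv <- NULL; junc <- NULL
  for (nm in names(target)) {
    p <- ap[ap$chrom == nm, , drop = FALSE]
    p <- p[order(p$gap_start), , drop = FALSE]
    estart <- p$gap_start - p$left_trim
    eend <- p$gap_end + p$right_trim
    if (nrow(p) > 1L && any(estart[-1] < eend[-nrow(p)])) {
      i <- which(estart[-1] < eend[-nrow(p)])[1]
      stop("overlapping patch intervals on ", nm, ": gaps at ",
           p$gap_start[i], " and ", p$gap_start[i + 1])
    }
    oldLen <- nchar(target[[nm]])
    if (nrow(p) > 0L && (any(estart < 0) || any(eend > oldLen)))
      stop("patch interval outside chromosome bounds on ", nm)

    patches <- character(nrow(p))
    for (i in seq_len(nrow(p))) {
      ds <- donor[[p$donor_name[i]]]
      sub <- substr(ds, p$donor_start[i] + 1L, p$donor_end[i])
      if (p$orientation[i] == "-") sub <- revComp(sub)
      patches[i] <- toupper(sub)
    }
    s <- target[[nm]]
    for (i in rev(seq_len(nrow(p)))) {
      s <- paste0(substr(s, 1L, estart[i]), patches[i],
                  substr(s, eend[i] + 1L, nchar(s)))
    }
    out[[nm]] <- s

    # liftover segments and patch intervals in new coordinates
    offset <- 0L; prev <- 0L
    segs <- NULL
    for (i in seq_len(nrow(p))) {
      if (estart[i] > prev)
        segs <- rbind(segs, data.frame(old_start = prev, old_end = estart[i],
                                       new_start = prev + offset))
      newS <- estart[i] + offset
      newE <- newS + nchar(patches[i])
      patchIv <- rbind(patchIv, data.frame(chrom = nm, new_start = newS,
                                           new_end = newE,
                                           stringsAsFactors = FALSE))
      junc <- rbind(junc, data.frame(chrom = nm, pos = c(newS, newE),
                                     stringsAsFactors = FALSE))
      offset <- offset + nchar(patches[i]) - (eend[i] - estart[i])
      prev <- eend[i]
    }
    if (oldLen > prev)
      segs <- rbind(segs, data.frame(old_start = prev, old_end = oldLen,
                                     new_start = prev + offset))
    if (is.null(segs))
      segs <- data.frame(old_start = 0L, old_end = oldLen, new_start = 0L)
    segments[[nm]] <- segs
  }

  residual <- findGaps(out)
  residualCounts <- data.frame(
    chrom = names(out),
    n_gaps = vapply(names(out), function(nm) sum(residual$chrom == nm),
                    integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  report <- list(
    perGap = plans,
    totals = list(found = nrow(plans), filled = nrow(ap),
                  unfilled = nrow(plans) - nrow(ap)),
    residualGaps = residualCounts)
  if (is.null(patchIv))
    patchIv <- data.frame(chrom = character(0), new_start = integer(0),
                          new_end = integer(0))
  if (is.null(junc))
    junc <- data.frame(chrom = character(0), pos = integer(0))
  methods::new("GapFillResult", assembly = out,
               liftover = list(segments = segments, patches = patchIv),
               plans = plans, junctions = junc, report = report)
}

#' Lift a coordinate from the old to the patched assembly
#'
#' Positions inside removed material (the N-run or trimmed flank bases)
#' return `NA` ("deleted"); retained positions map monotonically.
#'
#' @param chrom chromosome name.
#' @param pos integer vector of 0-based positions on the old assembly.
#' @param map liftover map ([liftoverMap()] of a [GapFillResult-class]).
#' @return integer vector of new positions, `NA` where deleted.
#' @export
liftover <- function(chrom, pos, map) {
  segs <- map$segments[[chrom]]
  if (is.null(segs)) stop("unknown chromosome: ", chrom)
  idx <- findInterval(pos, segs$old_start)
  out <- rep(NA_integer_, length(pos))
  ok <- idx >= 1L & pos < segs$old_end[pmax(idx, 1L)]
  out[ok] <- pos[ok] - segs$old_start[idx[ok]] + segs$new_start[idx[ok]]
  out
}

#' One-call gap-fill pipeline
#'
#' Finds the gaps, filters the alignments, plans one patch per gap and
#' applies the plans.
#'
#' @param target,donor assemblies (named character vectors or XStringSets).
#' @param aln alignment data.frame (donor = query, target = reference).
#' @param minAlnLen,minAlnIdentity alignment filter thresholds for gap
#'   filling.
#' @param flankWindow,minAnchorLen,maxPatchLen,trimCap see [planPatch()].
#' @param minGapLen minimum N-run length treated as a gap.
#' @return a [GapFillResult-class].
#' @export
fillGaps <- function(target, donor, aln, minAlnLen = 1000L,
                     minAlnIdentity = 90, flankWindow = 5000L,
                     minAnchorLen = 1000L, maxPatchLen = 5e6,
                     trimCap = 1000L, minGapLen = 1L) {
  target <- .asSeqs(target); donor <- .asSeqs(donor)
  gaps <- findGaps(target, minGapLen = minGapLen)
  flt <- filterAlignments(aln, minLen = minAlnLen, minIdentity = minAlnIdentity)
  plans <- planPatches(gaps, flt, flankWindow = flankWindow,
                       minAnchorLen = minAnchorLen, maxPatchLen = maxPatchLen,
                       trimCap = trimCap, donorLens = nchar(donor))
  applyPatches(target, donor, plans)
}

#' Serialize a liftover map to JSON
#'
#' @param map liftover map.
#' @param path output path.
#' @return `path` invisibly.
#' @export
writeLiftoverJson <- function(map, path) {
  jsonlite::write_json(map, path, dataframe = "columns", auto_unbox = TRUE)
  invisible(path)
}

#' Write the per-gap patch report as TSV
#'
#' @param result a [GapFillResult-class].
#' @param path output path.
#' @return `path` invisibly.
#' @export
writePatchReport <- function(result, path) {
  utils::write.table(patchReport(result)$perGap, path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
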