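# Paired-BES structural-difference classification between a query genome
# and the reference, plus flux estimation and truth evaluation.

#' Classify clone placements into structural-difference candidates
#'
#' Ends on different chromosomes give a translocation candidate. For
#' same-chromosome pairs: spans above `artifactSpan` are artifacts and
#' excluded; an abnormal orientation (`same_direction` or `opposite`, the
#' discordant-pair signal at inversion breakpoints) gives an inversion
#' candidate; otherwise a span above `spanMax` is a deletion candidate of
#' estimated size `span - expectedInsert` and a span below `spanMin` an
#' insertion candidate of size `expectedInsert - span`. The size estimator
#' uses the library mean because a clone's own insert length is unknown.
#' Clones with fewer than two aligned ends are not classifiable.
#'
#' @param placements From [placeClones()].
#' @param params An [AnalysisParams()].
#' @return data.frame of calls: `clone_id`, `span_class`,
#'   `orientation_class`, `interchrom`, `candidate_type`, `size_estimate`,
#'   and the placement coordinates needed to localize each call.
#' @export
classifySV <- function(placements, params = AnalysisParams()) {
    p <- placements
    spanCls <- .spanClass(p$span_len, params)
    spanCls[p$status != "both_same_chrom"] <- "not_applicable"
    interchrom <- p$status == "both_diff_chrom"
    orientBad <- p$status == "both_same_chrom" &
        p$orientation_class %in% c("same_direction", "opposite")
    type <- rep("none", nrow(p))
    type[interchrom] <- "translocation"
    type[spanCls == "artifact"] <- "artifact"
    inv <- orientBad & spanCls != "artifact"
    type[inv] <- "inversion"
    del <- spanCls == "too_long" & !inv
    ins <- spanCls == "too_short" & !inv
    type[del] <- "deletion"
    type[ins] <- "insertion"
    size <- rep(NA_real_, nrow(p))
    size[del] <- p$span_len[del] - params@expectedInsert
    size[ins] <- params@expectedInsert - p$span_len[ins]
    data.frame(clone_id = p$clone_id, status = p$status,
               chrom = p$chrom, span_start = p$span_start,
               span_end = p$span_end, span_len = p$span_len,
               span_class = spanCls,
               orientation_class = p$orientation_class,
               interchrom = interchrom, candidate_type = type,
               size_estimate = size,
               chrom1 = p$chrom1, start1 = p$start1, end1 = p$end1,
               strand1 = p$strand1,
               chrom2 = p$chrom2, start2 = p$start2, end2 = p$end2,
               strand2 = p$strand2, stringsAsFactors = FALSE)
}

#' Summarize structural-difference calls
#'
#' Counts per span class, orientation class and candidate type, with the
#' mean span per span class. The span classes and orientation classes each
#' partition the same-chromosome clones; both partitions are asserted.
#'
#' @param calls From [classifySV()].
#' @return list of data.frames `span` (class, count, mean_span),
#'   `orientation` (class, count) and `candidates` (type, count).
#' @export
svSummary <- function(calls) {
    same <- calls[calls$status == "both_same_chrom", , drop = FALSE]
    spanLv <- c("in_range", "too_short", "too_long", "artifact")
    span <- data.frame(
        span_class = spanLv,
        count = vapply(spanLv, function(x) sum(same$span_class == x),
                       numeric(1)),
        mean_span = vapply(spanLv, function(x)
            if (any(same$span_class == x))
                mean(same$span_len[same$span_class == x]) else NA_real_,
            numeric(1)), row.names = NULL, stringsAsFactors = FALSE)
    orLv <- c("toward", "opposite", "same_direction")
    orient <- data.frame(
        orientation_class = orLv,
        count = vapply(orLv, function(x)
            sum(same$orientation_class == x), numeric(1)),
        row.names = NULL, stringsAsFactors = FALSE)
    stopifnot(sum(span$count) == nrow(same),
              sum(orient$count) == nrow(same))
    tyLv <- c("none", "insertion", "deletion", "inversion",
              "translocation", "artifact")
    cand <- data.frame(
        candidate_type = tyLv,
        count = vapply(tyLv, function(x)
            sum(calls$candidate_type == x), numeric(1)),
        row.names = NULL, stringsAsFactors = FALSE)
    list(span = span, orientation = orient, candidates = cand)
}

# Merge candidate calls of one type into loci (union of overlapping spans,
# >= 1 bp overlap); each locus carries the maximum member size estimate.
# Translocation evidence is a pair of single reads, so each read interval
# is extended by the expected insert in the read's direction: the
# breakpoint lies within an insert length of either read.
.callLoci <- function(calls, type, expectedInsert = 150000) {
    if (type == "translocation") {
        q <- calls[calls$candidate_type == "translocation", , drop = FALSE]
        if (!nrow(q)) return(NULL)
        pad <- function(chrom, start, end, strand)
            data.frame(chrom = chrom,
                       start = ifelse(strand == "+", start,
                                      pmax(end - expectedInsert, 0)),
                       end = ifelse(strand == "+", start + expectedInsert,
                                    end),
                       size_estimate = NA_real_)
        iv <- rbind(pad(q$chrom1, q$start1, q$end1, q$strand1),
                    pad(q$chrom2, q$start2, q$end2, q$strand2))
    } else {
        q <- calls[calls$candidate_type == type, , drop = FALSE]
        if (!nrow(q)) return(NULL)
        iv <- data.frame(chrom = q$chrom, start = q$span_start,
                         end = q$span_end,
                         size_estimate = q$size_estimate)
    }
    out <- list()
    for (ch in sort(unique(iv$chrom))) {
        v <- iv[iv$chrom == ch, , drop = FALSE]
        red <- IRanges::reduce(.ir0(v$start, v$end), min.gapwidth = 0L,
                               with.revmap = TRUE)
        df <- .from_ir0(red)
        sz <- vapply(S4Vectors::mcols(red)$revmap, function(i)
            suppressWarnings(max(v$size_estimate[i], na.rm = TRUE)),
            numeric(1))
        sz[!is.finite(sz)] <- NA_real_
        out[[ch]] <- data.frame(type = type, chrom = ch,
                                start = df$start, end = df$end,
                                size_estimate = sz,
                                n_clones = lengths(
                                    S4Vectors::mcols(red)$revmap),
                                stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
}

#' Estimate genomic flux from indel candidates
#'
#' Collapses clone redundancy: insertion and deletion candidates whose
#' spans overlap are merged into loci, and each locus contributes its
#' maximum size estimate once. Flux is the summed locus size over both
#' types -- a lower bound, since events smaller than the span-window
#' resolution are invisible.
#'
#' @param calls From [classifySV()].
#' @param params An [AnalysisParams()] (unused sizes are already in the
#'   calls; kept for interface symmetry).
#' @return list with `total` (bp), `by_type` (named bp totals) and `loci`
#'   (data.frame of merged loci).
#' @export
estimateFlux <- function(calls, params = AnalysisParams()) {
    loci <- rbind(.callLoci(calls, "insertion", params@expectedInsert),
                  .callLoci(calls, "deletion", params@expectedInsert))
    if (is.null(loci))
        return(list(total = 0,
                    by_type = c(insertion = 0, deletion = 0),
                    loci = data.frame()))
    byType <- vapply(c("insertion", "deletion"), function(t)
        sum(loci$size_estimate[loci$type == t], na.rm = TRUE), numeric(1))
    list(total = sum(byType), by_type = byType, loci = loci)
}

#' Evaluate calls against the planted truth
#'
#' Calls of each type are merged into loci; a locus is a true positive
#' when it overlaps a truth event interval of matching type (for
#' translocations, either swapped block). Precision is over loci, recall
#' over truth events. With neither calls nor truth for a type, both are
#' vacuously 1.
#'
#' @param calls From [classifySV()].
#' @param truth Event table from [svEvents()] (reference coordinates).
#' @param params An [AnalysisParams()] (supplies the expected insert used
#'   to extend translocation read loci to the breakpoint-uncertainty
#'   region).
#' @return list with `summary` (per-type precision/recall), `truth` (the
#'   truth table with a `recovered` flag), `loci` (call loci with a `tp`
#'   flag).
#' @export
evaluateAgainstTruth <- function(calls, truth, params = AnalysisParams()) {
    types <- c("insertion", "deletion", "inversion", "translocation")
    truthIv <- .eventFootprints(truth)
    truthIv$end <- pmax(truthIv$end, truthIv$start + 1)  # insertion loci
    truthIv$sv_type <- truth$sv_type[match(truthIv$sv_id, truth$sv_id)]
    truth$recovered <- FALSE
    lociAll <- list()
    summ <- list()
    for (t in types) {
        loci <- .callLoci(calls, t, params@expectedInsert)
        tr <- truthIv[truthIv$sv_type == t, , drop = FALSE]
        nLoci <- if (is.null(loci)) 0L else nrow(loci)
        if (nLoci == 0L && nrow(tr) == 0L) {
            message("no calls and no truth for type '", t,
                    "': precision/recall vacuously 1")
            summ[[t]] <- data.frame(sv_type = t, n_loci = 0, n_truth = 0,
                                    tp = 0, precision = 1, recall = 1)
            next
        }
        tp <- logical(nLoci)
        if (nLoci) for (i in seq_len(nLoci)) {
            tp[i] <- any(tr$chrom == loci$chrom[i] &
                         tr$start < loci$end[i] &
                         tr$end > loci$start[i])
        }
        hitEvents <- character()
        if (nrow(tr) && nLoci) for (j in seq_len(nrow(tr))) {
            hit <- any(loci$chrom == tr$chrom[j] &
                       loci$start < tr$end[j] & loci$end > tr$start[j])
            if (hit) hitEvents <- c(hitEvents, tr$sv_id[j])
        }
        truth$recovered[truth$sv_id %in% hitEvents] <- TRUE
        if (nLoci) {
            loci$tp <- tp
            lociAll[[t]] <- loci
        }
        nTruthEv <- length(unique(tr$sv_id))
        summ[[t]] <- data.frame(
            sv_type = t, n_loci = nLoci, n_truth = nTruthEv,
            tp = sum(tp),
            precision = if (nLoci) mean(tp) else 1,
            recall = if (nTruthEv) length(unique(hitEvents)) / nTruthEv
                     else 1,
            stringsAsFactors = FALSE)
    }
    list(summary = do.call(rbind, c(summ, list(make.row.names = FALSE))),
         truth = truth,
         loci = do.call(rbind, c(lociAll, list(make.row.names = FALSE))))
}
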