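# BES alignment, clone placement, contig anchoring and reference-guided
# contig merging.

#' Align BAC end sequences to a reference by exact matching
#'
#' Finds exact full-length matches of each read, and of its reverse
#' complement, against every chromosome using a preprocessed pattern
#' dictionary. Reads matching no locus or more than one distinct locus are
#' discarded (ambiguity is dropped rather than randomly placed, keeping
#' placements deterministic and conservative).
#'
#' @param bes BES table from [extractBES()] (columns `clone_id`,
#'   `end_label`, `sequence`).
#' @param genome Reference `DNAStringSet` (may contain N gaps; reads
#'   overlapping masked sequence simply fail to match).
#' @return data.frame of unique hits: `read_id`, `clone_id`, `end_label`,
#'   `chrom`, `start`, `end` (0-based half-open), `strand`.
#' @export
alignBES <- function(bes, genome) {
    .check(nrow(bes) > 0, "no reads to align")
    readId <- paste(bes$clone_id, bes$end_label, sep = ".")
    seqs <- Biostrings::DNAStringSet(bes$sequence)
    names(seqs) <- readId
    # PDict needs pure ACGT; reads with ambiguity codes cannot match exactly
    clean <- !grepl("[^ACGT]", bes$sequence)
    hits <- list()
    if (any(clean)) {
        fwd <- seqs[clean]
        pdF <- Biostrings::PDict(fwd)
        pdR <- Biostrings::PDict(Biostrings::reverseComplement(fwd))
        rid <- names(fwd)
        for (ch in names(genome)) {
            for (str in c("+", "-")) {
                pd <- if (str == "+") pdF else pdR
                mi <- Biostrings::matchPDict(pd, genome[[ch]])
                starts <- BiocGenerics::start(mi)
                nHit <- lengths(starts)
                idx <- which(nHit > 0)
                if (!length(idx)) next
                hits[[length(hits) + 1L]] <- data.frame(
                    read_id = rep(rid[idx], nHit[idx]),
                    chrom = ch,
                    start = unlist(starts[idx], use.names = FALSE) - 1L,
                    strand = str, stringsAsFactors = FALSE)
            }
        }
    }
    if (!length(hits))
        return(data.frame(read_id = character(), clone_id = character(),
                          end_label = character(), chrom = character(),
                          start = numeric(), end = numeric(),
                          strand = character()))
    h <- do.call(rbind, hits)
    nLoci <- table(h$read_id)
    h <- h[h$read_id %in% names(nLoci)[nLoci == 1L], , drop = FALSE]
    i <- match(h$read_id, readId)
    out <- data.frame(read_id = h$read_id,
                      clone_id = bes$clone_id[i],
                      end_label = bes$end_label[i],
                      chrom = h$chrom, start = h$start,
                      end = h$start + nchar(bes$sequence[i]),
                      strand = h$strand, stringsAsFactors = FALSE)
    out <- out[order(out$clone_id, out$end_label), , drop = FALSE]
    rownames(out) <- NULL
    out
}

.placementTemplate <- function(n) {
    data.frame(clone_id = character(n), n_reads = integer(n),
               n_aligned = integer(n), status = character(n),
               chrom = NA_character_, span_start = NA_real_,
               span_end = NA_real_, span_len = NA_real_,
               orientation_class = "not_applicable",
               chrom1 = NA_character_, start1 = NA_real_, end1 = NA_real_,
               strand1 = NA_character_,
               chrom2 = NA_character_, start2 = NA_real_, end2 = NA_real_,
               strand2 = NA_character_, stringsAsFactors = FALSE)
}

#' Place clones from their BES hits
#'
#' Classifies each clone by how its end reads aligned: `no_end` (nothing
#' aligned), `one_end`, `both_diff_chrom`, or `both_same_chrom`. For
#' same-chromosome pairs the span is the outermost hit coordinates and the
#' orientation class compares the strands of the left and right hit (by
#' start coordinate, regardless of F/R label): `toward` (+ then -, the
#' expected cloning-vector geometry), `same_direction`, or `opposite`.
#'
#' @param hits Hit table from [alignBES()].
#' @param bes The BES table the hits came from (supplies the number of
#'   reads emitted per clone, 1 or 2).
#' @return One row per clone with status, span, orientation and the
#'   underlying hit coordinates (`chrom1/start1/...` ordered by position).
#' @export
placeClones <- function(hits, bes) {
    cl <- sort(unique(bes$clone_id))
    nReads <- table(bes$clone_id)
    .check(all(nReads %in% 1:2), "each clone must have 1 or 2 reads")
    out <- .placementTemplate(length(cl))
    out$clone_id <- cl
    out$n_reads <- as.integer(nReads[cl])
    hs <- split(hits, hits$clone_id)
    for (i in seq_along(cl)) {
        h <- hs[[cl[i]]]
        na <- if (is.null(h)) 0L else nrow(h)
        .check(na <= 2, paste("clone", cl[i], "has more than 2 hits"))
        out$n_aligned[i] <- na
        if (na == 0L) { out$status[i] <- "no_end"; next }
        h <- h[order(h$chrom, h$start), , drop = FALSE]
        out$chrom1[i] <- h$chrom[1]; out$start1[i] <- h$start[1]
        out$end1[i] <- h$end[1]; out$strand1[i] <- h$strand[1]
        if (na == 1L) { out$status[i] <- "one_end"; next }
        out$chrom2[i] <- h$chrom[2]; out$start2[i] <- h$start[2]
        out$end2[i] <- h$end[2]; out$strand2[i] <- h$strand[2]
        if (h$chrom[1] != h$chrom[2]) {
            out$status[i] <- "both_diff_chrom"
            next
        }
        out$status[i] <- "both_same_chrom"
        out$chrom[i] <- h$chrom[1]
        out$span_start[i] <- h$start[1]
        out$span_end[i] <- h$end[2]
        out$span_len[i] <- h$end[2] - h$start[1]
        s <- h$strand
        out$orientation_class[i] <-
            if (s[1] == "+" && s[2] == "-") "toward"
            else if (s[1] == s[2]) "same_direction"
            else "opposite"
    }
    out
}

#' Summarize clone placements
#'
#' The standard placement report: clone counts by pairing, alignment
#' status, span class and orientation class, with mean spans per span
#' class. The span and orientation classes each partition the
#' same-chromosome clones; the partitions are asserted.
#'
#' @param placements From [placeClones()].
#' @param params An [AnalysisParams()] supplying the span thresholds.
#' @return data.frame with columns `label`, `count`, `mean_span`.
#' @export
summarizePlacements <- function(placements, params = AnalysisParams()) {
    p <- placements
    same <- p[p$status == "both_same_chrom", , drop = FALSE]
    spanCls <- .spanClass(same$span_len, params)
    orient <- table(factor(same$orientation_class,
                           c("toward", "opposite", "same_direction")))
    cnt <- c(
        "Total number of BES" = sum(p$n_reads),
        "Clones with unpaired BES" = sum(p$n_reads == 1),
        "Clones with paired BES" = sum(p$n_reads == 2),
        "Clones where no end aligned" = sum(p$status == "no_end"),
        "Clones where only one end aligned" =
            sum(p$status == "one_end" & p$n_reads == 2),
        "Clones where BES aligned to different chromosomes" =
            sum(p$status == "both_diff_chrom"),
        "Clones where BES aligned to same chromosome" = nrow(same),
        "75 kbp < clones < 225 kbp" = sum(spanCls == "in_range"),
        "Clones < 75 kbp" = sum(spanCls == "too_short"),
        "Clones > 225 kbp" = sum(spanCls == "too_long"),
        "Clones excluded as artifacts (> 1.5 Mbp)" =
            sum(spanCls == "artifact"),
        "Clones with BES with expected orientation" = orient[["toward"]],
        "Clones with BES in opposite direction" = orient[["opposite"]],
        "Clones with BES same direction" = orient[["same_direction"]])
    stopifnot(sum(cnt[8:11]) == nrow(same), sum(orient) == nrow(same))
    meanSpan <- rep(NA_real_, length(cnt))
    names(meanSpan) <- names(cnt)
    for (cls in c("in_range", "too_short", "too_long")) {
        lab <- switch(cls, in_range = "75 kbp < clones < 225 kbp",
                      too_short = "Clones < 75 kbp",
                      too_long = "Clones > 225 kbp")
        if (any(spanCls == cls))
            meanSpan[lab] <- mean(same$span_len[spanCls == cls])
    }
    data.frame(label = names(cnt), count = as.numeric(cnt),
               mean_span = meanSpan, row.names = NULL,
               stringsAsFactors = FALSE)
}

.spanClass <- function(spanLen, params) {
    ifelse(is.na(spanLen), "not_applicable",
    ifelse(spanLen > params@artifactSpan, "artifact",
    ifelse(spanLen > params@spanMax, "too_long",
    ifelse(spanLen < params@spanMin, "too_short", "in_range"))))
}

#' Anchor FPC contigs to reference chromosomes
#'
#' A contig is anchored when at least `minPlaced` member clones have
#' same-chromosome placements and at least `agreeFrac` of the placed
#' members agree on one chromosome. Its position is the median of the
#' member span midpoints and its orientation the sign of the rank
#' correlation between contig order index and reference midpoint (ties
#' anchor as `+`).
#'
#' @param map An [FPCMap()].
#' @param placements From [placeClones()].
#' @param minPlaced,agreeFrac Anchoring thresholds (defaults 2 and 0.8).
#' @return data.frame `contig_id`, `chrom`, `position`, `orientation`,
#'   `anchored`, `n_placed`.
#' @export
anchorContigs <- function(map, placements, minPlaced = 2L,
                          agreeFrac = 0.8) {
    ctg <- contigs(map)
    ids <- unique(ctg$contig_id)
    if (!length(ids))
        return(data.frame(contig_id = character(), chrom = character(),
                          position = numeric(), orientation = character(),
                          anchored = logical(), n_placed = integer()))
    same <- placements[placements$status == "both_same_chrom", ,
                       drop = FALSE]
    out <- data.frame(contig_id = ids, chrom = NA_character_,
                      position = NA_real_, orientation = NA_character_,
                      anchored = FALSE, n_placed = 0L,
                      stringsAsFactors = FALSE)
    for (k in seq_along(ids)) {
        mem <- ctg[ctg$contig_id == ids[k], , drop = FALSE]
        pl <- same[same$clone_id %in% mem$clone_id, , drop = FALSE]
        out$n_placed[k] <- nrow(pl)
        if (nrow(pl) < minPlaced) next
        tab <- sort(table(pl$chrom), decreasing = TRUE)
        if (tab[1] / nrow(pl) < agreeFrac) next
        ch <- sort(names(tab)[tab == tab[1]])[1]
        pl <- pl[pl$chrom == ch, , drop = FALSE]
        mids <- (pl$span_start + pl$span_end) / 2
        ords <- mem$ord[match(pl$clone_id, mem$clone_id)]
        rho <- suppressWarnings(cor(ords, mids, method = "spearman"))
        out$chrom[k] <- ch
        out$position[k] <- median(mids)
        out$orientation[k] <- if (!is.na(rho) && rho < 0) "-" else "+"
        out$anchored[k] <- TRUE
    }
    out
}

# Reference extent [min span start, max span end] of each anchored contig
# on its anchor chromosome.
.contigExtents <- function(anchors, map, placements) {
    ctg <- contigs(map)
    same <- placements[placements$status == "both_same_chrom", ,
                       drop = FALSE]
    anc <- anchors[anchors$anchored, , drop = FALSE]
    ext <- lapply(seq_len(nrow(anc)), function(k) {
        mem <- ctg$clone_id[ctg$contig_id == anc$contig_id[k]]
        pl <- same[same$clone_id %in% mem &
                       same$chrom == anc$chrom[k], , drop = FALSE]
        data.frame(contig_id = anc$contig_id[k], chrom = anc$chrom[k],
                   ext_start = min(pl$span_start),
                   ext_end = max(pl$span_end),
                   orientation = anc$orientation[k],
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, c(ext, list(make.row.names = FALSE)))
}

#' Merge contigs joined by the reference
#'
#' Two anchored contigs merge when they are adjacent on the same chromosome
#' (no third anchored contig between them) and the distance between their
#' nearest member-clone span ends is at most `maxJoinGap` bp. Merging
#' concatenates the clone orders respecting orientation. Merges chain
#' transitively.
#'
#' @param anchors From [anchorContigs()].
#' @param map The [FPCMap()] the anchors refer to.
#' @param placements From [placeClones()] (supplies member span extents).
#' @param maxJoinGap Maximum joinable distance, bp (default 150 kb).
#' @return list with `map` (the merged [FPCMap()]) and `merges` (count).
#' @export
mergeContigsByReference <- function(anchors, map, placements,
                                    maxJoinGap = 150000) {
    anc <- anchors[anchors$anchored, , drop = FALSE]
    if (nrow(anc) < 2L) return(list(map = map, merges = 0L))
    ext <- .contigExtents(anchors, map, placements)
    merges <- 0L
    chains <- list()
    for (ch in sort(unique(ext$chrom))) {
        e <- ext[ext$chrom == ch, , drop = FALSE]
        e <- e[order(e$ext_start, e$ext_end, e$contig_id), , drop = FALSE]
        cur <- list(e[1, , drop = FALSE])
        if (nrow(e) >= 2L) for (i in 2:nrow(e)) {
            prev <- cur[[length(cur)]]
            gap <- e$ext_start[i] - max(prev$ext_end)
            if (gap <= maxJoinGap) {
                cur[[length(cur) + 1L]] <- e[i, , drop = FALSE]
                merges <- merges + 1L
            } else {
                chains[[length(chains) + 1L]] <- do.call(rbind, cur)
                cur <- list(e[i, , drop = FALSE])
            }
        }
        chains[[length(chains) + 1L]] <- do.call(rbind, cur)
    }
    # rebuild the clone table: merged chains become one contig each
    cl <- map@clones
    newRows <- list()
    cbLength <- numeric()
    mergedIds <- character()
    for (chain in chains) {
        if (nrow(chain) == 1L) next   # untouched contig
        ids <- chain$contig_id
        mergedIds <- c(mergedIds, ids)
        newId <- paste0("m_", sort(ids)[1])
        offShift <- 0
        parts <- list()
        for (k in seq_along(ids)) {
            mem <- cl[!is.na(cl$contig_id) & cl$contig_id == ids[k], ,
                      drop = FALSE]
            mem <- mem[order(mem$ord), , drop = FALSE]
            cbl <- map@cbLength[[ids[k]]]
            if (chain$orientation[k] == "-") {
                mem <- mem[rev(seq_len(nrow(mem))), , drop = FALSE]
                mem$cb_offset <- cbl - (mem$cb_offset + mem$nbands)
                mem$cb_offset <- cummax(pmax(mem$cb_offset, 0))
            }
            mem$cb_offset <- mem$cb_offset + offShift
            offShift <- offShift + cbl
            parts[[k]] <- mem
        }
        mrg <- do.call(rbind, parts)
        mrg$contig_id <- newId
        mrg$ord <- seq_len(nrow(mrg))
        newRows[[length(newRows) + 1L]] <- mrg
        cbLength[[newId]] <- offShift
    }
    untouched <- cl[is.na(cl$contig_id) | !(cl$contig_id %in% mergedIds), ,
                    drop = FALSE]
    keepCb <- map@cbLength[setdiff(names(map@cbLength), mergedIds)]
    newClones <- rbind(untouched, do.call(rbind, newRows))
    rownames(newClones) <- NULL
    list(map = FPCMap(newClones, c(keepCb, cbLength)), merges = merges)
}
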