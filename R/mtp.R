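# Minimum tiling path selection, unpaired-BES gap extension, and coverage
# statistics.

#' Select an eligible clone pool for tiling-path construction
#'
#' Pool A keeps only clones present in the fingerprint map (contig members
#' or singletons); pool B keeps all clones with BES placements. Clones with
#' a same-chromosome span outside `[insertMin, insertMax]` are excluded
#' (unusually short or long apparent inserts are unreliable). With
#' `pairedOnly = TRUE` only same-chromosome paired placements are kept;
#' otherwise one-end clones remain available for gap extension.
#'
#' @param placements From [placeClones()].
#' @param map An [FPCMap()] (defines pool A membership).
#' @param pool `"A"` or `"B"`.
#' @param pairedOnly Keep only clones with both ends on one chromosome.
#' @param params An [MTPParams()].
#' @return The eligible subset of `placements`.
#' @export
selectPool <- function(placements, map, pool = c("A", "B"),
                       pairedOnly = TRUE, params = MTPParams()) {
    pool <- match.arg(pool)
    p <- placements
    if (pool == "A") p <- p[p$clone_id %in% cloneIds(map), , drop = FALSE]
    same <- p$status == "both_same_chrom"
    spanOk <- !same | (p$span_len >= params@insertMin &
                       p$span_len <= params@insertMax)
    p <- p[spanOk, , drop = FALSE]
    if (pairedOnly) p <- p[p$status == "both_same_chrom", , drop = FALSE]
    else p <- p[p$status %in% c("both_same_chrom", "one_end"), ,
                drop = FALSE]
    rownames(p) <- NULL
    p
}

#' Build coverage islands from placed clones
#'
#' A coverage island is a maximal union of overlapping clone spans
#' (overlap of at least 1 bp; abutting spans do not merge). Breaks between
#' islands on a chromosome are the tiling-path gaps.
#'
#' @param placements Eligible placements (same-chromosome rows are used).
#' @param chrom Optional chromosome filter.
#' @return data.frame `island_id`, `chrom`, `start`, `end` (0-based
#'   half-open), sorted; plus a `member` list-column of clone ids.
#' @export
buildIslands <- function(placements, chrom = NULL) {
    p <- placements[placements$status == "both_same_chrom", , drop = FALSE]
    if (!is.null(chrom)) p <- p[p$chrom %in% chrom, , drop = FALSE]
    out <- list()
    for (ch in sort(unique(p$chrom))) {
        q <- p[p$chrom == ch, , drop = FALSE]
        ir <- .ir0(q$span_start, q$span_end)
        red <- IRanges::reduce(ir, min.gapwidth = 0L,
                               with.revmap = TRUE)
        df <- .from_ir0(red)
        members <- lapply(S4Vectors::mcols(red)$revmap,
                          function(i) sort(q$clone_id[i]))
        out[[ch]] <- data.frame(
            island_id = sprintf("%s_island%03d", ch,
                                seq_len(length(red))),
            chrom = ch, start = df$start, end = df$end,
            stringsAsFactors = FALSE)
        out[[ch]]$members <- members
    }
    res <- do.call(rbind, out)
    if (is.null(res))
        res <- data.frame(island_id = character(), chrom = character(),
                          start = numeric(), end = numeric())
    rownames(res) <- NULL
    res
}

#' Pick the tiling path across one coverage island
#'
#' Shortest-path clone selection: one node per clone (identical spans
#' deduplicated to the lexicographically smallest id), a directed edge
#' u -> v whenever v starts strictly inside u and extends past it, with
#' weight `cloneCountWeight + overlap(u, v)`. Because the weight constant
#' exceeds any possible overlap, the minimum-weight path from a clone
#' containing the island start to a clone containing its last base
#' minimizes clone count first and total overlap second. The graph is a
#' DAG (edges increase both start and end), so the optimum is found by
#' dynamic programming in start order; ties break on the lexicographic
#' clone-id sequence of the path.
#'
#' @param island One row of [buildIslands()] output.
#' @param placements The eligible placements (members are looked up by
#'   clone id).
#' @param params An [MTPParams()].
#' @return data.frame of the ordered path: `clone_id`, `span_start`,
#'   `span_end`, and `overlap` with the previous clone (NA for the first).
#' @export
pickMTP <- function(island, placements, params = MTPParams()) {
    mem <- placements[placements$clone_id %in% island$members[[1]], ,
                      drop = FALSE]
    .check(nrow(mem) > 0, "island has no member clones")
    mem <- mem[order(mem$span_start, mem$span_end, mem$clone_id), ,
               drop = FALSE]
    dup <- duplicated(mem[, c("span_start", "span_end")])
    mem <- mem[!dup, , drop = FALSE]   # keep lexicographically smallest id
    n <- nrow(mem)
    s <- mem$span_start; e <- mem$span_end; id <- mem$clone_id
    W <- params@cloneCountWeight
    dist <- rep(Inf, n)
    paths <- vector("list", n)
    isSource <- s == island$start
    dist[isSource] <- W
    for (v in which(isSource)) paths[[v]] <- v
    for (v in seq_len(n)) {
        if (isSource[v]) next
        for (u in seq_len(v - 1L)) {   # sorted by start: edges come from u < v
            if (!(s[v] > s[u] && s[v] < e[u] && e[v] > e[u])) next
            if (!is.finite(dist[u])) next
            cand <- dist[u] + W + (e[u] - s[v])
            if (cand < dist[v] ||
                (cand == dist[v] &&
                 .lexLess(id[c(paths[[u]], v)], id[paths[[v]]]))) {
                dist[v] <- cand
                paths[[v]] <- c(paths[[u]], v)
            }
        }
    }
    sinks <- which(e == island$end & is.finite(dist))
    .check(length(sinks) > 0, "island not coverable by its own members")
    best <- sinks[1]
    for (v in sinks[-1]) {
        if (dist[v] < dist[best] ||
            (dist[v] == dist[best] &&
             .lexLess(id[paths[[v]]], id[paths[[best]]])))
            best <- v
    }
    path <- paths[[best]]
    ov <- c(NA_real_, e[head(path, -1)] - s[path[-1]])
    data.frame(clone_id = id[path], span_start = s[path],
               span_end = e[path], overlap = ov,
               stringsAsFactors = FALSE)
}

#' Build the complete tiling path for all chromosomes
#'
#' Runs [buildIslands()] and [pickMTP()] over every coverage island and
#' assembles an [MTPResult()] with adjacent-clone overlaps and the
#' inter-island gaps per chromosome.
#'
#' @param placements Eligible placements from [selectPool()].
#' @param clones Clone table (supplies the `library` column).
#' @param params An [MTPParams()].
#' @return An [MTPResult()].
#' @export
buildMTP <- function(placements, clones, params = MTPParams()) {
    isl <- buildIslands(placements)
    pathRows <- list(); ovRows <- list(); gapRows <- list()
    for (i in seq_len(nrow(isl))) {
        p <- pickMTP(isl[i, , drop = FALSE], placements, params)
        pathRows[[i]] <- data.frame(
            chrom = isl$chrom[i], island = isl$island_id[i],
            ord = seq_len(nrow(p)), clone_id = p$clone_id,
            span_start = p$span_start, span_end = p$span_end,
            library = clones$library[match(p$clone_id, clones$clone_id)],
            augmented = FALSE, credited_start = NA_real_,
            credited_end = NA_real_, stringsAsFactors = FALSE)
        if (nrow(p) > 1L)
            ovRows[[i]] <- data.frame(
                chrom = isl$chrom[i], island = isl$island_id[i],
                left_id = head(p$clone_id, -1),
                right_id = p$clone_id[-1],
                overlap = p$overlap[-1], stringsAsFactors = FALSE)
    }
    for (ch in unique(isl$chrom)) {
        e <- isl[isl$chrom == ch, , drop = FALSE]
        if (nrow(e) > 1L)
            gapRows[[ch]] <- data.frame(
                chrom = ch, gap_start = head(e$end, -1),
                gap_end = e$start[-1], entered = FALSE,
                stringsAsFactors = FALSE)
    }
    empty <- function(cols) do.call(data.frame,
        c(stats::setNames(rep(list(character(0)), length(cols)), cols),
          list(stringsAsFactors = FALSE)))
    path <- if (length(pathRows)) do.call(rbind, pathRows) else
        data.frame(chrom = character(), island = character(),
                   ord = integer(), clone_id = character(),
                   span_start = numeric(), span_end = numeric(),
                   library = character(), augmented = logical(),
                   credited_start = numeric(), credited_end = numeric())
    ov <- if (length(ovRows)) do.call(rbind, ovRows) else
        data.frame(chrom = character(), island = character(),
                   left_id = character(), right_id = character(),
                   overlap = numeric())
    gaps <- if (length(gapRows)) do.call(rbind, gapRows) else
        data.frame(chrom = character(), gap_start = numeric(),
                   gap_end = numeric(), entered = logical())
    rownames(path) <- rownames(ov) <- rownames(gaps) <- NULL
    new("MTPResult", path = path, overlaps = ov, gaps = gaps,
        meta = list(params = params))
}

#' Extend a tiling path into gaps with unpaired-BES clones
#'
#' A clone whose single aligned end lies within `edgeWindow` of a gap edge,
#' on the covered side, with its read pointing into the gap (plus strand
#' toward a gap beginning to its right, minus strand toward a gap ending to
#' its left) is credited with an extension of `assumedInsert` bp from the
#' hit's inner edge into the gap, truncated at the gap's far side. Per gap,
#' only the clone with the longest credited extension is kept, so the path
#' stays minimal.
#'
#' @param mtp An [MTPResult()] from [buildMTP()].
#' @param placements Placements containing `one_end` rows (e.g. from
#'   [selectPool()] with `pairedOnly = FALSE`).
#' @param gaps data.frame of gaps to consider: columns `chrom`, `start`,
#'   `end`. Typically reference N-gaps, the tiling path's own inter-island
#'   gaps, or their union.
#' @param clones Clone table (for the `library` column).
#' @param params An [MTPParams()].
#' @return The augmented [MTPResult()]; `x@meta$augmentation` records the
#'   number of gaps receiving a clone and the added coverage in bp.
#' @export
augmentWithUnpaired <- function(mtp, placements, gaps, clones,
                                params = MTPParams()) {
    one <- placements[placements$status == "one_end", , drop = FALSE]
    added <- list()
    gapsTouched <- 0L
    addedBp <- 0
    if (nrow(gaps)) for (g in seq_len(nrow(gaps))) {
        ch <- gaps$chrom[g]; gs <- gaps$start[g]; ge <- gaps$end[g]
        cand <- one[!is.na(one$chrom1) & one$chrom1 == ch, , drop = FALSE]
        if (!nrow(cand)) next
        right <- cand$strand1 == "+" & cand$end1 <= gs &
            gs - cand$start1 <= params@edgeWindow &
            cand$start1 + params@assumedInsert > gs
        left <- cand$strand1 == "-" & cand$start1 >= ge &
            cand$end1 - ge <= params@edgeWindow &
            cand$end1 - params@assumedInsert < ge
        cand <- cand[right | left, , drop = FALSE]
        if (!nrow(cand)) next
        isRight <- cand$strand1 == "+"
        extStart <- ifelse(isRight, cand$start1,
                           pmax(cand$end1 - params@assumedInsert, gs))
        extEnd <- ifelse(isRight,
                         pmin(cand$start1 + params@assumedInsert, ge),
                         cand$end1)
        intoGap <- ifelse(isRight, extEnd - gs, ge - extStart)
        o <- order(-intoGap, cand$clone_id)
        pick <- o[1]
        gapsTouched <- gapsTouched + 1L
        addedBp <- addedBp + intoGap[pick]
        added[[length(added) + 1L]] <- data.frame(
            chrom = ch, island = NA_character_, ord = NA_integer_,
            clone_id = cand$clone_id[pick],
            span_start = extStart[pick], span_end = extEnd[pick],
            library = clones$library[match(cand$clone_id[pick],
                                           clones$clone_id)],
            augmented = TRUE, credited_start = extStart[pick],
            credited_end = extEnd[pick], stringsAsFactors = FALSE)
    }
    path <- rbind(mtp@path, do.call(rbind, added))
    rownames(path) <- NULL
    gapsOut <- mtp@gaps
    if (nrow(gapsOut) && length(added)) {
        ext <- do.call(rbind, added)
        for (g in seq_len(nrow(gapsOut))) {
            hit <- ext$chrom == gapsOut$chrom[g] &
                ext$credited_end > gapsOut$gap_start[g] &
                ext$credited_start < gapsOut$gap_end[g]
            if (any(hit)) gapsOut$entered[g] <- TRUE
        }
    }
    new("MTPResult", path = path, overlaps = mtp@overlaps, gaps = gapsOut,
        meta = c(mtp@meta,
                 list(augmentation = list(gaps_touched = gapsTouched,
                                          added_bp = addedBp))))
}

#' Tiling-path summary statistics
#'
#' Clone counts per library (gap-extending clones included), the number of
#' internal gaps remaining (inter-island breaks not entered by any credited
#' extension), and the mean overlap between adjacent clones, counting the
#' overlap of each credited extension with the covered region it extends.
#'
#' @param mtp An [MTPResult()].
#' @param libraries Optional library names fixing the row order.
#' @return list with `per_library` (data.frame), `total_clones`, `gaps`,
#'   `mean_overlap`.
#' @export
mtpStats <- function(mtp, libraries = NULL) {
    p <- mtp@path
    if (is.null(libraries)) libraries <- sort(unique(p$library))
    perLib <- data.frame(
        library = libraries,
        n_clones = vapply(libraries, function(l)
            sum(p$library == l, na.rm = TRUE), numeric(1)),
        stringsAsFactors = FALSE)
    ovs <- mtp@overlaps$overlap
    # overlap credited to augmented clones: the covered part of their span
    aug <- p[p$augmented, , drop = FALSE]
    if (nrow(aug)) {
        core <- p[!p$augmented, , drop = FALSE]
        for (i in seq_len(nrow(aug))) {
            cv <- core[core$chrom == aug$chrom[i], , drop = FALSE]
            if (!nrow(cv)) next
            ov <- pmin(cv$span_end, aug$span_end[i]) -
                pmax(cv$span_start, aug$span_start[i])
            if (any(ov > 0)) ovs <- c(ovs, max(ov))
        }
    }
    list(per_library = perLib,
         total_clones = nrow(p),
         gaps = sum(!mtp@gaps$entered),
         mean_overlap = if (length(ovs)) mean(ovs) else NA_real_)
}

#' Per-chromosome coverage of a tiling path
#'
#' Covered length is the union of clone spans and credited extensions
#' (nothing is double-counted).
#'
#' @param mtp An [MTPResult()].
#' @param genome The reference `DNAStringSet` (chromosome lengths).
#' @return data.frame `chrom`, `length`, `covered`, `pct`, with a final
#'   `Total` row.
#' @export
coverageTable <- function(mtp, genome) {
    p <- mtp@path
    out <- data.frame(chrom = names(genome),
                      length = as.numeric(BiocGenerics::width(genome)),
                      covered = 0, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(out))) {
        q <- p[p$chrom == out$chrom[i], , drop = FALSE]
        if (!nrow(q)) next
        ir <- .ir0(q$span_start, q$span_end)
        out$covered[i] <- sum(BiocGenerics::width(IRanges::reduce(ir)))
    }
    tot <- data.frame(chrom = "Total", length = sum(out$length),
                      covered = sum(out$covered))
    out <- rbind(out, tot)
    out$pct <- percentOf(out$covered, out$length, 1L)
    out
}

#' Count reference sequence gaps spanned by clones
#'
#' A gap is spanned when some clone span (or credited extension) strictly
#' contains both gap edges, and partially filled when an interval enters
#' the gap without containing it.
#'
#' @param x An [MTPResult()], a placements data.frame (same-chromosome
#'   spans are used), or a data.frame with `chrom`, `start`, `end`.
#' @param gaps Gap track data.frame from [gapTrack()].
#' @param gapClass Which gap classes to assess (default scaffold joins).
#' @return list `spanned`, `partially_filled`, `n_gaps`, and a per-gap
#'   data.frame `detail`.
#' @export
countSpannedSequenceGaps <- function(x, gaps,
                                     gapClass = "scaffold_join") {
    iv <- .asIntervals(x)
    g <- gaps[gaps$gap_class %in% gapClass, , drop = FALSE]
    spanned <- logical(nrow(g)); entered <- logical(nrow(g))
    for (i in seq_len(nrow(g))) {
        q <- iv[iv$chrom == g$chrom[i], , drop = FALSE]
        if (!nrow(q)) next
        spanned[i] <- any(q$start < g$start[i] & q$end > g$end[i])
        overlaps <- q$end > g$start[i] & q$start < g$end[i]
        entered[i] <- !spanned[i] && any(overlaps)
    }
    detail <- cbind(g, spanned = spanned, partially_filled = entered)
    rownames(detail) <- NULL
    list(spanned = sum(spanned), partially_filled = sum(entered),
         n_gaps = nrow(g), detail = detail)
}

# Normalize the interval sources countSpannedSequenceGaps accepts.
.asIntervals <- function(x) {
    if (is(x, "MTPResult"))
        return(data.frame(chrom = x@path$chrom, start = x@path$span_start,
                          end = x@path$span_end))
    if (all(c("status", "span_start") %in% names(x))) {
        q <- x[x$status == "both_same_chrom", , drop = FALSE]
        return(data.frame(chrom = q$chrom, start = q$span_start,
                          end = q$span_end))
    }
    .check(all(c("chrom", "start", "end") %in% names(x)),
           "cannot interpret interval input")
    x[, c("chrom", "start", "end")]
}
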