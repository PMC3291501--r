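# Fingerprint contig assembly: Sulston coincidence score, single-linkage
# clustering, greedy consensus-band seriation.

#' Count matching bands between two fingerprints
#'
#' Greedy one-to-one matching on the sorted band lists: two bands match when
#' their sizes differ by at most `tolerance` bp. The count is symmetric and
#' never exceeds the smaller band count.
#'
#' @param a,b Numeric band-size vectors (non-empty).
#' @param tolerance Match window in bp.
#' @return Integer matched-pair count.
#' @examples
#' matchBands(c(1000, 2000), c(1004, 5000), tolerance = 5)  # 1
#' @export
matchBands <- function(a, b, tolerance) {
    .check(length(a) > 0 && length(b) > 0, "fingerprints must be non-empty")
    a <- sort(a); b <- sort(b)
    i <- 1L; j <- 1L; m <- 0L
    na <- length(a); nb <- length(b)
    while (i <= na && j <= nb) {
        d <- a[i] - b[j]
        if (abs(d) <= tolerance) {
            m <- m + 1L; i <- i + 1L; j <- j + 1L
        } else if (d < 0) i <- i + 1L else j <- j + 1L
    }
    m
}

#' Sulston probability-of-coincidence score
#'
#' Probability that two unrelated fingerprints share at least the observed
#' number of matching bands by chance, under the classical binomial
#' approximation: with `nL`/`nH` the smaller/larger band count, each of the
#' `nL` bands independently finds a chance partner with probability
#' `q = 1 - (1 - 2 * tolerance / gelSpace)^nH`, and the score is the upper
#' binomial tail `P(X >= m)` at the observed match count `m`. Low scores
#' indicate genuine clone overlap.
#'
#' @param a,b Numeric band-size vectors.
#' @param params An [AssemblyParams()].
#' @return A probability in \[0, 1\]; symmetric in its arguments and
#'   non-increasing in the match count.
#' @examples
#' p <- AssemblyParams()
#' sulstonScore(c(1000, 2000, 3000), c(5000, 6000, 7000), p)  # ~1
#' @export
sulstonScore <- function(a, b, params = AssemblyParams()) {
    m <- matchBands(a, b, params@tolerance)
    .sulstonTail(m, length(a), length(b), params)
}

# Tail probability for a given match count and band counts.
.sulstonTail <- function(m, na, nb, params) {
    nL <- min(na, nb); nH <- max(na, nb)
    q <- 1 - (1 - 2 * params@tolerance / params@gelSpace)^nH
    pbinom(m - 1, nL, q, lower.tail = FALSE)
}

# Candidate clone pairs sharing >= minShared tolerance-width band buckets.
# A pair of bands within `tolerance` always shares a bucket when each band
# contributes floor(size/tol) and floor(size/tol)+1, so pairs with >=
# minShared matches are never missed. Pairs below the default join cutoff
# need ~20+ matches, so minShared = 3 leaves a wide safety margin.
.candidatePairs <- function(fps, tolerance, minShared = 3L) {
    ids <- names(fps)
    buckets <- lapply(fps, function(b)
        unique(c(floor(b / tolerance), floor(b / tolerance) + 1)))
    long <- data.frame(
        id = rep.int(seq_along(ids), lengths(buckets)),
        bucket = unlist(buckets, use.names = FALSE))
    byBucket <- split(long$id, long$bucket)
    byBucket <- byBucket[lengths(byBucket) >= 2L]
    if (!length(byBucket))
        return(matrix(integer(), ncol = 2))
    pairs <- do.call(cbind, lapply(byBucket, function(v) {
        v <- sort(unique(v))
        if (length(v) < 2L) return(matrix(integer(), nrow = 2))
        combn(v, 2L)
    }))
    if (!length(pairs)) return(matrix(integer(), ncol = 2))
    key <- paste(pairs[1, ], pairs[2, ])
    tab <- table(key)
    keep <- names(tab)[tab >= minShared]
    if (!length(keep)) return(matrix(integer(), ncol = 2))
    parts <- strsplit(keep, " ", fixed = TRUE)
    out <- matrix(as.integer(unlist(parts)), ncol = 2, byrow = TRUE)
    out[order(out[, 1], out[, 2]), , drop = FALSE]
}

#' Cluster fingerprints into contigs
#'
#' Builds the graph with an edge between every clone pair whose coincidence
#' score is at or below `params@cutoff` and takes its connected components
#' (single-linkage joining). Components of one clone become singletons;
#' larger components are ordered by greedy seriation (see Details) to give
#' each clone a consensus-band (CB) offset.
#'
#' Seriation seeds the contig with the pair sharing the most bands, then
#' repeatedly appends the unplaced clone with the largest match count to
#' either end; a clone's CB offset is its best neighbor's offset plus the
#' neighbor's unshared band count. Ties break on lexicographic clone id, so
#' the result is invariant to input order (up to mirror image).
#'
#' @param fps Named list of fingerprint band vectors (from
#'   [fingerprintClones()]).
#' @param params An [AssemblyParams()].
#' @param allPairs Score every pair exactly instead of using the shared-
#'   band-bucket prefilter (slower; used for verification).
#' @return An [FPCMap()].
#' @export
clusterContigs <- function(fps, params = AssemblyParams(),
                           allPairs = FALSE) {
    .check(length(fps) >= 1L, "need at least one fingerprint")
    .check(!is.null(names(fps)) && !anyDuplicated(names(fps)),
           "fingerprints must be uniquely named by clone id")
    ids <- names(fps)
    n <- length(fps)
    if (allPairs) {
        if (n >= 2L) {
            cp <- t(combn(seq_len(n), 2L))
        } else cp <- matrix(integer(), ncol = 2)
    } else {
        cp <- .candidatePairs(fps, params@tolerance)
    }
    edges <- matrix(integer(), ncol = 2)
    mEdge <- integer()
    if (nrow(cp)) {
        m <- vapply(seq_len(nrow(cp)), function(k)
            matchBands(fps[[cp[k, 1]]], fps[[cp[k, 2]]],
                       params@tolerance), integer(1))
        sc <- vapply(seq_len(nrow(cp)), function(k)
            .sulstonTail(m[k], length(fps[[cp[k, 1]]]),
                         length(fps[[cp[k, 2]]]), params), numeric(1))
        keep <- sc <= params@cutoff
        edges <- cp[keep, , drop = FALSE]
        mEdge <- m[keep]
    }
    g <- igraph::make_empty_graph(n = n, directed = FALSE)
    if (nrow(edges))
        g <- igraph::add_edges(g, t(edges))
    comp <- igraph::components(g)$membership
    members <- split(seq_len(n), comp)
    members <- members[order(vapply(members, function(v) min(ids[v]),
                                    character(1)))]
    cloneRows <- list()
    cbLength <- numeric()
    ctgNo <- 0L
    for (v in members) {
        if (length(v) == 1L) {
            cloneRows[[length(cloneRows) + 1L]] <- data.frame(
                clone_id = ids[v], contig_id = NA_character_,
                ord = NA_integer_, cb_offset = NA_real_,
                nbands = length(fps[[v]]), stringsAsFactors = FALSE)
            next
        }
        ctgNo <- ctgNo + 1L
        ctg <- sprintf("ctg%04d", ctgNo)
        sub <- fps[v]
        mm <- .pairwiseMatches(sub, params@tolerance)
        ordered <- orderContig(names(sub), mm,
                               lengths(sub))
        cloneRows[[length(cloneRows) + 1L]] <- data.frame(
            clone_id = ordered$clone_id, contig_id = ctg,
            ord = ordered$ord, cb_offset = ordered$cb_offset,
            nbands = lengths(sub)[ordered$clone_id],
            stringsAsFactors = FALSE)
        cbLength[[ctg]] <- max(ordered$cb_offset +
                                   lengths(sub)[ordered$clone_id])
    }
    clones <- do.call(rbind, cloneRows)
    rownames(clones) <- NULL
    FPCMap(clones, cbLength)
}

# Symmetric matrix of pairwise matched-band counts.
.pairwiseMatches <- function(fps, tolerance) {
    n <- length(fps)
    mm <- matrix(0L, n, n, dimnames = list(names(fps), names(fps)))
    if (n >= 2L) for (i in 1:(n - 1)) for (j in (i + 1):n) {
        mm[i, j] <- mm[j, i] <- matchBands(fps[[i]], fps[[j]], tolerance)
    }
    mm
}

#' Order the clones of one contig by greedy seriation
#'
#' @param cloneIds Clone ids in the contig (>= 2).
#' @param mMat Symmetric matrix of pairwise matched-band counts, dimnames =
#'   clone ids.
#' @param nbands Named vector of band counts per clone.
#' @return data.frame `clone_id`, `ord`, `cb_offset` (offsets shifted to
#'   start at 0).
#' @export
orderContig <- function(cloneIds, mMat, nbands) {
    .check(length(cloneIds) >= 2L, "a contig needs at least 2 clones")
    cloneIds <- sort(cloneIds)
    mMat <- mMat[cloneIds, cloneIds, drop = FALSE]
    n <- length(cloneIds)
    # seed: the pair with the largest m; ties -> lexicographically smallest
    best <- c(NA, NA); bestM <- -1L
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
        if (mMat[i, j] > bestM) { bestM <- mMat[i, j]; best <- c(i, j) }
    }
    orderIds <- cloneIds[best]
    off <- c(0, nbands[[orderIds[1]]] - mMat[best[1], best[2]])
    names(off) <- orderIds
    unplaced <- setdiff(cloneIds, orderIds)
    while (length(unplaced)) {
        first <- orderIds[1]; last <- orderIds[length(orderIds)]
        mL <- mMat[unplaced, first]; names(mL) <- unplaced
        mR <- mMat[unplaced, last]; names(mR) <- unplaced
        bestVal <- max(mL, mR)
        # smallest id among clones achieving the best match count; on a
        # left/right tie for that clone, prefer the right end
        u <- min(unplaced[pmax(mL, mR) == bestVal])
        side <- if (mR[[u]] == bestVal) "R" else "L"
        if (side == "R") {
            off[u] <- off[[last]] + nbands[[last]] - mMat[u, last]
            orderIds <- c(orderIds, u)
        } else {
            off[u] <- off[[first]] - (nbands[[u]] - mMat[u, first])
            orderIds <- c(u, orderIds)
        }
        unplaced <- setdiff(unplaced, u)
    }
    off <- off[orderIds] - min(off)
    # enforce non-decreasing offsets along the final order (left appends
    # with weak evidence can otherwise cross their neighbor)
    off <- cummax(off)
    data.frame(clone_id = orderIds, ord = seq_along(orderIds),
               cb_offset = as.numeric(off), stringsAsFactors = FALSE)
}

#' Contig size histogram
#'
#' Counts contigs per clone-count bin (the conventional physical-map report
#' bins) plus the singleton count.
#'
#' @param map An [FPCMap()].
#' @return data.frame with columns `bin` and `count`; the contig bins sum to
#'   the contig count, and the final `singletons` row counts unassembled
#'   clones.
#' @export
contigHistogram <- function(map) {
    sizes <- table(contigs(map)$contig_id)
    breaks <- c(">1000" = 1000, "800-999" = 800, "600-799" = 600,
                "400-599" = 400, "200-399" = 200, "100-199" = 100,
                "50-99" = 50, "25-49" = 25, "10-24" = 10, "3-9" = 3,
                "2" = 2)
    cnt <- integer(length(breaks))
    names(cnt) <- names(breaks)
    for (s in sizes) {
        lab <- if (s > 1000) ">1000"
               else names(breaks)[which(s >= breaks)[1]]
        cnt[lab] <- cnt[lab] + 1L
    }
    data.frame(bin = c(names(cnt), "singletons"),
               count = c(unname(cnt), length(singletons(map))),
               stringsAsFactors = FALSE)
}
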