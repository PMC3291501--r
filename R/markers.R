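# Genetic-marker tallies against the fingerprint map.

#' Tally marker hits against a fingerprint map
#'
#' For each marker: the number of distinct clones hit, the number of
#' distinct contigs those clones belong to (singleton clones count no
#' contig but are tracked), and the multiple-hit-marker class: a marker
#' hitting two or more clones is an MHM, subclassified as `multi_contig`
#' (two or more contigs), `single_contig_multi_clone` (one contig, several
#' clones), or `multi_singleton` (several clones, all singletons).
#'
#' @param hits data.frame with columns `marker_id`, `marker_type` (SSR or
#'   RFLP), `clone_id`; (marker, clone) pairs must be unique and every
#'   clone id known to the map.
#' @param map An [FPCMap()].
#' @return data.frame, one row per marker: `marker_id`, `marker_type`,
#'   `n_clones`, `n_contigs`, `n_singleton_clones`, `mhm_class`.
#' @export
tallyMarkers <- function(hits, map) {
    .check(!anyDuplicated(hits[, c("marker_id", "clone_id")]),
           "(marker_id, clone_id) pairs must be unique")
    unknown <- setdiff(hits$clone_id, cloneIds(map))
    .check(length(unknown) == 0,
           paste("unknown clone id(s):",
                 paste(head(unknown, 3), collapse = ", ")))
    cl <- map@clones
    ctgOf <- cl$contig_id[match(hits$clone_id, cl$clone_id)]
    sp <- split(seq_len(nrow(hits)), hits$marker_id)
    rows <- lapply(names(sp), function(mk) {
        i <- sp[[mk]]
        nClones <- length(unique(hits$clone_id[i]))
        ctgs <- unique(ctgOf[i][!is.na(ctgOf[i])])
        nSing <- sum(is.na(ctgOf[i]))
        cls <- if (nClones < 2) "none"
               else if (length(ctgs) >= 2) "multi_contig"
               else if (length(ctgs) == 1) "single_contig_multi_clone"
               else "multi_singleton"
        data.frame(marker_id = mk,
                   marker_type = hits$marker_type[i][1],
                   n_clones = nClones, n_contigs = length(ctgs),
                   n_singleton_clones = nSing, mhm_class = cls,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out[order(out$marker_id), , drop = FALSE]
}

#' Marker summary table
#'
#' Per marker type: mean contigs and clones hit, marker counts per
#' contig-count bin (0, 1, 2, >2) and clone-count bin (1, 2-4, 5-9, >=10),
#' and multiple-hit-marker class totals. Bin counts partition the markers
#' of each type.
#'
#' @param summaries From [tallyMarkers()]. Markers hitting no clone can be
#'   included as rows with `n_clones = 0`.
#' @return list of data.frames: `contig_bins`, `clone_bins`, `mhm`.
#' @export
markerTable <- function(summaries) {
    types <- c("SSR", "RFLP")
    cb <- lapply(types, function(ty) {
        s <- summaries[summaries$marker_type == ty, , drop = FALSE]
        data.frame(marker_type = ty, n_markers = nrow(s),
                   avg_contigs = if (nrow(s)) mean(s$n_contigs) else NA,
                   contigs_0 = sum(s$n_contigs == 0),
                   contigs_1 = sum(s$n_contigs == 1),
                   contigs_2 = sum(s$n_contigs == 2),
                   contigs_gt2 = sum(s$n_contigs > 2),
                   stringsAsFactors = FALSE)
    })
    kb <- lapply(types, function(ty) {
        s <- summaries[summaries$marker_type == ty, , drop = FALSE]
        data.frame(marker_type = ty,
                   avg_clones = if (nrow(s)) mean(s$n_clones) else NA,
                   clones_1 = sum(s$n_clones == 1),
                   clones_2_4 = sum(s$n_clones >= 2 & s$n_clones < 5),
                   clones_5_9 = sum(s$n_clones >= 5 & s$n_clones < 10),
                   clones_ge10 = sum(s$n_clones >= 10),
                   stringsAsFactors = FALSE)
    })
    mhm <- data.frame(
        multi_singleton = sum(summaries$mhm_class == "multi_singleton"),
        single_contig_multi_clone =
            sum(summaries$mhm_class == "single_contig_multi_clone"),
        multi_contig = sum(summaries$mhm_class == "multi_contig"))
    mhm$total <- mhm$multi_singleton + mhm$single_contig_multi_clone +
        mhm$multi_contig
    list(contig_bins = do.call(rbind, cb),
         clone_bins = do.call(rbind, kb),
         mhm = mhm)
}
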