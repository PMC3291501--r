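# End-to-end synthetic-study driver: simulate -> assemble -> anchor ->
# tiling paths -> structural scan -> markers -> reports.

#' Planted structural-variant set of the default study
#'
#' Events on a 2 x 5 Mb genome: deletions and insertions of 120/160/200 kb
#' (above the paired-end detection threshold), two 100 kb inversions, one
#' 150 kb reciprocal translocation, and 20 kb indels that sit below the
#' span-window resolution and should stay invisible. Events are spaced
#' > 450 kb (twice the maximum insert) so each clone overlaps at most one.
#'
#' @return An [svEvents()] table.
#' @export
defaultSVEvents <- function() {
    ev <- rbind(
        data.frame(sv_id = c("del120", "del160", "del200"),
                   sv_type = "deletion", ref_chrom = "chr1",
                   ref_start = c(4e5, 1.0e6, 1.62e6),
                   size = c(120000, 160000, 200000)),
        data.frame(sv_id = c("ins120", "ins160", "ins200"),
                   sv_type = "insertion", ref_chrom = "chr1",
                   ref_start = c(2.3e6, 2.8e6, 3.3e6),
                   size = c(120000, 160000, 200000)),
        data.frame(sv_id = "tra150", sv_type = "translocation",
                   ref_chrom = "chr1", ref_start = 3.9e6, size = 150000),
        data.frame(sv_id = c("inv100a", "inv100b"),
                   sv_type = "inversion", ref_chrom = "chr2",
                   ref_start = c(4e5, 1.0e6), size = 100000),
        data.frame(sv_id = c("del20a", "del20b", "del20c"),
                   sv_type = "deletion", ref_chrom = "chr2",
                   ref_start = c(2.25e6, 2.75e6, 3.25e6), size = 20000),
        data.frame(sv_id = c("ins20a", "ins20b", "ins20c"),
                   sv_type = "insertion", ref_chrom = "chr2",
                   ref_start = c(3.75e6, 4.25e6, 4.72e6), size = 20000))
    ev$partner_chrom <- ifelse(ev$sv_type == "translocation", "chr2", NA)
    ev$partner_start <- ifelse(ev$sv_type == "translocation", 1.6e6, NA)
    svEvents(ev$sv_id, ev$sv_type, ev$ref_chrom, ev$ref_start, ev$size,
             ev$partner_chrom, ev$partner_start)
}

#' Pipeline configuration
#'
#' Bundles every stage's parameters. Defaults define the package's
#' desk-scale study: a 2 x 5 Mb reference at 35% GC with random assembly
#' gaps, three reference BAC libraries (HindIII/BstYI/EcoRI, clone counts
#' proportional to the 5.4x/12x/10.9x coverage ratio of a three-library
#' design) at 10x combined clone coverage, a query library (HindIII, 10x)
#' from the rearranged sister genome, and the planted events of
#' [defaultSVEvents()].
#'
#' @param outdir Output directory (created if missing).
#' @param seed Master seed; every stage derives its stream from it.
#' @param nChrom,chromLength,gc Reference genome shape.
#' @param coverage,queryCoverage Combined clone coverage of the reference
#'   and query libraries.
#' @param nScaffoldJoin,nUnknown,nSized Assembly gap counts.
#' @param svEvents Planted events table, or NULL for none.
#' @param markers Simulate marker screening (logical).
#' @param nSSR,nRFLP Marker counts when `markers` is TRUE.
#' @param simParams,assemblyParams,mtpParams,analysisParams Stage
#'   parameter objects.
#' @return A `PipelineConfig` list.
#' @export
pipelineConfig <- function(outdir = tempfile("bacmap_run_"), seed = 1L,
                           nChrom = 2L, chromLength = 5e6, gc = 0.35,
                           coverage = 10, queryCoverage = 10,
                           nScaffoldJoin = 10L, nUnknown = 4L,
                           nSized = 4L,
                           svEvents = defaultSVEvents(),
                           markers = TRUE, nSSR = 120L, nRFLP = 30L,
                           simParams = SimParams(),
                           assemblyParams = AssemblyParams(),
                           mtpParams = MTPParams(),
                           analysisParams = AnalysisParams()) {
    cfg <- list(outdir = outdir, seed = as.integer(seed), nChrom = nChrom,
                chromLength = chromLength, gc = gc, coverage = coverage,
                queryCoverage = queryCoverage,
                nScaffoldJoin = nScaffoldJoin, nUnknown = nUnknown,
                nSized = nSized, svEvents = svEvents, markers = markers,
                nSSR = nSSR, nRFLP = nRFLP, simParams = simParams,
                assemblyParams = assemblyParams, mtpParams = mtpParams,
                analysisParams = analysisParams)
    class(cfg) <- "PipelineConfig"
    cfg
}

.stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
        stop(sprintf("[stage:%s] %s", name, conditionMessage(e)),
             call. = FALSE))
}

# Scaffold-join N-gaps plus a tiling path's own internal gaps, as one
# candidate-gap table for unpaired-BES extension.
.gapUnion <- function(gapTrackDf, mtp) {
    gN <- gapTrackDf[gapTrackDf$gap_class == "scaffold_join",
                     c("chrom", "start", "end"), drop = FALSE]
    gI <- data.frame(chrom = mtp@gaps$chrom, start = mtp@gaps$gap_start,
                     end = mtp@gaps$gap_end)
    out <- rbind(gN, gI)
    out <- out[order(out$chrom, out$start), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Run the full synthetic study
#'
#' Executes every stage on one seeded simulation and writes all interchange
#' files and summary tables (with the seed in each header) under
#' `config$outdir`. Reruns with the same configuration produce
#' byte-identical output.
#'
#' @param config A [pipelineConfig()].
#' @param quiet Suppress stage progress messages.
#' @return (Invisibly) a list with every intermediate object: genomes, gap
#'   track, clones, BES, fingerprints, map, placements, anchors, the four
#'   tiling paths and their statistics, structural-variant calls and
#'   truth evaluation, and marker tables.
#' @export
runPipeline <- function(config = pipelineConfig(), quiet = FALSE) {
    say <- function(...) if (!quiet) message(...)
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    out <- function(f) file.path(config$outdir, f)
    sp <- config$simParams
    seed <- config$seed

    say("simulate: reference genome and gaps")
    ref <- .stage("simulate", makeReference(config$nChrom,
                                            config$chromLength,
                                            config$gc, seed))
    gaps <- .stage("simulate", makeRandomGaps(
        ref, config$nScaffoldJoin, config$nUnknown, config$nSized,
        seed = seed + 1L))
    refGapped <- .stage("simulate", injectGaps(ref, gaps))
    variant <- .stage("simulate", deriveVariantGenome(
        ref, config$svEvents, seed = seed + 2L,
        minSpacing = 2 * sp@insertMax))

    say("simulate: BAC libraries")
    libs <- data.frame(library = c("REF_Ba", "REF_Bb", "REF_Bc"),
                       enzyme = c("HindIII", "BstYI", "EcoRI"),
                       weight = c(5.4, 12, 10.9),
                       stringsAsFactors = FALSE)
    genomeLen <- sum(as.numeric(BiocGenerics::width(ref)))
    nTotal <- round(config$coverage * genomeLen / sp@insertMean)
    libs$n <- round(nTotal * libs$weight / sum(libs$weight))
    clones <- .stage("simulate", do.call(rbind, lapply(
        seq_len(nrow(libs)), function(i)
            sampleClones(ref, libs$library[i], libs$enzyme[i], libs$n[i],
                         sp, seed = seed + 3L + i))))
    fpClones <- .stage("simulate", withSeed(seed + 10L, {
        keep <- sort(sample.int(nrow(clones),
                                round(sp@fingerprintedFrac *
                                          nrow(clones))))
        clones[keep, , drop = FALSE]
    }))
    fps <- .stage("simulate", fingerprintClones(
        fpClones, ref, enzyme = "HindIII", params = sp,
        seed = seed + 11L))
    bes <- .stage("simulate", extractBES(clones, ref, sp,
                                         seed = seed + 12L))

    say("assemble: fingerprint contigs")
    map <- .stage("assemble", clusterContigs(fps, config$assemblyParams))

    say("anchor: BES alignment and clone placement")
    hits <- .stage("anchor", alignBES(bes, refGapped))
    placements <- .stage("anchor", placeClones(hits, bes))
    placementSummary <- .stage("anchor", summarizePlacements(
        placements, config$analysisParams))
    anchors <- .stage("anchor", anchorContigs(map, placements))
    merged <- .stage("anchor", mergeContigsByReference(
        anchors, map, placements,
        maxJoinGap = config$mtpParams@assumedInsert))

    say("mtp: four tiling-path variants")
    mp <- config$mtpParams
    poolAp <- .stage("mtp", selectPool(placements, map, "A", TRUE, mp))
    poolAa <- .stage("mtp", selectPool(placements, map, "A", FALSE, mp))
    poolBp <- .stage("mtp", selectPool(placements, map, "B", TRUE, mp))
    poolBa <- .stage("mtp", selectPool(placements, map, "B", FALSE, mp))
    mtp1 <- .stage("mtp", buildMTP(poolAp, clones, mp))
    mtp3 <- .stage("mtp", buildMTP(poolBp, clones, mp))
    mtp2 <- .stage("mtp", augmentWithUnpaired(
        mtp1, poolAa, .gapUnion(gaps, mtp1), clones, mp))
    mtp4 <- .stage("mtp", augmentWithUnpaired(
        mtp3, poolBa, .gapUnion(gaps, mtp3), clones, mp))
    mtps <- list(mtp1 = mtp1, mtp2 = mtp2, mtp3 = mtp3, mtp4 = mtp4)
    stats <- lapply(mtps, mtpStats, libraries = libs$library)
    coverages <- lapply(mtps, coverageTable, genome = ref)
    spannedA <- .stage("mtp", countSpannedSequenceGaps(
        rbind(.asIntervals(poolAp),
              .creditedIntervals(mtp2)), gaps))
    spannedB <- .stage("mtp", countSpannedSequenceGaps(
        rbind(.asIntervals(poolBp),
              .creditedIntervals(mtp4)), gaps))

    say("svscan: query-genome library and classification")
    qLen <- sum(as.numeric(BiocGenerics::width(variant$genome)))
    nQuery <- round(config$queryCoverage * qLen / sp@insertMean)
    qClones <- .stage("svscan", sampleClones(
        variant$genome, "QRY_Ba", "HindIII", nQuery, sp,
        seed = seed + 20L))
    qBes <- .stage("svscan", extractBES(qClones, variant$genome, sp,
                                        seed = seed + 21L))
    qHits <- .stage("svscan", alignBES(qBes, refGapped))
    qPlacements <- .stage("svscan", placeClones(qHits, qBes))
    qSummary <- .stage("svscan", summarizePlacements(
        qPlacements, config$analysisParams))
    calls <- .stage("svscan", classifySV(qPlacements,
                                         config$analysisParams))
    callSummary <- .stage("svscan", svSummary(calls))
    flux <- .stage("svscan", estimateFlux(calls, config$analysisParams))
    truthEval <- if (!is.null(config$svEvents))
        .stage("svscan", suppressMessages(
            evaluateAgainstTruth(calls, variant$events))) else NULL

    markerHits <- NULL; markerSummaries <- NULL; markerTables <- NULL
    if (isTRUE(config$markers)) {
        say("markers: screening and tallies")
        mapClones <- fpClones[fpClones$clone_id %in% cloneIds(map), ,
                              drop = FALSE]
        markerHits <- .stage("markers", simulateMarkerHits(
            mapClones, ref, config$nSSR, config$nRFLP,
            seed = seed + 30L))
        markerSummaries <- .stage("markers", tallyMarkers(markerHits, map))
        markerTables <- .stage("markers", markerTable(markerSummaries))
    }

    say("report: writing output bundle")
    .stage("report", {
        writeGenomeFasta(ref, out("reference.fasta"))
        writeGenomeFasta(refGapped, out("reference_gapped.fasta"))
        writeAGP(refGapped, gaps, out("reference.agp"))
        writeGenomeFasta(variant$genome, out("query_genome.fasta"))
        .writeTSV(clones, out("clones.tsv"), seed)
        .writeTSV(qClones, out("query_clones.tsv"), seed)
        writeBESFasta(bes, out("bes.fasta"))
        writeBESFasta(qBes, out("query_bes.fasta"))
        writeFingerprints(fps, out("fingerprints.tsv"), seed)
        .writeTSV(map@clones, out("fpc_map.tsv"), seed)
        .writeTSV(contigHistogram(map), out("contig_histogram.tsv"), seed)
        writeHitsBED(hits, out("bes_hits.bed"))
        .writeTSV(placements, out("placements.tsv"), seed)
        .writeTSV(placementSummary, out("placement_summary.tsv"), seed)
        .writeTSV(anchors, out("contig_anchors.tsv"), seed)
        for (nm in names(mtps))
            .writeTSV(mtps[[nm]]@path, out(paste0(nm, ".tsv")), seed)
        .writeTSV(.mtpComparison(mtps, stats, coverages),
                  out("mtp_comparison.tsv"), seed)
        .writeTSV(qPlacements, out("query_placements.tsv"), seed)
        .writeTSV(qSummary, out("query_placement_summary.tsv"), seed)
        .writeTSV(calls, out("sv_calls.tsv"), seed)
        if (!is.null(config$svEvents)) {
            .writeTSV(variant$events, out("sv_truth.tsv"), seed)
            .writeTSV(truthEval$summary, out("sv_evaluation.tsv"), seed)
        }
        if (!is.null(markerHits)) {
            .writeTSV(markerHits, out("marker_hits.tsv"), seed)
            .writeTSV(markerSummaries, out("marker_summaries.tsv"), seed)
            .writeTSV(markerTables$contig_bins,
                      out("marker_contig_bins.tsv"), seed)
            .writeTSV(markerTables$clone_bins,
                      out("marker_clone_bins.tsv"), seed)
            .writeTSV(markerTables$mhm, out("marker_mhm.tsv"), seed)
        }
    })

    invisible(list(
        config = config, reference = ref, referenceGapped = refGapped,
        gaps = gaps, variant = variant, clones = clones,
        fingerprintedClones = fpClones, fingerprints = fps, bes = bes,
        map = map, hits = hits, placements = placements,
        placementSummary = placementSummary, anchors = anchors,
        merged = merged, pools = list(A_paired = poolAp, A_all = poolAa,
                                      B_paired = poolBp, B_all = poolBa),
        mtps = mtps, mtpStats = stats, coverages = coverages,
        spannedGaps = list(A = spannedA, B = spannedB),
        queryClones = qClones, queryPlacements = qPlacements,
        querySummary = qSummary, calls = calls,
        callSummary = callSummary, flux = flux, truthEval = truthEval,
        markerHits = markerHits, markerSummaries = markerSummaries,
        markerTables = markerTables))
}

# Credited extension intervals of an augmented tiling path.
.creditedIntervals <- function(mtp) {
    p <- mtp@path[mtp@path$augmented, , drop = FALSE]
    data.frame(chrom = p$chrom, start = p$credited_start,
               end = p$credited_end)
}

# One comparison row per tiling-path variant.
.mtpComparison <- function(mtps, stats, coverages) {
    data.frame(
        mtp = names(mtps),
        pool = c("A", "A", "B", "B"),
        bes = c("paired", "paired+unpaired", "paired",
                "paired+unpaired"),
        n_clones = vapply(stats, function(s) s$total_clones, numeric(1)),
        gaps = vapply(stats, function(s) s$gaps, numeric(1)),
        mean_overlap = vapply(stats, function(s)
            round(s$mean_overlap, 1), numeric(1)),
        covered_bp = vapply(coverages, function(cv)
            cv$covered[cv$chrom == "Total"], numeric(1)),
        covered_pct = vapply(coverages, function(cv)
            cv$pct[cv$chrom == "Total"], numeric(1)),
        row.names = NULL, stringsAsFactors = FALSE)
}
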