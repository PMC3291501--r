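# Shared fixtures, built lazily once per test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
    if (!exists(name, envir = .fixtures))
        assign(name, builder(), envir = .fixtures)
    get(name, envir = .fixtures)
}

# Small noise-free single-chromosome simulation (2 Mb, ~10x): genome,
# clones, fingerprints, BES, placements, map.
smallSim <- function() fixture("smallSim", function() {
    g <- makeReference(1, 2e6, gc = 0.35, seed = 2)
    sp <- SimParams(sizingCV = 0)
    cl <- sampleClones(g, "LibA", "HindIII", 130, sp, seed = 3)
    fp <- fingerprintClones(cl, g, "HindIII", sp, seed = 5)
    bes <- extractBES(cl, g, sp, seed = 4)
    hits <- alignBES(bes, g)
    pl <- placeClones(hits, bes)
    map <- clusterContigs(fp, AssemblyParams())
    list(genome = g, params = sp, clones = cl, fps = fp, bes = bes,
         hits = hits, placements = pl, map = map)
})

# Two-genome structural-variant simulation: 2 x 5 Mb reference, planted
# default events, 10x query clone coverage.
svSim <- function() fixture("svSim", function() {
    g <- makeReference(2, 5e6, gc = 0.35, seed = 11)
    vt <- deriveVariantGenome(g, defaultSVEvents(), seed = 12)
    sp <- SimParams()
    n <- round(10 * sum(as.numeric(Biostrings::width(vt$genome))) /
                   sp@insertMean)
    qc <- sampleClones(vt$genome, "QRY", "HindIII", n, sp, seed = 13)
    qb <- extractBES(qc, vt$genome, sp, seed = 14)
    qh <- alignBES(qb, g)
    qp <- placeClones(qh, qb)
    calls <- classifySV(qp, AnalysisParams())
    ev <- suppressMessages(evaluateAgainstTruth(calls, vt$events))
    list(reference = g, variant = vt, clones = qc, placements = qp,
         calls = calls, evaluation = ev)
})

# Planted-contig recovery simulation: 5 Mb, 10x, noise-free bands.
contigSim <- function() fixture("contigSim", function() {
    g <- makeReference(1, 5e6, gc = 0.35, seed = 21)
    sp <- SimParams(sizingCV = 0)
    cl <- sampleClones(g, "LibA", "HindIII", 333, sp, seed = 22)
    fp <- fingerprintClones(cl, g, "HindIII", sp, seed = 23)
    map <- clusterContigs(fp, AssemblyParams())
    list(genome = g, clones = cl, fps = fp, map = map)
})

# One full default pipeline run at a fixed seed.
pipelineRun <- function() fixture("pipelineRun", function() {
    cfg <- pipelineConfig(outdir = file.path(tempdir(), "bacmap_fix1"),
                          seed = 7)
    res <- suppressMessages(runPipeline(cfg, quiet = TRUE))
    res
})

# Truth overlap length of two clones, 0 if on different chromosomes.
truthOverlap <- function(clones, a, b) {
    i <- match(a, clones$clone_id); j <- match(b, clones$clone_id)
    if (clones$truth_chrom[i] != clones$truth_chrom[j]) return(0)
    max(0, min(clones$truth_end[i], clones$truth_end[j]) -
            max(clones$truth_start[i], clones$truth_start[j]))
}

# Marker-hit fixture reproducing the marginal structure of a published
# two-type marker screen (used to check tally identities).
markerFixture <- function() fixture("markerFixture", function() {
    # a map with plenty of contigs and singleton clones to point at
    nCtg <- 700
    ctgClones <- data.frame(
        clone_id = sprintf("cc%04d_%d", rep(seq_len(nCtg), each = 2),
                           rep(1:2, nCtg)),
        contig_id = sprintf("ctg%04d", rep(seq_len(nCtg), each = 2)),
        ord = rep(1:2, nCtg), cb_offset = rep(c(0, 5), nCtg),
        nbands = 20L, stringsAsFactors = FALSE)
    singles <- data.frame(
        clone_id = sprintf("sg%04d", seq_len(1200)),
        contig_id = NA_character_, ord = NA_integer_,
        cb_offset = NA_real_, nbands = 20L, stringsAsFactors = FALSE)
    cbl <- stats::setNames(rep(25, nCtg), sprintf("ctg%04d", seq_len(nCtg)))
    map <- FPCMap(rbind(ctgClones, singles), cbl)

    contigClone <- function(k, member = 1)
        sprintf("cc%04d_%d", ((k - 1) %% nCtg) + 1, member)
    singleClone <- function(k) sprintf("sg%04d", ((k - 1) %% 1200) + 1)

    hit <- function(marker, type, clones)
        data.frame(marker_id = marker, marker_type = type,
                   clone_id = clones, stringsAsFactors = FALSE)
    rows <- list()
    mk <- 0L
    add <- function(type, n, cloneFun) {
        for (i in seq_len(n)) {
            mk <<- mk + 1L
            rows[[length(rows) + 1L]] <<-
                hit(sprintf("M%05d", mk), type, cloneFun(i))
        }
    }
    # SSR: 417 zero-contig (one singleton clone each), of which none MHM;
    # 30 extra zero-contig markers hitting two singletons (multi_singleton)
    add("SSR", 417 - 30, function(i) singleClone(i))
    add("SSR", 30, function(i) c(singleClone(400 + 2 * i),
                                 singleClone(401 + 2 * i)))
    # SSR one-contig: 2601 total, 400 of them multi-clone on one contig
    add("SSR", 2601 - 400, function(i) contigClone(i))
    add("SSR", 400, function(i) c(contigClone(i, 1), contigClone(i, 2)))
    # SSR two-contig and >2-contig
    add("SSR", 301, function(i) c(contigClone(i), contigClone(i + 350)))
    add("SSR", 633, function(i) c(contigClone(i), contigClone(i + 233),
                                  contigClone(i + 466)))
    # RFLP: 98 zero-contig (11 of them multi-singleton), 331 one-contig
    # (103 multi-clone), 145 two-contig, 102 >2-contig
    add("RFLP", 98 - 11, function(i) singleClone(600 + i))
    add("RFLP", 11, function(i) c(singleClone(700 + 2 * i),
                                  singleClone(701 + 2 * i)))
    add("RFLP", 331 - 103, function(i) contigClone(i + 100))
    add("RFLP", 103, function(i) c(contigClone(i + 100, 1),
                                   contigClone(i + 100, 2)))
    add("RFLP", 145, function(i) c(contigClone(i), contigClone(i + 170)))
    add("RFLP", 102, function(i) c(contigClone(i), contigClone(i + 150),
                                   contigClone(i + 300)))
    list(map = map, hits = do.call(rbind, rows))
})
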