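test_that("reference generation is deterministic with correct shape and GC", {
    g <- makeReference(1, 2e6, gc = 0.5, seed = 7)
    expect_identical(names(g), "chr1")
    expect_identical(Biostrings::width(g), 2000000L)
    g2 <- makeReference(1, 2e6, gc = 0.5, seed = 7)
    expect_identical(as.character(g), as.character(g2))

    # observed GC within ~3 binomial standard errors at n = 6e6
    # (se = sqrt(0.35*0.65/6e6) ~ 2e-4, so a 0.01 window is generous)
    g3 <- makeReference(2, 3e6, gc = 0.35, seed = 1)
    af <- Biostrings::alphabetFrequency(g3, baseOnly = TRUE,
                                        collapse = TRUE)
    gcObs <- sum(af[c("G", "C")]) / sum(af)
    expect_lt(abs(gcObs - 0.35), 0.01)

    expect_error(makeReference(1, 100000, seed = 1), "too short")
})

test_that("gap injection writes N runs of the class-encoding lengths", {
    g <- makeReference(1, 300000, seed = 3)
    gt <- gapTrack(c("chr1", "chr1"), c(10000, 500), c(11000, 600))
    expect_identical(gt$gap_class[order(gt$start)],
                     c("unknown_size", "scaffold_join"))
    gg <- injectGaps(g, gt)
    s <- as.character(gg[[1]])
    expect_identical(substr(s, 10001, 11000), strrep("N", 1000))
    expect_identical(substr(s, 501, 600), strrep("N", 100))
    # everything else untouched
    expect_identical(substr(s, 1, 500), substr(as.character(g[[1]]), 1, 500))
    expect_identical(substr(s, 11001, 300000),
                     substr(as.character(g[[1]]), 11001, 300000))

    # empty track is the identity
    empty <- gapTrack(character(), numeric(), numeric())
    expect_identical(as.character(injectGaps(g, empty)),
                     as.character(g))

    # overlapping gaps rejected
    bad <- gapTrack(c("chr1", "chr1"), c(1000, 1500), c(2000, 2600))
    expect_error(injectGaps(g, bad), "overlap")

    # sized-run class
    gt3 <- gapTrack("chr1", 50000, 52500)
    expect_identical(gt3$gap_class, "sized")
})

test_that("digest sites expand IUPAC degeneracy and skip masked sequence", {
    expect_identical(digestSites("GAATTCAAGAATTC", "GAATTC"), c(0L, 8L))
    expect_identical(digestSites(strrep("N", 200), "GAATTC"), integer())

    # independent oracle: regex expansion of the IUPAC pattern
    g <- makeReference(1, 400000, gc = 0.4, seed = 5)
    s <- as.character(g[[1]])
    for (pat in c("RGATCY", "AAGCTT", "GAATTC")) {
        rx <- chartr("RY", "..", pat)
        rx <- gsub("R", "[AG]", gsub("Y", "[CT]", pat))
        hits <- gregexpr(rx, s)[[1]]
        want <- if (hits[1] == -1) integer() else as.integer(hits - 1L)
        expect_identical(digestSites(g[[1]], pat), want, label = pat)
    }
})

test_that("variant genome edits conserve or shift length exactly", {
    g <- makeReference(2, 1.5e6, gc = 0.4, seed = 9)

    del <- svEvents("d1", "deletion", "chr1", 5e5, 1e5)
    vd <- deriveVariantGenome(g, del, seed = 1)
    expect_identical(Biostrings::width(vd$genome)[1],
                     Biostrings::width(g)[1] - 100000L)

    inv <- svEvents("i1", "inversion", "chr1", 5e5, 1e5)
    vi <- deriveVariantGenome(g, inv, seed = 1)
    expect_identical(Biostrings::width(vi$genome), Biostrings::width(g))
    seg <- Biostrings::subseq(vi$genome[[1]], 5e5 + 1, 6e5)
    expect_identical(
        as.character(Biostrings::reverseComplement(seg)),
        as.character(Biostrings::subseq(g[[1]], 5e5 + 1, 6e5)))
    # outside the event the sequence is untouched
    expect_identical(as.character(Biostrings::subseq(vi$genome[[1]], 1, 5e5)),
                     as.character(Biostrings::subseq(g[[1]], 1, 5e5)))

    ins <- svEvents("n1", "insertion", "chr2", 7e5, 50000)
    vn <- deriveVariantGenome(g, ins, seed = 2)
    expect_identical(Biostrings::width(vn$genome)[2],
                     Biostrings::width(g)[2] + 50000L)

    tra <- svEvents("t1", "translocation", "chr1", 4e5, 120000,
                    partner_chrom = "chr2", partner_start = 9e5)
    vtr <- deriveVariantGenome(g, tra, seed = 3)
    expect_identical(Biostrings::width(vtr$genome), Biostrings::width(g))
    # base composition conserved genome-wide
    afr <- Biostrings::alphabetFrequency(g, collapse = TRUE)
    afv <- Biostrings::alphabetFrequency(vtr$genome, collapse = TRUE)
    expect_identical(afr, afv)
    # swapped content
    expect_identical(
        as.character(Biostrings::subseq(vtr$genome[[1]], 4e5 + 1, 4e5 + 120000)),
        as.character(Biostrings::subseq(g[[2]], 9e5 + 1, 9e5 + 120000)))

    # empty event list is the identity
    v0 <- deriveVariantGenome(g, NULL, seed = 1)
    expect_identical(as.character(v0$genome), as.character(g))

    # events violating the spacing invariant are rejected
    two <- svEvents(c("a", "b"), c("deletion", "deletion"), "chr1",
                    c(2e5, 4e5), c(1e5, 1e5))
    expect_error(deriveVariantGenome(g, two, seed = 1), "closer")
})

test_that("sampled clones obey the insert-size law", {
    sim <- smallSim()
    len <- sim$clones$truth_end - sim$clones$truth_start
    expect_true(all(len >= 75000 & len <= 225000))

    expect_identical(nrow(sampleClones(sim$genome, "L", "HindIII", 0,
                                       sim$params)), 0L)

    # enumeration oracle: mean accepted fragment length from the digest
    # site list, weighting each site pair by its geometric retention
    # probability and the Gaussian size-selection weight
    sp <- sim$params
    sites <- digestSites(sim$genome[[1]], "AAGCTT")
    p <- sp@partialDigestProb
    wsum <- 0; lsum <- 0
    for (i in seq_len(length(sites) - 1)) {
        js <- which(sites > sites[i] + sp@insertMin - 1 &
                    sites <= sites[i] + sp@insertMax)
        if (!length(js)) next
        L <- sites[js] - sites[i]
        w <- p * (1 - p)^(js - i - 1) *
            exp(-((L - sp@insertMean)^2) / (2 * sp@sizeSelectSD^2))
        wsum <- wsum + sum(w); lsum <- lsum + sum(w * L)
    }
    oracleMean <- lsum / wsum
    bigger <- sampleClones(sim$genome, "L", "HindIII", 400, sp, seed = 77)
    empMean <- mean(bigger$truth_end - bigger$truth_start)
    expect_lt(abs(empMean - oracleMean) / oracleMean, 0.05)
})

test_that("clone coverage approaches the Lander-Waterman expectation", {
    g <- makeReference(1, 2e6, gc = 0.35, seed = 31)
    sp <- SimParams()
    n <- round(10 * 2e6 / sp@insertMean)   # 10x coverage
    # measured over the edge-free interior: within an insert length of a
    # chromosome end the uniform-start assumption breaks down (negligible
    # on chromosome-scale sequence)
    clonable <- IRanges::IRanges(225000 + 1, 2e6 - 225000)
    fracs <- vapply(1:20, function(s) {
        cl <- sampleClones(g, "L", "HindIII", n, sp, seed = 1000 + s)
        cov <- IRanges::reduce(IRanges::IRanges(cl$truth_start + 1,
                                                cl$truth_end))
        sum(IRanges::width(IRanges::intersect(cov, clonable))) /
            IRanges::width(clonable)
    }, numeric(1))
    expect_gte(mean(fracs), 0.99)   # 1 - exp(-10) = 0.99995
})

test_that("BES extraction respects orientation and single-end failures", {
    sim <- smallSim()
    sp <- sim$params

    none <- extractBES(sim$clones, sim$genome,
                       SimParams(besSingleEndProb = 0, sizingCV = 0))
    expect_true(all(table(none$clone_id) == 2))
    all1 <- extractBES(sim$clones, sim$genome,
                       SimParams(besSingleEndProb = 1, sizingCV = 0))
    expect_true(all(table(all1$clone_id) == 1))

    # F read is the genome substring at the left insert end; R read the
    # reverse complement at the right end
    f1 <- none[none$end_label == "F", ][1, ]
    i <- match(f1$clone_id, sim$clones$clone_id)
    expect_identical(f1$sequence, as.character(Biostrings::subseq(
        sim$genome[[sim$clones$truth_chrom[i]]],
        sim$clones$truth_start[i] + 1,
        sim$clones$truth_start[i] + sp@besLen)))
    r1 <- none[none$end_label == "R" &
                   none$clone_id == f1$clone_id, ]
    expect_identical(r1$sequence, as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(
            as.character(Biostrings::subseq(
                sim$genome[[sim$clones$truth_chrom[i]]],
                sim$clones$truth_end[i] - sp@besLen + 1,
                sim$clones$truth_end[i]))))))

    # a read longer than the insert is rejected
    tiny <- sim$clones[1, ]
    expect_error(extractBES(tiny, sim$genome,
                            SimParams(besLen = 3e5)), "insert")
})

test_that("fingerprints are exact in the noise-free limit and conserve length", {
    sim <- smallSim()
    cl <- sim$clones[1:5, ]
    fp0 <- fingerprintClones(cl, sim$genome, "HindIII",
                             SimParams(sizingCV = 0, bandDetectMin = 1),
                             seed = 1)
    # digestion conserves length: bands sum to the insert length
    for (i in seq_len(nrow(cl)))
        expect_identical(sum(fp0[[cl$clone_id[i]]]),
                         as.integer(cl$truth_end[i] - cl$truth_start[i]))

    # identical truth intervals give identical noise-free fingerprints
    twin <- cl[c(1, 1), ]
    twin$clone_id <- c("twinA", "twinB")
    fpt <- fingerprintClones(twin, sim$genome, "HindIII",
                             SimParams(sizingCV = 0), seed = 9)
    expect_identical(fpt[["twinA"]], fpt[["twinB"]])

    # band floor drops small fragments
    fpBig <- fingerprintClones(cl, sim$genome, "HindIII",
                               SimParams(sizingCV = 0,
                                         bandDetectMin = 600), seed = 1)
    expect_true(all(unlist(fpBig) >= 600))
})
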