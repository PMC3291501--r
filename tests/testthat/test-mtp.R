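mkPlacements <- function(starts, ends, ids = NULL, chrom = "chr1",
                         status = "both_same_chrom") {
    n <- length(starts)
    if (is.null(ids)) ids <- sprintf("c%02d", seq_len(n))
    data.frame(clone_id = ids, n_reads = 2L, n_aligned = 2L,
               status = status, chrom = chrom, span_start = starts,
               span_end = ends, span_len = ends - starts,
               orientation_class = "toward",
               chrom1 = chrom, start1 = starts, end1 = starts + 600,
               strand1 = "+", chrom2 = chrom, start2 = ends - 600,
               end2 = ends, strand2 = "-", stringsAsFactors = FALSE)
}

test_that("pool selection filters by map membership, pairing and span", {
    map <- FPCMap(data.frame(clone_id = c("c01", "c02"),
                             contig_id = "ctg0001", ord = 1:2,
                             cb_offset = c(0, 1), nbands = 10L),
                  c(ctg0001 = 11))
    pl <- mkPlacements(c(0, 50000, 100000), c(150000, 200000, 400000))
    pl$status[2] <- "one_end"
    # c03: span 300 kb -> excluded everywhere; c02 one_end
    a <- selectPool(pl, map, "A", pairedOnly = TRUE)
    expect_identical(a$clone_id, "c01")
    aAll <- selectPool(pl, map, "A", pairedOnly = FALSE)
    expect_identical(sort(aAll$clone_id), c("c01", "c02"))
    b <- selectPool(pl, map, "B", pairedOnly = TRUE)
    expect_identical(b$clone_id, "c01")   # c03 span out of range
    pl2 <- pl
    pl2$span_end[3] <- 300000  # span 200 kb, not in map
    pl2$span_len[3] <- 200000
    b2 <- selectPool(pl2, map, "B", pairedOnly = TRUE)
    expect_identical(sort(b2$clone_id), c("c01", "c03"))
    a2 <- selectPool(pl2, map, "A", pairedOnly = TRUE)
    expect_identical(a2$clone_id, "c01")
})

test_that("coverage islands require at least 1 bp of overlap", {
    isl <- buildIslands(mkPlacements(c(0, 90000), c(100000, 200000)))
    expect_identical(nrow(isl), 1L)
    expect_equal(c(isl$start, isl$end), c(0, 200000))

    isl2 <- buildIslands(mkPlacements(c(0, 150000), c(100000, 250000)))
    expect_identical(nrow(isl2), 2L)

    # abutting half-open spans do not merge
    isl3 <- buildIslands(mkPlacements(c(0, 100000), c(100000, 200000)))
    expect_identical(nrow(isl3), 2L)
})

test_that("tiling path minimizes clone count, then overlap", {
    p <- MTPParams()
    # A[0,150k) B[50k,200k) C[100k,250k): A -> C wins with overlap 50k
    pl <- mkPlacements(c(0, 50000, 100000), c(150000, 200000, 250000),
                       ids = c("A", "B", "C"))
    isl <- buildIslands(pl)
    path <- pickMTP(isl[1, ], pl, p)
    expect_identical(path$clone_id, c("A", "C"))
    expect_identical(path$overlap, c(NA, 50000))

    # single-clone island
    one <- mkPlacements(0, 150000, ids = "Z")
    pz <- pickMTP(buildIslands(one)[1, ], one, p)
    expect_identical(pz$clone_id, "Z")
    expect_true(is.na(pz$overlap))

    # equal clone counts: the smaller total overlap wins (60k vs 40k)
    pl2 <- mkPlacements(c(0, 90000, 110000), c(150000, 250000, 250000),
                        ids = c("A", "B", "C"))
    path2 <- pickMTP(buildIslands(pl2)[1, ], pl2, p)
    expect_identical(path2$clone_id, c("A", "C"))
})

test_that("unpaired-end clones extend coverage into gaps by rule", {
    p <- MTPParams()
    clones <- data.frame(clone_id = c("c01", "c02", "u1", "u2", "u3"),
                         library = "LibA", stringsAsFactors = FALSE)
    core <- mkPlacements(c(0, 350000 + 295000),
                         c(350000, 350000 + 295000 + 150000),
                         ids = c("c01", "c02"))
    # u1: + hit just left of the island end, points into the gap
    one <- mkPlacements(c(345000, 345000, 100000),
                        c(345600, 345600, 100600),
                        ids = c("u1", "u2", "u3"), status = "one_end")
    one$strand1 <- c("+", "-", "+")
    one$chrom2 <- NA; one$start2 <- NA; one$end2 <- NA; one$strand2 <- NA
    mtp <- buildMTP(core, clones, p)
    expect_identical(nrow(mtpGaps(mtp)), 1L)
    gaps <- data.frame(chrom = mtpGaps(mtp)$chrom,
                       start = mtpGaps(mtp)$gap_start,
                       end = mtpGaps(mtp)$gap_end)
    aug <- augmentWithUnpaired(mtp, one, gaps, clones, p)
    added <- tilingPath(aug)[tilingPath(aug)$augmented, ]
    # u2 points away; u3 is 250 kb from the edge (> edgeWindow);
    # only u1 is added, credited [345k, 495k) truncated by nothing
    expect_identical(added$clone_id, "u1")
    expect_identical(c(added$credited_start, added$credited_end),
                     c(345000, 495000))
    expect_true(mtpGaps(aug)$entered)

    # stats: augmentation increases clone count by the number added
    st0 <- mtpStats(mtp); st1 <- mtpStats(aug)
    expect_equal(st1$total_clones, st0$total_clones + 1)
    expect_equal(st0$gaps, 1)
    expect_equal(st1$gaps, 0)
})

test_that("coverage accounting uses union semantics", {
    p <- MTPParams()
    clones <- data.frame(clone_id = c("A", "B"), library = "L")
    pl <- mkPlacements(c(0, 50000), c(150000, 200000), ids = c("A", "B"))
    mtp <- buildMTP(pl, clones, p)
    g <- Biostrings::DNAStringSet(c(chr1 = strrep("A", 1000000)))
    cov <- coverageTable(mtp, g)
    expect_identical(cov$covered[cov$chrom == "chr1"], 200000)
    expect_identical(cov$covered[cov$chrom == "Total"], 200000)
})

test_that("sequence-gap spanning distinguishes spanned from entered", {
    gaps <- gapTrack("chr1", 1000000, 1001000)
    spanSet <- data.frame(chrom = "chr1", start = 990000, end = 1010000)
    r <- countSpannedSequenceGaps(spanSet, gaps)
    expect_identical(r$spanned, 1L)
    expect_identical(r$partially_filled, 0L)

    # clone ending exactly at the gap start neither spans nor enters
    edge <- data.frame(chrom = "chr1", start = 900000, end = 1000000)
    r2 <- countSpannedSequenceGaps(edge, gaps)
    expect_identical(r2$spanned + r2$partially_filled, 0L)

    # an extension reaching 300 bp into the gap partially fills it
    part <- data.frame(chrom = "chr1", start = 900000, end = 1000300)
    r3 <- countSpannedSequenceGaps(part, gaps)
    expect_identical(r3$spanned, 0L)
    expect_identical(r3$partially_filled, 1L)
})

test_that("the four tiling-path variants are ordered as expected", {
    run <- pipelineRun()
    # pool B's eligible set contains pool A's
    expect_true(all(run$pools$A_paired$clone_id %in%
                        run$pools$B_paired$clone_id))
    covs <- vapply(run$coverages, function(cv)
        cv$covered[cv$chrom == "Total"], numeric(1))
    expect_gte(covs[["mtp3"]], covs[["mtp1"]])   # B >= A
    expect_gte(covs[["mtp2"]], covs[["mtp1"]])   # augmentation
    expect_gte(covs[["mtp4"]], covs[["mtp3"]])
    gaps <- vapply(run$mtpStats, function(s) s$gaps, numeric(1))
    expect_lte(gaps[["mtp4"]], gaps[["mtp3"]])
    expect_lte(gaps[["mtp3"]], gaps[["mtp1"]])
    cls <- vapply(run$mtpStats, function(s) s$total_clones, numeric(1))
    expect_gte(cls[["mtp2"]], cls[["mtp1"]])
    expect_gte(cls[["mtp4"]], cls[["mtp3"]])
})
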