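test_that("exact alignment recovers truth coordinates and drops ambiguity", {
    g <- makeReference(2, 400000, gc = 0.4, seed = 13)
    sub <- function(ch, from, len)
        as.character(Biostrings::subseq(g[[ch]], from + 1, from + len))
    rc <- function(s) as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(s)))
    bes <- data.frame(
        clone_id = c("c1", "c1", "c2", "c3", "c4"),
        end_label = c("F", "R", "F", "F", "F"),
        sequence = c(sub("chr1", 10000, 600),
                     rc(sub("chr1", 159400, 600)),
                     rc(sub("chr2", 50000, 600)),
                     strrep("ACGT", 150),          # absent from genome
                     sub("chr1", 20000, 600)),
        stringsAsFactors = FALSE)
    hits <- alignBES(bes, g)
    h1 <- hits[hits$read_id == "c1.F", ]
    expect_identical(c(h1$chrom, h1$start, h1$end, h1$strand),
                     c("chr1", 10000, 10600, "+"))
    h2 <- hits[hits$read_id == "c1.R", ]
    expect_identical(c(h2$chrom, h2$start, h2$strand),
                     c("chr1", 159400, "-"))
    expect_identical(hits[hits$read_id == "c2.F", "strand"], "-")
    expect_false("c3.F" %in% hits$read_id)

    # a read present at two loci is discarded
    dup <- g
    seqA <- sub("chr1", 20000, 600)
    dup[["chr2"]] <- Biostrings::replaceAt(
        dup[["chr2"]], IRanges::IRanges(300001, 300600),
        Biostrings::DNAString(seqA))
    hd <- alignBES(bes, dup)
    expect_false("c4.F" %in% hd$read_id)
    expect_true("c1.F" %in% hd$read_id)
})

test_that("clone placement classifies status, span, and orientation", {
    bes <- data.frame(clone_id = rep(c("a", "b", "c", "d", "e"), each = 2),
                      end_label = rep(c("F", "R"), 5),
                      sequence = "ACGT", stringsAsFactors = FALSE)
    hit <- function(clone, end, chrom, start, strand)
        data.frame(read_id = paste(clone, end, sep = "."),
                   clone_id = clone, end_label = end, chrom = chrom,
                   start = start, end = start + 600, strand = strand,
                   stringsAsFactors = FALSE)
    hits <- rbind(
        hit("a", "F", "chr1", 100000, "+"),   # toward, span 150 kb
        hit("a", "R", "chr1", 249400, "-"),
        hit("b", "F", "chr1", 500000, "+"),   # interchromosomal
        hit("b", "R", "chr3", 100000, "-"),
        hit("c", "F", "chr1", 800000, "+"),   # same direction
        hit("c", "R", "chr1", 900000, "+"),
        hit("d", "F", "chr2", 100000, "-"),   # opposite
        hit("d", "R", "chr2", 200000, "+"))
    pl <- placeClones(hits, bes)
    a <- pl[pl$clone_id == "a", ]
    expect_identical(a$status, "both_same_chrom")
    expect_identical(a$span_len, 150000)
    expect_identical(a$orientation_class, "toward")
    expect_identical(pl$status[pl$clone_id == "b"], "both_diff_chrom")
    expect_identical(pl$orientation_class[pl$clone_id == "c"],
                     "same_direction")
    expect_identical(pl$orientation_class[pl$clone_id == "d"], "opposite")
    expect_identical(pl$status[pl$clone_id == "e"], "no_end")

    # left/right is decided by coordinate, not by F/R label
    flip <- rbind(hit("a", "R", "chr1", 100000, "+"),
                  hit("a", "F", "chr1", 249400, "-"))
    pf <- placeClones(flip, bes[bes$clone_id == "a", ])
    expect_identical(pf$orientation_class, "toward")

    expect_error(placeClones(rbind(hits, hit("a", "F", "chr5", 1, "+")),
                             bes), "more than 2")
})

test_that("placement summary partitions are exact on simulated data", {
    sim <- smallSim()
    sm <- summarizePlacements(sim$placements, AnalysisParams())
    cnt <- function(lab) sm$count[sm$label == lab]
    expect_identical(cnt("Clones where BES aligned to same chromosome"),
                     cnt("75 kbp < clones < 225 kbp") +
                     cnt("Clones < 75 kbp") + cnt("Clones > 225 kbp") +
                     cnt("Clones excluded as artifacts (> 1.5 Mbp)"))
    expect_identical(cnt("Clones where BES aligned to same chromosome"),
                     cnt("Clones with BES with expected orientation") +
                     cnt("Clones with BES in opposite direction") +
                     cnt("Clones with BES same direction"))
    # noise-free simulation without SVs: every two-end clone is
    # same-chromosome, toward, with span equal to the truth insert
    same <- sim$placements[sim$placements$n_aligned == 2, ]
    expect_true(all(same$status == "both_same_chrom"))
    expect_true(all(same$orientation_class == "toward"))
    i <- match(same$clone_id, sim$clones$clone_id)
    expect_identical(same$span_len,
                     sim$clones$truth_end[i] - sim$clones$truth_start[i])

    empty <- summarizePlacements(sim$placements[0, ], AnalysisParams())
    expect_true(all(empty$count == 0))
})

test_that("contig anchoring recovers the truth chromosome and orientation", {
    sim <- smallSim()
    anc <- anchorContigs(sim$map, sim$placements)
    placed <- anc[anc$n_placed >= 5, ]
    expect_gt(nrow(placed), 0)
    expect_true(all(placed$anchored))
    # truth: all clones are from chr1
    expect_true(all(placed$chrom == "chr1"))

    # 50/50 split across chromosomes fails the 80% agreement rule
    map <- FPCMap(data.frame(
        clone_id = c("x1", "x2", "x3", "x4"), contig_id = "ctg0001",
        ord = 1:4, cb_offset = c(0, 2, 4, 6), nbands = 10L),
        c(ctg0001 = 16))
    pl <- data.frame(clone_id = c("x1", "x2", "x3", "x4"),
                     n_reads = 2L, n_aligned = 2L,
                     status = "both_same_chrom",
                     chrom = c("chr1", "chr1", "chr2", "chr2"),
                     span_start = c(0, 10000, 0, 10000) + 1000,
                     span_end = c(0, 10000, 0, 10000) + 151000,
                     span_len = 150000, orientation_class = "toward",
                     stringsAsFactors = FALSE)
    a2 <- anchorContigs(map, pl)
    expect_false(a2$anchored)

    # reversing the clone order flips the orientation sign
    pl3 <- pl
    pl3$chrom <- "chr1"
    pl3$span_start <- c(1, 2, 3, 4) * 50000
    pl3$span_end <- pl3$span_start + 150000
    a3 <- anchorContigs(map, pl3)
    expect_identical(a3$orientation, "+")
    revClones <- map@clones
    revClones$ord <- 5L - revClones$ord
    revClones$cb_offset <- c(6, 4, 2, 0)
    mapRev <- FPCMap(revClones, c(ctg0001 = 16))
    a4 <- anchorContigs(mapRev, pl3)
    expect_identical(a4$orientation, "-")
})

test_that("reference-guided merging joins adjacent contigs transitively", {
    mkMap <- function(nCtg) {
        rows <- do.call(rbind, lapply(seq_len(nCtg), function(k)
            data.frame(clone_id = sprintf("c%d_%d", k, 1:2),
                       contig_id = sprintf("ctg%04d", k), ord = 1:2,
                       cb_offset = c(0, 3), nbands = 10L)))
        FPCMap(rows, stats::setNames(rep(13, nCtg),
                                     sprintf("ctg%04d", seq_len(nCtg))))
    }
    mkPl <- function(starts, chroms) {
        n <- length(starts)
        data.frame(clone_id = sprintf("c%d_%d", rep(seq_len(n / 2),
                                                    each = 2),
                                      rep(1:2, n / 2)),
                   n_reads = 2L, n_aligned = 2L,
                   status = "both_same_chrom", chrom = chroms,
                   span_start = starts, span_end = starts + 150000,
                   span_len = 150000, orientation_class = "toward",
                   stringsAsFactors = FALSE)
    }
    map <- mkMap(2)
    # contig extents [0, 250k) and [270k, 520k): 20 kb apart
    pl <- mkPl(c(0, 100000, 270000, 370000), "chr1")
    anc <- anchorContigs(map, pl)
    mg <- mergeContigsByReference(anc, map, pl, maxJoinGap = 50000)
    expect_identical(mg$merges, 1L)
    expect_identical(nContigs(mg$map), 1L)

    # different chromosomes never merge
    pl2 <- mkPl(c(0, 100000, 270000, 370000),
                c("chr1", "chr1", "chr2", "chr2"))
    anc2 <- anchorContigs(map, pl2)
    mg2 <- mergeContigsByReference(anc2, map, pl2, maxJoinGap = 50000)
    expect_identical(mg2$merges, 0L)

    # three collinear contigs within the gap: 2 merges, one contig
    map3 <- mkMap(3)
    pl3 <- mkPl(c(0, 100000, 270000, 370000, 540000, 640000), "chr1")
    anc3 <- anchorContigs(map3, pl3)
    mg3 <- mergeContigsByReference(anc3, map3, pl3, maxJoinGap = 50000)
    expect_identical(mg3$merges, 2L)
    expect_identical(nContigs(mg3$map), 1L)
    expect_identical(nrow(contigs(mg3$map)), 6L)
})
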