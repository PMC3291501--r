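# Synthetic genomes, assembly gaps, and BAC libraries.
#
# Coordinates are 0-based half-open throughout the package; printed reports
# and AGP output convert to 1-based inclusive.

#' Generate a random reference genome
#'
#' Chromosomes of i.i.d. bases at a given GC content, the coordinate frame
#' for clone sampling, anchoring and tiling-path selection.
#'
#' @param nChrom Number of chromosomes (>= 1).
#' @param chromLength Chromosome length(s) in bp; recycled to `nChrom`. Must
#'   be at least large enough to host one maximum-size clone (225 kb).
#' @param gc GC fraction in (0, 1).
#' @param seed Integer seed; the same call with the same seed returns an
#'   identical genome.
#' @return A [Biostrings::DNAStringSet] named `chr1`, `chr2`, ...
#' @examples
#' g <- makeReference(1, 300000, gc = 0.35, seed = 7)
#' width(g)
#' @export
makeReference <- function(nChrom, chromLength, gc = 0.35, seed = 1L) {
    .check(nChrom >= 1, "'nChrom' must be >= 1")
    .check(gc > 0 && gc < 1, "'gc' must be in (0, 1)")
    chromLength <- rep_len(as.numeric(chromLength), nChrom)
    .check(all(chromLength >= 225000),
           "chromosome too short to host a single BAC clone (need >= 225 kb)")
    prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    raws <- charToRaw("ACGT")
    withSeed(seed, {
        seqs <- vapply(chromLength, function(n) {
            idx <- sample.int(4L, n, replace = TRUE, prob = prob)
            rawToChar(raws[idx])
        }, character(1))
        gn <- Biostrings::DNAStringSet(seqs)
        names(gn) <- paste0("chr", seq_len(nChrom))
        gn
    })
}

#' Build or validate an assembly gap track
#'
#' A gap track records runs of N in the reference: a run of exactly 1000 N is
#' a scaffold-join gap, 100 N an unknown-size gap, and any other run length a
#' sized gap. The class is derived from the interval length.
#'
#' @param chrom,start,end Gap intervals, 0-based half-open.
#' @return data.frame with columns `chrom`, `start`, `end`, `gap_class`.
#' @export
gapTrack <- function(chrom, start, end) {
    .check(all(end > start), "gap intervals must have end > start")
    len <- end - start
    cls <- ifelse(len == 1000, "scaffold_join",
                  ifelse(len == 100, "unknown_size", "sized"))
    df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                     gap_class = cls, stringsAsFactors = FALSE)
    df <- df[order(df$chrom, df$start), , drop = FALSE]
    rownames(df) <- NULL
    df
}

#' Place random assembly gaps on a genome
#'
#' Draws non-overlapping gap intervals of the three kinds (scaffold-join
#' 1000 N, unknown-size 100 N, and sized runs) at uniform positions, keeping
#' gaps at least `minSpacing` apart.
#'
#' @param genome A `DNAStringSet`.
#' @param nScaffoldJoin,nUnknown,nSized Gap counts per kind.
#' @param sizedLengths Pool of run lengths for sized gaps.
#' @param minSpacing Minimum distance between gaps, bp.
#' @param seed Integer seed.
#' @return A gap track data.frame (see [gapTrack()]).
#' @export
makeRandomGaps <- function(genome, nScaffoldJoin = 4, nUnknown = 2,
                           nSized = 2, sizedLengths = c(2000, 5000, 250),
                           minSpacing = 50000, seed = 1L) {
    withSeed(seed, {
        lens <- c(rep(1000, nScaffoldJoin), rep(100, nUnknown),
                  if (nSized) sizedLengths[
                      sample.int(length(sizedLengths), nSized, replace = TRUE)]
                  else numeric())
        chroms <- names(genome)
        widths <- BiocGenerics::width(genome)
        out <- list()
        placed <- list()
        for (i in seq_along(lens)) {
            ok <- FALSE
            for (try in 1:1000) {
                ci <- sample.int(length(chroms), 1L,
                                 prob = as.numeric(widths))
                s <- floor(runif(1, minSpacing,
                                 widths[ci] - lens[i] - minSpacing))
                e <- s + lens[i]
                prev <- placed[[chroms[ci]]]
                if (is.null(prev) ||
                    all(s - minSpacing >= prev[, 2] |
                        e + minSpacing <= prev[, 1])) {
                    placed[[chroms[ci]]] <- rbind(prev, c(s, e))
                    out[[length(out) + 1L]] <-
                        data.frame(chrom = chroms[ci], start = s, end = e)
                    ok <- TRUE
                    break
                }
            }
            if (!ok) stop("could not place gaps with requested spacing")
        }
        df <- do.call(rbind, out)
        gapTrack(df$chrom, df$start, df$end)
    })
}

#' Mask gap intervals with N
#'
#' Returns a copy of the genome whose sequence is N exactly on the gap
#' intervals, so the run length encodes the gap class (1000/100/other).
#'
#' @param genome A `DNAStringSet`.
#' @param gaps A gap track data.frame.
#' @return A `DNAStringSet` of the same lengths.
#' @export
injectGaps <- function(genome, gaps) {
    if (is.null(gaps) || nrow(gaps) == 0L) return(genome)
    .check(all(gaps$chrom %in% names(genome)), "unknown chromosome in gaps")
    .check(all(gaps$end > gaps$start), "gap intervals must have end > start")
    out <- genome
    for (ch in unique(gaps$chrom)) {
        g <- gaps[gaps$chrom == ch, , drop = FALSE]
        g <- g[order(g$start), , drop = FALSE]
        .check(all(g$start >= 0 & g$end <= length(out[[ch]])),
               "gap interval outside chromosome bounds")
        .check(all(head(g$end, -1) <= g$start[-1]),
               "overlapping gap intervals are not allowed")
        at <- .ir0(g$start, g$end)
        val <- Biostrings::DNAStringSet(strrep("N", g$end - g$start))
        out[[ch]] <- Biostrings::replaceAt(out[[ch]], at, val)
    }
    out
}

#' Construct a structural-variant truth table
#'
#' @param sv_id Event ids (unique).
#' @param sv_type One of `insertion`, `deletion`, `inversion`,
#'   `translocation`.
#' @param ref_chrom,ref_start Event locus on the reference (0-based).
#' @param size Event size in bp (> 0); for a translocation, the length of
#'   the two swapped blocks.
#' @param partner_chrom,partner_start Partner block for translocations.
#' @return data.frame of events, sorted by chromosome and position.
#' @export
svEvents <- function(sv_id, sv_type, ref_chrom, ref_start, size,
                     partner_chrom = NA_character_,
                     partner_start = NA_real_) {
    df <- data.frame(sv_id = as.character(sv_id),
                     sv_type = as.character(sv_type),
                     ref_chrom = as.character(ref_chrom),
                     ref_start = as.numeric(ref_start),
                     size = as.numeric(size),
                     partner_chrom = as.character(partner_chrom),
                     partner_start = as.numeric(partner_start),
                     stringsAsFactors = FALSE)
    .check(!anyDuplicated(df$sv_id), "sv_id values must be unique")
    .check(all(df$size > 0), "event size must be > 0")
    .check(all(df$sv_type %in%
               c("insertion", "deletion", "inversion", "translocation")),
           "unknown sv_type")
    tr <- df$sv_type == "translocation"
    .check(all(!is.na(df$partner_chrom[tr]) & !is.na(df$partner_start[tr])),
           "translocations need partner_chrom and partner_start")
    df[order(df$ref_chrom, df$ref_start), , drop = FALSE]
}

# Intervals occupied by events on each chromosome (translocations occupy
# both blocks; insertions a zero-width locus).
.eventFootprints <- function(events) {
    w <- ifelse(events$sv_type == "insertion", 0, events$size)
    fp <- data.frame(chrom = events$ref_chrom, start = events$ref_start,
                     end = events$ref_start + w, sv_id = events$sv_id)
    tr <- events$sv_type == "translocation"
    if (any(tr))
        fp <- rbind(fp, data.frame(chrom = events$partner_chrom[tr],
                                   start = events$partner_start[tr],
                                   end = events$partner_start[tr] +
                                       events$size[tr],
                                   sv_id = events$sv_id[tr]))
    fp[order(fp$chrom, fp$start), , drop = FALSE]
}

#' Derive a rearranged sister genome with known truth
#'
#' Applies planted insertions, deletions, inversions, and translocations to
#' a reference. Events must be separated by at least `minSpacing` (twice the
#' maximum insert size by default) so each clone can overlap at most one
#' event and truth labels stay unambiguous -- a simulation constraint, not a
#' claim about real genomes.
#'
#' @param ref Reference `DNAStringSet`.
#' @param events Event table from [svEvents()].
#' @param seed Seed for inserted random sequence.
#' @param minSpacing Minimum separation between event footprints, bp.
#' @return A list with `genome` (the variant `DNAStringSet`) and `events`
#'   (the input events with `variant_chrom`/`variant_start` bookkeeping
#'   columns giving each locus in variant-genome coordinates; truth
#'   intervals stay in reference coordinates, the frame in which calls are
#'   made).
#' @export
deriveVariantGenome <- function(ref, events, seed = 1L,
                                minSpacing = 2 * 225000) {
    if (is.null(events) || nrow(events) == 0L)
        return(list(genome = ref, events = events))
    fp <- .eventFootprints(events)
    .check(all(fp$chrom %in% names(ref)), "unknown chromosome in events")
    for (ch in unique(fp$chrom)) {
        f <- fp[fp$chrom == ch, , drop = FALSE]
        .check(all(f$start >= 0 & f$end <= length(ref[[ch]])),
               "event outside chromosome bounds")
        if (nrow(f) > 1L)
            .check(all(f$start[-1] - head(f$end, -1) >= minSpacing),
                   sprintf("events closer than %d bp (ambiguous truth)",
                           minSpacing))
    }
    out <- ref
    withSeed(seed, {
        # replaceAt takes all intervals in original coordinates, so shifts
        # need no manual bookkeeping within a chromosome.
        edits <- list()  # chrom -> list(at = IRanges, value = DNAStringSet)
        addEdit <- function(ch, at, value) {
            e <- edits[[ch]]
            if (is.null(e)) e <- list(at = NULL, value = character())
            e$at <- c(e$at, list(at))
            e$value <- c(e$value, as.character(value))
            edits[[ch]] <<- e
        }
        for (i in seq_len(nrow(events))) {
            ev <- events[i, ]
            ch <- ev$ref_chrom
            s <- ev$ref_start
            if (ev$sv_type == "deletion") {
                addEdit(ch, .ir0(s, s + ev$size), "")
            } else if (ev$sv_type == "insertion") {
                ins <- rawToChar(charToRaw("ACGT")[
                    sample.int(4L, ev$size, replace = TRUE)])
                addEdit(ch, IRanges::IRanges(s + 1, s), ins)  # zero width
            } else if (ev$sv_type == "inversion") {
                seg <- Biostrings::subseq(ref[[ch]], s + 1, s + ev$size)
                addEdit(ch, .ir0(s, s + ev$size),
                        Biostrings::reverseComplement(seg))
            } else { # translocation: swap equal-length blocks
                ch2 <- ev$partner_chrom
                s2 <- ev$partner_start
                blockA <- Biostrings::subseq(ref[[ch]], s + 1, s + ev$size)
                blockB <- Biostrings::subseq(ref[[ch2]], s2 + 1,
                                             s2 + ev$size)
                addEdit(ch, .ir0(s, s + ev$size), blockB)
                addEdit(ch2, .ir0(s2, s2 + ev$size), blockA)
            }
        }
        for (ch in names(edits)) {
            e <- edits[[ch]]
            at <- do.call(c, e$at)
            o <- order(BiocGenerics::start(at))
            out[[ch]] <- Biostrings::replaceAt(
                out[[ch]], at[o], Biostrings::DNAStringSet(e$value[o]))
        }
    })
    # variant-genome coordinates: cumulative length shift per chromosome
    events$variant_chrom <- events$ref_chrom
    events$variant_start <- events$ref_start
    for (ch in unique(events$ref_chrom)) {
        idx <- which(events$ref_chrom == ch)
        idx <- idx[order(events$ref_start[idx])]
        shift <- 0
        for (i in idx) {
            events$variant_start[i] <- events$ref_start[i] + shift
            if (events$sv_type[i] == "insertion") shift <- shift +
                    events$size[i]
            if (events$sv_type[i] == "deletion") shift <- shift -
                    events$size[i]
        }
    }
    list(genome = out, events = events)
}

#' Restriction sites of an IUPAC pattern
#'
#' All 0-based match start positions of `pattern` (IUPAC degeneracy
#' expanded, e.g. R = A|G) in `sequence`. Ambiguity letters in the subject
#' (N runs) never match.
#'
#' @param sequence A `DNAString` or character scalar.
#' @param pattern Non-empty IUPAC recognition pattern.
#' @return Sorted integer vector of 0-based cut positions.
#' @examples
#' digestSites("GAATTCAAGAATTC", "GAATTC")  # 0, 8
#' @export
digestSites <- function(sequence, pattern) {
    .check(is.character(pattern) && nchar(pattern) > 0,
           "'pattern' must be a non-empty IUPAC string")
    if (is.character(sequence)) sequence <- Biostrings::DNAString(sequence)
    m <- Biostrings::matchPattern(pattern, sequence, fixed = "subject")
    sort(BiocGenerics::start(m) - 1L)
}

# Per-chromosome complete-digest site lists for one enzyme.
.siteList <- function(genome, pattern)
    lapply(seq_along(genome), function(i) digestSites(genome[[i]], pattern))

# Count of site pairs whose fragment length falls in [lo, hi].
.acceptablePairCount <- function(sites, lo, hi) {
    if (length(sites) < 2L) return(0)
    n <- length(sites)
    hiIdx <- findInterval(sites + hi, sites)
    loIdx <- findInterval(sites + lo - 1, sites)
    sum(pmax(hiIdx - pmax(loIdx, seq_len(n)), 0))
}

#' Sample BAC clones from a genome
#'
#' Clones are partial-digest fragments: a random cut site is paired with the
#' next retained site (each site kept independently with
#' `partialDigestProb`), then size-selected -- accepted only inside
#' `[insertMin, insertMax]` and thinned with a Gaussian weight centred on
#' `insertMean` (`sizeSelectSD`), emulating gel excision of the target
#' fraction. Chromosomes are sampled with replacement proportionally to
#' their acceptable-fragment counts.
#'
#' @param genome `DNAStringSet` to clone from.
#' @param library Library name recorded with each clone.
#' @param enzyme Enzyme name; its pattern is looked up in `params@enzymes`.
#' @param nClones Number of clones to draw.
#' @param params A [SimParams()] object.
#' @param seed Integer seed.
#' @return data.frame with columns `clone_id`, `library`, `enzyme`,
#'   `truth_chrom`, `truth_start`, `truth_end` (0-based half-open).
#' @export
sampleClones <- function(genome, library, enzyme, nClones,
                         params = SimParams(), seed = 1L) {
    if (nClones == 0)
        return(data.frame(clone_id = character(), library = character(),
                          enzyme = character(), truth_chrom = character(),
                          truth_start = numeric(), truth_end = numeric(),
                          stringsAsFactors = FALSE))
    pat <- params@enzymes$pattern[match(enzyme, params@enzymes$name)]
    .check(!is.na(pat), paste("unknown enzyme:", enzyme))
    sites <- .siteList(genome, pat)
    counts <- vapply(sites, .acceptablePairCount, numeric(1),
                     lo = params@insertMin, hi = params@insertMax)
    .check(sum(counts) > 0,
           "no acceptable digest fragment exists in this genome")
    p <- params@partialDigestProb
    withSeed(seed, {
        chromIdx <- numeric(0); st <- numeric(0); en <- numeric(0)
        attempts <- 0
        maxAttempts <- 2000 * nClones
        while (length(st) < nClones) {
            batch <- max(64L, 4L * (nClones - length(st)))
            attempts <- attempts + batch
            if (attempts > maxAttempts)
                stop("failed to sample acceptable clone fragments ",
                     "(simulation scale unusable)")
            ci <- sample.int(length(sites), batch, replace = TRUE,
                             prob = counts)
            nSites <- lengths(sites)[ci]
            i <- floor(runif(batch) * (nSites - 1)) + 1
            j <- i + 1 + rgeom(batch, p)
            ok <- j <= nSites
            s <- rep(NA_real_, batch); e <- rep(NA_real_, batch)
            s[ok] <- mapply(function(c0, i0) sites[[c0]][i0], ci[ok], i[ok])
            e[ok] <- mapply(function(c0, j0) sites[[c0]][j0], ci[ok], j[ok])
            len <- e - s
            ok <- ok & !is.na(len) & len >= params@insertMin &
                len <= params@insertMax
            w <- exp(-((len - params@insertMean)^2) /
                         (2 * params@sizeSelectSD^2))
            ok <- ok & runif(batch) < w
            chromIdx <- c(chromIdx, ci[ok])
            st <- c(st, s[ok]); en <- c(en, e[ok])
        }
        keep <- seq_len(nClones)
        data.frame(
            clone_id = sprintf("%s_%05d", library, keep),
            library = library, enzyme = enzyme,
            truth_chrom = names(genome)[chromIdx[keep]],
            truth_start = st[keep], truth_end = en[keep],
            stringsAsFactors = FALSE)
    })
}

#' Extract BAC end sequences from clones
#'
#' The F read is the first `besLen` bases of the insert on the plus strand;
#' the R read is the reverse complement of the last `besLen` bases, so a
#' correctly placed pair points toward each other on the reference. With
#' probability `besSingleEndProb` a clone yields exactly one end, chosen
#' uniformly.
#'
#' @param clones Clone table from [sampleClones()].
#' @param genome The genome the clones were sampled from.
#' @param params A [SimParams()].
#' @param seed Integer seed (governs single-end failures only).
#' @return data.frame with `clone_id`, `end_label` (F/R), `sequence`, and
#'   truth bookkeeping columns `truth_chrom`, `truth_start`, `truth_strand`
#'   (never consumed by analysis code).
#' @export
extractBES <- function(clones, genome, params = SimParams(), seed = 1L) {
    if (nrow(clones) == 0L)
        return(data.frame(clone_id = character(), end_label = character(),
                          sequence = character(), truth_chrom = character(),
                          truth_start = numeric(),
                          truth_strand = character()))
    L <- params@besLen
    .check(all(clones$truth_end - clones$truth_start >= L),
           "besLen exceeds an insert length")
    reads <- list()
    for (ch in unique(clones$truth_chrom)) {
        cl <- clones[clones$truth_chrom == ch, , drop = FALSE]
        fSeq <- Biostrings::extractAt(genome[[ch]],
                                      .ir0(cl$truth_start,
                                           cl$truth_start + L))
        rSeq <- Biostrings::extractAt(genome[[ch]],
                                      .ir0(cl$truth_end - L, cl$truth_end))
        rSeq <- Biostrings::reverseComplement(
            Biostrings::DNAStringSet(rSeq))
        reads[[ch]] <- rbind(
            data.frame(clone_id = cl$clone_id, end_label = "F",
                       sequence = as.character(fSeq),
                       truth_chrom = ch, truth_start = cl$truth_start,
                       truth_strand = "+", stringsAsFactors = FALSE),
            data.frame(clone_id = cl$clone_id, end_label = "R",
                       sequence = as.character(rSeq),
                       truth_chrom = ch, truth_start = cl$truth_end - L,
                       truth_strand = "-", stringsAsFactors = FALSE))
    }
    bes <- do.call(rbind, reads)
    bes <- bes[order(match(bes$clone_id, clones$clone_id),
                     bes$end_label), , drop = FALSE]
    rownames(bes) <- NULL
    withSeed(seed, {
        single <- runif(nrow(clones)) < params@besSingleEndProb
        dropEnd <- ifelse(runif(nrow(clones)) < 0.5, "F", "R")
        names(dropEnd) <- clones$clone_id
        drop <- single[match(bes$clone_id, clones$clone_id)] &
            bes$end_label == dropEnd[bes$clone_id]
        bes[!drop, , drop = FALSE]
    })
}

#' Fingerprint clones by complete digestion
#'
#' Each clone insert is completely digested with the fingerprinting enzyme;
#' fragment sizes are perturbed by multiplicative Gaussian sizing noise
#' (`sizingCV`) and fragments below `bandDetectMin` are dropped. Clones with
#' no retained band are skipped with a warning.
#'
#' @param clones Clone table from [sampleClones()].
#' @param genome The source genome.
#' @param enzyme Fingerprinting enzyme name (default HindIII).
#' @param params A [SimParams()].
#' @param seed Integer seed for sizing noise.
#' @return Named list (by `clone_id`) of integer band-size vectors.
#' @export
fingerprintClones <- function(clones, genome, enzyme = "HindIII",
                              params = SimParams(), seed = 1L) {
    if (nrow(clones) == 0L) return(stats::setNames(list(), character()))
    pat <- params@enzymes$pattern[match(enzyme, params@enzymes$name)]
    .check(!is.na(pat), paste("unknown enzyme:", enzyme))
    inserts <- Biostrings::DNAStringSet(lapply(seq_len(nrow(clones)),
        function(i) Biostrings::subseq(genome[[clones$truth_chrom[i]]],
                                       clones$truth_start[i] + 1,
                                       clones$truth_end[i])))
    names(inserts) <- clones$clone_id
    hits <- Biostrings::vmatchPattern(pat, inserts, fixed = "subject")
    withSeed(seed, {
        out <- vector("list", nrow(clones))
        names(out) <- clones$clone_id
        keep <- logical(nrow(clones))
        for (i in seq_len(nrow(clones))) {
            cuts <- BiocGenerics::start(hits[[i]]) - 1L
            sizes <- diff(c(0, sort(cuts),
                            clones$truth_end[i] - clones$truth_start[i]))
            sizes <- sizes[sizes > 0]
            if (params@sizingCV > 0)
                sizes <- sizes * rnorm(length(sizes), 1, params@sizingCV)
            sizes <- round(sizes)
            sizes <- sizes[sizes >= params@bandDetectMin]
            if (length(sizes) == 0L) {
                warning("clone ", clones$clone_id[i],
                        " yielded no detectable band; skipped")
            } else {
                out[[i]] <- as.integer(sort(sizes))
                keep[i] <- TRUE
            }
        }
        out[keep]
    })
}

#' Simulate genetic-marker screening hits
#'
#' Places SSR and RFLP markers at uniform genome positions and reports a hit
#' for every clone whose truth interval contains the marker position,
#' emulating library hybridization screening at desk scale.
#'
#' @param clones Clone table (typically the fingerprinted subset).
#' @param genome The genome markers are placed on.
#' @param nSSR,nRFLP Marker counts per type.
#' @param seed Integer seed.
#' @return data.frame with `marker_id`, `marker_type`, `clone_id` (markers
#'   hitting no clone are omitted, as in real screening result lists).
#' @export
simulateMarkerHits <- function(clones, genome, nSSR = 120, nRFLP = 30,
                               seed = 1L) {
    withSeed(seed, {
        n <- nSSR + nRFLP
        widths <- as.numeric(BiocGenerics::width(genome))
        ci <- sample.int(length(genome), n, replace = TRUE, prob = widths)
        pos <- floor(runif(n) * widths[ci])
        ids <- c(sprintf("SSR%04d", seq_len(nSSR)),
                 sprintf("RFLP%04d", seq_len(nRFLP)))
        types <- rep(c("SSR", "RFLP"), c(nSSR, nRFLP))
        hits <- lapply(seq_len(n), function(i) {
            hit <- clones$truth_chrom == names(genome)[ci[i]] &
                clones$truth_start <= pos[i] & clones$truth_end > pos[i]
            if (!any(hit)) return(NULL)
            data.frame(marker_id = ids[i], marker_type = types[i],
                       clone_id = clones$clone_id[hit],
                       stringsAsFactors = FALSE)
        })
        out <- do.call(rbind, hits)
        if (is.null(out))
            out <- data.frame(marker_id = character(),
                              marker_type = character(),
                              clone_id = character())
        rownames(out) <- NULL
        out
    })
}
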