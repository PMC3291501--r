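# Readers/writers for the pipeline's interchange formats. Internal tables
# are 0-based half-open; AGP output is 1-based inclusive per the format.

.writeTSV <- function(df, path, seed = NULL, extra = NULL) {
    con <- file(path, open = "wt")
    on.exit(close(con))
    if (!is.null(seed)) writeLines(paste0("# seed=", seed), con)
    if (!is.null(extra)) writeLines(paste0("# ", extra), con)
    # list-columns (island members etc.) are not serialized
    df <- df[, !vapply(df, is.list, logical(1)), drop = FALSE]
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

.readTSV <- function(path)
    read.table(path, sep = "\t", header = TRUE, comment.char = "#",
               stringsAsFactors = FALSE)

#' Write a genome as FASTA
#' @param genome A `DNAStringSet`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writeGenomeFasta <- function(genome, path) {
    Biostrings::writeXStringSet(genome, path)
    invisible(path)
}

#' Write BES reads as FASTA
#'
#' Read ids are `<clone_id>.F` / `<clone_id>.R`.
#' @param bes BES table from [extractBES()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writeBESFasta <- function(bes, path) {
    seqs <- Biostrings::DNAStringSet(bes$sequence)
    names(seqs) <- paste(bes$clone_id, bes$end_label, sep = ".")
    Biostrings::writeXStringSet(seqs, path)
    invisible(path)
}

#' Write clone fingerprints as TSV
#'
#' One row per clone: `clone_id` and the comma-joined integer band sizes.
#' @param fps Named list from [fingerprintClones()].
#' @param path Output file.
#' @param seed Seed recorded in the header.
#' @return `path`, invisibly.
#' @export
writeFingerprints <- function(fps, path, seed = NULL) {
    df <- data.frame(clone_id = names(fps),
                     bands = vapply(fps, paste, character(1),
                                    collapse = ","),
                     stringsAsFactors = FALSE)
    .writeTSV(df, path, seed = seed)
}

#' Read fingerprints written by [writeFingerprints()]
#' @param path Input file.
#' @return Named list of integer band vectors.
#' @export
readFingerprints <- function(path) {
    df <- .readTSV(path)
    fps <- lapply(strsplit(df$bands, ",", fixed = TRUE), as.integer)
    names(fps) <- df$clone_id
    fps
}

#' Write a gapped assembly as AGP v2.0
#'
#' Sequence stretches between gaps become `W` component lines; gaps become
#' `N`/`U` gap lines (scaffold-join and unknown-size gaps as type
#' `scaffold` with linkage, sized runs as type `contig`).
#'
#' @param genome The gapped `DNAStringSet` (lengths only are used).
#' @param gaps Gap track data.frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writeAGP <- function(genome, gaps, path) {
    con <- file(path, open = "wt")
    on.exit(close(con))
    writeLines("##agp-version\t2.0", con)
    for (ch in names(genome)) {
        len <- length(genome[[ch]])
        g <- gaps[gaps$chrom == ch, , drop = FALSE]
        g <- g[order(g$start), , drop = FALSE]
        bounds <- rbind(data.frame(s = g$start, e = g$end,
                                   cls = g$gap_class),
                        data.frame(s = len, e = len, cls = "end"))
        pos <- 0; part <- 0L; comp <- 0L
        for (i in seq_len(nrow(bounds))) {
            if (bounds$s[i] > pos) {
                part <- part + 1L; comp <- comp + 1L
                writeLines(paste(ch, pos + 1, bounds$s[i], part, "W",
                                 sprintf("%s_comp%03d", ch, comp),
                                 1, bounds$s[i] - pos, "+",
                                 sep = "\t"), con)
            }
            if (bounds$cls[i] == "end") break
            part <- part + 1L
            gl <- bounds$e[i] - bounds$s[i]
            if (bounds$cls[i] == "unknown_size") {
                writeLines(paste(ch, bounds$s[i] + 1, bounds$e[i], part,
                                 "U", 100, "scaffold", "yes", "na",
                                 sep = "\t"), con)
            } else {
                gt <- if (bounds$cls[i] == "scaffold_join") "scaffold"
                      else "contig"
                lk <- if (gt == "scaffold") "yes" else "no"
                ev <- if (gt == "scaffold") "na" else ""
                writeLines(paste(ch, bounds$s[i] + 1, bounds$e[i], part,
                                 "N", gl, gt, lk, ev, sep = "\t"), con)
            }
            pos <- bounds$e[i]
        }
    }
    invisible(path)
}

#' Read a gap track back from an AGP file
#' @param path AGP file written by [writeAGP()].
#' @return A gap track data.frame.
#' @export
readAGPGaps <- function(path) {
    ln <- readLines(path)
    ln <- ln[!startsWith(ln, "#")]
    f <- strsplit(ln, "\t", fixed = TRUE)
    rows <- Filter(function(x) x[[5]] %in% c("N", "U"), f)
    if (!length(rows))
        return(data.frame(chrom = character(), start = numeric(),
                          end = numeric(), gap_class = character()))
    gapTrack(vapply(rows, `[[`, "", 1),
             as.numeric(vapply(rows, `[[`, "", 2)) - 1,
             as.numeric(vapply(rows, `[[`, "", 3)))
}

#' Write BES hits as BED6
#'
#' Name is the read id, score 0, standard 0-based half-open BED
#' coordinates.
#' @param hits Hit table from [alignBES()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writeHitsBED <- function(hits, path) {
    df <- data.frame(hits$chrom, hits$start, hits$end, hits$read_id, 0L,
                     hits$strand)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    invisible(path)
}
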