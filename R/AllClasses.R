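#' @import methods
#' @importFrom stats rgeom rnorm runif median cor pbinom rbinom
#' @importFrom utils write.table read.table head combn
NULL

# ---------------------------------------------------------------------------
# Parameter classes
# ---------------------------------------------------------------------------

#' Default restriction enzymes for BAC library construction
#'
#' Standard recognition sites for the three cloning enzymes used throughout:
#' HindIII (AAGCTT), BstYI (RGATCY, IUPAC-degenerate) and EcoRI (GAATTC).
#'
#' @return A data.frame with columns `name` and `pattern`.
#' @export
defaultEnzymes <- function() {
    data.frame(name = c("HindIII", "BstYI", "EcoRI"),
               pattern = c("AAGCTT", "RGATCY", "GAATTC"),
               stringsAsFactors = FALSE)
}

#' @rdname SimParams
#' @export
setClass("SimParams", representation(
    enzymes = "data.frame",
    insertMin = "numeric", insertMax = "numeric", insertMean = "numeric",
    artifactSpan = "numeric",
    besLen = "numeric", besSingleEndProb = "numeric",
    partialDigestProb = "numeric", sizeSelectSD = "numeric",
    bandDetectMin = "numeric", sizingCV = "numeric",
    fingerprintedFrac = "numeric",
    seed = "numeric"))

setValidity("SimParams", function(object) {
    msg <- character()
    if (!all(c("name", "pattern") %in% names(object@enzymes)))
        msg <- c(msg, "enzymes must have columns 'name' and 'pattern'")
    if (!(object@insertMin < object@insertMean &&
          object@insertMean < object@insertMax &&
          object@insertMax < object@artifactSpan))
        msg <- c(msg, "need insertMin < insertMean < insertMax < artifactSpan")
    for (p in c("besSingleEndProb", "partialDigestProb", "fingerprintedFrac"))
        if (slot(object, p) < 0 || slot(object, p) > 1)
            msg <- c(msg, paste0(p, " must be in [0, 1]"))
    if (object@partialDigestProb == 0)
        msg <- c(msg, "partialDigestProb must be > 0")
    if (object@sizingCV < 0) msg <- c(msg, "sizingCV must be >= 0")
    if (object@besLen <= 0) msg <- c(msg, "besLen must be > 0")
    if (length(msg)) msg else TRUE
})

#' Simulation parameters for BAC library generation
#'
#' Parameters of the clone/BES/fingerprint generator. Inserts are
#' partial-digest fragments (each internal cut site retained independently
#' with `partialDigestProb`), size-selected with a Gaussian weight centred on
#' `insertMean` with standard deviation `sizeSelectSD` and accepted only
#' inside `[insertMin, insertMax]` -- the in-silico analogue of excising a
#' pulsed-field gel fraction.
#'
#' @param enzymes data.frame of enzyme `name`/`pattern` (IUPAC) pairs.
#' @param insertMin,insertMax,insertMean Clone insert size window and target
#'   mean, in bp (defaults 75, 225 and 150 kb).
#' @param artifactSpan Span above which a paired-end placement is treated as
#'   an artifact (default 1.5 Mb).
#' @param besLen Length of a BAC end sequence read, bp (default 600).
#' @param besSingleEndProb Probability that a clone yields only one usable
#'   end read (default 0.024).
#' @param partialDigestProb Per-site retention probability of the partial
#'   digest (default 0.02).
#' @param sizeSelectSD Standard deviation of the Gaussian size-selection
#'   weight, bp (default 20 kb).
#' @param bandDetectMin Smallest fingerprint fragment called as a band, bp
#'   (default 600).
#' @param sizingCV Coefficient of variation of multiplicative band-sizing
#'   noise (default 0.005).
#' @param fingerprintedFrac Fraction of library clones that are fingerprinted
#'   and hence eligible for the map / clone pool A (default 0.6).
#' @param seed Default seed recorded with the parameters.
#' @return A `SimParams` object.
#' @examples
#' sp <- SimParams()
#' sp
#' @export
SimParams <- function(enzymes = defaultEnzymes(),
                      insertMin = 75000, insertMax = 225000,
                      insertMean = 150000, artifactSpan = 1500000,
                      besLen = 600, besSingleEndProb = 0.024,
                      partialDigestProb = 0.02, sizeSelectSD = 20000,
                      bandDetectMin = 600, sizingCV = 0.005,
                      fingerprintedFrac = 0.6, seed = 1L) {
    new("SimParams", enzymes = enzymes, insertMin = insertMin,
        insertMax = insertMax, insertMean = insertMean,
        artifactSpan = artifactSpan, besLen = besLen,
        besSingleEndProb = besSingleEndProb,
        partialDigestProb = partialDigestProb, sizeSelectSD = sizeSelectSD,
        bandDetectMin = bandDetectMin, sizingCV = sizingCV,
        fingerprintedFrac = fingerprintedFrac, seed = seed)
}

#' @rdname AssemblyParams
#' @export
setClass("AssemblyParams", representation(
    tolerance = "numeric", gelSpace = "numeric", cutoff = "numeric"))

setValidity("AssemblyParams", function(object) {
    msg <- character()
    if (object@tolerance <= 0) msg <- c(msg, "tolerance must be > 0")
    if (object@gelSpace <= 2 * object@tolerance)
        msg <- c(msg, "gelSpace must exceed 2 * tolerance")
    if (object@cutoff <= 0 || object@cutoff >= 1)
        msg <- c(msg, "cutoff must be in (0, 1)")
    if (length(msg)) msg else TRUE
})

#' Fingerprint assembly parameters
#'
#' @param tolerance Band match window in bp: two bands match when their sizes
#'   differ by at most this much (default 7).
#' @param gelSpace Number of distinguishable band positions G in the
#'   coincidence-score model (default 3600).
#' @param cutoff Maximum coincidence score at which two clones are joined
#'   (default 1e-12).
#' @return An `AssemblyParams` object.
#' @export
AssemblyParams <- function(tolerance = 7, gelSpace = 3600, cutoff = 1e-12) {
    new("AssemblyParams", tolerance = tolerance, gelSpace = gelSpace,
        cutoff = cutoff)
}

#' @rdname MTPParams
#' @export
setClass("MTPParams", representation(
    insertMin = "numeric", insertMax = "numeric",
    cloneCountWeight = "numeric", edgeWindow = "numeric",
    assumedInsert = "numeric"))

setValidity("MTPParams", function(object) {
    if (object@cloneCountWeight <= object@insertMax)
        "cloneCountWeight must exceed insertMax (clone count must dominate overlap lexicographically)"
    else TRUE
})

#' Minimum-tiling-path parameters
#'
#' @param insertMin,insertMax Allowed clone span window, bp.
#' @param cloneCountWeight Per-clone weight added to each graph edge; any
#'   value above `insertMax` makes clone count lexicographically dominant
#'   over total overlap (default 1e7).
#' @param edgeWindow How close to a gap edge a single aligned end must lie
#'   for the clone to be credited into the gap, bp (default 150 kb).
#' @param assumedInsert Insert length credited to an unpaired-end clone when
#'   extending into a gap, bp (default 150 kb).
#' @return An `MTPParams` object.
#' @export
MTPParams <- function(insertMin = 75000, insertMax = 225000,
                      cloneCountWeight = 1e7, edgeWindow = 150000,
                      assumedInsert = 150000) {
    new("MTPParams", insertMin = insertMin, insertMax = insertMax,
        cloneCountWeight = cloneCountWeight, edgeWindow = edgeWindow,
        assumedInsert = assumedInsert)
}

#' @rdname AnalysisParams
#' @export
setClass("AnalysisParams", representation(
    spanMin = "numeric", spanMax = "numeric", artifactSpan = "numeric",
    expectedInsert = "numeric"))

setValidity("AnalysisParams", function(object) {
    if (!(object@spanMin < object@spanMax &&
          object@spanMax < object@artifactSpan))
        "need spanMin < spanMax < artifactSpan"
    else TRUE
})

#' Structural-difference scan parameters
#'
#' @param spanMin,spanMax Expected paired-end span window, bp (defaults 75
#'   and 225 kb). Spans outside it are insertion/deletion candidates.
#' @param artifactSpan Spans above this are excluded as artifacts (default
#'   1.5 Mb).
#' @param expectedInsert Library mean insert used as the size-estimate
#'   baseline, bp (default 150 kb).
#' @return An `AnalysisParams` object.
#' @export
AnalysisParams <- function(spanMin = 75000, spanMax = 225000,
                           artifactSpan = 1500000,
                           expectedInsert = 150000) {
    new("AnalysisParams", spanMin = spanMin, spanMax = spanMax,
        artifactSpan = artifactSpan, expectedInsert = expectedInsert)
}

# ---------------------------------------------------------------------------
# FPCMap
# ---------------------------------------------------------------------------

#' @rdname FPCMap
#' @export
setClass("FPCMap", representation(
    clones = "data.frame",    # clone_id, contig_id (NA = singleton), ord,
                              # cb_offset, nbands
    cbLength = "numeric"))    # named by contig_id

setValidity("FPCMap", function(object) {
    cl <- object@clones
    msg <- character()
    need <- c("clone_id", "contig_id", "ord", "cb_offset", "nbands")
    if (!all(need %in% names(cl)))
        return(paste("clones must have columns", paste(need, collapse = ", ")))
    if (anyDuplicated(cl$clone_id))
        msg <- c(msg, "clone_id values must be unique")
    inctg <- !is.na(cl$contig_id)
    if (any(inctg)) {
        sizes <- table(cl$contig_id[inctg])
        if (any(sizes < 2))
            msg <- c(msg, "every contig must contain at least 2 clones")
        if (!setequal(names(sizes), names(object@cbLength)))
            msg <- c(msg, "cbLength must be named by the contig ids")
        for (ctg in names(sizes)) {
            sub <- cl[inctg & cl$contig_id == ctg, ]
            sub <- sub[order(sub$ord), ]
            if (any(sub$cb_offset < 0) || is.unsorted(sub$cb_offset))
                msg <- c(msg, paste0("contig ", ctg,
                    ": offsets must be non-negative and non-decreasing"))
            if (object@cbLength[[ctg]] < max(sub$nbands))
                msg <- c(msg, paste0("contig ", ctg,
                    ": cb length below largest clone band count"))
        }
    }
    if (length(msg)) msg else TRUE
})

#' Accessors for FPCMap objects
#'
#' `contigs()` returns the per-clone contig membership table (one row per
#' clone placed in a contig, with order index and consensus-band offset),
#' `singletons()` the ids of clones that joined no contig, `cloneIds()` all
#' clone ids in the map, `nContigs()` the contig count, and `totalCB()` the
#' summed consensus-band length of all contigs.
#'
#' @param x An `FPCMap`.
#' @return See the individual descriptions.
#' @name FPCMap-accessors
#' @aliases contigs singletons cloneIds nContigs totalCB
NULL

#' @rdname FPCMap-accessors
#' @export
setGeneric("contigs", function(x) standardGeneric("contigs"))
#' @rdname FPCMap-accessors
#' @export
setGeneric("singletons", function(x) standardGeneric("singletons"))
#' @rdname FPCMap-accessors
#' @export
setGeneric("cloneIds", function(x) standardGeneric("cloneIds"))
#' @rdname FPCMap-accessors
#' @export
setGeneric("nContigs", function(x) standardGeneric("nContigs"))
#' @rdname FPCMap-accessors
#' @export
setGeneric("totalCB", function(x) standardGeneric("totalCB"))

#' @rdname FPCMap-accessors
#' @export
setMethod("contigs", "FPCMap", function(x) {
    cl <- x@clones[!is.na(x@clones$contig_id), , drop = FALSE]
    cl[order(cl$contig_id, cl$ord), , drop = FALSE]
})
#' @rdname FPCMap-accessors
#' @export
setMethod("singletons", "FPCMap", function(x)
    sort(x@clones$clone_id[is.na(x@clones$contig_id)]))
#' @rdname FPCMap-accessors
#' @export
setMethod("cloneIds", "FPCMap", function(x) x@clones$clone_id)
#' @rdname FPCMap-accessors
#' @export
setMethod("nContigs", "FPCMap", function(x) length(x@cbLength))
#' @rdname FPCMap-accessors
#' @export
setMethod("totalCB", "FPCMap", function(x) sum(x@cbLength))

setMethod("show", "FPCMap", function(object) {
    cat("FPCMap with", nContigs(object), "contigs (",
        sum(!is.na(object@clones$contig_id)), "clones ) and",
        length(singletons(object)), "singletons;",
        "total CB length", totalCB(object), "\n")
})

#' Construct an FPCMap
#'
#' Usually produced by [clusterContigs()]; the constructor is exported for
#' tests and for rebuilding maps from serialized tables.
#'
#' @param clones data.frame with columns `clone_id`, `contig_id` (NA for
#'   singletons), `ord`, `cb_offset`, `nbands`.
#' @param cbLength Named numeric of consensus-band lengths per contig.
#' @return An `FPCMap`.
#' @export
FPCMap <- function(clones, cbLength = numeric()) {
    new("FPCMap", clones = clones, cbLength = cbLength)
}

# ---------------------------------------------------------------------------
# MTPResult
# ---------------------------------------------------------------------------

#' @rdname MTPResult
#' @export
setClass("MTPResult", representation(
    path = "data.frame",      # chrom, island, ord, clone_id, span_start,
                              # span_end, library, augmented,
                              # credited_start, credited_end
    overlaps = "data.frame",  # chrom, island, left_id, right_id, overlap
    gaps = "data.frame",      # chrom, gap_start, gap_end, entered
    meta = "list"))

setValidity("MTPResult", function(object) {
    p <- object@path
    msg <- character()
    need <- c("chrom", "island", "ord", "clone_id", "span_start", "span_end",
              "library", "augmented", "credited_start", "credited_end")
    if (!all(need %in% names(p)))
        return(paste("path must have columns", paste(need, collapse = ", ")))
    core <- p[!p$augmented, , drop = FALSE]
    if (nrow(core) && any(core$span_end <= core$span_start))
        msg <- c(msg, "clone spans must have positive length")
    if (nrow(object@overlaps) && any(object@overlaps$overlap < 1))
        msg <- c(msg, "adjacent tiling clones must overlap by >= 1 bp")
    if (length(msg)) msg else TRUE
})

setMethod("show", "MTPResult", function(object) {
    p <- object@path
    cat("MTPResult:", sum(!p$augmented), "tiling clones +",
        sum(p$augmented), "gap-extending clones over",
        length(unique(p$chrom)), "chromosome(s);",
        nrow(object@gaps), "internal gap(s)\n")
})

#' Accessors for MTPResult objects
#'
#' `tilingPath()` returns the ordered clone table (augmented gap-extending
#' clones flagged in the `augmented` column), `pathOverlaps()` the adjacent
#' clone overlaps, and `mtpGaps()` the internal (inter-island) gaps left
#' uncovered on each chromosome.
#'
#' @param x An `MTPResult`.
#' @return A data.frame.
#' @name MTPResult-accessors
#' @aliases tilingPath pathOverlaps mtpGaps
NULL

#' @rdname MTPResult-accessors
#' @export
setGeneric("tilingPath", function(x) standardGeneric("tilingPath"))
#' @rdname MTPResult-accessors
#' @export
setGeneric("pathOverlaps", function(x) standardGeneric("pathOverlaps"))
#' @rdname MTPResult-accessors
#' @export
setGeneric("mtpGaps", function(x) standardGeneric("mtpGaps"))

#' @rdname MTPResult-accessors
#' @export
setMethod("tilingPath", "MTPResult", function(x) x@path)
#' @rdname MTPResult-accessors
#' @export
setMethod("pathOverlaps", "MTPResult", function(x) x@overlaps)
#' @rdname MTPResult-accessors
#' @export
setMethod("mtpGaps", "MTPResult", function(x) x@gaps)
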