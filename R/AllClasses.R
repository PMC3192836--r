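#' @import methods
#' @importFrom stats rbinom rgamma rlnorm rmultinom rnorm rpois runif
NULL

## ---------------------------------------------------------------------------
## SimConfig
## ---------------------------------------------------------------------------

#' Simulation configuration
#'
#' An S4 container holding every tunable parameter of the synthetic-data
#' generator. All downstream generators ([simulateReadStacks()],
#' [simulateExpression()], [simulateTransfection()], [simulateSnpTrack()])
#' take a \code{SimConfig} so that one object fully determines a simulated
#' study. Stage-specific child seeds are derived from \code{seed} by fixed
#' offsets (reads +101, expression +202, transfection +303 + miRNA index,
#' SNP track +404), so identical configurations give byte-identical output.
#'
#' @slot seed integer root seed for all random draws.
#' @slot nMirna number of miRNA precursors to simulate.
#' @slot nGenes size of the target-gene universe.
#' @slot nSpecies number of species; the first three are named
#'   \code{"human"}, \code{"chimpanzee"}, \code{"macaque"}.
#' @slot nReplicates technical sequencing replicates per species.
#' @slot depth expected total mapped reads per sample.
#' @slot deFraction fraction of miRNA implanted as differentially expressed.
#' @slot deFold multiplicative fold applied to an implanted miRNA in its
#'   up-species (must exceed 1).
#' @slot targetDensity expected number of true target genes per miRNA.
#' @slot targetEffect log2 down-shift applied to true targets in the species
#'   where the targeting miRNA is up (and after transfection of that miRNA).
#' @slot nbDispersion negative-binomial dispersion of the gamma-Poisson count
#'   model; the small default models technical replication of pooled
#'   libraries.
#' @slot noiseSd Gaussian noise s.d. (log2) for expression and transfection
#'   matrices.
#' @slot mockNoiseSd per-mock-replicate measurement noise s.d. (log2) in the
#'   transfection generator.
#' @slot phyloSd s.d. of the phylogenetic drift component on log2 miRNA
#'   expression (0 disables it; see the vignette).
#' @slot snpRegionLength length (bp) of the upstream region simulated per
#'   precursor.
#' @slot snpDensity expected SNPs per bp in the simulated regions.
#' @slot snpBackground genome-background fraction of SNPs classified as
#'   human-derived.
#' @slot genomeSnpTotal number of genome-wide SNPs behind the genome totals.
#' @slot sweepWindows data.frame with columns \code{start}, \code{end},
#'   \code{excess} (and optionally \code{mirna_id}): intervals, in
#'   region-relative coordinates, where the derived fraction is raised by
#'   \code{excess}. Windows without \code{mirna_id} apply to the first locus
#'   passed to [simulateSnpTrack()].
#' @slot nIndividualsMrna individuals per species in the mRNA matrix.
#' @slot nIndividualsProtein individuals per species in the protein matrix.
#'
#' @seealso [simConfig()] for the validated constructor.
#' @exportClass SimConfig
setClass("SimConfig",
    representation(
        seed = "integer",
        nMirna = "integer",
        nGenes = "integer",
        nSpecies = "integer",
        nReplicates = "integer",
        depth = "numeric",
        deFraction = "numeric",
        deFold = "numeric",
        targetDensity = "numeric",
        targetEffect = "numeric",
        nbDispersion = "numeric",
        noiseSd = "numeric",
        mockNoiseSd = "numeric",
        phyloSd = "numeric",
        snpRegionLength = "integer",
        snpDensity = "numeric",
        snpBackground = "numeric",
        genomeSnpTotal = "numeric",
        sweepWindows = "data.frame",
        nIndividualsMrna = "integer",
        nIndividualsProtein = "integer"
    )
)

setValidity("SimConfig", function(object) {
    bad <- function(field, why) sprintf("invalid '%s': %s", field, why)
    msgs <- character(0)
    for (f in c("nMirna", "nGenes", "nSpecies", "nReplicates",
                "nIndividualsMrna", "nIndividualsProtein"))
        if (slot(object, f) < 1L) msgs <- c(msgs, bad(f, "must be >= 1"))
    if (object@depth <= 0) msgs <- c(msgs, bad("depth", "must be > 0"))
    if (object@deFraction < 0 || object@deFraction > 1)
        msgs <- c(msgs, bad("deFraction", "must be in [0, 1]"))
    if (object@deFold <= 1) msgs <- c(msgs, bad("deFold", "must be > 1"))
    if (object@nbDispersion <= 0)
        msgs <- c(msgs, bad("nbDispersion", "must be > 0"))
    if (object@targetDensity < 0)
        msgs <- c(msgs, bad("targetDensity", "must be >= 0"))
    for (f in c("noiseSd", "mockNoiseSd", "phyloSd", "snpDensity",
                "genomeSnpTotal"))
        if (slot(object, f) < 0) msgs <- c(msgs, bad(f, "must be >= 0"))
    if (object@snpBackground < 0 || object@snpBackground > 1)
        msgs <- c(msgs, bad("snpBackground", "must be in [0, 1]"))
    if (object@snpRegionLength < 1L)
        msgs <- c(msgs, bad("snpRegionLength", "must be >= 1"))
    sw <- object@sweepWindows
    if (nrow(sw)) {
        if (!all(c("start", "end", "excess") %in% names(sw)))
            msgs <- c(msgs, bad("sweepWindows",
                "needs columns start, end, excess"))
        else {
            if (any(sw$end <= sw$start))
                msgs <- c(msgs, bad("sweepWindows", "end must exceed start"))
            if (any(sw$start < 0) ||
                any(sw$end > object@snpRegionLength))
                msgs <- c(msgs, bad("sweepWindows",
                    "intervals must lie within the simulated region"))
            if (any(sw$excess < 0) ||
                any(sw$excess + object@snpBackground > 1))
                msgs <- c(msgs, bad("sweepWindows",
                    "excess + snpBackground must stay within [0, 1]"))
            grp <- if ("mirna_id" %in% names(sw)) sw$mirna_id else
                rep("", nrow(sw))
            for (g in unique(grp)) {
                w <- sw[grp == g, , drop = FALSE]
                if (nrow(w) > 1L) {
                    o <- order(w$start)
                    if (any(w$start[o][-1L] < w$end[o][-nrow(w)]))
                        msgs <- c(msgs, bad("sweepWindows",
                            "truth windows must not overlap"))
                }
            }
        }
    }
    if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Build a validated simulation configuration
#'
#' @param seed integer root seed.
#' @param nMirna,nGenes,nSpecies,nReplicates counts (see the class
#'   documentation for [SimConfig-class]).
#' @param depth expected total reads per sample.
#' @param deFraction,deFold implanted differential-expression fraction and
#'   fold.
#' @param targetDensity,targetEffect expected true targets per miRNA and the
#'   log2 shift applied to them.
#' @param nbDispersion negative-binomial dispersion.
#' @param noiseSd,mockNoiseSd,phyloSd Gaussian noise and drift parameters.
#' @param snpRegionLength,snpDensity,snpBackground,genomeSnpTotal SNP-track
#'   parameters.
#' @param sweepWindows data.frame of implanted derived-excess intervals.
#' @param nIndividualsMrna,nIndividualsProtein per-species sample sizes of
#'   the expression matrices.
#' @return A validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(seed = 1, nMirna = 50, deFraction = 0.1)
#' cfg
#' @export
simConfig <- function(seed = 1L, nMirna = 200L, nGenes = 2000L,
                      nSpecies = 3L, nReplicates = 2L, depth = 1e5,
                      deFraction = 0.1, deFold = 4, targetDensity = 20,
                      targetEffect = 1, nbDispersion = 1e-4,
                      noiseSd = 0.2, mockNoiseSd = 0.05, phyloSd = 0,
                      snpRegionLength = 150000L, snpDensity = 0.005,
                      snpBackground = 0.05, genomeSnpTotal = 1e6,
                      sweepWindows = data.frame(start = numeric(0),
                                                end = numeric(0),
                                                excess = numeric(0)),
                      nIndividualsMrna = 5L, nIndividualsProtein = 4L) {
    new("SimConfig",
        seed = as.integer(seed), nMirna = as.integer(nMirna),
        nGenes = as.integer(nGenes), nSpecies = as.integer(nSpecies),
        nReplicates = as.integer(nReplicates), depth = depth,
        deFraction = deFraction, deFold = deFold,
        targetDensity = targetDensity, targetEffect = targetEffect,
        nbDispersion = nbDispersion, noiseSd = noiseSd,
        mockNoiseSd = mockNoiseSd, phyloSd = phyloSd,
        snpRegionLength = as.integer(snpRegionLength),
        snpDensity = snpDensity, snpBackground = snpBackground,
        genomeSnpTotal = genomeSnpTotal, sweepWindows = sweepWindows,
        nIndividualsMrna = as.integer(nIndividualsMrna),
        nIndividualsProtein = as.integer(nIndividualsProtein))
}

#' @describeIn simConfig compact display.
#' @param object a \code{SimConfig}.
#' @export
setMethod("show", "SimConfig", function(object) {
    cat("SimConfig (seed ", object@seed, ")\n", sep = "")
    cat("  ", object@nMirna, " miRNA x ", object@nSpecies, " species x ",
        object@nReplicates, " replicates, depth ",
        format(object@depth, big.mark = ","), "\n", sep = "")
    cat("  DE implant: fraction ", object@deFraction, ", fold ",
        object@deFold, "; target effect ", object@targetEffect,
        " on ~", object@targetDensity, " genes/miRNA\n", sep = "")
    cat("  NB dispersion ", object@nbDispersion, ", noise sd ",
        object@noiseSd, ", phylo drift sd ", object@phyloSd, "\n", sep = "")
    cat("  SNP track: ", object@snpRegionLength, " bp/region, density ",
        object@snpDensity, ", background ", object@snpBackground, ", ",
        nrow(object@sweepWindows), " sweep window(s)\n", sep = "")
})

## ---------------------------------------------------------------------------
## GroundTruth
## ---------------------------------------------------------------------------

#' Ground truth of a simulated study
#'
#' Records what the generator implanted, so recovery and calibration can be
#' scored downstream.
#'
#' @slot deMirna data.frame with columns \code{mirna_id}, \code{up_species}.
#' @slot targetMap named list: miRNA id to character vector of true target
#'   gene ids.
#' @slot sweepWindows data.frame of implanted derived-excess intervals
#'   (region-relative coordinates).
#' @exportClass GroundTruth
setClass("GroundTruth",
    representation(deMirna = "data.frame", targetMap = "list",
                   sweepWindows = "data.frame"))

#' @describeIn GroundTruth-class constructor.
#' @param deMirna,targetMap,sweepWindows see slots.
#' @export
GroundTruth <- function(deMirna = data.frame(mirna_id = character(0),
                                             up_species = character(0)),
                        targetMap = list(),
                        sweepWindows = data.frame(start = numeric(0),
                                                  end = numeric(0),
                                                  excess = numeric(0))) {
    new("GroundTruth", deMirna = deMirna, targetMap = targetMap,
        sweepWindows = sweepWindows)
}

#' @describeIn GroundTruth-class implanted DE miRNA table.
#' @param x a \code{GroundTruth}.
#' @export
setGeneric("deMirna", function(x) standardGeneric("deMirna"))

#' @rdname GroundTruth-class
#' @export
setMethod("deMirna", "GroundTruth", function(x) x@deMirna)

#' @describeIn GroundTruth-class true miRNA-to-target map.
#' @export
setGeneric("targetMap", function(x) standardGeneric("targetMap"))

#' @rdname GroundTruth-class
#' @export
setMethod("targetMap", "GroundTruth", function(x) x@targetMap)

#' @describeIn GroundTruth-class implanted sweep windows.
#' @export
setGeneric("sweepWindows", function(x) standardGeneric("sweepWindows"))

#' @rdname GroundTruth-class
#' @export
setMethod("sweepWindows", "GroundTruth", function(x) x@sweepWindows)

#' @rdname GroundTruth-class
#' @param object a \code{GroundTruth}.
#' @export
setMethod("show", "GroundTruth", function(object) {
    cat("GroundTruth: ", nrow(object@deMirna), " implanted DE miRNA, ",
        length(object@targetMap), " miRNA with target sets, ",
        nrow(object@sweepWindows), " sweep window(s)\n", sep = "")
})

## ---------------------------------------------------------------------------
## ReadStack
## ---------------------------------------------------------------------------

#' A per-sample stack of aligned small-RNA reads
#'
#' Distinct small-RNA sequences with their genomic 5' positions and copy
#' numbers, as produced by collapsing perfectly mapped reads of one sample.
#' Coordinates are 0-based; \code{pos0} is the genomic coordinate of the
#' read's 5' end (on the minus strand this is the higher genomic coordinate).
#'
#' @slot sampleId sample label.
#' @slot records data.frame with columns \code{sequence} (18-28 nt over
#'   ACGT/ACGU), \code{chrom}, \code{pos0}, \code{strand}, \code{copies}.
#' @exportClass ReadStack
setClass("ReadStack",
    representation(sampleId = "character", records = "data.frame"))

setValidity("ReadStack", function(object) {
    r <- object@records
    need <- c("sequence", "chrom", "pos0", "strand", "copies")
    if (!all(need %in% names(r)))
        return(paste("records must have columns",
                     paste(need, collapse = ", ")))
    if (nrow(r)) {
        len <- nchar(r$sequence)
        if (any(len < 18L | len > 28L))
            return("read sequences must be 18-28 nt")
        if (any(grepl("[^ACGTUacgtu]", r$sequence)))
            return("read sequences must be over ACGT/ACGU")
        if (any(r$copies < 1L))
            return("copies must be >= 1")
        if (!all(r$strand %in% c("+", "-")))
            return("strand must be '+' or '-'")
    }
    TRUE
})

#' @describeIn ReadStack-class constructor.
#' @param sampleId,records see slots.
#' @export
ReadStack <- function(sampleId, records) {
    rownames(records) <- NULL
    ## canonical storage types so that round-trips are exact
    records$pos0 <- as.integer(records$pos0)
    records$copies <- as.integer(records$copies)
    new("ReadStack", sampleId = sampleId, records = records)
}

#' @describeIn ReadStack-class sample label.
#' @param x a \code{ReadStack}.
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @rdname ReadStack-class
#' @export
setMethod("sampleId", "ReadStack", function(x) x@sampleId)

#' @describeIn ReadStack-class read records.
#' @export
setGeneric("readRecords", function(x) standardGeneric("readRecords"))

#' @rdname ReadStack-class
#' @export
setMethod("readRecords", "ReadStack", function(x) x@records)

#' @rdname ReadStack-class
#' @param object a \code{ReadStack}.
#' @export
setMethod("show", "ReadStack", function(object) {
    cat("ReadStack '", object@sampleId, "': ", nrow(object@records),
        " distinct sequences, ", sum(object@records$copies),
        " total copies\n", sep = "")
})

## ---------------------------------------------------------------------------
## MirnaLoci
## ---------------------------------------------------------------------------

#' Annotated miRNA precursor loci
#'
#' One row per (miRNA, species): precursor sequence, mature arm coordinates
#' in precursor space (0-based half-open) and the genomic anchor of the
#' precursor. The mature 5' genomic position is derived strand-aware: on the
#' plus strand it is \code{precursor_start0 + mature_start0}; on the minus
#' strand it is \code{precursor_start0 + L - mature_start0 - 1} where
#' \code{L} is the precursor length.
#'
#' @slot table data.frame with columns \code{mirna_id}, \code{precursor_id},
#'   \code{species}, \code{precursor_seq}, \code{arm}, \code{mature_start0},
#'   \code{mature_end0}, \code{chrom}, \code{strand},
#'   \code{precursor_start0}.
#' @exportClass MirnaLoci
setClass("MirnaLoci", representation(table = "data.frame"))

setValidity("MirnaLoci", function(object) {
    t <- object@table
    need <- c("mirna_id", "precursor_id", "species", "precursor_seq", "arm",
              "mature_start0", "mature_end0", "chrom", "strand",
              "precursor_start0")
    if (!all(need %in% names(t)))
        return(paste("table must have columns",
                     paste(need, collapse = ", ")))
    if (nrow(t)) {
        if (any(t$mature_start0 < 0L) ||
            any(t$mature_end0 <= t$mature_start0) ||
            any(t$mature_end0 > nchar(t$precursor_seq)))
            return("mature interval must satisfy 0 <= start < end <= length(precursor)")
        if (!all(t$arm %in% c("5p", "3p")))
            return("arm must be '5p' or '3p'")
        if (!all(t$strand %in% c("+", "-")))
            return("strand must be '+' or '-'")
    }
    TRUE
})

#' @describeIn MirnaLoci-class constructor.
#' @param table see slot.
#' @export
MirnaLoci <- function(table) {
    rownames(table) <- NULL
    new("MirnaLoci", table = table)
}

#' @describeIn MirnaLoci-class underlying annotation table.
#' @param x a \code{MirnaLoci}.
#' @export
setGeneric("lociTable", function(x) standardGeneric("lociTable"))

#' @rdname MirnaLoci-class
#' @export
setMethod("lociTable", "MirnaLoci", function(x) x@table)

#' @rdname MirnaLoci-class
#' @export
setMethod("length", "MirnaLoci", function(x) nrow(x@table))

#' @rdname MirnaLoci-class
#' @param i row index.
#' @param j,drop ignored.
#' @param ... ignored.
#' @export
setMethod("[", "MirnaLoci", function(x, i, j, ..., drop = FALSE) {
    MirnaLoci(x@table[i, , drop = FALSE])
})

#' @rdname MirnaLoci-class
#' @param object a \code{MirnaLoci}.
#' @export
setMethod("show", "MirnaLoci", function(object) {
    cat("MirnaLoci: ", nrow(object@table), " loci (",
        length(unique(object@table$mirna_id)), " miRNA, ",
        length(unique(object@table$species)), " species)\n", sep = "")
})

## strand-aware genomic 5' position of the annotated mature, one locus row
mature5prime <- function(locusRow) {
    L <- nchar(locusRow$precursor_seq)
    if (locusRow$strand == "+")
        locusRow$precursor_start0 + locusRow$mature_start0
    else
        locusRow$precursor_start0 + L - locusRow$mature_start0 - 1L
}
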