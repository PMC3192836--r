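## 5'-anchored miRNA quantification from read stacks.

#' Quantify one miRNA in one read stack
#'
#' Implements 5'-anchored quantification: reads whose genomic 5' position
#' lies within 3 nt (inclusive) of the annotated mature 5' position are
#' retained; the retained sequence with the maximal copy number becomes the
#' reference sequence (ties broken by the lexicographically smallest
#' sequence); the miRNA's expression is the summed copy number of the
#' reference and of all other retained sequences sharing the reference's 5'
#' position. Records on the wrong strand are skipped and counted in the
#' \code{"skipped_strand"} attribute of the result.
#'
#' @param stack a [ReadStack-class].
#' @param locus a single-row [MirnaLoci-class] (or its table row).
#' @param window maximal absolute 5' offset retained (default 3 nt).
#' @return list with \code{mirna_id}, \code{sample_id}, \code{count},
#'   \code{reference_sequence} (empty string when nothing is retained).
#' @examples
#' loc <- MirnaLoci(data.frame(
#'     mirna_id = "mir-1", precursor_id = "mir-1-pre", species = "human",
#'     precursor_seq = strrep("ACGT", 20), arm = "5p",
#'     mature_start0 = 10, mature_end0 = 32, chrom = "chr1", strand = "+",
#'     precursor_start0 = 1000))
#' st <- ReadStack("s1", data.frame(
#'     sequence = strrep("ACGU", 5), chrom = "chr1", pos0 = 1010,
#'     strand = "+", copies = 12))
#' quantifyMirna(st, loc)$count
#' @export
quantifyMirna <- function(stack, locus, window = 3L) {
    row <- if (is(locus, "MirnaLoci")) {
        stopifnot(length(locus) == 1L)
        lociTable(locus)[1L, ]
    } else locus
    rec <- readRecords(stack)
    rec <- rec[rec$chrom == row$chrom, , drop = FALSE]
    skipped <- sum(rec$strand != row$strand)
    if (skipped > 0)
        warning(skipped, " record(s) skipped: strand mismatch at ",
                row$mirna_id)
    rec <- rec[rec$strand == row$strand, , drop = FALSE]
    g5 <- mature5prime(row)
    off <- if (row$strand == "+") rec$pos0 - g5 else g5 - rec$pos0
    rec <- rec[abs(off) <= window, , drop = FALSE]
    if (!nrow(rec)) {
        res <- list(mirna_id = row$mirna_id, sample_id = sampleId(stack),
                    count = 0L, reference_sequence = "")
        attr(res, "skipped_strand") <- skipped
        return(res)
    }
    ## collapse duplicate (sequence, pos0) rows before picking the reference
    key <- paste(rec$sequence, rec$pos0)
    copies <- tapply(rec$copies, key, sum)
    seqs <- sub(" .*$", "", names(copies))
    pos <- as.integer(sub("^.* ", "", names(copies)))
    best <- which(copies == max(copies))
    if (length(best) > 1L) best <- best[order(seqs[best])][1L]
    refPos <- pos[best]
    cnt <- sum(copies[pos == refPos])
    res <- list(mirna_id = row$mirna_id, sample_id = sampleId(stack),
                count = as.integer(cnt),
                reference_sequence = seqs[best])
    attr(res, "skipped_strand") <- skipped
    res
}

#' Quantify a full annotation set across samples
#'
#' Applies [quantifyMirna()] to every (miRNA, sample) pair, matching each
#' stack to the loci of its species (sample ids are expected to be
#' \code{"<species>_rep<k>"}, as produced by [simulateReadStacks()], or a
#' \code{species} vector can be supplied).
#'
#' @param stacks list of [ReadStack-class].
#' @param loci a [MirnaLoci-class].
#' @param species optional character vector giving each stack's species;
#'   defaults to the sample-id prefix before \code{"_rep"}.
#' @return a \code{SummarizedExperiment} with integer assay \code{"counts"}
#'   (miRNA x samples) and colData columns \code{species},
#'   \code{replicate}.
#' @export
quantifyAll <- function(stacks, loci, species = NULL) {
    tab <- lociTable(loci)
    sids <- vapply(stacks, sampleId, "")
    if (is.null(species)) species <- sub("_rep.*$", "", sids)
    ids <- unique(tab$mirna_id)
    m <- matrix(0L, length(ids), length(stacks),
                dimnames = list(ids, sids))
    for (j in seq_along(stacks)) {
        sub <- tab[tab$species == species[j], , drop = FALSE]
        for (i in seq_len(nrow(sub))) {
            q <- quantifyMirna(stacks[[j]], sub[i, ])
            m[q$mirna_id, j] <- q$count
        }
    }
    SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = m),
        colData = S4Vectors::DataFrame(
            species = species,
            replicate = sub("^.*_rep", "", sids),
            row.names = sids))
}

#' Detect a novel star-arm miRNA candidate
#'
#' Given reads mapping to the arm opposite an annotated mature miRNA, the
#' sequence with the maximal copy number is the star candidate. It is
#' accepted only if at least \code{minSeparation} nucleotides separate the
#' annotated mature interval and the candidate interval on the precursor
#' (linear gap length in precursor coordinates). Accepted candidates are
#' quantified with the same 5'-anchored semantics as known miRNA.
#'
#' @param locus a single-row [MirnaLoci-class].
#' @param oppositeArmRecords data.frame with columns \code{sequence},
#'   \code{pos0} (genomic 5' position), \code{copies} (and optionally
#'   \code{chrom}, \code{strand}).
#' @param minSeparation minimal gap, in nt, between mature and candidate
#'   (default 14).
#' @return \code{NULL} when there is no acceptable candidate, else a list
#'   with \code{sequence}, \code{position} (genomic 5'), \code{copies} and
#'   \code{separation}.
#' @export
detectNovelStar <- function(locus, oppositeArmRecords, minSeparation = 14L) {
    row <- if (is(locus, "MirnaLoci")) lociTable(locus)[1L, ] else locus
    rec <- oppositeArmRecords
    if (is.null(rec) || !nrow(rec)) return(NULL)
    best <- which(rec$copies == max(rec$copies))
    if (length(best) > 1L) best <- best[order(rec$sequence[best])][1L]
    cand <- rec[best, ]
    ## candidate interval in precursor coordinates
    relStart <- if (row$strand == "+") cand$pos0 - row$precursor_start0
        else row$precursor_start0 + nchar(row$precursor_seq) - 1L - cand$pos0
    relEnd <- relStart + nchar(cand$sequence)
    gap <- if (relStart >= row$mature_end0) relStart - row$mature_end0
        else if (relEnd <= row$mature_start0) row$mature_start0 - relEnd
        else 0L
    if (gap < minSeparation) return(NULL)
    list(sequence = cand$sequence, position = cand$pos0,
         copies = cand$copies, separation = as.integer(gap))
}

#' Detection filter on read support
#'
#' A miRNA counts as detected when it is covered by at least
#' \code{threshold} sequence reads (default 10).
#'
#' @param count non-negative read count (vectorized).
#' @param threshold detection threshold.
#' @return logical vector.
#' @examples
#' isDetected(c(0, 9, 10, 500))
#' @export
isDetected <- function(count, threshold = 10L) {
    if (any(count < 0)) stop("count must be non-negative")
    count >= threshold
}
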