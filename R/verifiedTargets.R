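## Experimentally verified miRNA targets from transfection experiments,
## human-specific expression classification, and lineage-level inhibition.

## per-cell-line effect: mean over the mock comparisons
effectPerCellLine <- function(effects) {
    vapply(effects, rowMeans, numeric(nrow(effects[[1L]])))
}

#' Proportion-based FDR of a transfection inhibition cutoff
#'
#' A gene passes the cutoff when its transfection effect (log2 mimic minus
#' log2 mock, averaged over mock replicates) is at most \code{cutoff} in
#' every cell line. The FDR of calling predicted targets verified at that
#' cutoff is the fraction of non-target genes passing divided by the
#' fraction of predicted target genes passing (default
#' \code{denominator = "passing"}); the alternative reading divides by the
#' fraction of predicted targets present in the expression data.
#'
#' @param effects named list of matrices (genes x mock replicates), one per
#'   cell line, as from [simulateTransfection()].
#' @param targets character vector of predicted target gene ids.
#' @param cutoff inhibition cutoff, <= 0.
#' @param denominator \code{"passing"} or \code{"expressed"}.
#' @return the FDR (NA when no target passes under \code{"passing"}).
#' @export
transfectionFdr <- function(effects, targets, cutoff,
                            denominator = c("passing", "expressed")) {
    denominator <- match.arg(denominator)
    if (cutoff > 0) stop("inhibition cutoff must be <= 0")
    if (!length(targets)) stop("empty target set")
    e <- effectPerCellLine(effects)
    genes <- rownames(effects[[1L]])
    isTarget <- genes %in% targets
    if (!any(isTarget)) stop("no predicted target is present in the data")
    pass <- rowSums(e <= cutoff) == ncol(e)
    fracNon <- mean(pass[!isTarget])
    fracTar <- mean(pass[isTarget])
    if (denominator == "passing") {
        if (fracTar == 0) return(NA_real_)
        fracNon / fracTar
    } else {
        ## fraction of predicted targets present in the expression data
        fracNon / (sum(isTarget) / length(unique(targets)))
    }
}

#' Verified target union across prediction algorithms
#'
#' For each algorithm, inhibition cutoffs are scanned from 0 down to
#' \code{maxCutoff} in steps of \code{step}; the loosest cutoff whose FDR
#' (see [transfectionFdr()]) falls below the per-miRNA threshold is
#' selected, and the algorithm contributes the predicted targets passing
#' that cutoff in both cell lines. The verified set is the union over
#' algorithms. Per-miRNA FDR thresholds can be overridden (e.g. a weakly
#' inhibiting miRNA may need a looser threshold).
#'
#' @param targetMaps named list (algorithm) of named lists (miRNA id) of
#'   predicted target gene vectors.
#' @param effects transfection effects for \code{mirnaId} (list of per-cell
#'   line matrices).
#' @param mirnaId the transfected miRNA.
#' @param fdrCutoff default FDR threshold (0.10).
#' @param overrides named numeric vector of per-miRNA thresholds.
#' @param maxCutoff,step cutoff scan grid (defaults 0 to -2 by 0.05).
#' @return list with \code{mirna_id}, \code{genes}, \code{fdr_cutoff},
#'   \code{algorithms} (contributing algorithms with their selected
#'   cutoffs); empty gene set with attribute \code{"no_algorithm"} when no
#'   algorithm achieves the FDR.
#' @export
verifiedUnion <- function(targetMaps, effects, mirnaId, fdrCutoff = 0.10,
                          overrides = numeric(0), maxCutoff = -2,
                          step = 0.05) {
    thr <- if (mirnaId %in% names(overrides)) overrides[[mirnaId]]
        else fdrCutoff
    grid <- seq(0, maxCutoff, by = -step)
    e <- effectPerCellLine(effects)
    genes <- rownames(effects[[1L]])
    verified <- character(0)
    algs <- list()
    for (alg in names(targetMaps)) {
        targets <- targetMaps[[alg]][[mirnaId]]
        if (is.null(targets) || !length(targets)) next
        sel <- NA_real_
        for (cut in grid) {
            f <- transfectionFdr(effects, targets, cut)
            if (!is.na(f) && f < thr) { sel <- cut; break }
        }
        if (is.na(sel)) next
        pass <- genes[rowSums(e <= sel) == ncol(e)]
        verified <- union(verified, intersect(pass, targets))
        algs[[alg]] <- sel
    }
    out <- list(mirna_id = mirnaId, genes = verified, fdr_cutoff = thr,
                algorithms = algs)
    if (!length(algs)) attr(out, "no_algorithm") <- TRUE
    out
}

#' Classify human-specific expression using the macaque outgroup
#'
#' A gene has human-specific expression when its human-macaque distance is
#' strictly greater than its chimpanzee-macaque distance.
#'
#' @param exprH,exprC,exprM expression levels (vectorized).
#' @return logical vector.
#' @examples
#' classifyHumanSpecific(5, 3, 3)  # TRUE
#' @export
classifyHumanSpecific <- function(exprH, exprC, exprM) {
    if (any(is.na(exprM))) stop("macaque expression is required")
    abs(exprH - exprM) > abs(exprC - exprM)
}

#' Lineage-level inhibition test on verified targets
#'
#' Partitions a verified target set into human-specific and remaining
#' genes, computes the inhibition ratio (genes with divergence direction
#' opposite the miRNA's, over genes without) in each partition, and tests
#' the difference with a two-sided Fisher's exact test.
#'
#' @param verifiedGenes character vector of verified target gene ids.
#' @param geneDirection named sign vector (+1 = higher in human) of
#'   expression divergence per gene.
#' @param mirnaDirection +1 when the miRNA is higher in human, -1 otherwise.
#' @param humanSpecific named logical vector (per gene) from
#'   [classifyHumanSpecific()].
#' @return list with \code{ratio_hs}, \code{ratio_rest}, \code{fisher_p}
#'   and the underlying 2x2 counts; an empty partition yields NA entries
#'   with attribute \code{"empty_partition"}.
#' @export
lineageInhibitionTest <- function(verifiedGenes, geneDirection,
                                  mirnaDirection, humanSpecific) {
    g <- intersect(verifiedGenes, names(geneDirection))
    hs <- g[humanSpecific[g]]
    rest <- setdiff(g, hs)
    if (!length(hs) || !length(rest)) {
        out <- list(ratio_hs = NA_real_, ratio_rest = NA_real_,
                    fisher_p = NA_real_)
        attr(out, "empty_partition") <- TRUE
        return(out)
    }
    inv <- function(set) sum(geneDirection[set] == -mirnaDirection)
    hsInv <- inv(hs); restInv <- inv(rest)
    list(ratio_hs = inhibitionRatio(hsInv, length(hs) - hsInv),
         ratio_rest = inhibitionRatio(restInv, length(rest) - restInv),
         fisher_p = fisherEnrichment(hsInv, length(hs) - hsInv,
                                     restInv, length(rest) - restInv),
         counts = c(hs_inverse = hsInv, hs_other = length(hs) - hsInv,
                    rest_inverse = restInv,
                    rest_other = length(rest) - restInv))
}
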