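## Sliding-window scan for a local excess of human-derived SNPs upstream of
## miRNA precursors, with a feature-anchored permutation null.

#' Classify a SNP as human-derived
#'
#' A SNP is human-derived when at least four of the six modern human
#' genomes carry the derived allele and all observed Neanderthal alleles
#' are ancestral.
#'
#' @param derivedCount integer 0-6, number of modern genomes with the
#'   derived allele (vectorized).
#' @param neaAncestral logical, all Neanderthal alleles ancestral.
#' @return logical vector.
#' @examples
#' classifyDerived(c(3, 4, 6), c(TRUE, TRUE, FALSE))
#' @export
classifyDerived <- function(derivedCount, neaAncestral) {
    stopifnot(all(derivedCount >= 0 & derivedCount <= 6))
    derivedCount >= 4L & neaAncestral
}

#' Sliding windows over a region
#'
#' Half-open windows \code{[s, s + win)} for
#' \code{s = start, start + step, ...} while \code{s + win <= end}.
#'
#' @param start0,end0 region bounds, 0-based half-open.
#' @param win,step window size and step in bp (defaults 50 kb / 10 kb).
#' @return an \code{IRanges} of windows (in 0-based start coordinates via
#'   \code{start(x) - 1}); empty with attribute \code{"short_region"} when
#'   the region is shorter than one window.
#' @export
makeWindows <- function(start0, end0, win = 50000L, step = 10000L) {
    if (end0 - start0 < win) {
        out <- IRanges::IRanges()
        attr(out, "short_region") <- TRUE
        return(out)
    }
    starts <- seq(start0, end0 - win, by = step)
    IRanges::IRanges(start = starts + 1L, width = win)
}

#' One-sided Fisher test of derived-SNP excess in a window
#'
#' Tests overrepresentation of human-derived SNPs in a window against the
#' genome average on the 2x2 table (window, genome) x (derived, other).
#' By default genome totals include the window's own SNPs; set
#' \code{excludeWindow = TRUE} to subtract them. A window with no SNPs has
#' p = 1 by convention.
#'
#' @param nDerivedW,nOtherW window counts.
#' @param nDerivedG,nOtherG genome totals.
#' @param excludeWindow subtract the window counts from the totals first.
#' @param twoSided use the two-sided test instead.
#' @return p-value.
#' @export
windowFisher <- function(nDerivedW, nOtherW, nDerivedG, nOtherG,
                         excludeWindow = FALSE, twoSided = FALSE) {
    if (nDerivedW + nOtherW == 0) return(1)
    if (excludeWindow) {
        nDerivedG <- nDerivedG - nDerivedW
        nOtherG <- nOtherG - nOtherW
    }
    stats::fisher.test(
        matrix(c(nDerivedW, nOtherW, nDerivedG, nOtherG), nrow = 2,
               byrow = TRUE),
        alternative = if (twoSided) "two.sided" else "greater")$p.value
}

#' Scan the upstream regions of a miRNA set for derived-SNP excess
#'
#' For each precursor, the \code{upstream} bp 5' of the precursor
#' (strand-aware) are tiled into sliding windows; each window's
#' derived/other SNP counts are tested against the genome totals with
#' [windowFisher()], and Bonferroni correction is applied across all
#' windows tested in the scan (all miRNA together).
#'
#' @param loci a [MirnaLoci-class] of the precursors to scan (e.g. the
#'   miRNA with human-specific expression).
#' @param snps \code{GRanges} with metadata columns \code{derived_count}
#'   and \code{nea_ancestral} (as from [simulateSnpTrack()] or
#'   [readSnpBed()]).
#' @param genomeTotals named numeric \code{c(derived = , other = )}.
#' @param win,step,upstream scan geometry (defaults 50 kb, 10 kb, 150 kb).
#' @param alpha family-wise significance level after Bonferroni (0.05).
#' @param ... passed to [windowFisher()].
#' @return list with \code{windows} (data.frame: mirna_id, start0, end0,
#'   n_derived, n_other, fisher_p, bonferroni_significant),
#'   \code{n_windows_tested}, and \code{n_significant} (the scan statistic:
#'   Bonferroni-significant windows over the whole set).
#' @export
scanMirnaSet <- function(loci, snps, genomeTotals, win = 50000L,
                         step = 10000L, upstream = 150000L, alpha = 0.05,
                         ...) {
    tab <- lociTable(loci)
    der <- classifyDerived(snps$derived_count, snps$nea_ancestral)
    rows <- list()
    truncated <- character(0)
    for (i in seq_len(nrow(tab))) {
        row <- tab[i, ]
        reg <- upstreamRegion(row, upstream)
        if (reg[2] - reg[1] < upstream)
            truncated <- c(truncated, row$mirna_id)
        wins <- makeWindows(reg[1], reg[2], win, step)
        if (!length(wins)) next
        gr <- GenomicRanges::GRanges(row$chrom, wins)
        onChrom <- as.character(GenomicRanges::seqnames(snps)) == row$chrom
        ov <- GenomicRanges::findOverlaps(gr, snps[onChrom])
        dHit <- der[onChrom][S4Vectors::subjectHits(ov)]
        wIdx <- S4Vectors::queryHits(ov)
        nd <- vapply(seq_along(wins), function(w)
            sum(dHit[wIdx == w]), 1L)
        no <- vapply(seq_along(wins), function(w)
            sum(!dHit[wIdx == w]), 1L)
        rows[[i]] <- data.frame(
            mirna_id = row$mirna_id,
            start0 = IRanges::start(wins) - 1L,
            end0 = IRanges::end(wins),
            n_derived = nd, n_other = no,
            fisher_p = vapply(seq_along(wins), function(w)
                windowFisher(nd[w], no[w], genomeTotals[["derived"]],
                             genomeTotals[["other"]], ...), 1.0),
            stringsAsFactors = FALSE)
    }
    windows <- do.call(rbind, rows)
    if (is.null(windows))
        return(list(windows = NULL, n_windows_tested = 0L,
                    n_significant = 0L))
    nTested <- nrow(windows)
    windows$bonferroni_significant <-
        pmin(windows$fisher_p * nTested, 1) < alpha
    out <- list(windows = windows, n_windows_tested = nTested,
                n_significant = sum(windows$bonferroni_significant))
    if (length(truncated)) attr(out, "truncated") <- truncated
    out
}

#' Feature-anchored permutation null
#'
#' Draws \code{nPerm} random subsets of \code{k} features from the pool
#' without replacement, evaluates the scan statistic on each, and reports
#' the exceedance count and empirical p-value
#' \code{exceedances / nPerm} (a statistic at least as extreme as the
#' observed one counts as an exceedance).
#'
#' @param pool vector (or list) of features to draw from.
#' @param k subset size (default 5).
#' @param nPerm number of permutations (default 1000).
#' @param statistic function mapping a k-subset of \code{pool} to a number.
#' @param observed the observed statistic.
#' @param seed RNG seed.
#' @return list with \code{exceedances}, \code{empirical_p} and the drawn
#'   statistics (\code{perm_stats}).
#' @examples
#' permutationNull(1:100, k = 5, nPerm = 200, statistic = max,
#'                 observed = 99, seed = 1)$empirical_p
#' @export
permutationNull <- function(pool, k = 5L, nPerm = 1000L, statistic,
                            observed, seed = 1L) {
    n <- if (is.list(pool) || is.vector(pool)) length(pool) else
        length(pool)
    if (k > n) stop("k exceeds the pool size")
    set.seed(seed)
    stats <- vapply(seq_len(nPerm), function(i)
        statistic(pool[sample.int(n, k)]), 1.0)
    exc <- sum(stats >= observed)
    list(exceedances = exc, empirical_p = exc / nPerm, perm_stats = stats)
}

#' @describeIn permutationNull empirical p from bare exceedance counts.
#' @param exceedances,nPerm counts.
#' @export
empiricalP <- function(exceedances, nPerm) {
    stopifnot(exceedances >= 0, exceedances <= nPerm, nPerm >= 1)
    exceedances / nPerm
}
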