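## Statistics linking miRNA expression divergence to mRNA/protein
## divergence of predicted targets.

#' Divergence-shift test between target groups
#'
#' Compares the expression-divergence values (human/chimpanzee, positive =
#' higher in human) of genes targeted by human-high miRNA against genes
#' targeted by chimpanzee-high miRNA. Genes targeted by both groups
#' (inconsistent expected effects) are excluded, as are genes whose
#' absolute divergence is below \code{minAbs}. The comparison is the
#' unpaired two-sample rank-sum test; under the regulatory model the
#' human-high group is expected to sit lower.
#'
#' @param divergence named numeric vector of per-gene divergence values.
#' @param targetsHumanHigh,targetsChimpHigh character vectors of gene ids.
#' @param minAbs minimal absolute divergence retained (default 0.5).
#' @param exact passed to [stats::wilcox.test()].
#' @return list with \code{p}, \code{median_human_high},
#'   \code{median_chimp_high}, \code{n_human_high}, \code{n_chimp_high}.
#' @export
divergenceShiftTest <- function(divergence, targetsHumanHigh,
                                targetsChimpHigh, minAbs = 0.5,
                                exact = NULL) {
    both <- intersect(targetsHumanHigh, targetsChimpHigh)
    th <- setdiff(targetsHumanHigh, both)
    tc <- setdiff(targetsChimpHigh, both)
    keep <- names(divergence)[abs(divergence) >= minAbs]
    x <- divergence[intersect(th, keep)]
    y <- divergence[intersect(tc, keep)]
    if (!length(x) || !length(y)) stop("no testable targets")
    wt <- stats::wilcox.test(x, y, exact = exact)
    list(p = wt$p.value,
         median_human_high = stats::median(x),
         median_chimp_high = stats::median(y),
         n_human_high = length(x), n_chimp_high = length(y))
}

#' Standardized between-species effect size
#'
#' Cohen's d with the pooled standard deviation (no small-sample
#' correction): \code{(mean_h - mean_c) / sd_pooled}. Genes with zero
#' pooled SD get \code{NA} and should be flagged by the caller; downstream
#' analyses retain only genes with absolute effect size strictly greater
#' than one.
#'
#' @param valuesH,valuesC numeric vectors with >= 2 replicates each.
#' @return standardized mean difference (positive = higher in human).
#' @examples
#' proteinEffectSize(c(3, 3), c(1, 1) + c(-1, 1))  # pooled sd 1 -> 2
#' @export
proteinEffectSize <- function(valuesH, valuesC) {
    nh <- length(valuesH); nc <- length(valuesC)
    if (nh < 2L || nc < 2L) stop("need >= 2 replicates per species")
    sp2 <- ((nh - 1) * stats::var(valuesH) +
            (nc - 1) * stats::var(valuesC)) / (nh + nc - 2)
    if (sp2 == 0) return(NA_real_)
    (mean(valuesH) - mean(valuesC)) / sqrt(sp2)
}

#' Association summary from bare counts
#'
#' The headline regulatory-contribution statistic: among all genes with
#' significant expression divergence, the percentage that can be negatively
#' associated with miRNA divergence, the percentage positively associated,
#' and the percent explained, 100 * (negative - positive) / total, all
#' rounded to the nearest integer.
#'
#' @param nNegative,nPositive,nTotalSignificant counts with
#'   \code{nNegative + nPositive <= nTotalSignificant}.
#' @return list of class \code{"associationSummary"} with the counts and
#'   \code{percent_negative}, \code{percent_positive},
#'   \code{percent_explained}.
#' @examples
#' associationSummary(68, 58, 479)$percent_explained  # 2
#' @export
associationSummary <- function(nNegative, nPositive, nTotalSignificant) {
    stopifnot(nNegative >= 0, nPositive >= 0,
              nNegative + nPositive <= nTotalSignificant)
    structure(list(
        n_total_significant = nTotalSignificant,
        n_negative = nNegative,
        n_positive = nPositive,
        percent_negative = round(100 * nNegative / nTotalSignificant),
        percent_positive = round(100 * nPositive / nTotalSignificant),
        percent_explained =
            round(100 * (nNegative - nPositive) / nTotalSignificant)),
        class = "associationSummary")
}

#' @export
print.associationSummary <- function(x, ...) {
    cat("Association summary: ", x$n_negative, " negative / ",
        x$n_positive, " positive of ", x$n_total_significant,
        " significant genes (", x$percent_negative, "% / ",
        x$percent_positive, "%); percent explained: ",
        x$percent_explained, "%\n", sep = "")
    invisible(x)
}

#' Count miRNA-target associations among significantly diverged genes
#'
#' Each significantly diverged gene targeted by at least one differentially
#' expressed miRNA is classified: negative when any miRNA-gene pair changes
#' in opposite directions (decisive even when same-direction pairs also
#' exist), positive when all its pairs change in the same direction.
#'
#' @param deCalls data.frame from [callDeSeq()] (rows with
#'   \code{passed = TRUE} are used) with \code{mirna_id} and
#'   \code{fold_change} (species1/species2).
#' @param targetMap named list: miRNA id to target gene ids.
#' @param divergence named numeric per-gene divergence (positive = higher
#'   in species1).
#' @param sigGenes character vector of genes passing the divergence
#'   significance cutoff.
#' @return an [associationSummary()].
#' @export
countAssociations <- function(deCalls, targetMap, divergence, sigGenes) {
    if (!length(sigGenes)) return(associationSummary(0, 0, 0L))
    de <- deCalls[deCalls$passed, , drop = FALSE]
    ## invert the map once: gene -> targeting miRNA
    pairs <- data.frame(
        mirna = rep(names(targetMap), lengths(targetMap)),
        gene = unlist(targetMap, use.names = FALSE),
        stringsAsFactors = FALSE)
    revMap <- split(pairs$mirna, pairs$gene)
    nNeg <- 0L; nPos <- 0L
    for (g in sigGenes) {
        gdir <- sign(unname(divergence[g]))
        if (length(gdir) != 1L || is.na(gdir) || gdir == 0) next
        mirs <- intersect(revMap[[g]], de$mirna_id)
        if (!length(mirs)) next
        mdir <- sign(log(de$fold_change[match(mirs, de$mirna_id)]))
        if (any(mdir == -gdir)) nNeg <- nNeg + 1L
        else if (any(mdir == gdir)) nPos <- nPos + 1L
    }
    associationSummary(nNeg, nPos, length(sigGenes))
}

## fast per-row pooled-variance two-sample t-test (two-sided p)
rowStudentT <- function(m, grp1, grp2) {
    x <- m[, grp1, drop = FALSE]; y <- m[, grp2, drop = FALSE]
    n1 <- ncol(x); n2 <- ncol(y)
    m1 <- rowMeans(x); m2 <- rowMeans(y)
    v1 <- rowSums((x - m1)^2) / (n1 - 1)
    v2 <- rowSums((y - m2)^2) / (n2 - 1)
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    tt <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    2 * stats::pt(abs(tt), n1 + n2 - 2, lower.tail = FALSE)
}

#' Permutation-based FDR for between-species expression differences
#'
#' Per-gene two-sample Student t-tests define the observed number of genes
#' significant at \code{alpha}; whole-column species labels are then
#' permuted \code{nPerm} times and the FDR is the mean permuted significant
#' count divided by the observed one.
#'
#' @param expression matrix genes x samples.
#' @param speciesLabels per-column labels (two groups).
#' @param alpha per-gene significance cutoff.
#' @param nPerm number of label permutations (default 1000).
#' @param seed RNG seed for the permutations.
#' @return list with \code{n_significant}, \code{fdr} (NA when nothing is
#'   observed significant) and \code{sig_genes}.
#' @export
permutationFdr <- function(expression, speciesLabels, alpha,
                           nPerm = 1000L, seed = 1L) {
    grp <- unique(speciesLabels)
    stopifnot(length(grp) == 2L)
    i1 <- which(speciesLabels == grp[1L])
    i2 <- which(speciesLabels == grp[2L])
    if (length(i1) < 2L || length(i2) < 2L)
        stop("need >= 2 samples per species")
    p <- rowStudentT(expression, i1, i2)
    nSig <- sum(p < alpha, na.rm = TRUE)
    set.seed(seed)
    nCol <- ncol(expression)
    permSig <- vapply(seq_len(nPerm), function(k) {
        idx <- sample.int(nCol)
        pp <- rowStudentT(expression, idx[seq_along(i1)],
                          idx[length(i1) + seq_along(i2)])
        sum(pp < alpha, na.rm = TRUE)
    }, 1.0)
    list(n_significant = nSig,
         fdr = if (nSig == 0) NA_real_ else mean(permSig) / nSig,
         sig_genes = rownames(expression)[which(p < alpha)])
}

#' Inhibition ratio of a gene set
#'
#' Number of down-regulated genes divided by the number of not-down-regulated
#' genes. A zero denominator returns \code{Inf} with attribute
#' \code{"degenerate"}.
#'
#' @param nDown,nNotDown non-negative counts.
#' @return the ratio.
#' @export
inhibitionRatio <- function(nDown, nNotDown) {
    stopifnot(nDown >= 0, nNotDown >= 0)
    if (nNotDown == 0) {
        out <- Inf
        attr(out, "degenerate") <- TRUE
        return(out)
    }
    nDown / nNotDown
}

#' Fisher enrichment test on down-regulation between two gene sets
#'
#' Two-sided Fisher's exact test on the 2x2 table
#' (set A, set B) x (down, not down).
#'
#' @param aDown,aNot,bDown,bNot counts.
#' @return two-sided p-value.
#' @export
fisherEnrichment <- function(aDown, aNot, bDown, bNot) {
    stopifnot(all(c(aDown, aNot, bDown, bNot) >= 0))
    stats::fisher.test(matrix(c(aDown, aNot, bDown, bNot), nrow = 2,
                              byrow = TRUE))$p.value
}
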