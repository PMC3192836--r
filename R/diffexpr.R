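## Differential miRNA expression between species, lineage assignment,
## cross-platform consistency and sample clustering.

#' Quantile normalization across samples
#'
#' Gives every column the identical sorted value multiset (the per-rank mean
#' across columns); ties receive the mean of their ranks' reference values.
#' Thin wrapper around \code{limma::normalizeQuantiles}.
#'
#' @param m numeric matrix with >= 2 columns.
#' @return normalized matrix with the input dimnames.
#' @examples
#' quantileNormalize(cbind(a = c(1, 2, 3), b = c(4, 5, 6)))
#' @export
quantileNormalize <- function(m) {
    m <- as.matrix(m)
    if (ncol(m) < 2L) {
        warning("single column: quantile normalization is a no-op")
        return(m)
    }
    out <- limma::normalizeQuantiles(m, ties = TRUE)
    dimnames(out) <- dimnames(m)
    out
}

#' Transcripts-per-million normalization
#'
#' @param counts non-negative counts.
#' @param totalMapped total mapped reads of the sample (> 0).
#' @return counts * 1e6 / totalMapped.
#' @export
tpmNormalize <- function(counts, totalMapped) {
    if (totalMapped <= 0) stop("totalMapped must be > 0")
    counts * 1e6 / totalMapped
}

#' Fisher's exact test between two count libraries
#'
#' Two-sided exact test on the 2x2 table contrasting one miRNA's count
#' against the remainder of each library:
#' \code{[[c1, N1 - c1], [c2, N2 - c2]]}. The two-sided p-value follows the
#' "probability at most that of the observed table" rule.
#'
#' @param c1,c2 counts of the miRNA in the two libraries.
#' @param N1,N2 library totals.
#' @return two-sided p-value.
#' @examples
#' fisherCountTest(5, 100, 5, 100)  # identical proportions: p = 1
#' @export
fisherCountTest <- function(c1, N1, c2, N2) {
    if (c1 > N1 || c2 > N2) stop("count exceeds its library total")
    if (any(c(c1, N1, c2, N2) < 0)) stop("counts must be non-negative")
    stats::fisher.test(matrix(c(c1, N1 - c1, c2, N2 - c2), nrow = 2,
                              byrow = TRUE))$p.value
}

#' Call differentially expressed miRNA from sequencing counts
#'
#' For each technical replicate pair, the two species' libraries are
#' normalized (quantile by default; the TPM alternative gives near-identical
#' calls), and a miRNA passes in that replicate when the Fisher exact
#' p-value is below \code{alpha}, the linear fold-change exceeds \code{fc}
#' (a 0.5 pseudocount guards against zeros), and the miRNA is covered by at
#' least \code{minReads} raw reads in at least one species. A miRNA is
#' called differentially expressed when it passes in both replicates with
#' the same direction; with a single replicate available the call is made in
#' single-replicate mode and flagged.
#'
#' @param counts integer matrix (miRNA x samples) or the
#'   \code{SummarizedExperiment} from [quantifyAll()].
#' @param sampleInfo data.frame with columns \code{species} and
#'   \code{replicate} (ignored when \code{counts} is a
#'   SummarizedExperiment).
#' @param species1,species2 the two species to contrast.
#' @param alpha,fc,minReads thresholds (defaults 0.01, 2, 10).
#' @param normalize \code{"quantile"}, \code{"tpm"} or \code{"none"}.
#' @return data.frame with one row per miRNA: \code{mirna_id},
#'   \code{p_value} (max across replicates), per-replicate p columns,
#'   \code{fold_change} (species1/species2, geometric mean across
#'   replicates), \code{direction}, \code{detected}, \code{passed},
#'   \code{replicate_consistent}; attribute \code{"single_replicate"} marks
#'   fallback mode.
#' @export
callDeSeq <- function(counts, sampleInfo = NULL, species1 = "human",
                      species2 = "chimpanzee", alpha = 0.01, fc = 2,
                      minReads = 10L,
                      normalize = c("quantile", "tpm", "none")) {
    normalize <- match.arg(normalize)
    if (is(counts, "SummarizedExperiment")) {
        sampleInfo <- as.data.frame(SummarizedExperiment::colData(counts))
        counts <- SummarizedExperiment::assay(counts, "counts")
    }
    stopifnot(!is.null(sampleInfo), nrow(sampleInfo) == ncol(counts))
    i1 <- which(sampleInfo$species == species1)
    i2 <- which(sampleInfo$species == species2)
    if (!length(i1) || !length(i2))
        stop("both species must be present in sampleInfo")
    nRep <- min(length(i1), length(i2))
    single <- nRep < 2L
    i1 <- i1[order(sampleInfo$replicate[i1])][seq_len(nRep)]
    i2 <- i2[order(sampleInfo$replicate[i2])][seq_len(nRep)]

    raw <- counts[, c(i1, i2), drop = FALSE]
    ## Counts entering the exact test. Quantile normalization keeps the raw
    ## scale (per-rank means), so library sizes stay honest. TPM rescales
    ## every library to 1e6, which would misstate the sampling depth inside
    ## an exact test; because Fisher's test depends on the counts and true
    ## totals only through the proportions, the TPM path tests the raw
    ## counts against the raw totals (an identical comparison of TPM
    ## values) and uses TPM only for the fold-change scale.
    norm <- switch(normalize,
        quantile = round(quantileNormalize(raw)),
        tpm = raw,
        none = raw)

    nMir <- nrow(counts)
    pRep <- matrix(NA_real_, nMir, nRep)
    foldRep <- matrix(NA_real_, nMir, nRep)
    detRep <- matrix(FALSE, nMir, nRep)
    for (r in seq_len(nRep)) {
        a <- norm[, r]; b <- norm[, nRep + r]
        Na <- sum(a); Nb <- sum(b)
        pRep[, r] <- vapply(seq_len(nMir), function(i)
            fisherCountTest(a[i], Na, b[i], Nb), 1.0)
        foldRep[, r] <- if (normalize == "tpm")
            (tpmNormalize(a, Na) + 0.5) / (tpmNormalize(b, Nb) + 0.5)
        else (a + 0.5) / (b + 0.5)
        detRep[, r] <- isDetected(raw[, r], minReads) |
            isDetected(raw[, nRep + r], minReads)
    }
    passRep <- pRep < alpha &
        (foldRep > fc | foldRep < 1 / fc) & detRep
    dirRep <- foldRep > 1
    fold <- exp(rowMeans(log(foldRep)))
    if (single) {
        passed <- passRep[, 1L]
        consistent <- rep(NA, nMir)
    } else {
        consistent <- apply(dirRep, 1L, function(z) all(z) || all(!z))
        passed <- apply(passRep, 1L, all) & consistent
    }
    out <- data.frame(
        mirna_id = rownames(counts) %||% paste0("mir", seq_len(nMir)),
        p_value = apply(pRep, 1L, max),
        fold_change = fold,
        direction = ifelse(fold > 1, paste0("up-in-", species1),
                           paste0("up-in-", species2)),
        detected = apply(detRep, 1L, any),
        passed = passed,
        replicate_consistent = consistent,
        stringsAsFactors = FALSE)
    for (r in seq_len(nRep)) out[[paste0("p_rep", r)]] <- pRep[, r]
    attr(out, "single_replicate") <- single
    out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Call differentially expressed miRNA from array intensities
#'
#' Two-sided two-sample t-test per miRNA on quantile-normalized log2
#' intensities, with the same significance and fold-change thresholds as the
#' sequencing pipeline. miRNA whose probes must be masked because the mature
#' sequences differ between species are removed before testing; miRNA with
#' fewer than two individuals per species are skipped and flagged.
#'
#' @param intensities log2 intensity matrix (miRNA x samples), already
#'   quantile normalized.
#' @param species character vector of per-column species labels.
#' @param species1,species2 contrast.
#' @param masked character vector of miRNA ids to exclude.
#' @param alpha,fc thresholds (defaults 0.01, 2).
#' @return data.frame with \code{mirna_id}, \code{p_value},
#'   \code{fold_change} (linear, species1/species2), \code{direction},
#'   \code{passed}, \code{skipped}.
#' @export
callDeArray <- function(intensities, species, species1 = "human",
                        species2 = "chimpanzee", masked = character(0),
                        alpha = 0.01, fc = 2) {
    stopifnot(length(species) == ncol(intensities))
    keep <- !(rownames(intensities) %in% masked)
    m <- intensities[keep, , drop = FALSE]
    a <- m[, species == species1, drop = FALSE]
    b <- m[, species == species2, drop = FALSE]
    res <- lapply(seq_len(nrow(m)), function(i) {
        x <- a[i, ]; y <- b[i, ]
        if (length(x) < 2L || length(y) < 2L)
            return(data.frame(p_value = NA_real_, fold_change = NA_real_,
                              skipped = TRUE))
        p <- tryCatch(stats::t.test(x, y)$p.value,
                      error = function(e) NA_real_)
        data.frame(p_value = p, fold_change = 2^(mean(x) - mean(y)),
                   skipped = FALSE)
    })
    res <- do.call(rbind, res)
    data.frame(
        mirna_id = rownames(m),
        p_value = res$p_value,
        fold_change = res$fold_change,
        direction = ifelse(res$fold_change > 1,
                           paste0("up-in-", species1),
                           paste0("up-in-", species2)),
        passed = !res$skipped & !is.na(res$p_value) & res$p_value < alpha &
            (res$fold_change > fc | res$fold_change < 1 / fc),
        skipped = res$skipped,
        stringsAsFactors = FALSE)
}

#' Filter an externally computed exact-test table
#'
#' Hook for negative-binomial exact tests computed outside this package
#' (e.g. a per-miRNA table of p-values and FDR): applies the
#' \code{p < alpha & FDR < fdr} criterion.
#'
#' @param tab data.frame with columns \code{p_value} and \code{fdr}.
#' @param alpha,fdr thresholds (defaults 0.001, 0.01).
#' @return the subset of rows passing both criteria.
#' @export
filterExactTestTable <- function(tab, alpha = 0.001, fdr = 0.01) {
    stopifnot(all(c("p_value", "fdr") %in% names(tab)))
    tab[tab$p_value < alpha & tab$fdr < fdr, , drop = FALSE]
}

#' Direction consistency between two sets of differential-expression calls
#'
#' For the miRNA passing in set A and measurable in set B, counts how many
#' show the same direction of change in B, and tests the excess over the
#' 50:50 expectation with a one-sided exact binomial tail.
#'
#' @param callsA,callsB data.frames with columns \code{mirna_id},
#'   \code{fold_change} (and \code{passed} in \code{callsA}).
#' @return list with \code{n_shared}, \code{n_consistent}, \code{percent}
#'   (rounded to the nearest integer) and \code{binomial_p} =
#'   P(X >= n_consistent | n_shared, 1/2).
#' @examples
#' consistencyStats(31, 37)$percent  # 84
#' @export
directionConsistency <- function(callsA, callsB) {
    sel <- callsA[callsA$passed, , drop = FALSE]
    idx <- match(sel$mirna_id, callsB$mirna_id)
    ok <- !is.na(idx) & is.finite(callsB$fold_change[idx])
    sel <- sel[ok, , drop = FALSE]
    idx <- idx[ok]
    if (!nrow(sel)) stop("no shared miRNA between the two call sets")
    cons <- sign(log(sel$fold_change)) ==
        sign(log(callsB$fold_change[idx]))
    consistencyStats(sum(cons), nrow(sel))
}

#' @describeIn directionConsistency the summary statistic on bare counts:
#'   percent consistent and the one-sided binomial tail probability.
#' @param nConsistent,nShared counts with \code{nConsistent <= nShared}.
#' @export
consistencyStats <- function(nConsistent, nShared) {
    if (nShared < 1L) stop("nShared must be >= 1")
    stopifnot(nConsistent <= nShared)
    list(n_shared = nShared, n_consistent = nConsistent,
         percent = round(100 * nConsistent / nShared),
         binomial_p = stats::pbinom(nConsistent - 1L, nShared, 0.5,
                                    lower.tail = FALSE))
}

#' Assign the evolutionary lineage of an expression difference
#'
#' For a miRNA differentially expressed between human and chimpanzee, the
#' macaque level is used as a proxy for the ancestral state: the change is
#' assigned to the human lineage when the human level is farther from the
#' macaque level than the chimpanzee level is, and the chimpanzee level lies
#' on the macaque side of the human level; the chimpanzee lineage by the
#' mirrored rule; otherwise unassigned.
#'
#' @param exprH,exprC,exprM expression levels (same normalized scale) in
#'   human, chimpanzee, macaque.
#' @return one of \code{"human"}, \code{"chimpanzee"}, \code{"unassigned"};
#'   a missing macaque level gives \code{"unassigned"} with attribute
#'   \code{"missing_outgroup"}.
#' @examples
#' assignLineage(100, 10, 12)  # "human"
#' @export
assignLineage <- function(exprH, exprC, exprM) {
    if (is.na(exprM)) {
        out <- "unassigned"
        attr(out, "missing_outgroup") <- TRUE
        return(out)
    }
    dH <- abs(exprH - exprM)
    dC <- abs(exprC - exprM)
    ## "on the macaque side of x": same side of x as the macaque level
    sameSide <- function(a, x) (a - x) * (exprM - x) >= 0
    if (dH > dC && sameSide(exprC, exprH)) "human"
    else if (dC > dH && sameSide(exprH, exprC)) "chimpanzee"
    else "unassigned"
}

#' UPGMA clustering of expression profiles
#'
#' Samples are clustered by average-linkage (UPGMA) agglomeration on the
#' distance 1 - Pearson correlation between sample columns. The returned
#' tree is ultrametric with node heights equal to half the merge distances
#' (the standard UPGMA dendrogram convention).
#'
#' @param m expression matrix (features x samples), >= 3 samples.
#' @return an \code{ape} \code{"phylo"} tree with the sample names as tips.
#' @export
upgmaCluster <- function(m) {
    if (ncol(m) < 3L) stop("need at least 3 samples")
    sds <- apply(m, 2L, stats::sd)
    if (any(sds == 0))
        stop("constant expression column: ",
             paste(colnames(m)[sds == 0], collapse = ", "))
    d <- stats::as.dist(1 - stats::cor(m))
    ape::as.phylo(stats::hclust(d, method = "average"))
}

#' Relative expression from Q-PCR cycle thresholds
#'
#' The level of a miRNA relative to an invariant endogenous control, on the
#' log2 scale: \code{-(ctMirna - ctReference)}, i.e. log2 of
#' 2^(-delta Ct).
#'
#' @param ctMirna,ctReference positive threshold-cycle numbers.
#' @return log2 relative expression.
#' @examples
#' qpcrRelativeExpression(24, 25)  # +1
#' @export
qpcrRelativeExpression <- function(ctMirna, ctReference) {
    stopifnot(all(ctMirna > 0), all(ctReference > 0))
    -(ctMirna - ctReference)
}
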