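## Seeded generators for every input the pipeline consumes.

speciesNames <- function(n) {
    base <- c("human", "chimpanzee", "macaque")
    if (n <= 3L) base[seq_len(n)] else c(base, paste0("species", 4:n))
}

## gamma-Poisson draw: NB with mean mu and dispersion phi
## (variance mu + phi * mu^2)
rnbGammaPois <- function(n, mu, phi) {
    g <- rgamma(n, shape = 1 / phi, rate = 1 / phi)
    rpois(n, mu * g)
}

randomSeq <- function(len) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

#' Simulate aligned small-RNA read stacks with known ground truth
#'
#' Generates miRNA precursor annotations for every species, draws per-sample
#' miRNA counts from a gamma-Poisson (negative-binomial) model and lays the
#' reads out as 5'-anchored stacks. All in-window reads of a miRNA share the
#' annotated mature 5' position and differ only in 3' length (isomiR
#' heterogeneity); an additional 5% of each miRNA's reads are placed as
#' decoys beyond the +/-3 nt quantification window to exercise the window
#' filter. A fraction \code{deFraction} of miRNA is implanted as
#' differentially expressed: their expected counts are multiplied by
#' \code{deFold} in one randomly assigned up-species. When \code{phyloSd > 0}
#' an additional drift term makes human and chimpanzee expression covary
#' relative to the macaque outgroup.
#'
#' @param cfg a [SimConfig-class].
#' @return A list with elements \code{stacks} (list of [ReadStack-class],
#'   one per species x replicate), \code{loci} ([MirnaLoci-class]) and
#'   \code{truth} ([GroundTruth-class]).
#' @examples
#' sim <- simulateReadStacks(simConfig(seed = 7, nMirna = 20, depth = 5000))
#' sim$stacks[[1]]
#' @export
simulateReadStacks <- function(cfg) {
    validObject(cfg)
    set.seed(cfg@seed + 101L)
    sp <- speciesNames(cfg@nSpecies)
    n <- cfg@nMirna

    precLen <- 82L
    matStart <- 15L
    matLen <- 22L
    ids <- sprintf("mir-%03d", seq_len(n))
    precSeqs <- vapply(seq_len(n), function(i) randomSeq(precLen), "")

    loci <- do.call(rbind, lapply(sp, function(s) {
        data.frame(
            mirna_id = ids,
            precursor_id = paste0(ids, "-pre"),
            species = s,
            precursor_seq = precSeqs,
            arm = "5p",
            mature_start0 = matStart,
            mature_end0 = matStart + matLen,
            chrom = "chr1",
            strand = "+",
            precursor_start0 = 200000L + (seq_len(n) - 1L) * 300000L,
            stringsAsFactors = FALSE)
    }))
    loci <- MirnaLoci(loci)

    ## implanted DE miRNA
    nDe <- round(cfg@deFraction * n)
    deIdx <- if (nDe > 0) sort(sample.int(n, nDe)) else integer(0)
    upSpecies <- if (nDe > 0) sample(sp, nDe, replace = TRUE) else character(0)
    deTab <- data.frame(mirna_id = ids[deIdx], up_species = upSpecies,
                        stringsAsFactors = FALSE)

    ## true target map over the gene universe
    genes <- sprintf("gene%04d", seq_len(cfg@nGenes))
    tmap <- lapply(seq_len(n), function(i) {
        k <- min(rpois(1L, cfg@targetDensity), cfg@nGenes)
        if (k > 0) sample(genes, k) else character(0)
    })
    names(tmap) <- ids
    truth <- GroundTruth(deMirna = deTab, targetMap = tmap,
                         sweepWindows = cfg@sweepWindows)

    ## per-miRNA base abundances and species effects (log2 drift)
    w <- rlnorm(n, meanlog = 0, sdlog = 1)
    drift <- matrix(0, n, cfg@nSpecies, dimnames = list(ids, sp))
    if (cfg@phyloSd > 0 && cfg@nSpecies >= 3L) {
        anc <- rnorm(n, 0, cfg@phyloSd)                 # human-chimp ancestor
        drift[, 1L] <- anc + rnorm(n, 0, cfg@phyloSd / 3)
        drift[, 2L] <- anc + rnorm(n, 0, cfg@phyloSd / 3)
        drift[, 3L] <- rnorm(n, 0, 2 * cfg@phyloSd)
    }

    stacks <- list()
    for (s in seq_along(sp)) {
        mean_s <- w * 2^drift[, s]
        if (nDe > 0) {
            up <- deIdx[upSpecies == sp[s]]
            mean_s[up] <- mean_s[up] * cfg@deFold
        }
        p <- mean_s / sum(mean_s)
        for (r in seq_len(cfg@nReplicates)) {
            counts <- rnbGammaPois(n, cfg@depth * p, cfg@nbDispersion)
            recs <- makeStackRecords(loci@table[loci@table$species == sp[s], ],
                                     counts)
            stacks[[paste0(sp[s], "_rep", r)]] <-
                ReadStack(paste0(sp[s], "_rep", r), recs)
        }
    }
    list(stacks = stacks, loci = loci, truth = truth)
}

## Lay one sample's miRNA counts out as read records. About 5% of each
## miRNA's drawn count is diverted to a decoy beyond the +/-3 window; the
## remainder shares the mature 5' position, split into three 3'-length
## isomiRs. Stack copies therefore sum exactly to the drawn totals.
makeStackRecords <- function(lociTab, counts) {
    out <- vector("list", nrow(lociTab))
    for (i in seq_len(nrow(lociTab))) {
        K <- counts[i]
        if (K == 0) next
        row <- lociTab[i, ]
        g5 <- row$precursor_start0 + row$mature_start0
        decoy <- round(0.05 * K)
        inWin <- K - decoy
        lens <- c(22L, 21L, 23L)
        split <- if (inWin > 0)
            as.vector(rmultinom(1L, inWin, c(0.7, 0.2, 0.1)))
        else c(0L, 0L, 0L)
        keep <- split > 0
        seqs <- vapply(lens, function(L)
            substr(row$precursor_seq, row$mature_start0 + 1L,
                   row$mature_start0 + L), "")
        rec <- data.frame(sequence = seqs[keep], chrom = row$chrom,
                          pos0 = g5, strand = row$strand,
                          copies = split[keep], stringsAsFactors = FALSE)
        if (decoy > 0) {
            dseq <- substr(row$precursor_seq, row$mature_start0 + 6L,
                           row$mature_start0 + 6L + 21L)
            rec <- rbind(rec, data.frame(
                sequence = dseq, chrom = row$chrom, pos0 = g5 + 5L,
                strand = row$strand, copies = decoy,
                stringsAsFactors = FALSE))
        }
        out[[i]] <- rec
    }
    out <- out[!vapply(out, is.null, TRUE)]
    if (!length(out))
        return(data.frame(sequence = character(0), chrom = character(0),
                          pos0 = integer(0), strand = character(0),
                          copies = integer(0), stringsAsFactors = FALSE))
    do.call(rbind, out)
}

#' Simulate mRNA and protein expression matrices with implanted target shifts
#'
#' Gene baselines are drawn once and shared across species; the true targets
#' of each implanted miRNA are shifted down by \code{targetEffect} log2 units
#' in the species where that miRNA is up, and Gaussian noise with s.d.
#' \code{noiseSd} is added per individual. Both matrices carry human,
#' chimpanzee and macaque columns so that outgroup-based classification can
#' be exercised.
#'
#' @param cfg a [SimConfig-class].
#' @param truth the [GroundTruth-class] from [simulateReadStacks()].
#' @return list with \code{mrna} and \code{protein}, each a
#'   \code{SummarizedExperiment} (assay \code{"log2"}, colData column
#'   \code{species}).
#' @export
simulateExpression <- function(cfg, truth) {
    validObject(cfg)
    set.seed(cfg@seed + 202L)
    sp <- speciesNames(cfg@nSpecies)
    genes <- sprintf("gene%04d", seq_len(cfg@nGenes))
    if (length(truth@targetMap) &&
        !all(unlist(truth@targetMap) %in% genes))
        stop("target map gene universe does not match the configuration")

    base <- rnorm(cfg@nGenes, 8, 2)
    shift <- matrix(0, cfg@nGenes, cfg@nSpecies,
                    dimnames = list(genes, sp))
    de <- truth@deMirna
    for (k in seq_len(nrow(de))) {
        tg <- truth@targetMap[[de$mirna_id[k]]]
        if (length(tg))
            shift[tg, de$up_species[k]] <-
                shift[tg, de$up_species[k]] - cfg@targetEffect
    }

    build <- function(nInd) {
        cols <- unlist(lapply(sp, function(s) paste0(s, "_", seq_len(nInd))))
        m <- matrix(0, cfg@nGenes, length(cols),
                    dimnames = list(genes, cols))
        for (s in seq_along(sp)) {
            idx <- (s - 1L) * nInd + seq_len(nInd)
            m[, idx] <- base + shift[, s] +
                matrix(rnorm(cfg@nGenes * nInd, 0, cfg@noiseSd),
                       cfg@nGenes, nInd)
        }
        SummarizedExperiment::SummarizedExperiment(
            assays = list(log2 = m),
            colData = S4Vectors::DataFrame(
                species = rep(sp, each = nInd), row.names = cols))
    }
    list(mrna = build(cfg@nIndividualsMrna),
         protein = build(cfg@nIndividualsProtein))
}

#' Simulate a transfection experiment for one miRNA
#'
#' For two cell lines, the true targets of \code{mirnaId} receive a mean
#' log2 effect of \code{-targetEffect}; every gene also has a per-cell-line
#' off-target response (s.d. \code{noiseSd}) that is shared between the two
#' mock comparisons, plus independent per-mock measurement noise
#' (s.d. \code{mockNoiseSd}). The effect of gene g against mock replicate r
#' is \code{log2(mimic) - log2(mock_r)}.
#'
#' @param cfg a [SimConfig-class].
#' @param truth the [GroundTruth-class] carrying the true target map.
#' @param mirnaId miRNA to transfect; must be a name of the target map.
#' @return named list with one matrix per cell line (genes x
#'   \code{c("mock1", "mock2")}) of log2 effects; attribute
#'   \code{"trueTargets"} gives the implanted target set.
#' @export
simulateTransfection <- function(cfg, truth, mirnaId) {
    validObject(cfg)
    idx <- match(mirnaId, names(truth@targetMap))
    if (is.na(idx))
        stop("unknown miRNA id: ", mirnaId)
    set.seed(cfg@seed + 303L + idx)
    genes <- sprintf("gene%04d", seq_len(cfg@nGenes))
    tg <- truth@targetMap[[idx]]
    mu <- ifelse(genes %in% tg, -cfg@targetEffect, 0)
    out <- lapply(c("cellA", "cellB"), function(cl) {
        g <- mu + rnorm(cfg@nGenes, 0, cfg@noiseSd)
        m <- cbind(mock1 = g + rnorm(cfg@nGenes, 0, cfg@mockNoiseSd),
                   mock2 = g + rnorm(cfg@nGenes, 0, cfg@mockNoiseSd))
        rownames(m) <- genes
        m
    })
    names(out) <- c("cellA", "cellB")
    attr(out, "trueTargets") <- tg
    out
}

#' Simulate a derived-SNP track upstream of miRNA precursors
#'
#' Places SNPs uniformly in the \code{snpRegionLength} bp upstream of each
#' supplied precursor (strand-aware). Each SNP is human-derived (at least 4
#' of 6 modern genomes derived and all Neanderthal alleles ancestral) with
#' probability \code{snpBackground}, raised by the window's \code{excess}
#' inside implanted sweep windows. Sweep windows in the configuration apply
#' to the first locus in \code{loci} unless they carry a \code{mirna_id}
#' column. Genome-wide totals are drawn once from \code{genomeSnpTotal}
#' background sites and include the simulated regions' own SNPs.
#'
#' @param cfg a [SimConfig-class].
#' @param loci a [MirnaLoci-class]; one upstream region is simulated per row.
#' @return list with \code{snps} (a \code{GRanges} with metadata columns
#'   \code{derived_count}, \code{nea_ancestral}, \code{mirna_id}) and
#'   \code{genomeTotals} (named numeric: \code{derived}, \code{other}).
#' @export
simulateSnpTrack <- function(cfg, loci) {
    validObject(cfg)
    set.seed(cfg@seed + 404L)
    tab <- lociTable(loci)
    sw <- cfg@sweepWindows
    allPos <- integer(0); allDer <- integer(0); allNea <- logical(0)
    allId <- character(0); chroms <- character(0)
    nDerivedRegions <- 0L; nOtherRegions <- 0L
    for (i in seq_len(nrow(tab))) {
        row <- tab[i, ]
        reg <- upstreamRegion(row, cfg@snpRegionLength)
        if (reg[2] <= reg[1]) next
        L <- reg[2] - reg[1]
        nSnp <- rpois(1L, L * cfg@snpDensity)
        if (nSnp == 0) next
        pos <- sort(sample.int(L, min(nSnp, L))) - 1L + reg[1]
        pDer <- rep(cfg@snpBackground, length(pos))
        myWin <- sw[if ("mirna_id" %in% names(sw))
            sw$mirna_id == row$mirna_id else rep(i == 1L, nrow(sw)), ,
            drop = FALSE]
        for (k in seq_len(nrow(myWin))) {
            rel <- pos - reg[1]
            inWin <- rel >= myWin$start[k] & rel < myWin$end[k]
            pDer[inWin] <- pDer[inWin] + myWin$excess[k]
        }
        isDer <- runif(length(pos)) < pDer
        derCount <- integer(length(pos))
        neaAnc <- logical(length(pos))
        nd <- sum(isDer)
        if (nd) {
            derCount[isDer] <- sample(4:6, nd, replace = TRUE)
            neaAnc[isDer] <- TRUE
        }
        nn <- sum(!isDer)
        if (nn) {
            ## non-derived: either too few modern derived genomes, or a
            ## derived Neanderthal allele
            lowCount <- runif(nn) < 0.8
            derCount[!isDer] <- ifelse(lowCount,
                sample(0:3, nn, replace = TRUE),
                sample(4:6, nn, replace = TRUE))
            neaAnc[!isDer] <- lowCount & runif(nn) < 0.9
        }
        allPos <- c(allPos, pos)
        allDer <- c(allDer, derCount)
        allNea <- c(allNea, neaAnc)
        allId <- c(allId, rep(row$mirna_id, length(pos)))
        chroms <- c(chroms, rep(row$chrom, length(pos)))
        nDerivedRegions <- nDerivedRegions + nd
        nOtherRegions <- nOtherRegions + nn
    }
    snps <- GenomicRanges::GRanges(
        seqnames = if (length(allPos)) chroms else character(0),
        ranges = IRanges::IRanges(start = allPos + 1L, width = 1L),
        derived_count = allDer, nea_ancestral = allNea, mirna_id = allId)
    gDer <- if (cfg@genomeSnpTotal > 0)
        rbinom(1L, as.integer(cfg@genomeSnpTotal), cfg@snpBackground) else 0L
    totals <- c(derived = gDer + nDerivedRegions,
                other = max(cfg@genomeSnpTotal - gDer, 0) + nOtherRegions)
    list(snps = snps, genomeTotals = totals)
}

## strand-aware upstream region [start, end) of one precursor row
upstreamRegion <- function(locusRow, len) {
    if (locusRow$strand == "+")
        c(max(locusRow$precursor_start0 - len, 0), locusRow$precursor_start0)
    else {
        e <- locusRow$precursor_start0 + nchar(locusRow$precursor_seq)
        c(e, e + len)
    }
}
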