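test_that("invalid configuration fields are rejected by name", {
    expect_error(simConfig(deFraction = 1.5), "deFraction")
    expect_error(simConfig(deFold = 1), "deFold")
    expect_error(simConfig(depth = 0), "depth")
    expect_error(simConfig(nbDispersion = 0), "nbDispersion")
    expect_error(simConfig(nMirna = 0), "nMirna")
    expect_error(simConfig(
        sweepWindows = data.frame(start = c(0, 5000),
                                  end = c(10000, 15000),
                                  excess = 0.2)), "overlap")
    expect_error(simConfig(
        sweepWindows = data.frame(start = 0, end = 2e5, excess = 0.2)),
        "within the simulated region")
})

test_that("read-stack generation is deterministic and respects the implant", {
    cfg <- simConfig(seed = 42, nMirna = 30, depth = 2e4, deFraction = 0)
    a <- simulateReadStacks(cfg)
    b <- simulateReadStacks(cfg)
    expect_identical(a, b)                        # byte-identical
    expect_identical(nrow(deMirna(a$truth)), 0L)  # empty implant

    cfg2 <- simConfig(seed = 42, nMirna = 30, depth = 2e4,
                      deFraction = 0.2, deFold = 4)
    c2 <- simulateReadStacks(cfg2)
    expect_gt(nrow(deMirna(c2$truth)), 0L)
    expect_true(all(deMirna(c2$truth)$mirna_id %in%
                        lociTable(c2$loci)$mirna_id))
})

test_that("implanted fold is recovered in quantified counts", {
    cfg <- simConfig(seed = 5, nMirna = 200, depth = 1e5,
                     deFraction = 0.1, deFold = 4)
    sim <- simulateReadStacks(cfg)
    se <- quantifyAll(sim$stacks, sim$loci)
    m <- SummarizedExperiment::assay(se, "counts")
    tot <- colSums(m)
    de <- deMirna(sim$truth)
    sp <- unique(de$up_species)
    for (s in sp) {
        others <- setdiff(c("human", "chimpanzee", "macaque"), s)
        ids <- de$mirna_id[de$up_species == s]
        up <- rowMeans(m[ids, grep(s, colnames(m)), drop = FALSE] /
                       rep(tot[grep(s, colnames(m))] / 1e6,
                           each = length(ids)))
        dn <- rowMeans(m[ids, grep(others[1], colnames(m)), drop = FALSE] /
                       rep(tot[grep(others[1], colnames(m))] / 1e6,
                           each = length(ids)))
        ratio <- mean(up / dn)
        expect_gt(ratio, 2)      # within 50% of the implanted fold of 4
        expect_lt(ratio, 6)
    }
})

test_that("stack records are valid and decoys carry ~5% of the copies", {
    sim <- smallSim()
    tab <- lociTable(sim$loci)
    st <- sim$stacks[["human_rep1"]]
    rec <- readRecords(st)
    expect_true(all(rec$copies >= 1))
    expect_true(all(nchar(rec$sequence) >= 18 & nchar(rec$sequence) <= 28))
    g5 <- tab$precursor_start0[tab$species == "human"] +
        tab$mature_start0[tab$species == "human"]
    decoy <- sum(rec$copies[rec$pos0 %in% (g5 + 5L)])
    inwin <- sum(rec$copies[rec$pos0 %in% g5])
    expect_identical(decoy + inwin, sum(rec$copies))  # conservation
    expect_gt(decoy / sum(rec$copies), 0.03)
    expect_lt(decoy / sum(rec$copies), 0.07)
})

test_that("expression generator shifts true targets and only them", {
    cfg <- simConfig(seed = 9, nMirna = 20, nGenes = 1500, depth = 2e4,
                     deFraction = 0.25, deFold = 4, targetDensity = 60,
                     targetEffect = 1, noiseSd = 0.2)
    sim <- simulateReadStacks(cfg)
    expr <- simulateExpression(cfg, sim$truth)
    m <- SummarizedExperiment::assay(expr$mrna, "log2")
    species <- SummarizedExperiment::colData(expr$mrna)$species
    de <- deMirna(sim$truth)
    hUp <- de$mirna_id[de$up_species == "human"]
    expect_gt(length(hUp), 0)
    tg <- unique(unlist(targetMap(sim$truth)[hUp]))
    tgOnly <- setdiff(tg, unlist(targetMap(sim$truth)[
        de$mirna_id[de$up_species != "human"]]))
    expect_gte(length(tgOnly), 50)
    div <- rowMeans(m[, species == "human"]) -
        rowMeans(m[, species == "chimpanzee"])
    expect_gt(mean(div[tgOnly]), -1.2)   # Gaussian CI around -1
    expect_lt(mean(div[tgOnly]), -0.8)
    nt <- setdiff(rownames(m), unique(unlist(targetMap(sim$truth))))
    expect_lt(abs(mean(div[nt])), 0.1)
})

test_that("null expression generator shows no target shift", {
    cfg <- simConfig(seed = 10, nMirna = 20, nGenes = 800, depth = 2e4,
                     deFraction = 0.25, deFold = 4, targetDensity = 40,
                     targetEffect = 0)
    sim <- simulateReadStacks(cfg)
    expr <- simulateExpression(cfg, sim$truth)
    m <- SummarizedExperiment::assay(expr$mrna, "log2")
    species <- SummarizedExperiment::colData(expr$mrna)$species
    div <- rowMeans(m[, species == "human"]) -
        rowMeans(m[, species == "chimpanzee"])
    tg <- unique(unlist(targetMap(sim$truth)))
    nt <- setdiff(rownames(m), tg)
    expect_gt(t.test(div[tg], div[nt])$p.value, 0.01)
})

test_that("transfection generator implants inhibition and mock concordance", {
    cfg <- simConfig(seed = 12, nMirna = 10, nGenes = 2000, depth = 1e4,
                     targetDensity = 80, targetEffect = 1, noiseSd = 0.3)
    sim <- simulateReadStacks(cfg)
    id <- names(targetMap(sim$truth))[1]
    tf1 <- simulateTransfection(cfg, sim$truth, id)
    tf2 <- simulateTransfection(cfg, sim$truth, id)
    expect_identical(tf1, tf2)                       # determinism
    expect_error(simulateTransfection(cfg, sim$truth, "mir-none"),
                 "unknown miRNA")
    tg <- attr(tf1, "trueTargets")
    eff <- rowMeans(tf1$cellA)
    expect_lt(mean(eff[tg]), -0.7)                   # implanted shift
    expect_lt(abs(mean(eff[setdiff(names(eff), tg)])), 0.1)
    # mock replicates agree because off-target response is shared
    expect_gt(cor(tf1$cellA[, "mock1"], tf1$cellA[, "mock2"]), 0.9)
})

test_that("snp track matches background and implanted excess", {
    sw <- data.frame(start = 50000, end = 100000, excess = 0.3)
    cfg <- simConfig(seed = 3, nMirna = 10, snpDensity = 0.005,
                     snpBackground = 0.05, sweepWindows = sw)
    sim <- simulateReadStacks(cfg)
    snp <- simulateSnpTrack(cfg, sim$loci[1:5])
    der <- classifyDerived(snp$snps$derived_count, snp$snps$nea_ancestral)
    first <- snp$snps$mirna_id == lociTable(sim$loci)$mirna_id[1]
    reg <- lociTable(sim$loci)$precursor_start0[1] - cfg@snpRegionLength
    rel <- GenomicRanges::start(snp$snps) - 1L - reg
    inWin <- first & rel >= 50000 & rel < 100000
    expect_gt(mean(der[inWin]), 0.25)                # ~0.35 expected
    expect_lt(mean(der[first & !inWin]), 0.10)       # ~0.05 expected
    expect_lt(mean(der[!first]), 0.10)
    # determinism and empty-region degenerate case
    snp2 <- simulateSnpTrack(cfg, sim$loci[1:5])
    expect_identical(snp, snp2)
    cfg0 <- simConfig(seed = 3, nMirna = 10, snpDensity = 0,
                      genomeSnpTotal = 0)
    snp0 <- simulateSnpTrack(cfg0, sim$loci[1:2])
    expect_identical(length(snp0$snps), 0L)
    expect_identical(unname(snp0$genomeTotals), c(0, 0))
})

test_that("null snp regions are consistent with the background rate", {
    fails <- 0L
    for (s in 1:30) {
        cfg <- simConfig(seed = s, nMirna = 3, snpDensity = 0.002,
                         snpBackground = 0.05)
        sim <- simulateReadStacks(cfg)
        snp <- simulateSnpTrack(cfg, sim$loci[1])
        der <- classifyDerived(snp$snps$derived_count,
                               snp$snps$nea_ancestral)
        p <- binom.test(sum(der), length(der), 0.05)$p.value
        if (p < 0.01) fails <- fails + 1L
    }
    expect_lte(fails, 2L)   # ~1% expected failure rate at alpha 0.01
})
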