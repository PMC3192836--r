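test_that("quantile normalization equalizes column distributions", {
    m <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
    got <- quantileNormalize(m)
    expect_equal(unname(got[, "a"]), c(2.5, 3.5, 4.5))
    expect_equal(unname(got[, "b"]), c(2.5, 3.5, 4.5))
    # identical columns are a fixed point
    m2 <- cbind(x = c(5, 1, 9), y = c(5, 1, 9))
    expect_equal(quantileNormalize(m2), m2)
    # equal column sums afterwards, any input
    set.seed(4)
    m3 <- matrix(rexp(60), 20, 3)
    expect_equal(diff(range(colSums(quantileNormalize(m3)))), 0)
    expect_warning(quantileNormalize(m3[, 1, drop = FALSE]), "no-op")
})

test_that("tpm normalization is a straight rescaling", {
    expect_equal(tpmNormalize(10, 1e6), 10)
    expect_equal(tpmNormalize(0, 123), 0)
    cnt <- c(5, 10, 85)
    expect_equal(sum(tpmNormalize(cnt, sum(cnt))), 1e6)
    expect_error(tpmNormalize(5, 0), "> 0")
})

test_that("count-library Fisher test matches the enumeration oracle", {
    expect_equal(fisherCountTest(5, 100, 5, 100), 1.0)
    expect_equal(fisherCountTest(0, 10, 0, 10), 1.0)
    expect_equal(fisherCountTest(12, 1000, 2, 1000),
                 fisherOracle2s(12, 1000, 2, 1000))
    expect_error(fisherCountTest(11, 10, 0, 10), "exceeds")

    # exhaustive sweep over all tables with small margins
    for (N1 in c(3, 7, 12)) for (N2 in c(4, 9, 15)) {
        for (c1 in 0:N1) for (c2 in 0:N2) {
            expect_equal(fisherCountTest(c1, N1, c2, N2),
                         fisherOracle2s(c1, N1, c2, N2),
                         tolerance = 1e-12)
        }
    }
    # random tables up to N1 + N2 = 200
    set.seed(19)
    for (i in 1:200) {
        N1 <- sample(1:100, 1); N2 <- sample(1:100, 1)
        c1 <- sample(0:N1, 1); c2 <- sample(0:N2, 1)
        expect_equal(fisherCountTest(c1, N1, c2, N2),
                     fisherOracle2s(c1, N1, c2, N2), tolerance = 1e-12)
    }
})

test_that("sequencing DE calls recover implants and respect all filters", {
    cfg <- simConfig(seed = 2, nMirna = 200, depth = 1e5,
                     deFraction = 0.1, deFold = 4)
    sim <- simulateReadStacks(cfg)
    se <- quantifyAll(sim$stacks, sim$loci)
    calls <- callDeSeq(se, normalize = "tpm")
    de <- deMirna(sim$truth)
    hc <- de[de$up_species %in% c("human", "chimpanzee"), ]
    expect_gte(mean(calls$passed[match(hc$mirna_id, calls$mirna_id)]),
               0.95)
    # direction of the call matches the implanted up-species
    got <- calls[match(hc$mirna_id, calls$mirna_id), ]
    expect_identical(got$direction[got$passed],
                     paste0("up-in-", hc$up_species[got$passed]))
    # no false positives among null miRNA here
    nulls <- setdiff(calls$mirna_id, de$mirna_id)
    expect_lte(mean(calls$passed[match(nulls, calls$mirna_id)]), 0.02)

    # detection filter: 9 reads everywhere can never pass
    m <- matrix(c(9L, 9L, 0L, 0L), 1,
                dimnames = list("m1", c("h1", "h2", "c1", "c2")))
    info <- data.frame(species = c("human", "human", "chimpanzee",
                                   "chimpanzee"),
                       replicate = c(1, 2, 1, 2))
    expect_false(callDeSeq(m, info, normalize = "none")$passed)

    # swapping species labels flips direction but not the decision
    sw <- callDeSeq(se, species1 = "chimpanzee", species2 = "human",
                    normalize = "tpm")
    expect_identical(calls$passed, sw$passed)
    expect_equal(calls$fold_change, 1 / sw$fold_change, tolerance = 1e-9)
})

test_that("single-replicate mode is flagged", {
    m <- matrix(c(200L, 10L, 1000L, 1100L), 2, byrow = TRUE,
                dimnames = list(c("m1", "m2"), c("h1", "c1")))
    info <- data.frame(species = c("human", "chimpanzee"),
                       replicate = c(1, 1))
    calls <- callDeSeq(m, info, normalize = "none")
    expect_true(attr(calls, "single_replicate"))
    expect_true(calls$passed[1])
    expect_false(calls$passed[2])
})

test_that("null count data give calibrated or conservative p-values", {
    psT <- c(); psQ <- c()
    for (s in 1:10) {
        cfg <- simConfig(seed = s, nMirna = 200, depth = 1e5,
                         deFraction = 0)
        sim <- simulateReadStacks(cfg)
        se <- quantifyAll(sim$stacks, sim$loci)
        psT <- c(psT, callDeSeq(se, normalize = "tpm")$p_rep1)
        psQ <- c(psQ, callDeSeq(se, normalize = "quantile")$p_rep1)
    }
    # TPM path: uniform (the exact hypergeometric null holds)
    expect_gt(suppressWarnings(ks.test(psT, "punif")$p.value), 0.001)
    # both paths: empirical CDF never exceeds the diagonal by > 0.03
    grid <- seq(0, 1, 0.01)
    expect_lt(max(ecdf(psT)(grid) - grid), 0.03)
    expect_lt(max(ecdf(psQ)(grid) - grid), 0.03)
})

test_that("array DE calls use the t-test and drop masked probes", {
    set.seed(6)
    base <- matrix(rnorm(50 * 6, 8, 0.3), 50, 6,
                   dimnames = list(sprintf("mir-%02d", 1:50),
                                   c(paste0("h", 1:3), paste0("c", 1:3))))
    base["mir-01", 1:3] <- base["mir-01", 1:3] + 3   # strong implant
    species <- rep(c("human", "chimpanzee"), each = 3)
    calls <- callDeArray(base, species)
    expect_true(calls$passed[calls$mirna_id == "mir-01"])
    # identical groups never pass
    flat <- base; flat[, 4:6] <- flat[, 1:3]
    expect_false(any(callDeArray(flat, species)$passed))
    # masked miRNA are absent from the output
    calls2 <- callDeArray(base, species, masked = "mir-01")
    expect_false("mir-01" %in% calls2$mirna_id)
    # t statistic equals the closed form on a 3+3 toy vector
    x <- c(1.0, 1.2, 0.8); y <- c(2.0, 2.1, 1.9)
    tt <- t.test(x, y, var.equal = FALSE)$p.value
    toy <- matrix(c(x, y), 1, dimnames = list("m", NULL))
    expect_equal(callDeArray(toy, species, alpha = 1, fc = 1)$p_value, tt)
})

test_that("external exact-test tables are filtered on p and FDR", {
    tab <- data.frame(mirna_id = c("a", "b", "c"),
                      p_value = c(1e-4, 1e-4, 0.01),
                      fdr = c(0.001, 0.5, 0.001))
    expect_identical(filterExactTestTable(tab)$mirna_id, "a")
})

test_that("direction consistency reproduces the proportion arithmetic", {
    expect_identical(consistencyStats(31, 37)$percent, 84)
    expect_identical(consistencyStats(82, 106)$percent, 77)
    full <- consistencyStats(37, 37)
    expect_identical(full$percent, 100)
    expect_equal(full$binomial_p, 0.5^37)
    expect_error(consistencyStats(0, 0), ">= 1")

    callsA <- data.frame(mirna_id = c("a", "b", "c"),
                         fold_change = c(3, 0.2, 4),
                         passed = c(TRUE, TRUE, FALSE))
    callsB <- data.frame(mirna_id = c("a", "b", "c"),
                         fold_change = c(2, 3, 4))
    got <- directionConsistency(callsA, callsB)
    expect_identical(got$n_shared, 2L)
    expect_identical(got$n_consistent, 1L)
    expect_identical(got$percent, 50)
})

test_that("lineage assignment uses the outgroup distance rule", {
    expect_identical(assignLineage(100, 10, 12), "human")
    expect_identical(assignLineage(10, 100, 12), "chimpanzee")
    expect_identical(assignLineage(100, 10, 55), "unassigned")
    # intermediate human level, chimpanzee farthest from the outgroup
    expect_identical(assignLineage(50, 80, 10), "chimpanzee")
    out <- assignLineage(10, 20, NA)
    expect_identical(as.character(out), "unassigned")
    expect_true(attr(out, "missing_outgroup"))
})

test_that("UPGMA clustering reproduces hand agglomeration and topology", {
    # 3-leaf toy: d(A,B)=2, d(A,C)=d(B,C)=8 -> (A,B) at height 1, C at 4
    # build columns whose correlation distances are exactly those values
    d <- matrix(c(0, 2, 8, 2, 0, 8, 8, 8, 0), 3,
                dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
    tree <- ape::as.phylo(hclust(as.dist(d), method = "average"))
    bt <- sort(unname(ape::branching.times(tree)))
    expect_equal(bt, c(1, 4))

    # constant column is rejected by name
    m <- cbind(s1 = c(1, 2, 3), s2 = c(2, 1, 3), s3 = c(5, 5, 5))
    expect_error(upgmaCluster(m), "s3")

    # two identical columns merge first at height 0
    m2 <- cbind(x = c(1, 2, 3, 1), y = c(1, 2, 3, 1), z = c(4, 1, 2, 9))
    tr <- upgmaCluster(m2)
    expect_equal(min(ape::branching.times(tr)), 0, tolerance = 1e-12)

    # implanted phylogenetic signal: human and chimpanzee are sisters
    cfg <- simConfig(seed = 14, nMirna = 150, depth = 5e4, deFraction = 0,
                     phyloSd = 0.5)
    sim <- simulateReadStacks(cfg)
    se <- quantifyAll(sim$stacks, sim$loci)
    lm <- log2(SummarizedExperiment::assay(se, "counts") + 1)
    tr3 <- upgmaCluster(lm)
    hc <- grep("human|chimpanzee", tr3$tip.label, value = TRUE)
    expect_true(ape::is.monophyletic(tr3, hc))
})

test_that("Q-PCR relative expression is the negated delta-Ct", {
    expect_identical(qpcrRelativeExpression(25, 25), 0)
    expect_identical(qpcrRelativeExpression(24, 25), 1)
    expect_identical(qpcrRelativeExpression(27, 25), -2)
    expect_error(qpcrRelativeExpression(-1, 25))
})
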