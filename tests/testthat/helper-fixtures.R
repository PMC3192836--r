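# Small fixtures built in code.

toyLocus <- function(precursor = strrep("ACGT", 25), matureStart = 10L,
                     matureLen = 22L, strand = "+", anchor = 1000L,
                     id = "mir-t1") {
    MirnaLoci(data.frame(
        mirna_id = id, precursor_id = paste0(id, "-pre"),
        species = "human", precursor_seq = precursor, arm = "5p",
        mature_start0 = matureStart, mature_end0 = matureStart + matureLen,
        chrom = "chr1", strand = strand, precursor_start0 = anchor,
        stringsAsFactors = FALSE))
}

toyStack <- function(records, sampleId = "s1") {
    ReadStack(sampleId, records)
}

stackRecord <- function(sequence, pos0, copies, chrom = "chr1",
                        strand = "+") {
    data.frame(sequence = sequence, chrom = chrom, pos0 = pos0,
               strand = strand, copies = copies, stringsAsFactors = FALSE)
}

smallSim <- function(seed = 11, ...) {
    simulateReadStacks(simConfig(seed = seed, nMirna = 30, depth = 2e4,
                                 nGenes = 300, ...))
}
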