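## Shared format readers/writers, configuration and the run manifest.
## All genomic coordinates are 0-based half-open internally; the BED-like
## SNP format is written natively, other 1-based formats are converted at
## the boundary. Writers emit a fixed column order with "\n" line endings,
## so identical objects produce bit-identical files.

stopParse <- function(path, line, field, why) {
    stop(sprintf("%s: line %d, field '%s': %s", path, line, field, why))
}

#' Read/write a read stack as TSV
#'
#' Columns: \code{sequence, chrom, pos0, strand, copies}.
#'
#' @param path file path.
#' @param sampleId sample label for the returned [ReadStack-class]
#'   (defaults to the file base name).
#' @return [readReadStack()] returns a [ReadStack-class];
#'   [writeReadStack()] returns the path invisibly.
#' @export
readReadStack <- function(path, sampleId = NULL) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("sequence", "chrom", "pos0", "strand", "copies")
    if (!all(need %in% names(df)))
        stop(path, ": expected columns ", paste(need, collapse = ", "))
    ReadStack(sampleId %||% sub("\\.tsv$", "", basename(path)), df[need])
}

#' @rdname readReadStack
#' @param stack a [ReadStack-class].
#' @export
writeReadStack <- function(stack, path) {
    utils::write.table(
        readRecords(stack)[c("sequence", "chrom", "pos0", "strand",
                             "copies")],
        path, sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n")
    invisible(path)
}

#' Read/write miRNA precursor annotations
#'
#' Precursor sequences travel as FASTA (via \pkg{Biostrings}); the mature
#' coordinates and genomic anchors as a TSV with columns
#' \code{mirna_id, precursor_id, species, arm, mature_start0, mature_end0,
#' chrom, strand, precursor_start0}.
#'
#' @param fastaPath,annotPath file paths.
#' @return [readMirnaLoci()] returns a [MirnaLoci-class].
#' @export
readMirnaLoci <- function(fastaPath, annotPath) {
    seqs <- Biostrings::readDNAStringSet(fastaPath)
    ann <- utils::read.delim(annotPath, stringsAsFactors = FALSE)
    key <- paste(ann$precursor_id, ann$species, sep = "|")
    m <- match(key, names(seqs))
    if (anyNA(m))
        stop(annotPath, ": precursor(s) missing from FASTA: ",
             paste(head(ann$precursor_id[is.na(m)]), collapse = ", "))
    ann$precursor_seq <- as.character(seqs)[m]
    MirnaLoci(ann[c("mirna_id", "precursor_id", "species",
                    "precursor_seq", "arm", "mature_start0",
                    "mature_end0", "chrom", "strand",
                    "precursor_start0")])
}

#' @rdname readMirnaLoci
#' @param loci a [MirnaLoci-class].
#' @export
writeMirnaLoci <- function(loci, fastaPath, annotPath) {
    tab <- lociTable(loci)
    seqs <- Biostrings::DNAStringSet(chartr("Uu", "Tt", tab$precursor_seq))
    names(seqs) <- paste(tab$precursor_id, tab$species, sep = "|")
    Biostrings::writeXStringSet(seqs, fastaPath)
    utils::write.table(
        tab[c("mirna_id", "precursor_id", "species", "arm",
              "mature_start0", "mature_end0", "chrom", "strand",
              "precursor_start0")],
        annotPath, sep = "\t", quote = FALSE, row.names = FALSE,
        eol = "\n")
    invisible(c(fastaPath, annotPath))
}

#' Read/write a labeled numeric matrix as TSV
#'
#' Row ids in the first column, sample ids in the header. Duplicate row or
#' column ids are an error naming the offender.
#'
#' @param path file path.
#' @return matrix with dimnames.
#' @export
readMatrixTsv <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            check.names = FALSE)
    ids <- df[[1L]]
    if (anyDuplicated(ids))
        stop(path, ": duplicate row id '", ids[duplicated(ids)][1L], "'")
    if (anyDuplicated(names(df)[-1L]))
        stop(path, ": duplicate sample id '",
             names(df)[-1L][duplicated(names(df)[-1L])][1L], "'")
    m <- as.matrix(df[-1L])
    rownames(m) <- ids
    m
}

#' @rdname readMatrixTsv
#' @param m matrix with dimnames.
#' @param idColumn header of the id column (default "id").
#' @export
writeMatrixTsv <- function(m, path, idColumn = "id") {
    df <- data.frame(rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    names(df)[1L] <- idColumn
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, eol = "\n")
    invisible(path)
}

#' Read/write the derived-SNP track (BED-like TSV)
#'
#' Columns: \code{chrom, pos0, end, derived_count, nea_ancestral} with
#' \code{end == pos0 + 1} enforced and \code{nea_ancestral} coded 0/1.
#'
#' @param path file path.
#' @return a \code{GRanges} with metadata columns \code{derived_count},
#'   \code{nea_ancestral}.
#' @export
readSnpBed <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("chrom", "pos0", "end", "derived_count", "nea_ancestral")
    if (!all(need %in% names(df)))
        stop(path, ": expected columns ", paste(need, collapse = ", "))
    bad <- which(df$end != df$pos0 + 1L)
    if (length(bad))
        stopParse(path, bad[1L] + 1L, "end", "end must equal pos0 + 1")
    bad <- which(df$derived_count < 0L | df$derived_count > 6L)
    if (length(bad))
        stopParse(path, bad[1L] + 1L, "derived_count", "must be in 0..6")
    GenomicRanges::GRanges(df$chrom,
                           IRanges::IRanges(start = df$pos0 + 1L,
                                            width = 1L),
                           derived_count = as.integer(df$derived_count),
                           nea_ancestral = df$nea_ancestral == 1L)
}

#' @rdname readSnpBed
#' @param snps a \code{GRanges} as returned by [readSnpBed()] or
#'   [simulateSnpTrack()].
#' @export
writeSnpBed <- function(snps, path) {
    df <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(snps)),
        pos0 = GenomicRanges::start(snps) - 1L,
        end = GenomicRanges::start(snps),
        derived_count = snps$derived_count,
        nea_ancestral = as.integer(snps$nea_ancestral))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, eol = "\n")
    invisible(path)
}

#' Write a dendrogram as Newick
#'
#' @param tree an \code{ape} \code{"phylo"} object (e.g. from
#'   [upgmaCluster()]).
#' @param path file path.
#' @export
writeNewick <- function(tree, path) {
    ape::write.tree(tree, file = path)
    invisible(path)
}

#' Load a simulation configuration from YAML
#'
#' Keys mirror the arguments of [simConfig()]; \code{sweepWindows} is a
#' list of mappings with \code{start}, \code{end}, \code{excess} (and
#' optional \code{mirna_id}).
#'
#' @param path YAML file.
#' @return a validated [SimConfig-class].
#' @export
loadSimConfig <- function(path) {
    y <- yaml::read_yaml(path)
    if (!is.null(y$sweepWindows))
        y$sweepWindows <- do.call(rbind, lapply(y$sweepWindows,
                                                as.data.frame))
    do.call(simConfig, y)
}

#' Write a ground truth object as YAML
#'
#' @param truth a [GroundTruth-class].
#' @param path YAML file.
#' @export
writeGroundTruth <- function(truth, path) {
    yaml::write_yaml(list(
        de_mirna = as.list(truth@deMirna),
        target_map = truth@targetMap,
        sweep_windows = as.list(truth@sweepWindows)), path)
    invisible(path)
}

#' Seeded-run manifest
#'
#' Records everything needed to reproduce a run: the configuration hash,
#' the seed, the package version and md5 checksums of the input files.
#'
#' @param cfg a [SimConfig-class] (or any serializable configuration).
#' @param inputFiles character vector of file paths.
#' @return list with \code{config_hash}, \code{seed}, \code{package},
#'   \code{version}, \code{input_checksums}, \code{timestamp}.
#' @export
runManifest <- function(cfg, inputFiles = character(0)) {
    tmp <- tempfile()
    on.exit(unlink(tmp))
    saveRDS(cfg, tmp)
    list(config_hash = unname(tools::md5sum(tmp)),
         seed = if (is(cfg, "SimConfig")) cfg@seed else NA_integer_,
         package = "mirdiv",
         version = as.character(utils::packageVersion("mirdiv")),
         input_checksums = as.list(tools::md5sum(inputFiles)),
         timestamp = format(Sys.time(), tz = "UTC"))
}
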