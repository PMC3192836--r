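## Consensus ortholog assignment from multi-method hit tables and mature
## coordinate projection via precursor alignment.

#' Hit-length plausibility filter
#'
#' A mapped hit is kept only when its length is strictly more than 70% and
#' strictly less than 130% of the query precursor length.
#'
#' @param queryLen,hitLen positive lengths (vectorized).
#' @return logical vector.
#' @examples
#' filterHitByLength(100, c(70, 71, 129, 130))
#' @export
filterHitByLength <- function(queryLen, hitLen) {
    if (any(queryLen <= 0) || any(hitLen <= 0))
        stop("lengths must be positive")
    hitLen > 0.70 * queryLen & hitLen < 1.30 * queryLen
}

#' Call a precursor ortholog from multi-method hits
#'
#' Hits for one query precursor (already length-filtered) are grouped into
#' candidate loci by 50% reciprocal overlap of their target intervals; a
#' locus supported by at least 2 of the 3 mapping methods is called. If no
#' locus reaches 2 methods the result is \code{NULL}; if two or more loci
#' do, the query is ambiguous and \code{NULL} is returned with attribute
#' \code{"ambiguous" = TRUE}.
#'
#' @param hits data.frame with columns \code{query_id}, \code{method},
#'   \code{chrom}, \code{start0}, \code{end0} for a single query.
#' @param minMethods minimal number of distinct supporting methods.
#' @return \code{NULL}, or a list with \code{query_id}, \code{chrom},
#'   \code{start0}, \code{end0} (merged span of the supporting hits) and
#'   \code{supporting_methods}.
#' @export
callOrtholog <- function(hits, minMethods = 2L) {
    if (!nrow(hits)) return(NULL)
    if (length(unique(hits$query_id)) != 1L)
        stop("hits must all belong to one query precursor")
    n <- nrow(hits)
    ## same-locus relation: same chrom and >= 50% mutual overlap
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(n)) for (j in seq_len(n)) {
        if (j <= i) next
        if (hits$chrom[i] != hits$chrom[j]) next
        ov <- min(hits$end0[i], hits$end0[j]) -
              max(hits$start0[i], hits$start0[j])
        li <- hits$end0[i] - hits$start0[i]
        lj <- hits$end0[j] - hits$start0[j]
        if (ov >= 0.5 * li && ov >= 0.5 * lj)
            parent[find(i)] <- find(j)
    }
    comp <- vapply(seq_len(n), find, 1L)
    loci <- lapply(unique(comp), function(g) {
        sub <- hits[comp == g, , drop = FALSE]
        list(query_id = sub$query_id[1L], chrom = sub$chrom[1L],
             start0 = min(sub$start0), end0 = max(sub$end0),
             supporting_methods = sort(unique(sub$method)))
    })
    supported <- loci[vapply(loci, function(l)
        length(l$supporting_methods) >= minMethods, TRUE)]
    if (length(supported) == 1L) return(supported[[1L]])
    if (length(supported) > 1L)       # two well-supported loci: ambiguous
        return(structure(list(), class = "ambiguousOrtholog"))
    NULL
}

#' Test whether an ortholog call is ambiguous
#'
#' @param call result of [callOrtholog()].
#' @return TRUE when two or more candidate loci each had sufficient method
#'   support.
#' @export
isAmbiguous <- function(call) inherits(call, "ambiguousOrtholog")

#' Project a mature miRNA onto an orthologous precursor
#'
#' Globally aligns the two precursor sequences (match +1, mismatch -1, gap
#' open -5, gap extend -1) and returns the target-precursor characters
#' aligned to the query mature interval, with gap columns dropped, together
#' with the projected interval (0-based half-open) on the target.
#'
#' @param querySeq,targetSeq precursor sequences (ACGT/ACGU).
#' @param matureStart0,matureEnd0 mature interval on the query, 0-based
#'   half-open.
#' @return list with \code{sequence}, \code{start0}, \code{end0}.
#' @export
extractMatureOrtholog <- function(querySeq, targetSeq, matureStart0,
                                  matureEnd0) {
    if (!nzchar(querySeq) || !nzchar(targetSeq))
        stop("precursor sequences must be non-empty")
    stopifnot(matureStart0 >= 0, matureEnd0 > matureStart0,
              matureEnd0 <= nchar(querySeq))
    qd <- chartr("Uu", "Tt", toupper(querySeq))
    td <- chartr("Uu", "Tt", toupper(targetSeq))
    sub <- Biostrings::nucleotideSubstitutionMatrix(match = 1,
                                                    mismatch = -1)
    al <- Biostrings::pairwiseAlignment(qd, td, type = "global",
                                        substitutionMatrix = sub,
                                        gapOpening = 5, gapExtension = 1)
    qa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1L]]
    ta <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1L]]
    qpos <- cumsum(qa != "-")          # query coordinate at each column
    tpos <- cumsum(ta != "-")          # target coordinate at each column
    inMature <- qa != "-" & qpos > matureStart0 & qpos <= matureEnd0
    keep <- inMature & ta != "-"
    if (!any(keep)) stop("mature unalignable")
    tIdx <- tpos[keep]                 # 1-based target positions
    list(sequence = substr(targetSeq, min(tIdx), max(tIdx)),
         start0 = min(tIdx) - 1L, end0 = max(tIdx))
}

#' Should an array probe for this miRNA be masked?
#'
#' Cross-species hybridization to a single probe is unreliable as soon as
#' the mature sequences differ, so the probe is masked when the two mature
#' sequences differ at any position or in length. RNA/DNA alphabet and case
#' are normalized first.
#'
#' @param matureA,matureB mature sequences.
#' @return logical.
#' @examples
#' maskForArray("ACGUACGU", "ACGTACGT")  # FALSE: same sequence
#' maskForArray("ACGUACGU", "ACGAACGU")  # TRUE
#' @export
maskForArray <- function(matureA, matureB) {
    if (!nzchar(matureA) || !nzchar(matureB))
        stop("mature sequences must be non-empty")
    norm <- function(s) chartr("Uu", "Tt", toupper(s))
    norm(matureA) != norm(matureB)
}
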