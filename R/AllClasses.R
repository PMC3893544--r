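#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom Biostrings AAStringSet DNAStringSet BStringSet width
NULL

#' Grouped multiple sequence alignment
#'
#' An aligned set of sequences (rows of equal width, gap character
#' \code{-}) together with a named partition of the rows into groups
#' (e.g. a donor clade, the recipient lineage, an outgroup).  Groups
#' need not cover all rows but must be disjoint subsets of the row ids.
#'
#' @slot seqs An [Biostrings::XStringSet-class] (AA or DNA) of aligned rows,
#'   all of equal width, with unique names.
#' @slot groups Named list of character vectors of row ids.
#'
#' @seealso [groupedAlignment()], [alnSeqs()], [alnGroups()]
#' @exportClass GroupedAlignment
setClass("GroupedAlignment",
    representation(seqs = "XStringSet", groups = "list"))

setValidity("GroupedAlignment", function(object) {
    msg <- character()
    nm <- names(object@seqs)
    if (is.null(nm) || anyDuplicated(nm))
        msg <- c(msg, "alignment rows must have unique names")
    if (length(object@seqs) && length(unique(width(object@seqs))) != 1L)
        msg <- c(msg, "alignment rows must have equal width")
    members <- unlist(object@groups, use.names = FALSE)
    if (!all(members %in% nm))
        msg <- c(msg, "group members must be row ids")
    if (anyDuplicated(members))
        msg <- c(msg, "groups must be disjoint")
    if (length(msg)) msg else TRUE
})

#' Construct a GroupedAlignment
#'
#' @param seqs Named [Biostrings::AAStringSet-class] or
#'   [Biostrings::DNAStringSet-class] of equal-width aligned rows.
#' @param groups Named list of character vectors of row ids (may be empty).
#' @return A [GroupedAlignment-class] object.
#' @examples
#' aln <- groupedAlignment(
#'     Biostrings::AAStringSet(c(a = "MK-A", b = "MKLA")),
#'     groups = list(g1 = "a"))
#' alnWidth(aln)
#' @export
groupedAlignment <- function(seqs, groups = list()) {
    new("GroupedAlignment", seqs = seqs, groups = groups)
}

#' @describeIn groupedAlignment Aligned rows as an XStringSet.
#' @param x A \code{GroupedAlignment}.
#' @export
alnSeqs <- function(x) x@seqs

#' @describeIn groupedAlignment Named list of row-id groups.
#' @export
alnGroups <- function(x) x@groups

#' @describeIn groupedAlignment Number of alignment columns.
#' @export
alnWidth <- function(x) if (length(x@seqs)) width(x@seqs)[1L] else 0L

#' @describeIn groupedAlignment Alignment as a character matrix
#'   (rows = sequences, columns = alignment columns).
#' @export
alnMatrix <- function(x) {
    m <- do.call(rbind, strsplit(as.character(x@seqs), "", fixed = TRUE))
    rownames(m) <- names(x@seqs)
    m
}

setMethod("show", "GroupedAlignment", function(object) {
    cat("GroupedAlignment with", length(object@seqs), "rows x",
        alnWidth(object), "columns\n")
    if (length(object@groups))
        cat("groups:", paste(sprintf("%s(%d)", names(object@groups),
            lengths(object@groups)), collapse = ", "), "\n")
})

#' Exon/intron structure of a gene on its genomic sequence
#'
#' Intervals are stored 1-based inclusive (the convention of
#' [IRanges::IRanges-class]); introns are exactly the gaps between
#' consecutive exons.
#'
#' @slot gene_id Gene identifier.
#' @slot exons [IRanges::IRanges-class] of exon intervals, ordered,
#'   non-overlapping.
#' @slot introns [IRanges::IRanges-class] of intron intervals.
#' @slot strand "+" or "-".
#' @exportClass GeneStructure
setClass("GeneStructure",
    representation(gene_id = "character", exons = "IRanges",
                   introns = "IRanges", strand = "character"))

setValidity("GeneStructure", function(object) {
    ex <- object@exons
    if (length(ex) > 1L) {
        s <- IRanges::start(ex); e <- IRanges::end(ex)
        if (is.unsorted(s) || any(s[-1L] <= e[-length(e)]))
            return("exons must be ordered and non-overlapping")
        gaps <- IRanges::IRanges(e[-length(e)] + 1L, s[-1L] - 1L)
        if (length(gaps) != length(object@introns) ||
            any(IRanges::start(gaps) != IRanges::start(object@introns)) ||
            any(IRanges::end(gaps) != IRanges::end(object@introns)))
            return("introns must be exactly the gaps between exons")
    }
    if (!object@strand %in% c("+", "-")) return("strand must be + or -")
    TRUE
})

#' @describeIn mapIntrons Construct a GeneStructure from exon intervals;
#'   introns are derived as the inter-exon gaps.
#' @param gene_id Gene identifier.
#' @param exons IRanges of exon intervals (1-based inclusive).
#' @param strand "+" or "-".
#' @export
geneStructure <- function(gene_id, exons, strand = "+") {
    introns <- if (length(exons) > 1L) {
        IRanges::IRanges(IRanges::end(exons)[-length(exons)] + 1L,
                         IRanges::start(exons)[-1L] - 1L)
    } else IRanges::IRanges()
    new("GeneStructure", gene_id = gene_id, exons = exons,
        introns = introns, strand = strand)
}

#' @describeIn mapIntrons Exon intervals of a GeneStructure.
#' @export
exons <- function(x) x@exons

#' @describeIn mapIntrons Intron intervals of a GeneStructure.
#' @export
introns <- function(x) x@introns

setMethod("show", "GeneStructure", function(object) {
    cat("GeneStructure for", object@gene_id, "(", object@strand, "):",
        length(object@exons), "exons,", length(object@introns),
        "introns\n")
    if (length(object@introns)) {
        cat("  intron positions:",
            paste(sprintf("%d-%d", IRanges::start(object@introns),
                          IRanges::end(object@introns)), collapse = ", "),
            "\n")
    }
})

#' Result of the alien-index screening stage
#'
#' One row per query that reached the scoring stage, carrying the best
#' in-group and out-group hits, the score ratio, the candidate call and
#' any flags.  Produced by [alienScore()] and [runScreen()].
#'
#' @slot verdicts A [S4Vectors::DataFrame-class] with columns
#'   \code{query_id}, \code{best_ingroup_id}, \code{best_ingroup_score},
#'   \code{best_outgroup_id}, \code{best_outgroup_score}, \code{ratio},
#'   \code{is_candidate}, \code{flags} (comma-joined).
#' @slot config List of screening parameters used.
#' @exportClass AlienScreen
setClass("AlienScreen",
    representation(verdicts = "DataFrame", config = "list"))

#' @describeIn alienScore Verdict table of an AlienScreen as a DataFrame.
#' @export
verdicts <- function(x) x@verdicts

#' @describeIn alienScore Query ids called as HGT candidates.
#' @export
candidates <- function(x) {
    v <- x@verdicts
    as.character(v$query_id[v$is_candidate])
}

setMethod("show", "AlienScreen", function(object) {
    v <- object@verdicts
    cat("AlienScreen:", nrow(v), "queries scored,",
        sum(v$is_candidate), "candidates (ratio threshold",
        object@config$ratio_threshold, ")\n")
})

#' Type-I functional divergence fit
#'
#' Maximum-likelihood fit of the two-cluster Poisson-gamma rate mixture:
#' with probability \eqn{1-\theta_1} a site shares one gamma-distributed
#' rate between the clusters, with probability \eqn{\theta_1} the rates
#' are independent.
#'
#' @slot theta1 ML estimate of the divergence coefficient.
#' @slot se Standard error of theta1 (observed information).
#' @slot alpha Gamma shape estimate.
#' @slot lnL0,lnL1 Log-likelihoods under theta1 = 0 and free theta1.
#' @slot lrt Likelihood-ratio statistic 2(lnL1 - lnL0).
#' @slot p_value Chi-square p-value (1 df, the field's convention).
#' @slot p_value_mixture Boundary-corrected p (50:50 chi0/chi1 mixture).
#' @slot posterior Per-site posterior probability of rate divergence.
#' @slot mle Named numeric of all fitted parameters.
#' @exportClass DivergenceFit
setClass("DivergenceFit",
    representation(theta1 = "numeric", se = "numeric", alpha = "numeric",
                   lnL0 = "numeric", lnL1 = "numeric", lrt = "numeric",
                   p_value = "numeric", p_value_mixture = "numeric",
                   posterior = "numeric", mle = "numeric"))

setMethod("show", "DivergenceFit", function(object) {
    cat(sprintf(
        "Type-I functional divergence: theta1 = %.4f +/- %.4f (alpha = %.3f)\n",
        object@theta1, object@se, object@alpha))
    cat(sprintf("  LRT = %.4f, p = %.4g (chi-square, 1 df)\n",
        object@lrt, object@p_value))
    cat(sprintf("  %d sites with posterior > 0.7\n",
        sum(object@posterior > 0.7)))
})

#' Fitted codon substitution model
#'
#' @slot model Model name ("M0", "M3", "M1a", "M2a", "M7", "M8",
#'   "branch-site-A", "branch-site-A-null").
#' @slot lnL Maximized log-likelihood.
#' @slot mle Named numeric vector of parameter estimates.
#' @slot classes data.frame of site classes (omega, proportion; for
#'   branch-site models the background/foreground omegas).
#' @slot posteriors Matrix (sites x classes) of NEB posteriors, or a
#'   0-row matrix for M0.
#' @slot branch_lengths Named numeric of edge lengths used.
#' @slot converged Logical convergence flag.
#' @exportClass CodonFit
setClass("CodonFit",
    representation(model = "character", lnL = "numeric", mle = "numeric",
                   classes = "data.frame", posteriors = "matrix",
                   branch_lengths = "numeric", converged = "logical"))

setMethod("show", "CodonFit", function(object) {
    cat(sprintf("CodonFit [%s]: lnL = %.4f%s\n", object@model, object@lnL,
        if (object@converged) "" else " (not converged)"))
    p <- object@mle
    cat("  ", paste(sprintf("%s = %.4g", names(p), p), collapse = ", "),
        "\n")
})

#' qPCR reference-gene stability report
#'
#' Per-gene stability under three measures (geNorm M, the DeltaCt
#' method's mean pairwise SD, BestKeeper's raw-Ct SD) and the composite
#' rank (geometric mean of the per-method ranks).
#'
#' @slot table data.frame with columns \code{gene}, \code{genorm_m},
#'   \code{delta_ct_sd}, \code{bestkeeper_sd}, per-method ranks, and
#'   \code{composite_rank}, ordered most to least stable.
#' @exportClass StabilityReport
setClass("StabilityReport", representation(table = "data.frame"))

#' @describeIn stabilityRank Stability table of a StabilityReport.
#' @export
stabilityTable <- function(x) x@table

setMethod("show", "StabilityReport", function(object) {
    cat("Reference-gene stability (most stable first):\n")
    print(object@table, row.names = FALSE, digits = 4)
})
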