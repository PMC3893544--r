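## Readers and writers for the external formats the pipeline touches.
## All sequence parsing is delegated to Biostrings; trees to ape.
## Internal coordinates are 0-based half-open; BLAST-dialect columns
## (1-based inclusive) are converted on ingest.

#' Read sequences from a FASTA file
#'
#' Ids are the first whitespace token of each header.  Lowercase
#' residues are uppercased (a message notes how many records were
#' affected).  Duplicate ids are an error; an empty file yields an
#' empty set with a warning.
#'
#' @param path Path to a FASTA file.
#' @param moltype "dna" or "protein".
#' @return A named [Biostrings::DNAStringSet-class] or
#'   [Biostrings::AAStringSet-class].
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">a", "ACGT"), tf)
#' readFastaSeqs(tf)
#' @export
readFastaSeqs <- function(path, moltype = c("dna", "protein")) {
    moltype <- match.arg(moltype)
    stopifnot(file.exists(path))
    raw <- Biostrings::readBStringSet(path)
    if (length(raw) == 0L) {
        warning("empty FASTA file: ", path)
        return(if (moltype == "dna") Biostrings::DNAStringSet()
               else Biostrings::AAStringSet())
    }
    names(raw) <- sub("\\s.*$", "", names(raw))
    dups <- unique(names(raw)[duplicated(names(raw))])
    if (length(dups))
        stop("duplicate FASTA ids in ", path, ": ",
             paste(dups, collapse = ", "))
    chr <- as.character(raw)
    low <- grepl("[a-z]", chr)
    if (any(low)) {
        message(sum(low), " record(s) contained lowercase residues; ",
                "uppercased")
        chr <- toupper(chr)
    }
    out <- if (moltype == "dna") Biostrings::DNAStringSet(chr)
           else Biostrings::AAStringSet(chr)
    names(out) <- names(raw)
    out
}

#' @describeIn readFastaSeqs Write a (possibly quality-less) XStringSet
#'   to FASTA.
#' @param records XStringSet to write.
#' @export
writeFastaSeqs <- function(records, path) {
    Biostrings::writeXStringSet(records, path)
    invisible(path)
}

#' Read a FASTQ file into a quality-scaled read set
#'
#' @param path FASTQ path.
#' @param quality_offset Phred offset, 33 by default.
#' @return A [Biostrings::QualityScaledDNAStringSet-class].
#' @export
readFastqReads <- function(path, quality_offset = 33L) {
    stopifnot(file.exists(path))
    Biostrings::readQualityScaledDNAStringSet(path,
        quality.scoring = if (quality_offset == 64L) "solexa" else "phred")
}

#' @describeIn readFastqReads Write reads (with qualities) as FASTQ.
#' @param reads A QualityScaledDNAStringSet.
#' @export
writeFastqReads <- function(reads, path) {
    Biostrings::writeQualityScaledXStringSet(reads, path)
    invisible(path)
}

#' Read a subject-to-lineage map
#'
#' Two-column TSV: subject id and a semicolon-joined lineage ordered
#' kingdom to species.
#'
#' @param path TSV path.
#' @return Named list of character lineage vectors.
#' @export
readLineageMap <- function(path) {
    stopifnot(file.exists(path))
    tab <- read.delim(path, header = FALSE, sep = "\t",
                      colClasses = "character", quote = "",
                      col.names = c("subject_id", "lineage"))
    if (anyDuplicated(tab$subject_id))
        stop("duplicate subject ids in lineage map: ", path)
    lin <- strsplit(tab$lineage, ";", fixed = TRUE)
    lin <- lapply(lin, trimws)
    if (any(lengths(lin) == 0L))
        stop("empty lineage in map: ", path)
    names(lin) <- tab$subject_id
    lin
}

#' @describeIn readLineageMap Write a lineage map to TSV.
#' @param lineages Named list of character lineage vectors.
#' @export
writeLineageMap <- function(lineages, path) {
    write.table(
        data.frame(subject_id = names(lineages),
                   lineage = vapply(lineages, paste, "", collapse = ";")),
        path, sep = "\t", quote = FALSE, row.names = FALSE,
        col.names = FALSE)
    invisible(path)
}

.HIT_COLS <- c("query_id", "subject_id", "percent_identity", "aln_length",
               "mismatches", "gap_opens", "qstart", "qend", "sstart",
               "send", "e_value", "bit_score")

#' Read a 12-column tabular homology-hit file
#'
#' Expects the classic 12-column tab-separated hit format (query,
#' subject, percent identity, alignment length, mismatches, gap opens,
#' qstart, qend, sstart, send, e-value, bit score).  Hits are joined
#' with a subject-to-lineage map, grouped by query and sorted by
#' descending bit score within query.  Query coordinates are converted
#' to 0-based half-open.
#'
#' @param path Hit-table TSV path.
#' @param lineage_map Named list from [readLineageMap()], or a path to
#'   a lineage-map TSV.
#' @param unmapped "drop" (default; drops hits whose subject has no
#'   lineage, with a warning) or "error".
#' @return A data.frame of hits with a \code{lineage} list-column,
#'   sorted by query then descending bit score.  Subjects missing from
#'   the map are reported in \code{attr(, "unmapped")}.
#' @export
readHitTable <- function(path, lineage_map, unmapped = c("drop", "error")) {
    unmapped <- match.arg(unmapped)
    stopifnot(file.exists(path))
    if (is.character(lineage_map)) lineage_map <- readLineageMap(lineage_map)
    tab <- read.delim(path, header = FALSE, sep = "\t", quote = "",
                      colClasses = "character", col.names = .HIT_COLS)
    for (col in c("percent_identity", "e_value", "bit_score")) {
        v <- suppressWarnings(as.numeric(tab[[col]]))
        bad <- which(is.na(v) & !is.na(tab[[col]]))
        if (length(bad))
            stop("non-numeric ", col, " in ", path, " at line ",
                 bad[1L])
        tab[[col]] <- v
    }
    for (col in c("aln_length", "mismatches", "gap_opens", "qstart",
                  "qend", "sstart", "send"))
        tab[[col]] <- as.integer(tab[[col]])
    if (any(!is.finite(tab$bit_score)))
        stop("non-finite bit score in ", path)
    ## BLAST dialect is 1-based inclusive; store 0-based half-open
    tab$qstart <- tab$qstart - 1L
    miss <- !(tab$subject_id %in% names(lineage_map))
    unmapped_ids <- unique(tab$subject_id[miss])
    if (length(unmapped_ids)) {
        if (unmapped == "error")
            stop("subjects missing from lineage map: ",
                 paste(unmapped_ids, collapse = ", "))
        warning(length(unmapped_ids),
                " subject(s) missing from lineage map; hits dropped")
        tab <- tab[!miss, , drop = FALSE]
    }
    tab <- tab[order(tab$query_id, -tab$bit_score), , drop = FALSE]
    rownames(tab) <- NULL
    tab$lineage <- unname(lineage_map[tab$subject_id])
    attr(tab, "unmapped") <- unmapped_ids
    tab
}

#' @describeIn readHitTable Write hits back to the 12-column format
#'   (query coordinates re-converted to 1-based inclusive).
#' @param hits Hit data.frame as returned by [readHitTable()].
#' @export
writeHitTable <- function(hits, path) {
    out <- hits[, .HIT_COLS]
    out$qstart <- out$qstart + 1L
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    invisible(path)
}

#' Read / write Newick trees
#'
#' Thin wrappers over [ape::read.tree()] / [ape::write.tree()] that
#' validate leaf-name uniqueness.  Internal-node labels are used for
#' bootstrap support values.
#'
#' @param path Newick file path.
#' @return An [ape::read.tree()] \code{phylo} object.
#' @export
readNewickTree <- function(path) {
    stopifnot(file.exists(path))
    tr <- ape::read.tree(path)
    if (is.null(tr)) stop("could not parse Newick file: ", path)
    if (anyDuplicated(tr$tip.label))
        stop("duplicate leaf names in ", path)
    tr
}

#' @describeIn readNewickTree Write a phylo object as Newick.
#' @param tree A \code{phylo} object.
#' @export
writeNewickTree <- function(tree, path) {
    ape::write.tree(tree, file = path)
    invisible(path)
}

#' Assemble an RNA-seq fragment-count table
#'
#' @param counts Numeric matrix, transcripts x stages (fragments; a
#'   read pair is one fragment).  Non-negative.
#' @param lengths Named numeric of transcript effective lengths (nt).
#' @param host_free Character vector of stage (column) names sampled
#'   away from any host.
#' @return A [SummarizedExperiment::SummarizedExperiment-class] with
#'   assay \code{counts}, rowData column \code{length}, colData column
#'   \code{host_free}.
#' @export
makeCountTable <- function(counts, lengths, host_free = character()) {
    counts <- as.matrix(counts)
    if (any(counts < 0)) stop("counts must be non-negative")
    if (!all(rownames(counts) %in% names(lengths)))
        stop("every transcript needs a length")
    if (!all(host_free %in% colnames(counts)))
        stop("host_free stages absent from count table: ",
             paste(setdiff(host_free, colnames(counts)), collapse = ", "))
    SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts),
        rowData = S4Vectors::DataFrame(
            length = unname(lengths[rownames(counts)])),
        colData = S4Vectors::DataFrame(
            host_free = colnames(counts) %in% host_free,
            row.names = colnames(counts)))
}

#' @describeIn makeCountTable Read a count table from TSV (columns:
#'   transcript_id, length, then one column per stage).
#' @param path TSV path.
#' @param host_free Stage names that are host-free.
#' @export
readCountTable <- function(path, host_free = character()) {
    tab <- read.delim(path, check.names = FALSE)
    m <- as.matrix(tab[, -(1:2), drop = FALSE])
    rownames(m) <- tab[[1L]]
    makeCountTable(m, setNames(tab[[2L]], tab[[1L]]), host_free)
}

#' @describeIn makeCountTable Write a count table back to TSV
#'   (round-trips with \code{readCountTable}).
#' @param ct SummarizedExperiment from \code{makeCountTable}.
#' @export
writeCountTable <- function(ct, path) {
    out <- data.frame(transcript_id = rownames(ct),
                      length = SummarizedExperiment::rowData(ct)$length,
                      as.data.frame(SummarizedExperiment::assay(ct)),
                      check.names = FALSE)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Assemble a qPCR cycle-threshold table
#'
#' Columns are individual replicate wells; \code{condition} labels
#' group wells into biological conditions.
#'
#' @param ct Numeric matrix, genes x wells, of Ct values (> 0; NA for
#'   failed wells).
#' @param condition Character vector, one condition label per well.
#' @return SummarizedExperiment with assay \code{ct} and colData
#'   column \code{condition}.
#' @export
makeCtTable <- function(ct, condition) {
    ct <- as.matrix(ct)
    if (any(ct <= 0, na.rm = TRUE)) stop("Ct values must be positive")
    if (length(condition) != ncol(ct))
        stop("one condition label per well required")
    tab <- table(condition)
    if (any(tab < 2L))
        warning("condition(s) with fewer than 2 replicates: ",
                paste(names(tab)[tab < 2L], collapse = ", "))
    if (is.null(colnames(ct)))
        colnames(ct) <- sprintf("well%02d", seq_len(ncol(ct)))
    SummarizedExperiment::SummarizedExperiment(
        assays = list(ct = ct),
        colData = S4Vectors::DataFrame(condition = condition,
                                       row.names = colnames(ct)))
}

#' @describeIn makeCtTable Read a Ct table from TSV (first column gene,
#'   remaining columns wells; first row after header holds condition
#'   labels in a \code{#condition} pseudo-gene row).
#' @param path TSV path.
#' @export
readCtTable <- function(path) {
    tab <- read.delim(path, check.names = FALSE, colClasses = "character")
    cond_row <- which(tab[[1L]] == "#condition")
    if (length(cond_row) != 1L)
        stop("Ct TSV must contain one #condition row")
    condition <- as.character(tab[cond_row, -1L])
    genes <- tab[-cond_row, , drop = FALSE]
    m <- apply(as.matrix(genes[, -1L, drop = FALSE]), 2L, as.numeric)
    m <- matrix(m, nrow = nrow(genes),
                dimnames = list(genes[[1L]], colnames(tab)[-1L]))
    makeCtTable(m, condition)
}

#' @describeIn makeCtTable Write a Ct table to TSV (round-trips with
#'   \code{readCtTable}).
#' @param cttab SummarizedExperiment from \code{makeCtTable}.
#' @export
writeCtTable <- function(cttab, path) {
    m <- SummarizedExperiment::assay(cttab, "ct")
    body <- as.data.frame(m, check.names = FALSE)
    cond <- as.data.frame(as.list(as.character(cttab$condition)),
                          col.names = colnames(m),
                          check.names = FALSE)
    out <- cbind(gene = c("#condition", rownames(m)),
                 rbind(cond, body))
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
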