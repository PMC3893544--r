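## The HGT screening stage: read quality trimming, k-mer read
## assignment, host-contamination filtering on host-free-stage read
## evidence, ORF prediction, length gates, the alien score ratio, and
## the sister-taxon cDNA exclusion filter.

#' Screening configuration
#'
#' Bundles the constants of the screen with their field defaults:
#' Phred floor 25 for read trimming, 300 nt / 100 aa length gates, an
#' alien score-ratio threshold of 1.2, and the taxonomic names that
#' partition hits (in-group rank, e.g. "Lamiales") and drive the
#' sister-taxon exclusion (e.g. "Mimulus guttatus").
#'
#' @param quality_floor Minimum base quality kept by [trimReads()].
#' @param min_transcript_nt Minimum transcript length (inclusive).
#' @param min_orf_aa Minimum predicted ORF length (inclusive).
#' @param ratio_threshold Alien score-ratio threshold (candidates need
#'   a strictly greater ratio).
#' @param ingroup_rank_name Taxon name whose presence in a hit's
#'   lineage marks it as in-group.
#' @param sister_taxon_name Taxon name triggering cDNA-level
#'   exclusion.
#' @param kmer_length k for read-to-transcript assignment.
#' @return A named list of class \code{screen_config}.
#' @export
screenConfig <- function(quality_floor = 25L, min_transcript_nt = 300L,
                         min_orf_aa = 100L, ratio_threshold = 1.2,
                         ingroup_rank_name = "Lamiales",
                         sister_taxon_name = "Mimulus guttatus",
                         kmer_length = 21L) {
    stopifnot(ratio_threshold > 0, quality_floor > 0,
              min_transcript_nt > 0, min_orf_aa > 0, kmer_length > 0)
    structure(list(quality_floor = quality_floor,
                   min_transcript_nt = min_transcript_nt,
                   min_orf_aa = min_orf_aa,
                   ratio_threshold = ratio_threshold,
                   ingroup_rank_name = ingroup_rank_name,
                   sister_taxon_name = sister_taxon_name,
                   kmer_length = kmer_length),
              class = "screen_config")
}

#' Adapter and quality trimming of reads
#'
#' For each read the first exact adapter occurrence and everything 3'
#' of it is removed; then the read is truncated at the first base
#' whose quality falls below the floor (conservative first-failure
#' truncation rather than a sliding window).  Empty reads are
#' dropped.
#'
#' @param reads A [Biostrings::QualityScaledDNAStringSet-class].
#' @param quality_floor Minimum Phred score kept (default 25).
#' @param adapters Character vector of adapter sequences (optional).
#' @return A trimmed QualityScaledDNAStringSet (possibly shorter than
#'   the input; dropped-read count attached as
#'   \code{attr(,"n_dropped")}).
#' @export
trimReads <- function(reads, quality_floor = 25L,
                      adapters = character()) {
    seqs <- as.character(reads)
    quals <- as.character(Biostrings::quality(reads))
    for (ad in adapters) {
        hit <- regexpr(ad, seqs, fixed = TRUE)
        cut <- hit != -1L
        seqs[cut] <- substr(seqs[cut], 1L, hit[cut] - 1L)
        quals[cut] <- substr(quals[cut], 1L, hit[cut] - 1L)
    }
    ## truncate at first sub-floor base
    qnum <- lapply(quals, function(q) utf8ToInt(q) - 33L)
    keep_len <- vapply(seq_along(seqs), function(i) {
        q <- qnum[[i]]
        bad <- which(q < quality_floor)
        if (length(bad)) bad[1L] - 1L else length(q)
    }, integer(1L))
    seqs <- substr(seqs, 1L, keep_len)
    quals <- substr(quals, 1L, keep_len)
    nonempty <- nchar(seqs) > 0L
    out <- Biostrings::QualityScaledDNAStringSet(
        Biostrings::DNAStringSet(setNames(seqs[nonempty],
                                          names(reads)[nonempty])),
        Biostrings::PhredQuality(quals[nonempty]))
    attr(out, "n_dropped") <- sum(!nonempty)
    out
}

.kmerSet <- function(seq, k) {
    n <- nchar(seq)
    if (n < k) return(character())
    unique(substring(seq, 1:(n - k + 1L), k:n))
}

#' Assign reads to transcripts by shared k-mers
#'
#' Each fragment (a read pair counts once; mates' k-mers are pooled)
#' is assigned to every transcript sharing its maximal number of
#' matching k-mers, with ties receiving fractional 1/t credit.  Both
#' strands of the fragment are considered.  This is a deliberately
#' simple stand-in for probabilistic multi-mapping estimators.
#'
#' @param transcripts Named DNAStringSet.
#' @param reads Staged read list as from [simulateReads()] (per stage:
#'   \code{reads}, \code{host_free}), or a single
#'   QualityScaledDNAStringSet (treated as one attached stage).
#' @param k k-mer length (must not exceed the read length).
#' @param paired Logical; consecutive reads are mates of one fragment.
#' @return CountTable ([makeCountTable()]) of fragment counts per
#'   transcript per stage, with the number of unassignable fragments
#'   per stage in \code{metadata(.)$unassigned}.
#' @export
assignReads <- function(transcripts, reads, k = 21L, paired = TRUE) {
    if (!is.list(reads))
        reads <- list(stage1 = list(reads = reads, host_free = FALSE))
    tx_chr <- as.character(transcripts)
    tx_kmers <- lapply(tx_chr, .kmerSet, k = k)
    ## k-mer -> transcript index lookup
    all_k <- unlist(tx_kmers, use.names = FALSE)
    owner <- rep(seq_along(tx_kmers), lengths(tx_kmers))
    lookup <- split(owner, all_k)
    counts <- matrix(0, length(transcripts), length(reads),
                     dimnames = list(names(transcripts), names(reads)))
    unassigned <- setNames(integer(length(reads)), names(reads))
    for (s in names(reads)) {
        rr <- as.character(reads[[s]]$reads)
        if (length(rr) == 0L) next
        if (any(nchar(rr) < k))
            rr <- rr[nchar(rr) >= k]
        nfrag <- if (paired) length(rr) %/% 2L else length(rr)
        for (f in seq_len(nfrag)) {
            pieces <- if (paired) rr[c(2L * f - 1L, 2L * f)] else rr[f]
            km <- unique(unlist(lapply(pieces, function(p) c(
                .kmerSet(p, k),
                .kmerSet(as.character(Biostrings::reverseComplement(
                    Biostrings::DNAString(p))), k)))))
            hits <- unlist(lookup[km], use.names = FALSE)
            if (is.null(hits) || !length(hits)) {
                unassigned[s] <- unassigned[s] + 1L
                next
            }
            tab <- tabulate(hits, nbins = length(transcripts))
            best <- which(tab == max(tab))
            counts[best, s] <- counts[best, s] + 1 / length(best)
        }
    }
    host_free <- vapply(reads, `[[`, logical(1L), "host_free")
    ct <- makeCountTable(counts,
        setNames(Biostrings::width(transcripts), names(transcripts)),
        host_free = names(reads)[host_free])
    S4Vectors::metadata(ct)$unassigned <- unassigned
    ct
}

#' Remove transcripts without host-free read evidence
#'
#' Transcripts whose fragment count summed across all host-free
#' stages is at least one are kept; the rest are host-mRNA
#' contamination candidates and removed.  The union-over-stages rule
#' is used (a transcript needs evidence in any host-free stage, not
#' all).
#'
#' @param transcripts Named DNAStringSet.
#' @param count_table CountTable from [assignReads()].
#' @param host_free_stages Stage names to use; defaults to the
#'   host-free flags stored in the table.
#' @return List with \code{kept} and \code{removed} DNAStringSets.
#' @export
contaminationFilter <- function(transcripts, count_table,
                                host_free_stages = NULL) {
    if (is.null(host_free_stages))
        host_free_stages <-
            colnames(count_table)[count_table$host_free]
    missing <- setdiff(host_free_stages, colnames(count_table))
    if (length(missing))
        stop("stage(s) absent from count table: ",
             paste(missing, collapse = ", "))
    if (!length(host_free_stages))
        stop("no host-free stage available")
    m <- SummarizedExperiment::assay(count_table)[,
        host_free_stages, drop = FALSE]
    evidence <- rowSums(m) >= 1
    keep_ids <- rownames(m)[evidence]
    list(kept = transcripts[names(transcripts) %in% keep_ids],
         removed = transcripts[!names(transcripts) %in% keep_ids])
}

.GENCODE <- function() Biostrings::GENETIC_CODE

.translateFrame <- function(seq, offset) {
    n <- nchar(seq)
    usable <- n - offset
    ncod <- usable %/% 3L
    if (ncod == 0L) return("")
    cods <- substring(seq, offset + seq(1L, by = 3L, length.out = ncod),
                      offset + seq(3L, by = 3L, length.out = ncod))
    gc <- .GENCODE()
    aa <- gc[cods]
    aa[is.na(aa)] <- "X"   # ambiguity codes
    paste(aa, collapse = "")
}

#' Predict the best ORF of a transcript
#'
#' Scans all six reading frames for the longest segment starting at
#' ATG and ending at the first in-frame stop (or the sequence end);
#' the stop is excluded from the protein.  Ties prefer forward over
#' reverse frames, then the leftmost start.  If no ATG exists in any
#' frame, the longest stop-free stretch is used and flagged.
#'
#' @param transcript A DNAString/character of length >= 3, or a
#'   one-element DNAStringSet.
#' @return List with \code{protein} (AAStringSet of one record),
#'   \code{frame} (1..3 forward, -1..-3 reverse), \code{start},
#'   \code{end} (0-based half-open nt coordinates on the input
#'   strand), and \code{no_atg} flag.
#' @examples
#' predictOrf("ATGAAATAA")$protein
#' @export
predictOrf <- function(transcript) {
    if (methods::is(transcript, "XStringSet"))
        transcript <- transcript[[1L]]
    seq <- toupper(as.character(transcript))
    if (nchar(seq) < 3L) stop("transcript shorter than one codon")
    rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(seq)))
    frames <- list()
    for (st in c("+", "-")) {
        s <- if (st == "+") seq else rc
        for (off in 0:2) {
            aa <- .translateFrame(s, off)
            if (nchar(aa))
                frames[[length(frames) + 1L]] <-
                    list(aa = aa, strand = st, offset = off)
        }
    }
    best <- NULL
    for (fr in frames) {
        aa <- fr$aa
        ## segments between stops
        stops <- c(0L, gregexpr("\\*", aa)[[1L]])
        if (stops[2L] == -1L) stops <- 0L
        bounds <- c(stops, nchar(aa) + 1L)
        for (b in seq_len(length(bounds) - 1L)) {
            seg_start <- bounds[b] + 1L
            seg_end <- bounds[b + 1L] - 1L
            if (seg_end < seg_start) next
            seg <- substr(aa, seg_start, seg_end)
            m <- regexpr("M", seg, fixed = TRUE)
            cand <- if (m != -1L) {
                list(aa = substr(seg, m, nchar(seg)),
                     aa_start = seg_start + m - 1L, no_atg = FALSE)
            } else {
                list(aa = seg, aa_start = seg_start, no_atg = TRUE)
            }
            cand$strand <- fr$strand; cand$offset <- fr$offset
            better <- is.null(best) ||
                (!cand$no_atg && best$no_atg) ||
                (cand$no_atg == best$no_atg &&
                 nchar(cand$aa) > nchar(best$aa)) ||
                (cand$no_atg == best$no_atg &&
                 nchar(cand$aa) == nchar(best$aa) &&
                 best$strand == "-" && cand$strand == "+")
            if (better) best <- cand
        }
    }
    n <- nchar(seq)
    nt_start_on_frame <- best$offset + (best$aa_start - 1L) * 3L  # 0-based
    nt_len <- nchar(best$aa) * 3L
    if (best$strand == "+") {
        start <- nt_start_on_frame; end <- start + nt_len
    } else {
        end <- n - nt_start_on_frame; start <- end - nt_len
    }
    frame <- (best$offset + 1L) * if (best$strand == "+") 1L else -1L
    list(protein = Biostrings::AAStringSet(setNames(best$aa, "orf")),
         frame = frame, start = start, end = end, no_atg = best$no_atg)
}

#' Length gates on transcript and predicted ORF
#'
#' @param transcript DNAString/character transcript.
#' @param orf Result of [predictOrf()] on it.
#' @param config [screenConfig()].
#' @return List \code{pass} (logical) and \code{reason} (empty when
#'   passing; otherwise "transcript_too_short" and/or
#'   "orf_too_short").  Both boundaries are inclusive.
#' @export
lengthGates <- function(transcript, orf, config = screenConfig()) {
    if (methods::is(transcript, "XStringSet"))
        transcript <- transcript[[1L]]
    nt <- nchar(as.character(transcript))
    aa <- Biostrings::width(orf$protein)[1L]
    reason <- character()
    if (nt < config$min_transcript_nt)
        reason <- c(reason, "transcript_too_short")
    if (aa < config$min_orf_aa)
        reason <- c(reason, "orf_too_short")
    list(pass = length(reason) == 0L, reason = reason)
}

.isSelfHit <- function(hits) {
    hits$subject_id == hits$query_id |
        (hits$percent_identity >= 100 - 1e-9 &
         hits$mismatches == 0L & hits$gap_opens == 0L)
}

#' Alien score-ratio verdict for one query
#'
#' Partitions the query's hits by whether the in-group rank name
#' occurs in the subject lineage, and computes the ratio of the best
#' out-group bit score to the best in-group bit score.  The query is
#' a candidate when the ratio strictly exceeds the threshold.  A
#' query with no in-group hit gets ratio +Inf and is a candidate with
#' flag \code{no_ingroup_hit}; with no out-group hit it is not a
#' candidate (flag \code{no_outgroup_hit}).  Self-hits (same id, or
#' 100\% identity with no mismatches or gaps) are removed first.
#'
#' @param hits Hit data.frame rows for one query ([readHitTable()]
#'   layout, lineage list-column present).
#' @param config [screenConfig()].
#' @return One-row data.frame with query_id, best in/out-group hit ids
#'   and scores, ratio, is_candidate and flags (comma-joined).
#' @export
alienScore <- function(hits, config = screenConfig()) {
    flags <- character()
    if (nrow(hits)) hits <- hits[!.isSelfHit(hits), , drop = FALSE]
    qid <- if (nrow(hits)) hits$query_id[1L] else NA_character_
    ingroup <- vapply(hits$lineage, function(l)
        config$ingroup_rank_name %in% l, logical(1L))
    bi <- which(ingroup)[1L]
    bo <- which(!ingroup)[1L]
    best_in <- if (!is.na(bi)) hits[bi, ] else NULL
    best_out <- if (!is.na(bo)) hits[bo, ] else NULL
    if (is.null(best_in)) flags <- c(flags, "no_ingroup_hit")
    if (is.null(best_out)) flags <- c(flags, "no_outgroup_hit")
    ratio <- if (is.null(best_out)) 0
             else if (is.null(best_in)) Inf
             else best_out$bit_score / best_in$bit_score
    is_candidate <- !is.null(best_out) && ratio > config$ratio_threshold
    data.frame(
        query_id = qid,
        best_ingroup_id = if (is.null(best_in)) NA_character_
                          else best_in$subject_id,
        best_ingroup_score = if (is.null(best_in)) NA_real_
                             else best_in$bit_score,
        best_outgroup_id = if (is.null(best_out)) NA_character_
                           else best_out$subject_id,
        best_outgroup_score = if (is.null(best_out)) NA_real_
                              else best_out$bit_score,
        ratio = ratio, is_candidate = is_candidate,
        flags = paste(flags, collapse = ","))
}

#' Sister-taxon cDNA-level exclusion
#'
#' A candidate whose best (non-self) cDNA-level hit carries the
#' sister taxon in its lineage is removed (flag
#' \code{sister_taxon_cdna_hit}); candidates with no cDNA hits are
#' retained and logged.
#'
#' @param verdict_tab Verdict data.frame (rows from [alienScore()]).
#' @param cdna_hits Nucleotide-level hit data.frame for the candidate
#'   cDNAs.
#' @param config [screenConfig()].
#' @return The verdict table with sister-affiliated candidates
#'   demoted and flagged.
#' @export
sisterTaxonFilter <- function(verdict_tab, cdna_hits,
                              config = screenConfig()) {
    for (i in which(verdict_tab$is_candidate)) {
        qid <- verdict_tab$query_id[i]
        h <- cdna_hits[cdna_hits$query_id == qid, , drop = FALSE]
        if (nrow(h)) h <- h[!.isSelfHit(h), , drop = FALSE]
        if (!nrow(h)) {
            message("candidate ", qid, " has no cDNA-level hits; kept")
            next
        }
        top <- h[which.max(h$bit_score), ]
        if (config$sister_taxon_name %in% top$lineage[[1L]]) {
            verdict_tab$is_candidate[i] <- FALSE
            verdict_tab$flags[i] <- paste(c(
                setdiff(strsplit(verdict_tab$flags[i], ",")[[1L]], ""),
                "sister_taxon_cdna_hit"), collapse = ",")
        }
    }
    verdict_tab
}

#' Run the full HGT screening pipeline
#'
#' Applies, in order: read trimming, k-mer read assignment,
#' host-contamination filtering, ORF prediction, length gates, the
#' alien score ratio, and the sister-taxon cDNA filter.  The report
#' has one row per transcript that survived contamination filtering
#' and the length gates, sorted by descending ratio.
#'
#' @param transcripts Named DNAStringSet of assembled transcripts.
#' @param reads Staged read list (see [assignReads()]); NULL skips
#'   trimming/assignment/contamination filtering (all transcripts
#'   kept).
#' @param protein_hits Protein-level hit data.frame
#'   ([readHitTable()] layout) for the transcripts' ORFs.
#' @param cdna_hits Nucleotide-level hit data.frame for the
#'   transcripts; NULL skips the sister filter.
#' @param config [screenConfig()].
#' @param adapters Adapter sequences for trimming.
#' @return An [AlienScreen-class] object; \code{metadata}-style
#'   extras (removed contaminants, gate failures) are in
#'   \code{verdicts(x)}'s attributes and \code{x@config}.
#' @export
runScreen <- function(transcripts, reads, protein_hits,
                      cdna_hits = NULL, config = screenConfig(),
                      adapters = character()) {
    removed_ids <- character()
    if (!is.null(reads)) {
        reads <- lapply(reads, function(st) {
            st$reads <- trimReads(st$reads, config$quality_floor,
                                  adapters)
            st
        })
        ct <- assignReads(transcripts, reads, k = config$kmer_length)
        cf <- contaminationFilter(transcripts, ct)
        removed_ids <- names(cf$removed)
        transcripts <- cf$kept
    }
    rows <- list()
    for (id in names(transcripts)) {
        orf <- predictOrf(transcripts[[id]])
        gate <- lengthGates(transcripts[[id]], orf, config)
        if (!gate$pass) next
        h <- protein_hits[protein_hits$query_id == id, , drop = FALSE]
        v <- alienScore(if (nrow(h)) h else
            cbind(h, data.frame(lineage = I(list()))[0, , drop = FALSE]),
            config)
        v$query_id <- id
        rows[[id]] <- v
    }
    tab <- if (length(rows)) do.call(rbind, rows) else
        data.frame(query_id = character(), best_ingroup_id = character(),
                   best_ingroup_score = numeric(),
                   best_outgroup_id = character(),
                   best_outgroup_score = numeric(), ratio = numeric(),
                   is_candidate = logical(), flags = character())
    if (!is.null(cdna_hits) && nrow(tab))
        tab <- sisterTaxonFilter(tab, cdna_hits, config)
    tab <- tab[order(-tab$ratio, tab$query_id), , drop = FALSE]
    rownames(tab) <- NULL
    v <- S4Vectors::DataFrame(tab)
    S4Vectors::metadata(v) <- list(contamination_removed = removed_ids)
    new("AlienScreen", verdicts = v, config = unclass(config))
}

#' @describeIn runScreen Write the verdict report as TSV (one row per
#'   surviving transcript, ratio-descending).
#' @param x An AlienScreen object.
#' @param path Output TSV path.
#' @export
writeScreenReport <- function(x, path) {
    write.table(as.data.frame(verdicts(x)), path, sep = "\t",
                quote = FALSE, row.names = FALSE)
    invisible(path)
}
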