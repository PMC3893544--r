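## Pairwise alignment and identity, codon back-translation, alignment
## trimming, group-diagnostic sites/indels, spliced alignment of cDNA
## onto genomic sequence, intron-position homology and
## intron-retention calls.

.defaultScoring <- function(moltype) {
    if (moltype == "protein")
        list(substitutionMatrix = "BLOSUM62", gapOpening = 11,
             gapExtension = 1)
    else
        list(substitutionMatrix =
                 Biostrings::nucleotideSubstitutionMatrix(
                     match = 2, mismatch = -3),
             gapOpening = 5, gapExtension = 2)
}

#' Optimal pairwise alignment
#'
#' Needleman-Wunsch (global) or Smith-Waterman (local) alignment with
#' affine gaps: BLOSUM62 / open 11 / extend 1 for proteins, match 2 /
#' mismatch -3 / open 5 / extend 2 for nucleotides (a gap of length L
#' costs open + L * extend).
#'
#' @param a,b Character strings, XString or one-record XStringSet.
#' @param mode "global" or "local".
#' @param moltype "protein" or "dna".
#' @param scoring Optional list overriding \code{substitutionMatrix},
#'   \code{gapOpening}, \code{gapExtension}.
#' @return List with \code{aligned_a}, \code{aligned_b} (gapped
#'   strings) and \code{score}.
#' @examples
#' pairwiseAlign("ACGT", "ACT", moltype = "dna")$score
#' @export
pairwiseAlign <- function(a, b, mode = c("global", "local"),
                          moltype = c("protein", "dna"),
                          scoring = NULL) {
    mode <- match.arg(mode)
    moltype <- match.arg(moltype)
    a <- as.character(a); b <- as.character(b)
    if (!nchar(a) || !nchar(b)) stop("empty sequence")
    sc <- .defaultScoring(moltype)
    sc[names(scoring)] <- scoring
    sa <- if (moltype == "protein") Biostrings::AAString(a)
          else Biostrings::DNAString(a)
    sb <- if (moltype == "protein") Biostrings::AAString(b)
          else Biostrings::DNAString(b)
    pa <- Biostrings::pairwiseAlignment(sa, sb, type = mode,
        substitutionMatrix = sc$substitutionMatrix,
        gapOpening = sc$gapOpening, gapExtension = sc$gapExtension)
    list(aligned_a = as.character(Biostrings::alignedPattern(pa)),
         aligned_b = as.character(Biostrings::alignedSubject(pa)),
         score = Biostrings::score(pa))
}

#' Percent identity of two sequences
#'
#' 100 x matches / aligned columns, gap-containing columns excluded,
#' reported to one decimal.  Mode "local" uses only the best local
#' alignment.
#'
#' @inheritParams pairwiseAlign
#' @return Numeric identity in 0-100.
#' @export
percentIdentity <- function(a, b, mode = c("global", "local"),
                            moltype = c("protein", "dna")) {
    mode <- match.arg(mode); moltype <- match.arg(moltype)
    a <- as.character(a); b <- as.character(b)
    ## canonical argument order: ties between co-optimal alignments
    ## would otherwise make the identity order-dependent
    if (nchar(b) < nchar(a) || (nchar(b) == nchar(a) && b < a)) {
        tmp <- a; a <- b; b <- tmp
    }
    al <- pairwiseAlign(a, b, mode, moltype)
    ca <- strsplit(al$aligned_a, "")[[1L]]
    cb <- strsplit(al$aligned_b, "")[[1L]]
    ok <- ca != "-" & cb != "-"
    if (!sum(ok)) return(0)
    round(100 * sum(ca[ok] == cb[ok]) / sum(ok), 1)
}

#' Back-translate a protein alignment to a codon alignment
#'
#' Each amino-acid column expands to the residue's source codon; gaps
#' expand to \code{---}.  Every cDNA must translate (frame 0, stops
#' trimmed) exactly to its protein row.
#'
#' @param protein_aln Named AAStringSet (aligned, gaps allowed) or
#'   [GroupedAlignment-class].
#' @param cdna Named DNAStringSet of coding sequences (ids matching
#'   the protein rows; trailing stop codons allowed).
#' @return Named DNAStringSet codon alignment.
#' @export
backTranslateAlignment <- function(protein_aln, cdna) {
    if (methods::is(protein_aln, "GroupedAlignment"))
        protein_aln <- alnSeqs(protein_aln)
    out <- character(length(protein_aln))
    for (i in seq_along(protein_aln)) {
        id <- names(protein_aln)[i]
        if (!id %in% names(cdna)) stop("no cDNA for ", id)
        nt <- sub("(TAA|TAG|TGA)$", "", toupper(as.character(cdna[[id]])))
        if (nchar(nt) %% 3L != 0L)
            stop("cDNA length of ", id, " not a multiple of 3")
        cods <- substring(nt, seq(1L, nchar(nt), 3L),
                          seq(3L, nchar(nt), 3L))
        aa_exp <- unname(Biostrings::GENETIC_CODE[cods])
        row <- strsplit(as.character(protein_aln[[i]]), "")[[1L]]
        res <- row[row != "-"]
        if (length(res) != length(cods))
            stop("protein/cDNA length mismatch for ", id)
        mism <- which(res != aa_exp & res != "X")
        if (length(mism))
            stop("translation mismatch for ", id, " at residue ",
                 mism[1L], ": alignment has ", res[mism[1L]],
                 ", cDNA encodes ", aa_exp[mism[1L]])
        filled <- rep("---", length(row))
        filled[row != "-"] <- cods
        out[i] <- paste(filled, collapse = "")
    }
    Biostrings::DNAStringSet(setNames(out, names(protein_aln)))
}

#' Remove gapped and ambiguous alignment columns
#'
#' Under the strict default any column containing a gap (or, with
#' \code{drop_ambiguous}, an ambiguity character) is removed; a
#' \code{max_gap_fraction} above 0 relaxes this to columns whose gap
#' fraction exceeds the threshold.
#'
#' @param aln Named XStringSet or [GroupedAlignment-class].
#' @param max_gap_fraction Maximum tolerated gap fraction (default 0).
#' @param drop_ambiguous Also drop columns with X/N/B/Z/J/? characters.
#' @return Object of the input's kind with attribute
#'   \code{kept_columns} (old column index per new column).
#' @export
trimAlignment <- function(aln, max_gap_fraction = 0,
                          drop_ambiguous = TRUE) {
    grouped <- methods::is(aln, "GroupedAlignment")
    seqs <- if (grouped) alnSeqs(aln) else aln
    m <- do.call(rbind, strsplit(as.character(seqs), ""))
    gapfrac <- colMeans(m == "-")
    drop <- gapfrac > max_gap_fraction
    if (drop_ambiguous)
        drop <- drop | apply(m, 2L, function(col)
            any(col %in% c("X", "N", "B", "Z", "J", "?", ".")))
    if (all(drop)) stop("trimming removed every column")
    kept <- which(!drop)
    newm <- m[, kept, drop = FALSE]
    chr <- apply(newm, 1L, paste, collapse = "")
    out <- if (methods::is(seqs, "AAStringSet"))
        Biostrings::AAStringSet(setNames(chr, names(seqs)))
    else Biostrings::DNAStringSet(setNames(chr, names(seqs)))
    if (grouped) out <- groupedAlignment(out, alnGroups(aln))
    attr(out, "kept_columns") <- kept
    out
}

#' Group-diagnostic residues and deletions in an alignment
#'
#' Residue sites are columns where every group member shares one
#' residue that no non-member carries; deletion sites are maximal
#' column runs where every group member is gapped and no non-member
#' is.  Relaxed mode accepts group purity down to
#' \code{min_purity}.
#'
#' @param aln [GroupedAlignment-class] with the group defined.
#' @param group_name Name of the group to diagnose.
#' @param min_purity Minimum fraction of group members carrying the
#'   diagnostic state (default 1: strict).
#' @return data.frame with columns \code{column} (1-based MSA column;
#'   for deletions the run start), \code{kind}
#'   ("residue"/"deletion"), \code{length} (1 for residues; run
#'   length for deletions), \code{group_state}, \code{outside_states},
#'   \code{purity}.
#' @export
diagnosticSites <- function(aln, group_name, min_purity = 1) {
    grp <- alnGroups(aln)[[group_name]]
    if (is.null(grp) || length(grp) < 2L)
        stop("group must exist and have >= 2 members")
    m <- alnMatrix(aln)
    if (length(grp) == nrow(m))
        stop("group covers all rows; no outside sequences")
    gi <- rownames(m) %in% grp
    res <- list()
    ## residue sites
    for (j in seq_len(ncol(m))) {
        gc <- m[gi, j]; oc <- m[!gi, j]
        tab <- table(gc[gc != "-"])
        if (!length(tab)) next
        state <- names(tab)[which.max(tab)]
        purity <- max(tab) / length(gc)
        if (purity >= min_purity && !state %in% oc) {
            res[[length(res) + 1L]] <- data.frame(
                column = j, kind = "residue", length = 1L,
                group_state = state,
                outside_states = paste(sort(unique(oc)), collapse = ""),
                purity = purity)
        }
    }
    ## deletion runs: columns where group all '-', outside none '-'
    delcol <- vapply(seq_len(ncol(m)), function(j)
        mean(m[gi, j] == "-") >= min_purity && !any(m[!gi, j] == "-"),
        logical(1L))
    r <- rle(delcol)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
        j <- starts[k]
        res[[length(res) + 1L]] <- data.frame(
            column = j, kind = "deletion", length = r$lengths[k],
            group_state = "-",
            outside_states = paste(sort(unique(as.vector(
                m[!gi, j:ends[k]]))), collapse = ""),
            purity = mean(m[gi, j:ends[k]] == "-"))
    }
    out <- if (length(res)) do.call(rbind, res) else
        data.frame(column = integer(), kind = character(),
                   length = integer(), group_state = character(),
                   outside_states = character(), purity = numeric())
    out[order(out$column), , drop = FALSE]
}

## Vectorized spliced-alignment DP (Gotoh with an extra intron state).
## States at cell (i = cDNA pos, j = genomic pos):
##   M  - x[i] aligned to y[j]
##   Dx - x[i] aligned to a gap (cDNA-only gap, affine)
##   Dy - y[j] aligned to a gap (short genomic deletion, affine)
##   N  - y[j] inside an intron (fixed opening penalty, free length)
## Dy and N are anchored within a row at A = max(M, Dx) via prefix
## running-max scans (gap-into-gap chains are never optimal, so
## feeding gap states from A only is exact).  Leading and trailing
## genomic sequence is free (the cDNA aligns genomic-locally).
.splicedDP <- function(cdna, genomic, match = 2, mismatch = -3,
                       gap_open = 5, gap_extend = 2,
                       intron_open = 10) {
    x <- strsplit(cdna, "")[[1L]]
    y <- strsplit(genomic, "")[[1L]]
    n <- length(x); m <- length(y)
    NEG <- -1e9
    Hprev <- rep(0, m + 1L)        # H[0][j] = 0: free leading genomic
    Dxprev <- rep(NEG, m + 1L)
    choiceH <- matrix(raw(1L), n, m)  # 1 M, 2 Dx, 3 Dy, 4 N
    choiceA <- matrix(raw(1L), n, m)  # 1 M, 2 Dx
    openDx <- matrix(raw(1L), n, m)   # 1 = gap opened at this row
    srcDy <- matrix(0L, n, m)         # anchor genomic column of Dy run
    srcN <- matrix(0L, n, m)          # anchor genomic column of intron
    js <- seq_len(m)
    ## earliest index attaining the running maximum of v
    runmax_src <- function(v) {
        r <- cummax(v)
        strict_new <- v > c(NEG, r[-length(r)])
        strict_new[1L] <- TRUE
        list(max = r, idx = cummax(ifelse(strict_new, seq_along(v), 0L)))
    }
    for (i in seq_len(n)) {
        sub <- ifelse(y == x[i], match, mismatch)
        M <- Hprev[js] + sub
        open <- Hprev[-1L] - gap_open - gap_extend
        ext <- Dxprev[-1L] - gap_extend
        Dx <- pmax(open, ext)
        openDx[i, ] <- as.raw(open >= ext)
        A <- pmax(M, Dx)
        choiceA[i, ] <- as.raw(ifelse(M >= Dx, 1L, 2L))
        ## anchored within-row genomic-gap states; v[j] = anchor at
        ## column j-1
        sD <- runmax_src(c(NEG, (A + gap_extend * js)[-m]))
        Dy <- sD$max - gap_open - gap_extend * js
        srcDy[i, ] <- sD$idx - 1L
        sN <- runmax_src(c(NEG, A[-m]))
        Nst <- sN$max - intron_open
        srcN[i, ] <- sN$idx - 1L
        H <- pmax(A, Dy, Nst)
        choiceH[i, ] <- as.raw(
            ifelse(H == M, 1L,
            ifelse(H == Dx, 2L,
            ifelse(H == Dy, 3L, 4L))))
        Hprev <- c(NEG, H)
        Dxprev <- c(NEG, Dx)
    }
    endj <- which.max(Hprev[-1L])
    list(score = Hprev[endj + 1L], end = endj, choiceH = choiceH,
         choiceA = choiceA, openDx = openDx, srcDy = srcDy,
         srcN = srcN, n = n, m = m)
}

.splicedTraceback <- function(dp) {
    i <- dp$n; j <- dp$end
    exon_cols <- integer(0)   # genomic column aligned to each cDNA pos
    gap_runs <- list()        # genomic-only runs (start, end, intron?)
    dx_chain <- function(i, j) {
        repeat {
            was_open <- as.integer(dp$openDx[i, j]) == 1L
            i <- i - 1L
            if (was_open || i < 1L) break
        }
        i
    }
    step_A <- function(i, j) {
        if (as.integer(dp$choiceA[i, j]) == 1L) {
            exon_cols <<- c(exon_cols, j)
            c(i - 1L, j - 1L)
        } else {
            c(dx_chain(i, j), j)
        }
    }
    while (i >= 1L && j >= 1L) {
        ch <- as.integer(dp$choiceH[i, j])
        if (ch == 1L) {
            exon_cols <- c(exon_cols, j)
            i <- i - 1L; j <- j - 1L
        } else if (ch == 2L) {
            i <- dx_chain(i, j)
        } else {
            src <- if (ch == 3L) dp$srcDy[i, j] else dp$srcN[i, j]
            if (src < 1L) break
            gap_runs[[length(gap_runs) + 1L]] <-
                c(start = src + 1L, end = j, intron = ch == 4L)
            ij <- step_A(i, src)
            i <- ij[1L]; j <- ij[2L]
        }
    }
    list(exon_cols = rev(exon_cols), gap_runs = rev(gap_runs))
}

## Canonical intron representation: shift each intron left while the
## base leaving the upstream exon equals the intron's last base (the
## two descriptions splice to the same product).
.leftJustifyIntrons <- function(yc, intron_iv, gstart = 1L) {
    s <- IRanges::start(intron_iv); e <- IRanges::end(intron_iv)
    for (r in seq_along(s)) {
        floor_s <- if (r > 1L) e[r - 1L] + 2L else gstart + 1L
        while (s[r] > floor_s && yc[s[r] - 1L] == yc[e[r]]) {
            s[r] <- s[r] - 1L; e[r] <- e[r] - 1L
        }
    }
    IRanges::IRanges(s, e)
}

#' Map introns by spliced alignment of cDNA onto genomic sequence
#'
#' Aligns the cDNA to its genomic sequence allowing long genomic-only
#' gaps at a fixed opening cost (the intron state); genomic-only runs
#' of at least \code{min_intron} nt become introns.  Intron
#' boundaries are left-justified when junction sequence repeats make
#' them ambiguous.  GT..AG conformity is reported, not enforced.
#'
#' @param cdna,genomic Character/XString sequences (cDNA = spliced
#'   product of genomic, possibly with small divergence).
#' @param min_intron Minimum genomic-only run length called as an
#'   intron (default 40 nt).
#' @param min_exon_identity Error if exonic identity falls below this
#'   (default 0.9).
#' @param gene_id Identifier for the returned structure.
#' @return A [GeneStructure-class]; \code{attr(,"gt_ag")} flags GT..AG
#'   conformity per intron.
#' @export
mapIntrons <- function(cdna, genomic, min_intron = 40L,
                       min_exon_identity = 0.9, gene_id = "gene") {
    cdna <- toupper(as.character(cdna))
    genomic <- toupper(as.character(genomic))
    dp <- .splicedDP(cdna, genomic)
    tb <- .splicedTraceback(dp)
    if (!length(tb$exon_cols)) stop("spliced alignment failed")
    yc <- strsplit(genomic, "")[[1L]]
    aligned <- tb$exon_cols
    gstart <- min(aligned); gend <- max(aligned)
    intr <- do.call(rbind, tb$gap_runs)
    intron_iv <- IRanges::IRanges()
    if (!is.null(intr)) {
        len <- intr[, "end"] - intr[, "start"] + 1L
        intr <- intr[len >= min_intron, , drop = FALSE]
        if (nrow(intr))
            intron_iv <- .leftJustifyIntrons(
                yc, IRanges::IRanges(intr[, "start"], intr[, "end"]),
                gstart)
    }
    ## exons = aligned span minus introns
    if (length(intron_iv)) {
        ex_start <- c(gstart, IRanges::end(intron_iv) + 1L)
        ex_end <- c(IRanges::start(intron_iv) - 1L, gend)
    } else {
        ex_start <- gstart; ex_end <- gend
    }
    gs <- geneStructure(gene_id,
                        IRanges::IRanges(ex_start, ex_end))
    ## exonic identity: spliced genomic vs cDNA
    spliced <- paste(vapply(seq_along(ex_start), function(k)
        substr(genomic, ex_start[k], ex_end[k]), ""), collapse = "")
    pid <- percentIdentity(cdna, spliced, mode = "global",
                           moltype = "dna") / 100
    if (pid < min_exon_identity)
        stop(sprintf(
            "exonic identity %.1f%% below %.0f%%: not a spliced pair",
            100 * pid, 100 * min_exon_identity))
    attr(gs, "gt_ag") <- if (length(intron_iv)) {
        vapply(seq_along(intron_iv), function(r)
            paste0(yc[IRanges::start(intron_iv)[r]],
                   yc[IRanges::start(intron_iv)[r] + 1L]) == "GT" &&
            paste0(yc[IRanges::end(intron_iv)[r] - 1L],
                   yc[IRanges::end(intron_iv)[r]]) == "AG",
            logical(1L))
    } else logical(0)
    attr(gs, "exon_identity") <- pid
    gs
}

#' Intron-position homology across genes via a shared protein MSA
#'
#' Expresses every intron as (codon index in MSA coordinates, phase
#' 0/1/2) and marks, for each gene, which of the reference gene's
#' introns are present at homologous positions and which are absent.
#'
#' @param structures Named list of [GeneStructure-class] objects.
#' @param reference_id Name of the reference gene in
#'   \code{structures}.
#' @param protein_aln Named AAStringSet containing a row per gene
#'   (ungapped row length = gene's codon count).
#' @param orf_offset Named integer: nt offset of the ORF start within
#'   each gene's spliced cDNA (0 if the structure starts at the ORF).
#' @return data.frame with one row per (gene, reference intron):
#'   \code{gene}, \code{ref_intron} (index), \code{msa_codon},
#'   \code{phase}, \code{status} ("shared"/"absent").
#' @export
compareStructures <- function(structures, reference_id, protein_aln,
                              orf_offset = NULL) {
    ids <- names(structures)
    if (!reference_id %in% ids) stop("reference gene not in structures")
    miss <- setdiff(ids, names(protein_aln))
    if (length(miss))
        stop("gene(s) absent from MSA: ", paste(miss, collapse = ", "))
    if (is.null(orf_offset))
        orf_offset <- setNames(rep(0L, length(ids)), ids)
    ## cDNA coordinate of each intron (nt 5' exonic length), then codon
    ## + phase, then MSA column via the gene's gapped row
    intron_codons <- function(id) {
        st <- structures[[id]]
        if (!length(introns(st))) return(NULL)
        ex <- exons(st)
        cum <- cumsum(IRanges::width(ex))
        cdna_pos <- cum[seq_along(introns(st))]      # nt before intron k
        cds_pos <- cdna_pos - orf_offset[[id]]
        codon <- cds_pos %/% 3L + 1L                 # codon after which
        phase <- cds_pos %% 3L
        row <- strsplit(as.character(protein_aln[[id]]), "")[[1L]]
        respos <- which(row != "-")
        msa_codon <- respos[pmin(codon, length(respos))]
        data.frame(intron = seq_along(cdna_pos), msa_codon = msa_codon,
                   phase = phase)
    }
    ref <- intron_codons(reference_id)
    if (is.null(ref)) stop("reference gene has no introns")
    rows <- list()
    for (id in ids) {
        g <- intron_codons(id)
        for (k in seq_len(nrow(ref))) {
            shared <- !is.null(g) &&
                any(g$msa_codon == ref$msa_codon[k] &
                    g$phase == ref$phase[k])
            rows[[length(rows) + 1L]] <- data.frame(
                gene = id, ref_intron = k,
                msa_codon = ref$msa_codon[k], phase = ref$phase[k],
                status = if (shared) "shared" else "absent")
        }
    }
    do.call(rbind, rows)
}

#' Detect partial intron retention between two isoforms
#'
#' Globally aligns two isoforms of one gene, extracts the differing
#' block(s), and, given the gene's known structure, calls partial
#' retention when a single inserted block lies at an intron boundary.
#'
#' @param isoform_a,isoform_b Character/XString cDNA isoforms
#'   (\code{isoform_a} = the longer candidate-retention isoform by
#'   convention; order is detected automatically).
#' @param structure Optional [GeneStructure-class] of the gene;
#'   \code{cdna_intron_positions} may be given instead.
#' @param cdna_intron_positions Optional integer vector of nt
#'   positions (0-based, position within the shorter isoform after
#'   which each intron sits).
#' @return List with \code{n_blocks}, \code{length}, \code{position}
#'   (0-based nt offset in the shorter isoform), \code{call}
#'   ("identical", "partial_retention", "insertion",
#'   "multiple_blocks") and \code{block} (sequence).
#' @export
detectIntronRetention <- function(isoform_a, isoform_b,
                                  structure = NULL,
                                  cdna_intron_positions = NULL) {
    a <- toupper(as.character(isoform_a))
    b <- toupper(as.character(isoform_b))
    if (nchar(a) < nchar(b)) { tmp <- a; a <- b; b <- tmp }
    if (a == b)
        return(list(n_blocks = 0L, length = 0L, position = NA_integer_,
                    call = "identical", block = ""))
    al <- pairwiseAlign(a, b, mode = "global", moltype = "dna")
    ca <- strsplit(al$aligned_a, "")[[1L]]
    cb <- strsplit(al$aligned_b, "")[[1L]]
    gaps_b <- cb == "-"
    r <- rle(gaps_b)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    blocks <- which(r$values)
    mism <- sum(ca != cb & !gaps_b & ca != "-")
    if (!length(blocks) || any(ca == "-"))
        return(list(n_blocks = length(blocks), length = 0L,
                    position = NA_integer_, call = "complex",
                    block = ""))
    if (length(blocks) > 1L)
        return(list(n_blocks = length(blocks),
                    length = r$lengths[blocks],
                    position = NA_integer_, call = "multiple_blocks",
                    block = ""))
    k <- blocks[1L]
    len <- r$lengths[k]
    pos <- sum(!gaps_b[seq_len(starts[k] - 1L)])  # 0-based in shorter
    blockseq <- paste(ca[starts[k]:ends[k]], collapse = "")
    if (is.null(cdna_intron_positions) && !is.null(structure)) {
        ex <- exons(structure)
        cum <- cumsum(IRanges::width(ex))
        cdna_intron_positions <- cum[seq_len(length(introns(structure)))]
    }
    call <- if (!is.null(cdna_intron_positions) &&
                pos %in% cdna_intron_positions)
        "partial_retention" else "insertion"
    list(n_blocks = 1L, length = len, position = pos, call = call,
         block = blockseq, mismatches = mism)
}
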