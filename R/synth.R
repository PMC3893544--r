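## Synthetic-data generators.  Every generator is deterministic given
## its seed and returns the ground truth alongside the data, so each
## pipeline stage can be tested against known answers without any
## external download.

.NT <- c("A", "C", "G", "T")

## Substitute a coding sequence (vector of codon strings) at an
## expected rate of `subs_per_site` amino-acid-changing-or-not nt
## substitutions per nt site, rejecting mutations that create stops.
.mutateCDS <- function(codons, subs_per_site) {
    nnt <- 3L * length(codons)
    nmut <- rpois(1L, subs_per_site * nnt)
    gc <- Biostrings::GENETIC_CODE
    for (m in seq_len(nmut)) {
        repeat {
            pos <- sample.int(nnt, 1L)
            ci <- (pos - 1L) %/% 3L + 1L
            off <- (pos - 1L) %% 3L + 1L
            cod <- strsplit(codons[ci], "")[[1L]]
            cod[off] <- sample(setdiff(.NT, cod[off]), 1L)
            cand <- paste(cod, collapse = "")
            if (gc[[cand]] != "*") { codons[ci] <- cand; break }
        }
    }
    codons
}

.randomCDS <- function(n_codons) {
    sample(senseCodons(), n_codons, replace = TRUE)
}

.randomNt <- function(n) paste(sample(.NT, n, replace = TRUE),
                               collapse = "")

#' Default study taxonomy for the simulators
#'
#' A small plant species tree (branch lengths in substitutions/site)
#' with named lineages: the recipient is a Lamiales holoparasite, its
#' sister taxon is also Lamiales, the donor clade is Brassicales (one
#' member of which doubles as the host), plus outgroup rosids,
#' Solanales and a monocot.
#'
#' @return List with \code{tree} (phylo), \code{lineages} (named list
#'   of lineage vectors per species), and the roles
#'   \code{recipient}, \code{sister}, \code{donor_clade}, \code{host}.
#' @export
defaultTaxonomy <- function() {
    txt <- paste0(
        "((Oryza_sativa:0.9,(((Arabidopsis_thaliana:0.12,",
        "Brassica_rapa:0.12):0.08,Capsella_rubella:0.2):0.55,",
        "(Vitis_vinifera:0.55,(Solanum_lycopersicum:0.5,",
        "(Orobanche_aegyptiaca:0.22,Mimulus_guttatus:0.22):0.28):0.15)",
        ":0.2):0.15):0.1);")
    tree <- ape::read.tree(text = txt)
    lin <- list(
        Oryza_sativa = c("Viridiplantae", "Liliopsida", "Poales",
                         "Oryza sativa"),
        Arabidopsis_thaliana = c("Viridiplantae", "eudicotyledons",
            "Brassicales", "Brassicaceae", "Arabidopsis thaliana"),
        Brassica_rapa = c("Viridiplantae", "eudicotyledons",
            "Brassicales", "Brassicaceae", "Brassica rapa"),
        Capsella_rubella = c("Viridiplantae", "eudicotyledons",
            "Brassicales", "Brassicaceae", "Capsella rubella"),
        Vitis_vinifera = c("Viridiplantae", "eudicotyledons", "Vitales",
                           "Vitis vinifera"),
        Solanum_lycopersicum = c("Viridiplantae", "eudicotyledons",
            "Solanales", "Solanum lycopersicum"),
        Orobanche_aegyptiaca = c("Viridiplantae", "eudicotyledons",
            "Lamiales", "Orobanchaceae", "Orobanche aegyptiaca"),
        Mimulus_guttatus = c("Viridiplantae", "eudicotyledons",
            "Lamiales", "Phrymaceae", "Mimulus guttatus"))
    list(tree = tree, lineages = lin,
         recipient = "Orobanche_aegyptiaca",
         sister = "Mimulus_guttatus",
         donor_clade = c("Arabidopsis_thaliana", "Brassica_rapa",
                         "Capsella_rubella"),
         host = "Arabidopsis_thaliana")
}

## Evolve one coding gene family along a taxonomy tree; returns a
## list species -> codon vector.  Deletions (codon-aligned, geometric
## lengths) are recorded so the true alignment is recoverable.
.evolveFamily <- function(tree, root_codons, indel_rate = 0,
                          indel_mean_len = 2) {
    ti <- .treeInfo(ape::reorder.phylo(tree, "cladewise"))
    edge <- tree$edge
    len <- tree$edge.length
    if (any(len < 0)) stop("branch length < 0")
    ntip <- length(tree$tip.label)
    ## preorder traversal from root
    ord <- ape::reorder.phylo(tree, "cladewise")$edge
    lenord <- ape::reorder.phylo(tree, "cladewise")$edge.length
    state <- vector("list", ntip + tree$Nnode)
    ncod <- length(root_codons)
    state[[ntip + 1L]] <- list(cod = root_codons,
                               col = seq_len(ncod))  # root
    for (e in seq_len(nrow(ord))) {
        par <- state[[ord[e, 1L]]]
        cod <- .mutateCDS(par$cod, lenord[e])
        col <- par$col
        if (indel_rate > 0) {
            ndel <- rpois(1L, indel_rate * length(cod) * lenord[e])
            for (d in seq_len(ndel)) {
                if (length(cod) < 4L) break
                l <- min(1L + rpois(1L, indel_mean_len - 1L),
                         length(cod) - 3L)
                s <- sample.int(length(cod) - l + 1L, 1L)
                cod <- cod[-(s:(s + l - 1L))]
                col <- col[-(s:(s + l - 1L))]
            }
        }
        state[[ord[e, 2L]]] <- list(cod = cod, col = col)
    }
    out <- state[seq_len(ntip)]
    names(out) <- tree$tip.label
    attr(out, "n_columns") <- ncod
    out
}

## True protein alignment of a family from the per-species column ids.
.familyAlignment <- function(fam) {
    ncol <- attr(fam, "n_columns")
    rows <- vapply(fam, function(sp) {
        aa <- rep("-", ncol)
        aa[sp$col] <- unname(
            Biostrings::GENETIC_CODE[sp$cod])
        paste(aa, collapse = "")
    }, "")
    Biostrings::AAStringSet(rows)
}

#' Simulate a taxonomy-labelled reference protein database
#'
#' One coding gene family per gene is evolved along the taxonomy by a
#' Poisson nucleotide substitution process (stop codons rejected),
#' optionally with codon-aligned deletions of geometric length.  The
#' database stands in for a public protein collection: every species'
#' copy becomes a subject with a lineage entry.
#'
#' @param taxonomy As returned by [defaultTaxonomy()].
#' @param n_genes Number of gene families.
#' @param gene_length_codons Length of each family's root CDS
#'   (recycled).
#' @param indel_rate Expected deletions per codon per substitution
#'   unit (default 0).
#' @param seed Integer seed; the output is reproducible bit for bit.
#' @return List with \code{proteins} (AAStringSet, ids
#'   \code{species|famNNN}), \code{cds} (DNAStringSet, same ids),
#'   \code{lineages} (named list), \code{alignments} (list of true
#'   per-family protein alignments), \code{families} (list of raw
#'   per-family codon states).
#' @export
simulateReferenceDB <- function(taxonomy = defaultTaxonomy(),
                                n_genes = 10L,
                                gene_length_codons = 160L,
                                indel_rate = 0, seed = 1L) {
    set.seed(seed)
    glen <- rep_len(gene_length_codons, n_genes)
    fams <- vector("list", n_genes)
    prot <- character(); cds <- character()
    for (g in seq_len(n_genes)) {
        fam <- .evolveFamily(taxonomy$tree, .randomCDS(glen[g]),
                             indel_rate = indel_rate)
        fams[[g]] <- fam
        ids <- sprintf("%s|fam%03d", names(fam), g)
        cds_g <- vapply(fam, function(sp) paste(sp$cod, collapse = ""), "")
        prot_g <- vapply(fam, function(sp)
            paste(Biostrings::GENETIC_CODE[sp$cod], collapse = ""), "")
        names(cds_g) <- names(prot_g) <- ids
        prot <- c(prot, prot_g); cds <- c(cds, cds_g)
    }
    subj_species <- sub("\\|.*$", "", names(prot))
    list(proteins = Biostrings::AAStringSet(prot),
         cds = Biostrings::DNAStringSet(cds),
         lineages = setNames(taxonomy$lineages[subj_species],
                             names(prot)),
         alignments = lapply(fams, .familyAlignment),
         families = fams, taxonomy = taxonomy)
}

.plantIntrons <- function(cds, positions, lengths) {
    ## positions: 0-based nt offsets into the CDS where introns sit
    pieces <- character(); intr <- IRanges::IRanges()
    prev <- 0L; genomic <- ""
    ord <- order(positions)
    positions <- positions[ord]; lengths <- lengths[ord]
    for (i in seq_along(positions)) {
        exon <- substr(cds, prev + 1L, positions[i])
        iseq <- paste0("GT", .randomNt(lengths[i] - 4L), "AG")
        start <- nchar(genomic) + nchar(exon) + 1L
        genomic <- paste0(genomic, exon, iseq)
        intr <- c(intr, IRanges::IRanges(start, start + lengths[i] - 1L))
        prev <- positions[i]
    }
    genomic <- paste0(genomic, substr(cds, prev + 1L, nchar(cds)))
    list(genomic = genomic, introns = intr)
}

#' Simulate the recipient transcriptome with planted foreign genes
#'
#' Builds a transcriptome for the recipient species containing native
#' genes (the recipient's own family copies plus extra divergence),
#' horizontally acquired genes (donor-clade copies with configurable
#' divergence), and host-contaminant transcripts (exact host copies).
#' Genomic versions of the native and HGT genes carry introns at
#' recorded positions; HGT genes share the donor family's intron
#' positions.  One HGT gene is emitted as two isoforms differing by a
#' partial intron retention of configurable length.
#'
#' @param reference Output of [simulateReferenceDB()].
#' @param n_native,n_hgt,n_contaminant Transcript counts per label.
#' @param native_divergence Extra substitutions/site applied to native
#'   copies (keeps them distinct from their own reference entry).
#' @param hgt_divergence Substitutions/site between an HGT gene and
#'   its donor-clade source copy (the easy screening regime uses
#'   values well below the recipient-to-donor distance).
#' @param utr_length 5' and 3' UTR length added around each ORF.
#' @param n_introns Introns planted per gene.
#' @param intron_length_range Intron length range (nt).
#' @param retention_length Length (nt) of the partially retained
#'   intron fragment distinguishing the two isoforms of the first HGT
#'   gene (0 disables; default 21).
#' @param seed Integer seed.
#' @return List with \code{transcripts} (DNAStringSet),
#'   \code{genomic} (DNAStringSet of genomic versions),
#'   \code{structures} (list of [GeneStructure-class]),
#'   \code{truth} (data.frame: transcript_id, label, family, source
#'   species, ORF coordinates), \code{retention} (list describing the
#'   planted isoform pair, or NULL).
#' @export
simulateRecipientTranscriptome <- function(reference,
        n_native = 20L, n_hgt = 3L, n_contaminant = 5L,
        native_divergence = 0.1, hgt_divergence = 0.15,
        utr_length = 60L, n_introns = 2L,
        intron_length_range = c(60L, 120L),
        retention_length = 21L, seed = 1L) {
    set.seed(seed + 1L)
    tax <- reference$taxonomy
    if (all(tax$donor_clade %in% c(tax$recipient, tax$sister)))
        stop("donor clade equals recipient clade: no screening signal")
    n_fam <- length(reference$families)
    need <- n_native + n_hgt + n_contaminant
    fam_of <- ((seq_len(need) - 1L) %% n_fam) + 1L
    labels <- rep(c("native", "hgt", "contaminant"),
                  c(n_native, n_hgt, n_contaminant))
    donor <- tax$host

    tx <- character(); gseq <- character(); structs <- list()
    truth <- data.frame(transcript_id = character(),
                        label = character(), family = integer(),
                        source_species = character(),
                        orf_start = integer(), orf_end = integer(),
                        stringsAsFactors = FALSE)
    retention <- NULL
    intron_pos_cache <- list()   # per family: donor intron positions
    for (i in seq_len(need)) {
        fam <- reference$families[[fam_of[i]]]
        lab <- labels[i]
        src <- switch(lab, native = tax$recipient, hgt = donor,
                      contaminant = donor)
        cod <- fam[[src]]$cod
        cod <- switch(lab,
            native = .mutateCDS(cod, native_divergence),
            hgt = .mutateCDS(cod, hgt_divergence),
            contaminant = cod)
        cdsseq <- paste(cod, collapse = "")
        utr5 <- .randomNt(utr_length); utr3 <- .randomNt(utr_length)
        cdna <- paste0(utr5, "ATG", cdsseq, "TAA", utr3)
        id <- sprintf("%s%02d", switch(lab, native = "ntv",
                                       hgt = "hgt", contaminant = "ctm"), i)
        tx[id] <- cdna
        truth <- rbind(truth, data.frame(
            transcript_id = id, label = lab, family = fam_of[i],
            source_species = src, orf_start = utr_length + 1L,
            orf_end = utr_length + 3L + nchar(cdsseq) + 3L))
        if (lab %in% c("native", "hgt") && n_introns > 0L) {
            key <- as.character(fam_of[i])
            ncod_src <- length(cod)
            if (lab == "hgt") {
                ## donor-matching positions, shared within the family
                if (is.null(intron_pos_cache[[key]])) {
                    intron_pos_cache[[key]] <- sort(sample(
                        seq(30L, ncod_src * 3L - 30L, by = 3L), n_introns))
                }
                pos <- intron_pos_cache[[key]]
            } else {
                pos <- sort(sample(
                    seq(30L, ncod_src * 3L - 30L, by = 3L), n_introns))
            }
            ilen <- sample(seq(intron_length_range[1L],
                               intron_length_range[2L]), n_introns,
                           replace = TRUE)
            orf <- paste0("ATG", cdsseq, "TAA")
            pl <- .plantIntrons(orf, pos + 3L, ilen)  # offset for ATG
            gseq[id] <- pl$genomic
            ## record canonical (left-justified) intron coordinates
            iv <- .leftJustifyIntrons(strsplit(pl$genomic, "")[[1L]],
                                      pl$introns)
            ex_start <- c(1L, IRanges::end(iv) + 1L)
            ex_end <- c(IRanges::start(iv) - 1L, nchar(pl$genomic))
            structs[[id]] <- geneStructure(id,
                IRanges::IRanges(ex_start, ex_end))
        }
    }
    ## isoform pair with partial intron retention
    hgt_ids <- truth$transcript_id[truth$label == "hgt"]
    if (retention_length > 0L && length(hgt_ids)) {
        gid <- hgt_ids[1L]
        st <- structs[[gid]]
        if (length(introns(st)) >= 2L) {
            intr <- introns(st)[2L]
            row <- truth[truth$transcript_id == gid, ]
            base <- tx[[gid]]
            ## cDNA position of the intron = 5' exonic nt before it,
            ## offset by the 5' UTR
            exon_nt_before <- IRanges::start(intr) - 1L -
                IRanges::width(introns(st))[1L]
            cpos <- row$orf_start - 1L + exon_nt_before
            ## the emulated retention preserves the reading frame and
            ## must not create an in-frame stop; keep the GT donor
            ## dinucleotide and resample until the isoform ORF is clean
            stopifnot(retention_length %% 3L == 0L)
            g0 <- gseq[[gid]]
            repeat {
                retained <- paste0("GT",
                    .randomNt(retention_length - 2L))
                iso <- paste0(substr(base, 1L, cpos), retained,
                              substr(base, cpos + 1L, nchar(base)))
                orf_nt <- substr(iso, row$orf_start,
                                 row$orf_end + retention_length - 3L)
                aa <- as.character(Biostrings::translate(
                    Biostrings::DNAString(orf_nt),
                    if.fuzzy.codon = "solve"))
                if (!grepl("*", aa, fixed = TRUE)) break
            }
            gseq[[gid]] <- paste0(
                substr(g0, 1L, IRanges::start(intr) - 1L), retained,
                substr(g0, IRanges::start(intr) + retention_length,
                       nchar(g0)))
            iso_id <- paste0(gid, "_iso1")
            tx[iso_id] <- iso
            truth <- rbind(truth, data.frame(
                transcript_id = iso_id, label = "hgt",
                family = row$family, source_species = row$source_species,
                orf_start = row$orf_start, orf_end = row$orf_end +
                    retention_length))
            retention <- list(gene = gid, isoform = iso_id,
                              length = retention_length,
                              cdna_position = cpos,
                              intron_index = 2L)
        }
    }
    list(transcripts = Biostrings::DNAStringSet(tx),
         genomic = Biostrings::DNAStringSet(gseq),
         structures = structs, truth = truth, retention = retention,
         reference = reference)
}

#' Simulate staged paired-end read sets
#'
#' Contaminant transcripts receive zero fragments in host-free stages
#' and positive coverage in attached stages; native and HGT
#' transcripts are covered in all stages.  Fragment starts are
#' uniform; a per-base error rate applies independent substitutions.
#'
#' @param transcriptome Output of [simulateRecipientTranscriptome()].
#' @param stages Named logical vector: stage name -> host_free flag.
#'   At least one host-free and one attached stage required.
#' @param depth Expected per-base coverage per stage.
#' @param read_length Read length (nt).
#' @param insert_size Fragment length (nt).
#' @param error_rate Per-base substitution error probability.
#' @param seed Integer seed.
#' @return Named list per stage: \code{list(reads =
#'   QualityScaledDNAStringSet, host_free = flag, origin = character
#'   vector of source transcript per fragment)}.  Mate 1 and mate 2 of
#'   fragment i are reads \code{2i-1} and \code{2i}.
#' @export
simulateReads <- function(transcriptome,
                          stages = c(germination = TRUE,
                                     radicle = TRUE,
                                     attached1 = FALSE,
                                     attached2 = FALSE),
                          depth = 6, read_length = 50L,
                          insert_size = 120L, error_rate = 0,
                          seed = 1L) {
    if (!any(stages) || !any(!stages))
        stop("need at least one host-free and one attached stage")
    set.seed(seed + 2L)
    tx <- transcriptome$transcripts
    truth <- transcriptome$truth
    out <- list()
    for (s in names(stages)) {
        host_free <- stages[[s]]
        seqs <- character(); origin <- character()
        for (i in seq_along(tx)) {
            id <- names(tx)[i]
            lab <- truth$label[truth$transcript_id == id]
            if (host_free && lab == "contaminant") next
            L <- Biostrings::width(tx)[i]
            if (read_length > L) {
                warning("read length exceeds transcript ", id,
                        "; skipped")
                next
            }
            ins <- min(insert_size, L)
            nfrag <- rpois(1L, depth * L / (2 * read_length))
            if (nfrag == 0L) next
            starts <- sample.int(L - ins + 1L, nfrag, replace = TRUE)
            frag <- substring(as.character(tx[[i]]), starts,
                              starts + ins - 1L)
            r1 <- substr(frag, 1L, read_length)
            r2 <- vapply(frag, function(f) as.character(
                Biostrings::reverseComplement(Biostrings::DNAString(
                    substr(f, nchar(f) - read_length + 1L, nchar(f))))),
                "", USE.NAMES = FALSE)
            reads <- as.vector(rbind(r1, r2))
            if (error_rate > 0) {
                reads <- vapply(reads, function(r) {
                    b <- strsplit(r, "")[[1L]]
                    hit <- runif(length(b)) < error_rate
                    if (any(hit))
                        b[hit] <- vapply(b[hit], function(x)
                            sample(setdiff(.NT, x), 1L), "")
                    paste(b, collapse = "")
                }, "", USE.NAMES = FALSE)
            }
            names(reads) <- sprintf("%s:%s:f%04d/%d", s, id,
                rep(seq_len(nfrag), each = 2L), rep(1:2, nfrag))
            seqs <- c(seqs, reads)
            origin <- c(origin, rep(id, nfrag))
        }
        dna <- Biostrings::DNAStringSet(seqs)
        qual <- Biostrings::PhredQuality(
            vapply(Biostrings::width(dna), function(w)
                paste(rep("G", w), collapse = ""), ""))  # Q38
        out[[s]] <- list(
            reads = Biostrings::QualityScaledDNAStringSet(dna, qual),
            host_free = host_free, origin = origin)
    }
    out
}

#' Simulate a tabular homology-hit set for the screen
#'
#' Emulates a protein (or nucleotide) database search of each query
#' against the reference collection: each query is locally aligned to
#' every member of its own gene family (other families would score
#' below reporting thresholds) and the alignment scores are converted
#' to bit scores with Karlin-Altschul parameters.
#'
#' @param queries Named XStringSet of query sequences (protein ORFs or
#'   cDNAs).
#' @param query_family Integer vector, family index per query.
#' @param reference Output of [simulateReferenceDB()].
#' @param level "protein" or "nucleotide".
#' @return Hit data.frame in the layout of [readHitTable()] (already
#'   lineage-joined and sorted).
#' @export
simulateHitTable <- function(queries, query_family, reference,
                             level = c("protein", "nucleotide")) {
    level <- match.arg(level)
    subjects <- if (level == "protein") reference$proteins
                else reference$cds
    subj_fam <- as.integer(sub("^.*\\|fam", "", names(subjects)))
    rows <- list()
    for (qi in seq_along(queries)) {
        members <- which(subj_fam == query_family[qi])
        if (level == "protein") {
            pa <- Biostrings::pairwiseAlignment(
                rep(queries[qi], length(members)), subjects[members],
                type = "local", substitutionMatrix = "BLOSUM62",
                gapOpening = 11, gapExtension = 1)
            bits <- (0.267 * Biostrings::score(pa) - log(0.041)) / log(2)
        } else {
            mat <- Biostrings::nucleotideSubstitutionMatrix(
                match = 2, mismatch = -3)
            pa <- Biostrings::pairwiseAlignment(
                rep(queries[qi], length(members)), subjects[members],
                type = "local", substitutionMatrix = mat,
                gapOpening = 5, gapExtension = 2)
            bits <- (0.625 * Biostrings::score(pa) - log(0.41)) / log(2)
        }
        pid <- Biostrings::pid(pa, type = "PID2")
        w <- Biostrings::nchar(pa)
        keep <- which(bits > 0)
        if (!length(keep)) next
        rows[[length(rows) + 1L]] <- data.frame(
            query_id = names(queries)[qi],
            subject_id = names(subjects)[members][keep],
            percent_identity = round(pid[keep], 2),
            aln_length = w[keep],
            mismatches = round(w[keep] * (1 - pid[keep] / 100)),
            gap_opens = 0L,
            qstart = Biostrings::start(Biostrings::pattern(pa))[keep] - 1L,
            qend = Biostrings::end(Biostrings::pattern(pa))[keep],
            sstart = Biostrings::start(Biostrings::subject(pa))[keep],
            send = Biostrings::end(Biostrings::subject(pa))[keep],
            e_value = 2^(-bits[keep]) * 1e9,
            bit_score = round(bits[keep], 1))
    }
    tab <- do.call(rbind, rows)
    tab <- tab[order(tab$query_id, -tab$bit_score), , drop = FALSE]
    rownames(tab) <- NULL
    tab$lineage <- unname(reference$lineages[tab$subject_id])
    tab
}

#' Simulate a codon alignment under site or branch-site regimes
#'
#' Root codons are drawn from the equilibrium frequencies and evolved
#' along the tree under a GY94 process; each site's class is recorded.
#' In branch-site mode the foreground branches substitute the
#' foreground omega for sites of the selected classes.
#'
#' @param tree \code{phylo} with branch lengths (expected
#'   substitutions per codon).
#' @param kappa Transition/transversion ratio (> 0).
#' @param omegas Numeric vector of class omegas (>= 0).
#' @param proportions Class proportions summing to 1.
#' @param n_codons Number of codon sites.
#' @param freqs Codon equilibrium frequencies (default equal).
#' @param foreground Tip labels of the foreground clade; with
#'   \code{omega_fg}, switches the last class to \code{omega_fg} on
#'   foreground branches.
#' @param omega_fg Foreground omega for branch-site simulation.
#' @param seed Integer seed.
#' @return List with \code{alignment} (DNAStringSet) and
#'   \code{site_class} (integer vector of true classes).
#' @export
simulateCodonAlignment <- function(tree, kappa = 2, omegas = 0.2,
                                   proportions = 1, n_codons = 300L,
                                   freqs = NULL, foreground = NULL,
                                   omega_fg = NULL, seed = 1L) {
    if (abs(sum(proportions) - 1) > 1e-8)
        stop("class proportions must sum to 1")
    if (any(omegas < 0) || kappa <= 0)
        stop("omega must be >= 0 and kappa > 0")
    set.seed(seed)
    cc <- .CODONS
    if (is.null(freqs)) freqs <- rep(1 / cc$n, cc$n)
    site_class <- sample.int(length(omegas), n_codons, replace = TRUE,
                             prob = proportions)
    ## one common rate scale over classes (matches the inference side)
    Qs <- lapply(omegas, function(w)
        buildQ(kappa, w, freqs, scale = FALSE))
    S <- sum(proportions * vapply(Qs, attr, numeric(1L), "mu"))
    egs <- lapply(Qs, function(Q) .codonEigen(Q / S, freqs))
    eg_fg <- if (!is.null(omega_fg))
        .codonEigen(buildQ(kappa, omega_fg, freqs, scale = FALSE) / S,
                    freqs) else NULL
    tr <- ape::reorder.phylo(tree, "cladewise")
    ntip <- length(tr$tip.label)
    fg_edges <- if (is.null(foreground)) integer() else {
        ti <- .treeInfo(tree)
        fge <- .foregroundEdges(ti, foreground)
        ## map postorder edge rows back to cladewise rows
        key <- paste(ti$edge[fge, 1L], ti$edge[fge, 2L])
        which(paste(tr$edge[, 1L], tr$edge[, 2L]) %in% key)
    }
    states <- matrix(NA_integer_, ntip + tr$Nnode, n_codons)
    states[ntip + 1L, ] <- sample.int(cc$n, n_codons, replace = TRUE,
                                      prob = freqs)
    for (e in seq_len(nrow(tr$edge))) {
        parent <- states[tr$edge[e, 1L], ]
        child <- integer(n_codons)
        is_fg <- e %in% fg_edges
        for (k in seq_along(omegas)) {
            idx <- which(site_class == k)
            if (!length(idx)) next
            eg <- if (is_fg && !is.null(eg_fg) && k == length(omegas))
                eg_fg else egs[[k]]
            P <- .codonP(eg, tr$edge.length[e])
            for (i in idx)
                child[i] <- sample.int(cc$n, 1L, prob = P[parent[i], ])
        }
        states[tr$edge[e, 2L], ] <- child
    }
    rows <- apply(states[seq_len(ntip), , drop = FALSE], 1L, function(s)
        paste(cc$codons[s], collapse = ""))
    aln <- Biostrings::DNAStringSet(setNames(rows, tr$tip.label))
    list(alignment = aln, site_class = site_class,
         ancestral = states, tree = tr)
}

.AA20 <- setdiff(unique(Biostrings::GENETIC_CODE), "*")

## Evolve one protein site along a tree at rate r; returns tip states
## and substitution count.
.evolveProteinSite <- function(tr, rate, root_aa) {
    ntip <- length(tr$tip.label)
    st <- character(ntip + tr$Nnode)
    st[ntip + 1L] <- root_aa
    nsub <- 0L
    for (e in seq_len(nrow(tr$edge))) {
        a <- st[tr$edge[e, 1L]]
        k <- rpois(1L, rate * tr$edge.length[e])
        nsub <- nsub + k
        for (j in seq_len(k)) a <- sample(setdiff(.AA20, a), 1L)
        st[tr$edge[e, 2L]] <- a
    }
    list(tips = setNames(st[seq_len(ntip)], tr$tip.label), nsub = nsub)
}

#' Simulate a two-cluster alignment with rate-shifted sites
#'
#' A fraction \code{theta_true} of sites draw independent gamma(alpha)
#' rates in the two clusters (type-I divergent sites); the remainder
#' share a single gamma rate.  Substitutions are placed by a Poisson
#' process along each cluster's tree with uniform amino-acid
#' replacement.
#'
#' @param tree1,tree2 \code{phylo} trees of the two clusters (>= 4
#'   tips each recommended).
#' @param theta_true Fraction of divergent sites, between 0 and 1.
#' @param alpha Gamma shape (> 0) of the rate distribution.
#' @param n_sites Number of alignment columns.
#' @param seed Integer seed.
#' @return List with \code{alignment} (AAStringSet over both
#'   clusters' tips), \code{divergent} (logical truth per site),
#'   \code{rates} (n_sites x 2 matrix), \code{counts} (true
#'   substitution counts per site per cluster), and the cluster
#'   membership.
#' @export
simulateDivergenceAlignment <- function(tree1, tree2, theta_true = 0.3,
                                        alpha = 0.5, n_sites = 500L,
                                        seed = 1L) {
    if (alpha <= 0) stop("alpha must be > 0")
    if (theta_true < 0 || theta_true > 1)
        stop("theta_true must be in [0, 1]")
    set.seed(seed)
    tr1 <- ape::reorder.phylo(tree1, "cladewise")
    tr2 <- ape::reorder.phylo(tree2, "cladewise")
    divergent <- runif(n_sites) < theta_true
    r_shared <- rgamma(n_sites, alpha, alpha)
    r1 <- ifelse(divergent, rgamma(n_sites, alpha, alpha), r_shared)
    r2 <- ifelse(divergent, rgamma(n_sites, alpha, alpha), r_shared)
    m1 <- matrix("", length(tr1$tip.label), n_sites,
                 dimnames = list(tr1$tip.label, NULL))
    m2 <- matrix("", length(tr2$tip.label), n_sites,
                 dimnames = list(tr2$tip.label, NULL))
    counts <- matrix(0L, n_sites, 2L)
    for (s in seq_len(n_sites)) {
        root <- sample(.AA20, 1L)
        e1 <- .evolveProteinSite(tr1, r1[s], root)
        e2 <- .evolveProteinSite(tr2, r2[s], root)
        m1[, s] <- e1$tips; m2[, s] <- e2$tips
        counts[s, ] <- c(e1$nsub, e2$nsub)
    }
    aln <- Biostrings::AAStringSet(c(
        setNames(apply(m1, 1L, paste, collapse = ""), rownames(m1)),
        setNames(apply(m2, 1L, paste, collapse = ""), rownames(m2))))
    list(alignment = aln, divergent = divergent,
         rates = cbind(r1, r2), counts = counts,
         cluster1 = tr1$tip.label, cluster2 = tr2$tip.label)
}

#' Simulate a qPCR cycle-threshold table with planted fold changes
#'
#' Target-gene Ct follows baseline - log2(fold) + N(0, noise_sd) per
#' replicate; reference genes have condition-independent baselines
#' plus optional linear drift across conditions (noise-free unless
#' \code{reference_noise_sd} is given).
#'
#' @param fold_changes Named numeric of planted target fold changes per
#'   condition (calibrator = 1 must be included).
#' @param reference_genes Character vector of candidate reference gene
#'   names.
#' @param n_replicates Biological replicates per condition.
#' @param noise_sd Ct noise SD (>= 0).
#' @param target Target gene name.
#' @param target_baseline Target baseline Ct in the calibrator.
#' @param reference_baselines Named numeric baselines for the
#'   references (defaults spread around 18-24).
#' @param reference_drift Named numeric per-condition-step Ct drift
#'   for each reference (default 0: all stable).
#' @param reference_noise_sd Optional named numeric per-gene noise SD
#'   for the references (default 0 for all: the planted noise applies
#'   to the target); lets a planted most-stable gene combine zero
#'   drift with the smallest noise.
#' @param seed Integer seed.
#' @return SummarizedExperiment as from [makeCtTable()].
#' @export
simulateQpcr <- function(fold_changes = c(ctrl = 1, treated = 3.2),
                         reference_genes = c("ACT", "EF1a", "EFTu",
                                             "PP2A"),
                         n_replicates = 5L, noise_sd = 0.1,
                         target = "SSL", target_baseline = 24,
                         reference_baselines = NULL,
                         reference_drift = NULL,
                         reference_noise_sd = NULL, seed = 1L) {
    if (noise_sd < 0) stop("noise_sd must be >= 0")
    set.seed(seed)
    conds <- names(fold_changes)
    if (is.null(reference_baselines))
        reference_baselines <- setNames(
            seq(18, 24, length.out = length(reference_genes)),
            reference_genes)
    if (is.null(reference_drift))
        reference_drift <- setNames(rep(0, length(reference_genes)),
                                    reference_genes)
    if (is.null(reference_noise_sd))
        reference_noise_sd <- setNames(
            rep(0, length(reference_genes)), reference_genes)
    genes <- c(target, reference_genes)
    nw <- length(conds) * n_replicates
    m <- matrix(NA_real_, length(genes), nw,
                dimnames = list(genes,
                    sprintf("%s_r%d", rep(conds, each = n_replicates),
                            rep(seq_len(n_replicates), length(conds)))))
    cond_vec <- rep(conds, each = n_replicates)
    for (ci in seq_along(conds)) {
        cols <- which(cond_vec == conds[ci])
        m[target, cols] <- target_baseline -
            log2(fold_changes[[ci]]) + rnorm(n_replicates, 0, noise_sd)
        for (g in reference_genes)
            m[g, cols] <- reference_baselines[[g]] +
                reference_drift[[g]] * (ci - 1L) +
                rnorm(n_replicates, 0, reference_noise_sd[[g]])
    }
    makeCtTable(m, cond_vec)
}

#' One-call synthetic screening benchmark
#'
#' Builds the full input bundle for [runScreen()]: reference database,
#' recipient transcriptome (native / HGT / contaminant transcripts),
#' staged reads, and protein plus cDNA hit tables, with ground truth.
#'
#' @param seed Integer seed driving every stage.
#' @param n_native,n_hgt,n_contaminant Transcript counts.
#' @param depth Per-base read coverage per stage.
#' @param error_rate Read error rate.
#' @param hgt_divergence,native_divergence,retention_length See
#'   [simulateRecipientTranscriptome()] (retention off by default so
#'   the benchmark has exactly \code{n_hgt} foreign transcripts).
#' @return List with \code{transcriptome}, \code{reads},
#'   \code{protein_hits}, \code{cdna_hits}, \code{reference} and
#'   \code{truth}.
#' @export
simulateScreenBenchmark <- function(seed = 1L, n_native = 20L,
                                    n_hgt = 3L, n_contaminant = 5L,
                                    depth = 6, error_rate = 0,
                                    hgt_divergence = 0.15,
                                    native_divergence = 0.1,
                                    retention_length = 0L) {
    ref <- simulateReferenceDB(n_genes = 10L, seed = seed)
    tr <- simulateRecipientTranscriptome(ref,
        n_native = n_native, n_hgt = n_hgt,
        n_contaminant = n_contaminant,
        hgt_divergence = hgt_divergence,
        native_divergence = native_divergence,
        retention_length = retention_length, seed = seed)
    reads <- simulateReads(tr, depth = depth, error_rate = error_rate,
                           seed = seed)
    ## protein-level hits of each transcript's ORF
    orfs <- Biostrings::AAStringSet(vapply(
        seq_len(nrow(tr$truth)), function(i) {
            row <- tr$truth[i, ]
            cds <- substr(as.character(
                tr$transcripts[[row$transcript_id]]),
                row$orf_start, row$orf_end)
            as.character(Biostrings::translate(
                Biostrings::DNAString(sub("(TAA|TAG|TGA)$", "", cds)),
                if.fuzzy.codon = "solve"))
        }, ""))
    names(orfs) <- tr$truth$transcript_id
    prot_hits <- simulateHitTable(orfs, tr$truth$family, ref,
                                  level = "protein")
    cdna <- tr$transcripts[tr$truth$transcript_id]
    cdna_hits <- simulateHitTable(cdna, tr$truth$family, ref,
                                  level = "nucleotide")
    list(transcriptome = tr, reads = reads, protein_hits = prot_hits,
         cdna_hits = cdna_hits, reference = ref, truth = tr$truth)
}
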