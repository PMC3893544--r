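test_that("pairwise alignment handles the elementary cases", {
    a <- pairwiseAlign("ACGT", "ACGT", moltype = "dna")
    expect_equal(a$aligned_a, a$aligned_b)
    expect_equal(a$score, 8)
    expect_equal(percentIdentity("ACGT", "ACGT", moltype = "dna"), 100)

    a2 <- pairwiseAlign("ACGT", "ACT", moltype = "dna")
    expect_equal(sum(strsplit(a2$aligned_b, "")[[1]] == "-"), 1)

    expect_equal(percentIdentity("AAAA", "AAAT", moltype = "dna"), 75)
    expect_error(pairwiseAlign("", "ACGT", moltype = "dna"), "empty")

    ## symmetry
    set.seed(2)
    for (i in 1:10) {
        x <- paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = "")
        y <- paste(sample(c("A", "C", "G", "T"), 25, TRUE), collapse = "")
        expect_equal(percentIdentity(x, y, moltype = "dna"),
                     percentIdentity(y, x, moltype = "dna"))
    }
})

test_that("global alignment score equals brute-force enumeration", {
    set.seed(31)
    for (i in 1:25) {
        la <- sample(3:6, 1); lb <- sample(3:6, 1)
        a <- paste(sample(c("A", "C", "G", "T"), la, TRUE), collapse = "")
        b <- paste(sample(c("A", "C", "G", "T"), lb, TRUE), collapse = "")
        got <- pairwiseAlign(a, b, mode = "global", moltype = "dna")$score
        want <- bruteAlignScore(a, b)
        expect_equal(got, want, info = paste(a, b))
    }
})

test_that("back-translation expands residues to codons and round-trips", {
    prot <- Biostrings::AAStringSet(c(x = "MK"))
    cdna <- Biostrings::DNAStringSet(c(x = "ATGAAA"))
    expect_equal(as.character(
        backTranslateAlignment(prot, cdna)[[1]]), "ATGAAA")
    ## gap column expands to ---
    prot2 <- Biostrings::AAStringSet(c(x = "M-K"))
    expect_equal(as.character(
        backTranslateAlignment(prot2, cdna)[[1]]), "ATG---AAA")
    ## stop trimmed automatically
    cdna_stop <- Biostrings::DNAStringSet(c(x = "ATGAAATAA"))
    expect_equal(as.character(
        backTranslateAlignment(prot, cdna_stop)[[1]]), "ATGAAA")
    ## mismatch errors with position
    bad <- Biostrings::DNAStringSet(c(x = "ATGCCC"))
    expect_error(backTranslateAlignment(prot, bad), "residue 2")

    ## translate(backTranslate(x)) == x over simulated families
    ref <- simulateReferenceDB(n_genes = 5, gene_length_codons = 60,
                               seed = 13)
    for (g in 1:5) {
        ids <- grep(sprintf("fam%03d", g), names(ref$cds), value = TRUE)
        prot_aln <- Biostrings::AAStringSet(setNames(
            vapply(ids, function(i) as.character(
                Biostrings::translate(ref$cds[[i]],
                                      no.init.codon = TRUE)), ""), ids))
        back <- backTranslateAlignment(prot_aln, ref$cds[ids])
        expect_equal(as.character(back), as.character(ref$cds[ids]))
    }
})

test_that("alignment trimming drops gapped/ambiguous columns with a column map", {
    aln <- Biostrings::AAStringSet(c(a = "MKLA", b = "MKLA"))
    out <- trimAlignment(aln)
    expect_equal(as.character(out), as.character(aln))
    expect_equal(attr(out, "kept_columns"), 1:4)

    aln2 <- Biostrings::AAStringSet(c(a = "MK-A", b = "MKLA"))
    out2 <- trimAlignment(aln2)
    expect_equal(as.character(out2[["a"]]), "MKA")
    expect_equal(attr(out2, "kept_columns"), c(1, 2, 4))

    aln3 <- Biostrings::AAStringSet(c(a = "MKXA", b = "MKLA"))
    expect_equal(attr(trimAlignment(aln3), "kept_columns"), c(1, 2, 4))
    expect_error(trimAlignment(
        Biostrings::AAStringSet(c(a = "--", b = "K-"))), "every column")

    ## the column map composes with the original to give the trimmed rows
    set.seed(9)
    for (i in 1:10) {
        chars <- c("A", "R", "N", "D", "-")
        m <- matrix(sample(chars, 6 * 30, TRUE,
                           prob = c(rep(0.23, 4), 0.08)), 6, 30)
        rows <- apply(m, 1, paste, collapse = "")
        a <- Biostrings::AAStringSet(setNames(rows, paste0("r", 1:6)))
        tr <- tryCatch(trimAlignment(a), error = function(e) NULL)
        if (is.null(tr)) next
        km <- attr(tr, "kept_columns")
        expect_equal(as.character(tr),
                     setNames(apply(m[, km, drop = FALSE], 1, paste,
                                    collapse = ""), paste0("r", 1:6)))
    }
})

test_that("diagnostic sites find group-unique residues and deletions", {
    aln <- groupedAlignment(Biostrings::AAStringSet(c(
        g1 = "MKKAW", g2 = "MKKAW", o1 = "MRKAW", o2 = "MQKAW",
        o3 = "MEKAW")), groups = list(grp = c("g1", "g2")))
    d <- diagnosticSites(aln, "grp")
    expect_equal(d$column, 2)
    expect_equal(d$group_state, "K")

    ## a single shared one-column deletion in the group only
    aln2 <- groupedAlignment(Biostrings::AAStringSet(c(
        g1 = "MK-AW", g2 = "MK-AW", o1 = "MKLAW", o2 = "MKLAW")),
        groups = list(grp = c("g1", "g2")))
    d2 <- diagnosticSites(aln2, "grp")
    del <- d2[d2$kind == "deletion", ]
    expect_equal(del$column, 3)
    expect_equal(del$length, 1)

    expect_error(diagnosticSites(groupedAlignment(
        Biostrings::AAStringSet(c(a = "MK", b = "MK")),
        groups = list(all = c("a", "b"))), "all"), "all rows")

    ## planted group-specific substitutions are recovered exactly
    set.seed(17)
    base <- sample(c("A", "R", "N", "D", "C", "E", "G"), 40, TRUE)
    rows <- lapply(1:6, function(i) base)
    planted <- sort(sample(40, 5))
    for (p in planted) {
        newres <- setdiff(c("K", "W", "Y"), base[p])[1]
        rows[[1]][p] <- newres; rows[[2]][p] <- newres
    }
    aln3 <- groupedAlignment(Biostrings::AAStringSet(setNames(
        vapply(rows, paste, "", collapse = ""),
        c("g1", "g2", "o1", "o2", "o3", "o4"))),
        groups = list(grp = c("g1", "g2")))
    d3 <- diagnosticSites(aln3, "grp")
    expect_equal(d3$column[d3$kind == "residue"], planted)
})

test_that("spliced alignment recovers planted gene structures exactly", {
    ## exact single intron
    set.seed(23)
    nt <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                            collapse = "")
    E1 <- nt(150); E2 <- nt(200)
    I1 <- paste0("GT", nt(70), "AG")
    gs <- mapIntrons(paste0(E1, E2), paste0(E1, I1, E2))
    expect_equal(length(introns(gs)), 1L)
    ## recovered intron splices back to the cDNA
    g <- paste0(E1, I1, E2)
    iv <- introns(gs)
    spliced <- paste0(substr(g, 1, IRanges::start(iv) - 1),
                      substr(g, IRanges::end(iv) + 1, nchar(g)))
    expect_equal(spliced, paste0(E1, E2))

    ## simulated gene structures: splice(genomic, introns) == cDNA ORF
    ref <- simulateReferenceDB(n_genes = 4, seed = 5)
    tr <- simulateRecipientTranscriptome(ref, n_native = 6, n_hgt = 2,
                                         n_contaminant = 1, seed = 5)
    for (id in names(tr$structures)) {
        row <- tr$truth[tr$truth$transcript_id == id, ]
        orf_cdna <- substr(as.character(tr$transcripts[[id]]),
                           row$orf_start, row$orf_end)
        got <- mapIntrons(orf_cdna, as.character(tr$genomic[[id]]),
                          gene_id = id)
        want <- tr$structures[[id]]
        expect_equal(IRanges::start(introns(got)),
                     IRanges::start(introns(want)), info = id)
        expect_equal(IRanges::end(introns(got)),
                     IRanges::end(introns(want)), info = id)
    }
})

test_that("intron-position homology marks shared and absent introns", {
    ## two genes, same protein, same introns; third lacks the last one
    ex_a <- IRanges::IRanges(c(1, 101, 201), c(100, 200, 300))
    ex_b <- IRanges::IRanges(c(1, 121, 241), c(120, 240, 360))
    sa <- geneStructure("gA", ex_a)
    ## gB has introns at the same codon positions (after codon 33 and 66
    ## relative to its own exon lengths 120/120/120 -> codon 40/80)
    sb <- geneStructure("gB", ex_b)
    ## identical structures share everything
    tabAA <- compareStructures(list(gA = sa, gA2 = sa), "gA",
        Biostrings::AAStringSet(c(gA = paste(rep("K", 100), collapse = ""),
                                  gA2 = paste(rep("K", 100),
                                              collapse = ""))))
    expect_true(all(tabAA$status == "shared"))

    ## a gene lacking the reference's intron is marked absent
    s_short <- geneStructure("gC", IRanges::IRanges(1, 300))
    tabAC <- compareStructures(list(gA = sa, gC = s_short), "gA",
        Biostrings::AAStringSet(c(gA = paste(rep("K", 100), collapse = ""),
                                  gC = paste(rep("K", 100),
                                             collapse = ""))))
    expect_true(all(tabAC$status[tabAC$gene == "gC"] == "absent"))
    expect_error(compareStructures(list(gA = sa), "gA",
        Biostrings::AAStringSet(c(other = "KKK"))), "absent from MSA")
})

test_that("HGT genes share donor intron positions in simulated families", {
    ref <- simulateReferenceDB(n_genes = 2, seed = 19)
    tr <- simulateRecipientTranscriptome(ref, n_native = 2, n_hgt = 4,
                                         n_contaminant = 0,
                                         retention_length = 0, seed = 19)
    ## two HGT genes from the same family share identical intron
    ## positions (donor-matching); natives drew their own
    fam_of <- setNames(tr$truth$family, tr$truth$transcript_id)
    hgt <- intersect(tr$truth$transcript_id[tr$truth$label == "hgt"],
                     names(tr$structures))
    shared_fam <- names(which(table(fam_of[hgt]) >= 2))
    if (length(shared_fam)) {
        pair <- hgt[fam_of[hgt] == shared_fam[1]][1:2]
        cum_exonic <- function(id) {
            st <- tr$structures[[id]]
            cumsum(IRanges::width(exons(st)))[
                seq_along(introns(st))]
        }
        expect_equal(cum_exonic(pair[1]), cum_exonic(pair[2]))
    }
})

test_that("isoform comparison calls partial intron retention", {
    expect_equal(detectIntronRetention("ACGTACGT", "ACGTACGT")$call,
                 "identical")
    s <- syntheticSSLLocus(1)
    r <- detectIntronRetention(s$cassl_seq1[[1]], s$cassl_seq2[[1]],
        cdna_intron_positions = s$cassl_retention_position)
    expect_equal(r$call, "partial_retention")
    expect_equal(r$length, 21L)
    expect_equal(r$position, s$cassl_retention_position)
    ## away from any intron position: plain insertion
    r2 <- detectIntronRetention(s$cassl_seq1[[1]], s$cassl_seq2[[1]],
                                cdna_intron_positions = 10L)
    expect_equal(r2$call, "insertion")
})
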