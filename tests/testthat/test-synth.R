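test_that("the reference database is seed-deterministic with coherent lineages", {
    r1 <- simulateReferenceDB(n_genes = 3, seed = 7)
    r2 <- simulateReferenceDB(n_genes = 3, seed = 7)
    expect_identical(as.character(r1$proteins), as.character(r2$proteins))
    expect_identical(as.character(r1$cds), as.character(r2$cds))
    r3 <- simulateReferenceDB(n_genes = 3, seed = 8)
    expect_false(identical(as.character(r1$proteins),
                           as.character(r3$proteins)))
    ## every subject has a non-empty lineage
    expect_true(all(lengths(r1$lineages) > 0))
    ## proteins are the translations of the CDS
    expect_equal(as.character(r1$proteins[[1]]),
                 as.character(Biostrings::translate(
                     r1$cds[[1]], no.init.codon = TRUE)))
})

test_that("zero branch lengths make all family members identical", {
    tax <- defaultTaxonomy()
    tax$tree$edge.length[] <- 0
    ref <- simulateReferenceDB(taxonomy = tax, n_genes = 2, seed = 3)
    for (g in 1:2) {
        ids <- grep(sprintf("fam%03d", g), names(ref$cds), value = TRUE)
        expect_equal(length(unique(as.character(ref$cds[ids]))), 1L)
    }
    tax$tree$edge.length[1] <- -0.5
    expect_error(simulateReferenceDB(taxonomy = tax, n_genes = 1,
                                     seed = 1), "branch length")
})

test_that("the recipient transcriptome labels every transcript once", {
    ref <- simulateReferenceDB(n_genes = 5, seed = 4)
    tr <- simulateRecipientTranscriptome(ref, n_native = 6, n_hgt = 2,
                                         n_contaminant = 3, seed = 4)
    expect_equal(sort(tr$truth$transcript_id),
                 sort(names(tr$transcripts)))
    expect_equal(sum(tr$truth$label == "native"), 6L)
    expect_equal(sum(tr$truth$label == "contaminant"), 3L)
    ## n_hgt = 0 leaves no hgt labels
    tr0 <- simulateRecipientTranscriptome(ref, n_native = 2, n_hgt = 0,
                                          n_contaminant = 1, seed = 4)
    expect_false("hgt" %in% tr0$truth$label)
    ## planted introns are recoverable by exact string subtraction
    for (id in names(tr$structures)[1:2]) {
        st <- tr$structures[[id]]
        g <- as.character(tr$genomic[[id]])
        spliced <- paste(vapply(seq_along(exons(st)), function(k)
            substr(g, IRanges::start(exons(st))[k],
                   IRanges::end(exons(st))[k]), ""), collapse = "")
        row <- tr$truth[tr$truth$transcript_id == id, ]
        orf_cdna <- substr(as.character(tr$transcripts[[id]]),
                           row$orf_start, row$orf_end)
        expect_equal(spliced, orf_cdna)
    }
})

test_that("the retention isoforms differ by exactly one in-frame block", {
    ref <- simulateReferenceDB(n_genes = 4, seed = 6)
    tr <- simulateRecipientTranscriptome(ref, n_native = 2, n_hgt = 2,
                                         n_contaminant = 0,
                                         retention_length = 21,
                                         seed = 6)
    expect_false(is.null(tr$retention))
    a <- as.character(tr$transcripts[[tr$retention$isoform]])
    b <- as.character(tr$transcripts[[tr$retention$gene]])
    expect_equal(nchar(a) - nchar(b), 21L)
    r <- detectIntronRetention(a, b,
        cdna_intron_positions = tr$retention$cdna_position)
    expect_equal(r$call, "partial_retention")
    expect_equal(r$length, 21L)
})

test_that("staged reads respect contamination structure and error rates", {
    b <- simulateScreenBenchmark(seed = 9, n_native = 3, n_hgt = 1,
                                 n_contaminant = 2, depth = 4)
    truth <- b$truth
    contaminants <- truth$transcript_id[truth$label == "contaminant"]
    tx <- b$transcriptome$transcripts
    for (s in names(b$reads)) {
        st <- b$reads[[s]]
        if (st$host_free)
            expect_length(intersect(st$origin, contaminants), 0)
        else
            expect_gt(length(intersect(st$origin, contaminants)), 0)
    }
    ## error-free reads are exact substrings of their source (mate 1)
    st <- b$reads[[1]]
    reads <- as.character(st$reads)
    for (f in seq_len(min(25, length(st$origin)))) {
        src <- as.character(tx[[st$origin[f]]])
        expect_true(grepl(reads[2 * f - 1], src, fixed = TRUE))
    }
    ## with errors, reads are no longer all exact substrings
    be <- simulateScreenBenchmark(seed = 9, n_native = 3, n_hgt = 1,
                                  n_contaminant = 2, depth = 4,
                                  error_rate = 0.05)
    ste <- be$reads[[1]]
    hits <- vapply(seq_len(min(30, length(ste$origin))), function(f)
        grepl(as.character(ste$reads)[2 * f - 1],
              as.character(tx[[ste$origin[f]]]), fixed = TRUE),
        logical(1))
    expect_lt(mean(hits), 1)
})

test_that("read depth tracks the Poisson expectation", {
    ref <- simulateReferenceDB(n_genes = 2, seed = 14)
    tr <- simulateRecipientTranscriptome(ref, n_native = 2, n_hgt = 0,
                                         n_contaminant = 0, seed = 14)
    depth <- 8; rl <- 50
    counts <- matrix(0, 2, 10)
    for (s in 1:10) {
        rd <- simulateReads(tr, stages = c(a = TRUE, b = FALSE),
                            depth = depth, read_length = rl, seed = s)
        tab <- table(rd[["a"]]$origin)
        counts[, s] <- as.numeric(tab[names(tr$transcripts)])
    }
    L <- Biostrings::width(tr$transcripts)
    lambda <- depth * L / (2 * rl)
    for (i in 1:2) {
        expect_lt(abs(mean(counts[i, ]) - lambda[i]),
                  3 * sqrt(lambda[i] / 10))
    }
})

test_that("codon and divergence simulators validate their inputs", {
    tr <- toyTree(4)
    expect_error(simulateCodonAlignment(tr, kappa = -1), "kappa")
    expect_error(simulateCodonAlignment(tr, omegas = -0.5), "omega")
    expect_error(simulateCodonAlignment(tr, omegas = c(0.5, 1),
                                        proportions = c(0.6, 0.6)),
                 "sum to 1")
    t1 <- toyTree(4, 1); t2 <- toyTree(4, 2)
    expect_error(simulateDivergenceAlignment(t1, t2, alpha = 0),
                 "alpha")
    expect_error(simulateDivergenceAlignment(t1, t2, theta_true = 2),
                 "theta")
    expect_error(simulateQpcr(noise_sd = -1), "noise_sd")
    ## determinism of the codon simulator
    a1 <- simulateCodonAlignment(tr, seed = 5)
    a2 <- simulateCodonAlignment(tr, seed = 5)
    expect_identical(as.character(a1$alignment),
                     as.character(a2$alignment))
})

test_that("divergent sites decorrelate cluster substitution counts", {
    t1 <- toyTree(6, seed = 3, scale = 2)
    t2 <- toyTree(6, seed = 4, scale = 2)
    t1$tip.label <- paste0("p", 1:6); t2$tip.label <- paste0("q", 1:6)
    sim <- simulateDivergenceAlignment(t1, t2, theta_true = 1,
                                       alpha = 0.2, n_sites = 1500,
                                       seed = 8)
    r_div <- cor(sim$counts[, 1], sim$counts[, 2])
    expect_lt(abs(r_div), 0.1)
    sim0 <- simulateDivergenceAlignment(t1, t2, theta_true = 0,
                                        alpha = 0.2, n_sites = 1500,
                                        seed = 8)
    expect_gt(cor(sim0$counts[, 1], sim0$counts[, 2]), 0.4)
})
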