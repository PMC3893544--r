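mkReads <- function(seqs, quals) {
    Biostrings::QualityScaledDNAStringSet(
        Biostrings::DNAStringSet(setNames(seqs,
            sprintf("r%03d", seq_along(seqs)))),
        Biostrings::PhredQuality(quals))
}

test_that("trimming truncates at the first low-quality base and cuts adapters", {
    q30 <- function(n) paste(rep("?", n), collapse = "")   # Q30
    ## all qualities above the floor: unchanged
    r <- mkReads("ACGTACGT", q30(8))
    out <- trimReads(r, 25)
    expect_equal(as.character(out[[1]]), "ACGTACGT")
    ## adapter removal before quality clipping
    r2 <- mkReads("ACGTNNNN", q30(8))
    out2 <- trimReads(r2, 25, adapters = "NNNN")
    expect_equal(as.character(out2[[1]]), "ACGT")
    ## truncation at the first sub-floor base
    r3 <- mkReads("ACGTACGT", paste0(q30(4), "#", q30(3)))  # Q2 at 5
    out3 <- trimReads(r3, 25)
    expect_equal(as.character(out3[[1]]), "ACGT")
    ## fully bad read dropped
    r4 <- mkReads(c("ACGT", "AAAA"), c("####", q30(4)))
    out4 <- trimReads(r4, 25)
    expect_length(out4, 1)
    expect_equal(attr(out4, "n_dropped"), 1L)
    ## adapter longer than read: unchanged
    r5 <- mkReads("ACG", q30(3))
    out5 <- trimReads(r5, 25, adapters = "ACGTACGTAA")
    expect_equal(as.character(out5[[1]]), "ACG")
})

test_that("trimming agrees with a character-level reference on random reads", {
    set.seed(42)
    n <- 2000L
    seqs <- vapply(seq_len(n), function(i) paste(
        sample(c("A", "C", "G", "T", "N"), sample(30:60, 1), TRUE,
               prob = c(0.24, 0.24, 0.24, 0.24, 0.04)),
        collapse = ""), "")
    quals <- vapply(nchar(seqs), function(w) intToUtf8(
        sample(33:73, w, TRUE)), "")
    adapters <- c("AGATCGGAAG", "NNN")
    out <- trimReads(mkReads(seqs, quals), 25, adapters)
    ref <- lapply(seq_len(n), function(i)
        naiveTrim(seqs[i], quals[i], 25, adapters))
    ref_seq <- vapply(ref, `[[`, "", "seq")
    keep <- nchar(ref_seq) > 0
    expect_equal(unname(as.character(out)), unname(ref_seq[keep]))
    expect_equal(attr(out, "n_dropped"), sum(!keep))
})

test_that("k-mer read assignment counts fragments with fractional ties", {
    tx <- Biostrings::DNAStringSet(c(
        t1 = paste(rep("ACGTTGCAAC", 10), collapse = ""),
        t2 = paste(rep("GGCATCCGTA", 10), collapse = "")))
    ## one single-end read matching t1 exactly
    rd <- list(st = list(reads = mkReads(substr(as.character(tx[[1]]),
                                                1, 30),
                                         paste(rep("I", 30),
                                               collapse = "")),
                         host_free = TRUE))
    ct <- assignReads(tx, rd, k = 15, paired = FALSE)
    expect_equal(unname(SummarizedExperiment::assay(ct)["t1", "st"]), 1)
    expect_equal(unname(SummarizedExperiment::assay(ct)["t2", "st"]), 0)
    ## identical transcripts share the fragment 0.5/0.5
    tx2 <- Biostrings::DNAStringSet(c(a = as.character(tx[[1]]),
                                      b = as.character(tx[[1]])))
    ct2 <- assignReads(tx2, rd, k = 15, paired = FALSE)
    expect_equal(unname(SummarizedExperiment::assay(ct2)[, "st"]),
                 c(0.5, 0.5))
    ## unassignable read is reported
    rd3 <- list(st = list(reads = mkReads(paste(rep("T", 30),
                                                collapse = ""),
                                          paste(rep("I", 30),
                                                collapse = "")),
                          host_free = FALSE))
    ct3 <- assignReads(tx, rd3, k = 15, paired = FALSE)
    expect_equal(unname(S4Vectors::metadata(ct3)$unassigned["st"]), 1L)
})

test_that("error-free synthetic reads are assigned back to their sources", {
    b <- simulateScreenBenchmark(seed = 11, n_native = 4, n_hgt = 1,
                                 n_contaminant = 2, depth = 4)
    ct <- assignReads(b$transcriptome$transcripts, b$reads, k = 21)
    m <- SummarizedExperiment::assay(ct)
    for (s in names(b$reads)) {
        truth_counts <- table(b$reads[[s]]$origin)
        got <- m[names(truth_counts), s]
        expect_equal(unname(got), as.numeric(truth_counts))
    }
})

test_that("contamination filtering keeps only host-free-supported transcripts", {
    tx <- Biostrings::DNAStringSet(c(keepme = "ACGT", dropme = "GGGG"))
    cm <- matrix(c(3, 0, 9, 7), 2, 2,
                 dimnames = list(c("keepme", "dropme"),
                                 c("free", "att")))
    ct <- makeCountTable(cm, c(keepme = 4, dropme = 4),
                         host_free = "free")
    out <- contaminationFilter(tx, ct)
    expect_equal(names(out$kept), "keepme")
    expect_equal(names(out$removed), "dropme")
    expect_error(contaminationFilter(tx, ct, "nostage"), "absent")
})

test_that("ORF prediction handles frames, strands and ambiguity", {
    o <- predictOrf("ATGAAATAA")
    expect_equal(as.character(o$protein[[1]]), "MK")
    expect_equal(o$frame, 1L)
    ## reverse complement embedded in a longer sequence
    rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString("ATGAAAGGGCCCTTTTAA")))
    seq <- paste0("CCCC", rc, "GG")
    o2 <- predictOrf(seq)
    expect_equal(as.character(o2$protein[[1]]), "MKGPF")
    expect_lt(o2$frame, 0)
    ## ambiguity codes translate to X
    o3 <- predictOrf("ATGAANAAATAA")
    expect_true(grepl("X", as.character(o3$protein[[1]])))
    ## no ATG anywhere: longest stop-free stretch, flagged
    o4 <- predictOrf("CCCCCCCCCCCC")
    expect_true(o4$no_atg)
})

test_that("length gates are inclusive at the published boundaries", {
    cfg <- screenConfig()
    mk <- function(nt_len, aa_len) {
        orf <- list(protein = Biostrings::AAStringSet(setNames(
            paste(rep("K", aa_len), collapse = ""), "orf")))
        lengthGates(paste(rep("A", nt_len), collapse = ""), orf, cfg)
    }
    expect_false(mk(299, 100)$pass)
    expect_equal(mk(299, 100)$reason, "transcript_too_short")
    expect_true(mk(300, 100)$pass)
    expect_false(mk(300, 99)$pass)
    ## random cases equal direct boolean evaluation
    set.seed(8)
    for (i in 1:200) {
        nt <- sample(250:350, 1); aa <- sample(80:120, 1)
        expect_equal(mk(nt, aa)$pass, nt >= 300 && aa >= 100)
    }
})

mkHits <- function(df) {
    if (is.null(df$percent_identity)) df$percent_identity <- 90
    df$aln_length <- 100L
    df$mismatches <- 10L
    df$gap_opens <- 0L
    df$qstart <- 0L; df$qend <- 100L; df$sstart <- 1L; df$send <- 100L
    df$e_value <- 1e-50
    df[order(-df$bit_score), ]
}

test_that("alien score ratio classifies against the 1.2 threshold", {
    cfg <- screenConfig()
    lamiales <- list(c("Viridiplantae", "Lamiales", "Genus sp"))
    brassicales <- list(c("Viridiplantae", "Brassicales", "Other sp"))
    h <- mkHits(data.frame(query_id = "q", subject_id = c("in1", "out1"),
                           bit_score = c(100, 121),
                           lineage = I(c(lamiales, brassicales))))
    v <- alienScore(h, cfg)
    expect_equal(v$ratio, 1.21)
    expect_true(v$is_candidate)

    h2 <- mkHits(data.frame(query_id = "q", subject_id = c("in1", "out1"),
                            bit_score = c(100, 110),
                            lineage = I(c(lamiales, brassicales))))
    expect_false(alienScore(h2, cfg)$is_candidate)

    ## exactly at the threshold is not a candidate (strict >)
    h3 <- mkHits(data.frame(query_id = "q", subject_id = c("in1", "out1"),
                            bit_score = c(100, 120),
                            lineage = I(c(lamiales, brassicales))))
    expect_false(alienScore(h3, cfg)$is_candidate)

    ## no ingroup hit: ratio +Inf, flagged candidate
    h4 <- mkHits(data.frame(query_id = "q", subject_id = "out1",
                            bit_score = 80, lineage = I(brassicales)))
    v4 <- alienScore(h4, cfg)
    expect_true(v4$is_candidate)
    expect_equal(v4$ratio, Inf)
    expect_match(v4$flags, "no_ingroup_hit")

    ## no outgroup hit: not a candidate
    h5 <- mkHits(data.frame(query_id = "q", subject_id = "in1",
                            bit_score = 80, lineage = I(lamiales)))
    v5 <- alienScore(h5, cfg)
    expect_false(v5$is_candidate)
    expect_match(v5$flags, "no_outgroup_hit")

    ## empty hit list: both flags
    v6 <- alienScore(h5[0, ], cfg)
    expect_false(v6$is_candidate)
    expect_match(v6$flags, "no_ingroup_hit")
    expect_match(v6$flags, "no_outgroup_hit")

    ## self-hits are removed before scoring
    h7 <- mkHits(data.frame(query_id = "q",
                            subject_id = c("q", "in1", "out1"),
                            bit_score = c(500, 100, 121),
                            lineage = I(c(lamiales, lamiales,
                                          brassicales))))
    expect_equal(alienScore(h7, cfg)$ratio, 1.21)
})

test_that("the ratio is invariant to common score rescaling and the threshold is monotone", {
    lamiales <- list(c("Viridiplantae", "Lamiales", "Genus sp"))
    brassicales <- list(c("Viridiplantae", "Brassicales", "Other sp"))
    set.seed(5)
    for (i in 1:20) {
        bi <- runif(1, 50, 200); bo <- runif(1, 50, 260)
        h <- mkHits(data.frame(query_id = "q",
                               subject_id = c("in1", "out1"),
                               bit_score = c(bi, bo),
                               lineage = I(c(lamiales, brassicales))))
        v1 <- alienScore(h, screenConfig())
        h$bit_score <- h$bit_score * 3.7
        v2 <- alienScore(h, screenConfig())
        expect_equal(v1$ratio, v2$ratio, tolerance = 1e-12)
        ## raising the threshold never adds candidates
        lo <- alienScore(h, screenConfig(ratio_threshold = 1.2))
        hi <- alienScore(h, screenConfig(ratio_threshold = 2.0))
        expect_true(lo$is_candidate >= hi$is_candidate)
    }
})

test_that("sister-taxon cDNA affiliation removes candidates", {
    cfg <- screenConfig()
    vt <- data.frame(query_id = "q", best_ingroup_id = "in1",
                     best_ingroup_score = 100,
                     best_outgroup_id = "out1",
                     best_outgroup_score = 150, ratio = 1.5,
                     is_candidate = TRUE, flags = "")
    sister <- list(c("Viridiplantae", "Lamiales", "Mimulus guttatus"))
    donor <- list(c("Viridiplantae", "Brassicales", "Arabidopsis thaliana"))
    ch <- mkHits(data.frame(query_id = "q", subject_id = "m1",
                            bit_score = 300, lineage = I(sister)))
    out <- sisterTaxonFilter(vt, ch, cfg)
    expect_false(out$is_candidate)
    expect_match(out$flags, "sister_taxon_cdna_hit")

    ch2 <- mkHits(data.frame(query_id = "q", subject_id = "a1",
                             bit_score = 300, lineage = I(donor)))
    expect_true(sisterTaxonFilter(vt, ch2, cfg)$is_candidate)

    ## no cDNA hits: retained with a message
    expect_message(out3 <- sisterTaxonFilter(vt, ch2[0, ], cfg),
                   "no cDNA")
    expect_true(out3$is_candidate)
})

test_that("the full screen is deterministic and empty input yields an empty report", {
    empty <- runScreen(Biostrings::DNAStringSet(), NULL,
                       data.frame(query_id = character(),
                                  subject_id = character(),
                                  bit_score = numeric()))
    expect_equal(nrow(verdicts(empty)), 0L)

    b <- simulateScreenBenchmark(seed = 21, n_native = 4, n_hgt = 1,
                                 n_contaminant = 1, depth = 4)
    s1 <- runScreen(b$transcriptome$transcripts, b$reads,
                    b$protein_hits, b$cdna_hits)
    s2 <- runScreen(b$transcriptome$transcripts, b$reads,
                    b$protein_hits, b$cdna_hits)
    expect_identical(as.data.frame(verdicts(s1)),
                     as.data.frame(verdicts(s2)))
    expect_setequal(candidates(s1),
        b$truth$transcript_id[b$truth$label == "hgt"])
})
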