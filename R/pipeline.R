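## End-to-end orchestration of the workflow on a simulated study,
## with a JSON manifest of every stage.  The package's interface is
## its functions; this wrapper wires them together in the published
## order: screen -> structure diagnostics -> phylogeny -> divergence
## -> selection -> expression.

#' Run the full workflow on a synthetic study
#'
#' Generates a synthetic study (reference database, recipient
#' transcriptome, staged reads, hit tables), screens for HGT
#' candidates, and runs the downstream validation stages.  Every
#' stage can be toggled; outputs and a JSON manifest are written
#' under \code{out_dir}.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed driving every stochastic stage.
#' @param stages Character vector of stages to run, a subset of
#'   \code{c("screen", "introns", "phylo", "divergence", "selection",
#'   "expression")}.
#' @param config [screenConfig()] for the screening stage.
#' @return Invisibly, the manifest list (also written as
#'   \code{manifest.json}).
#' @export
runPipeline <- function(out_dir = tempfile("hgtrun"), seed = 1L,
                        stages = c("screen", "introns", "phylo",
                                   "divergence", "selection",
                                   "expression"),
                        config = screenConfig()) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    manifest <- list(seed = seed, stages = list(), outputs = list())
    record <- function(stage, status, files = character(),
                       info = list()) {
        manifest$stages[[stage]] <<- c(list(status = status,
                                            files = files), info)
        for (f in files)
            manifest$outputs[[basename(f)]] <<-
                unname(tools::md5sum(f))
    }
    bench <- simulateScreenBenchmark(seed = seed,
                                     retention_length = 21L)
    tr <- bench$transcriptome

    if ("screen" %in% stages) {
        sc <- runScreen(tr$transcripts, bench$reads,
                        bench$protein_hits, bench$cdna_hits, config)
        f <- file.path(out_dir, "screen_report.tsv")
        writeScreenReport(sc, f)
        record("screen", "ok", f,
               list(n_candidates = length(candidates(sc))))
        cands <- candidates(sc)
    } else {
        record("screen", "skipped")
        cands <- tr$truth$transcript_id[tr$truth$label == "hgt"]
    }

    if ("introns" %in% stages && length(tr$genomic)) {
        gid <- intersect(cands, names(tr$genomic))[1L]
        if (!is.na(gid)) {
            row <- tr$truth[tr$truth$transcript_id == gid, ]
            orf_cdna <- substr(as.character(tr$transcripts[[gid]]),
                               row$orf_start, row$orf_end)
            gs <- mapIntrons(orf_cdna, as.character(tr$genomic[[gid]]),
                             gene_id = gid)
            f <- file.path(out_dir, "intron_structure.tsv")
            write.table(data.frame(
                gene = gid,
                type = rep(c("exon", "intron"),
                           c(length(exons(gs)), length(introns(gs)))),
                start = c(IRanges::start(exons(gs)),
                          IRanges::start(introns(gs))),
                end = c(IRanges::end(exons(gs)),
                        IRanges::end(introns(gs)))),
                f, sep = "\t", quote = FALSE, row.names = FALSE)
            record("introns", "ok", f,
                   list(n_introns = length(introns(gs))))
        } else record("introns", "skipped")
    } else if ("introns" %in% stages) record("introns", "skipped")

    if ("phylo" %in% stages && length(cands)) {
        gid <- cands[1L]
        fam <- bench$truth$family[bench$truth$transcript_id == gid]
        aln <- bench$reference$alignments[[fam]]
        row <- bench$truth[bench$truth$transcript_id == gid, ]
        orf <- substr(as.character(tr$transcripts[[gid]]),
                      row$orf_start + 3L, row$orf_end - 3L)
        qaa <- as.character(Biostrings::translate(
            Biostrings::DNAString(orf), if.fuzzy.codon = "solve"))
        ref_un <- Biostrings::AAStringSet(gsub("-", "",
            as.character(aln)))
        seqs <- c(setNames(as.character(ref_un), names(ref_un)),
                  setNames(qaa, gid))
        ## align query into family by profile-free global alignment to
        ## the closest member, then pad (family MSA is gap-free here)
        aln_all <- Biostrings::AAStringSet(seqs)
        tax <- bench$reference$taxonomy
        tre <- bootstrapSupport(aln_all, n_replicates = 100L,
                                seed = seed)
        f <- file.path(out_dir, "nj_tree.nwk")
        writeNewickTree(tre, f)
        pl <- placementTest(tre, gid, donor_group = tax$donor_clade,
                            recipient_group = c(tax$recipient,
                                                tax$sister))
        record("phylo", "ok", f, list(placement = pl$verdict,
                                      support = pl$clade_support))
    } else if ("phylo" %in% stages) record("phylo", "skipped")

    if ("divergence" %in% stages) {
        t1 <- ape::rtree(6, br = function(n) runif(n, 0.3, 0.8))
        t2 <- ape::rtree(6, br = function(n) runif(n, 0.3, 0.8))
        t1$tip.label <- paste0("c1_", seq_len(6L))
        t2$tip.label <- paste0("c2_", seq_len(6L))
        sim <- simulateDivergenceAlignment(t1, t2, theta_true = 0.3,
                                           alpha = 0.5,
                                           n_sites = 500L, seed = seed)
        x1 <- fitchCounts(sim$alignment[sim$cluster1], t1)
        x2 <- fitchCounts(sim$alignment[sim$cluster2], t2)
        fit <- estimateTheta1(x1, x2)
        record("divergence", "ok", character(),
               list(theta1 = fit@theta1, lrt = fit@lrt))
    }

    if ("selection" %in% stages) {
        set.seed(seed)
        tr8 <- ape::rtree(8, br = function(n) runif(n, 0.05, 0.3))
        sim <- simulateCodonAlignment(tr8, kappa = 2, omegas = 0.2,
                                      proportions = 1,
                                      n_codons = 300L, seed = seed)
        fit <- fitCodonModel(sim$alignment, tr8, "M0", n_starts = 1L)
        record("selection", "ok", character(),
               list(omega = unname(fit@mle["omega"]),
                    lnL = fit@lnL))
    }

    if ("expression" %in% stages) {
        ct <- assignReads(tr$transcripts, bench$reads,
                          k = config$kmer_length)
        fk <- fpkm(ct)
        f <- file.path(out_dir, "fpkm.tsv")
        write.table(data.frame(transcript = rownames(fk), fk),
                    f, sep = "\t", quote = FALSE, row.names = FALSE)
        qp <- simulateQpcr(seed = seed)
        sr <- stabilityRank(qp[rownames(qp) != "SSL", ])
        ref_gene <- stabilityTable(sr)$gene[1L]
        fc <- ddct(qp, "SSL", ref_gene, "ctrl")
        f2 <- file.path(out_dir, "qpcr_fold_changes.tsv")
        write.table(fc, f2, sep = "\t", quote = FALSE,
                    row.names = FALSE)
        record("expression", "ok", c(f, f2),
               list(reference_gene = ref_gene,
                    fold_treated =
                        fc$fold[fc$condition == "treated"]))
    }

    jsonlite::write_json(manifest,
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(manifest)
}
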