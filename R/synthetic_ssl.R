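## Synthetic stand-in for the deposited SSL sequence records.  The
## real records are database accessions; this generator reproduces
## their published architecture deterministically so the structural
## analyses can be exercised end to end offline: a 1597-bp
## parasite-gene cDNA with a 369-codon ORF, its genomic clone with
## two introns, a second parasite's two mRNA isoforms differing by a
## 21-bp partial retention of intron 2, and a host-clade homolog at
## 88% amino-acid identity.  Every sequence is synthetic and labelled
## as such.

#' Synthetic SSL gene set with the published architecture
#'
#' Deterministically generates a set of synthetic sequences whose
#' architecture mirrors the strictosidine synthase-like (SSL) genes
#' at the centre of the host-to-parasite HGT case study: the
#' root-parasite cDNA (1597 nt, ORF of 369 aa), its genomic clone
#' carrying 2 introns, the shoot-parasite isoform pair (Seq2 plus a
#' Seq1 with a 21-bp partial retention of intron 2), and a
#' host-clade homolog protein at exactly 88.0% amino-acid identity
#' to the shoot-parasite protein.  These are synthetic stand-ins
#' with planted ground truth, not the deposited records.
#'
#' @param seed Integer seed (default 1).
#' @return List with \code{oassl_cdna}, \code{oassl_genomic}
#'   (DNAStringSet), \code{oassl_orf_start} (0-based nt offset),
#'   \code{intron_positions_cdna} (nt before each intron, on the
#'   cDNA), \code{cassl_seq2}, \code{cassl_seq1} (DNAStringSet),
#'   \code{cassl_retention_position} (0-based nt offset in Seq2),
#'   \code{cassl_protein}, \code{host_homolog_protein}
#'   (AAStringSet).
#' @export
syntheticSSLLocus <- function(seed = 1L) {
    set.seed(seed + 101L)
    ## --- root-parasite gene: 1597-nt cDNA, 369-aa ORF -------------
    n_aa <- 369L
    orf_codons <- .randomCDS(n_aa)
    ## avoid internal ATG-free requirement: first codon must be ATG
    orf_codons[1L] <- "ATG"
    ## make sure no earlier frame produces a longer ORF: UTRs built
    ## stop-rich
    stopish <- function(n) {
        out <- character(0)
        while (sum(nchar(out)) < n)
            out <- c(out, sample(c("TAA", "TGA", "TAG",
                                   .randomNt(3L)), 1L))
        substr(paste(out, collapse = ""), 1L, n)
    }
    utr5 <- stopish(100L)
    ## a stop immediately 5' of the ATG (in the ORF frame) pins the
    ## predicted ORF to the planted one
    substr(utr5, 98L, 100L) <- "TAA"
    orf_nt <- paste(c(orf_codons, "TAA"), collapse = "")  # 1110 nt
    utr3 <- stopish(1597L - 100L - nchar(orf_nt))
    cdna <- paste0(utr5, orf_nt, utr3)
    stopifnot(nchar(cdna) == 1597L)
    ## genomic clone: two introns inside the ORF at codon boundaries
    ipos_cdna <- 100L + c(333L, 789L)   # nt of cDNA before each intron
    ilen <- c(153L, 462L)
    pieces <- c(substr(cdna, 1L, ipos_cdna[1L]),
                paste0("GT", .randomNt(ilen[1L] - 4L), "AG"),
                substr(cdna, ipos_cdna[1L] + 1L, ipos_cdna[2L]),
                paste0("GT", .randomNt(ilen[2L] - 4L), "AG"),
                substr(cdna, ipos_cdna[2L] + 1L, nchar(cdna)))
    genomic <- paste(pieces, collapse = "")

    ## --- shoot-parasite isoforms and host homolog -----------------
    n_aa2 <- 375L
    cassl_codons <- .randomCDS(n_aa2)
    cassl_codons[1L] <- "ATG"
    c_utr5 <- stopish(80L)
    substr(c_utr5, 78L, 80L) <- "TGA"
    c_orf <- paste(c(cassl_codons, "TAA"), collapse = "")
    c_utr3 <- stopish(200L)
    seq2 <- paste0(c_utr5, c_orf, c_utr3)
    ## retention at the homologous intron-2 position (codon boundary)
    ret_pos <- 80L + 789L
    retained <- paste0("GT", substr(.randomCDS(1L), 3L, 3L),
                       paste(.randomCDS(6L), collapse = ""))  # 21 nt
    seq1 <- paste0(substr(seq2, 1L, ret_pos), retained,
                   substr(seq2, ret_pos + 1L, nchar(seq2)))
    cassl_prot <- paste(Biostrings::GENETIC_CODE[cassl_codons],
                        collapse = "")
    ## host homolog: exactly 45/375 residues substituted -> 88.0%
    aa <- strsplit(cassl_prot, "")[[1L]]
    sub_at <- sort(sample(2:n_aa2, 45L))
    for (k in sub_at)
        aa[k] <- sample(setdiff(.AA20, aa[k]), 1L)
    host_prot <- paste(aa, collapse = "")

    list(oassl_cdna = Biostrings::DNAStringSet(
             c(OaSSL_synthetic_cdna = cdna)),
         oassl_genomic = Biostrings::DNAStringSet(
             c(OaSSL_synthetic_genomic = genomic)),
         oassl_orf_start = 100L,
         intron_positions_cdna = ipos_cdna,
         intron_lengths = ilen,
         cassl_seq2 = Biostrings::DNAStringSet(
             c(CaSSL_synthetic_seq2 = seq2)),
         cassl_seq1 = Biostrings::DNAStringSet(
             c(CaSSL_synthetic_seq1 = seq1)),
         cassl_retention_position = ret_pos,
         cassl_protein = Biostrings::AAStringSet(
             c(CaSSL_synthetic_protein = cassl_prot)),
         host_homolog_protein = Biostrings::AAStringSet(
             c(host_homolog_synthetic = host_prot)))
}
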