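## Expression analysis: FPKM from fragment counts, qPCR
## reference-gene stability (geNorm M, the DeltaCt method,
## BestKeeper) with a composite rank, and comparative-Ct fold changes
## with plain Student's t-tests.

#' FPKM from a fragment-count table
#'
#' FPKM = fragments / (transcript length in kb x stage total in
#' millions); one read pair is one fragment (counts are assumed to be
#' fragment counts already).
#'
#' @param count_table CountTable from [makeCountTable()] /
#'   [assignReads()].
#' @return Numeric matrix of FPKM, transcripts x stages.
#' @export
fpkm <- function(count_table) {
    m <- SummarizedExperiment::assay(count_table)
    len <- SummarizedExperiment::rowData(count_table)$length
    if (any(len <= 0)) stop("non-positive transcript length")
    tot <- colSums(m)
    if (any(tot == 0)) stop("stage with zero total fragments: ",
        paste(colnames(m)[tot == 0], collapse = ", "))
    sweep(m / (len / 1e3), 2L, tot / 1e6, "/")
}

## Ct table -> per-gene x per-sample (condition x replicate mean) Ct
.ctBySample <- function(ct_table) {
    m <- SummarizedExperiment::assay(ct_table, "ct")
    cond <- as.character(ct_table$condition)
    sapply(unique(cond), function(cc)
        rowMeans(m[, cond == cc, drop = FALSE], na.rm = TRUE))
}

#' geNorm expression-stability measure M
#'
#' Ct values are converted to relative quantities per gene
#' (2^(minCt - Ct)); a gene's M is the mean over all other genes of
#' the standard deviation across samples of the pairwise log2
#' quantity ratio.  Lower M = more stable.
#'
#' @param ct_table CtTable from [makeCtTable()] (replicates are
#'   averaged per condition first).
#' @return Named numeric of M values.
#' @export
genormM <- function(ct_table) {
    q <- .ctBySample(ct_table)
    if (nrow(q) < 3L) stop("geNorm needs >= 3 genes")
    if (ncol(q) < 2L) stop("geNorm needs >= 2 samples")
    lq <- apply(q, 1L, min) - q   # log2 relative quantity per gene
    n <- nrow(q)
    M <- setNames(numeric(n), rownames(q))
    for (g in seq_len(n)) {
        sds <- vapply(setdiff(seq_len(n), g), function(h)
            sd(lq[g, ] - lq[h, ], na.rm = TRUE), numeric(1L))
        M[g] <- mean(sds)
    }
    M
}

#' Reference-gene stability ranking
#'
#' Combines three measures -- geNorm M, the DeltaCt method (mean SD
#' of pairwise delta-Ct against every other gene) and BestKeeper (SD
#' of raw Ct) -- into a composite rank, the geometric mean of the
#' per-method ranks (ties share averaged ranks).  With fewer than 3
#' genes geNorm is skipped with a warning.
#'
#' @param ct_table CtTable of the candidate reference genes.
#' @return A [StabilityReport-class], ordered most stable first.
#' @export
stabilityRank <- function(ct_table) {
    q <- .ctBySample(ct_table)
    genes <- rownames(q)
    n <- length(genes)
    delta_ct <- vapply(seq_len(n), function(g)
        mean(vapply(setdiff(seq_len(n), g), function(h)
            sd(q[g, ] - q[h, ], na.rm = TRUE), numeric(1L))),
        numeric(1L))
    bestkeeper <- apply(q, 1L, sd, na.rm = TRUE)
    gm <- if (n >= 3L) genormM(ct_table) else {
        warning("fewer than 3 genes: geNorm skipped")
        setNames(rep(NA_real_, n), genes)
    }
    ranks <- cbind(genorm = if (all(is.na(gm))) NA else rank(gm),
                   delta_ct = rank(delta_ct),
                   bestkeeper = rank(bestkeeper))
    composite <- apply(ranks, 1L, function(r)
        exp(mean(log(r[!is.na(r)]))))
    tab <- data.frame(gene = genes, genorm_m = as.numeric(gm),
                      delta_ct_sd = delta_ct,
                      bestkeeper_sd = bestkeeper,
                      rank_genorm = ranks[, "genorm"],
                      rank_delta_ct = ranks[, "delta_ct"],
                      rank_bestkeeper = ranks[, "bestkeeper"],
                      composite_rank = composite)
    tab <- tab[order(tab$composite_rank, tab$gene), , drop = FALSE]
    rownames(tab) <- NULL
    new("StabilityReport", table = tab)
}

#' Comparative-Ct (delta-delta-Ct) fold changes
#'
#' Per replicate, delta-Ct = Ct(target) - Ct(reference); per
#' condition, delta-delta-Ct = mean delta-Ct(condition) - mean
#' delta-Ct(calibrator) and fold = 2^-ddCt.  The SE of the fold is
#' propagated from the replicate variances by the delta method, and
#' each condition is compared with the calibrator by a plain
#' two-sample Student's t-test (equal variances, two-sided) on the
#' replicate delta-Ct values.
#'
#' @param ct_table CtTable with the target and reference genes.
#' @param target Target gene name.
#' @param reference Reference gene name (e.g. the top gene of
#'   [stabilityRank()]).
#' @param calibrator Calibrator condition label.
#' @return data.frame per condition: \code{fold}, \code{se},
#'   \code{ddct}, \code{t}, \code{p_value} (NA for the calibrator).
#' @export
ddct <- function(ct_table, target, reference, calibrator) {
    m <- SummarizedExperiment::assay(ct_table, "ct")
    cond <- as.character(ct_table$condition)
    if (!calibrator %in% cond) stop("calibrator condition missing")
    if (!all(c(target, reference) %in% rownames(m)))
        stop("target or reference gene missing from Ct table")
    dct <- m[target, ] - m[reference, ]
    cal <- dct[cond == calibrator]
    cal <- cal[is.finite(cal)]
    if (length(cal) < 2L) stop("calibrator needs >= 2 replicates")
    out <- lapply(unique(cond), function(cc) {
        d <- dct[cond == cc]; d <- d[is.finite(d)]
        dd <- mean(d) - mean(cal)
        se_dd <- sqrt(var(d) / length(d) + var(cal) / length(cal))
        fold <- 2^(-dd)
        se_fold <- log(2) * fold * se_dd   # delta method
        if (cc == calibrator) {
            data.frame(condition = cc, fold = 1, se = se_fold,
                       ddct = 0, t = NA_real_, p_value = NA_real_)
        } else {
            tt <- tryCatch(t.test(d, cal, var.equal = TRUE),
                           error = function(e) NULL)  # constant data
            data.frame(condition = cc, fold = fold, se = se_fold,
                       ddct = dd,
                       t = if (is.null(tt)) NA_real_
                           else unname(tt$statistic),
                       p_value = if (is.null(tt)) NA_real_
                                 else tt$p.value)
        }
    })
    do.call(rbind, out)
}
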