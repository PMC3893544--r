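## GY94-style codon substitution machinery: 61-state generator,
## transition probabilities via symmetric eigendecomposition (the
## chain is time-reversible), Felsenstein pruning with underflow
## scaling, and ML fitting of the standard site and branch-site
## model ladder.

.codon_universe <- function() {
    gc <- Biostrings::GENETIC_CODE
    sense <- names(gc)[gc != "*"]
    list(codons = sense, aa = unname(gc[sense]))
}

.CODONS <- NULL  # filled at load time

.onLoad <- function(libname, pkgname) {
    u <- .codon_universe()
    ntc <- do.call(rbind, strsplit(u$codons, ""))
    n <- length(u$codons)
    diffpos <- matrix(0L, n, n)
    ts <- matrix(FALSE, n, n)
    for (p in 1:3) {
        d <- outer(ntc[, p], ntc[, p], "!=")
        diffpos <- diffpos + d
        pur <- ntc[, p] %in% c("A", "G")
        ts <- ts | (d & outer(pur, pur, "==") )
    }
    syn <- outer(u$aa, u$aa, "==")
    assign(".CODONS", list(
        codons = u$codons, aa = u$aa, n = n, nt = ntc,
        one_diff = diffpos == 1L, is_transition = ts, is_syn = syn),
        envir = parent.env(environment()))
}

#' Sense-codon state space (universal code)
#'
#' @return Character vector of the 61 sense codons in the fixed order
#'   used throughout the codon machinery.
#' @export
senseCodons <- function() .CODONS$codons

#' Build a GY94 codon rate matrix
#'
#' Off-diagonal rate between codons differing at exactly one
#' nucleotide is the target codon's equilibrium frequency times 1,
#' kappa, omega or omega*kappa for synonymous transversions,
#' synonymous transitions, nonsynonymous transversions and
#' nonsynonymous transitions respectively; multi-nucleotide changes
#' are forbidden.  The matrix is scaled so the expected number of
#' substitutions per codon per time unit is 1.
#'
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param omega Nonsynonymous/synonymous rate ratio (>= 0).
#' @param freqs Equilibrium frequencies over the 61 sense codons
#'   (default equal).
#' @param scale Scale to one expected substitution per codon per time
#'   unit (default TRUE).  Mixture models scale all classes by one
#'   common factor instead, so they pass FALSE and normalize jointly.
#' @return 61 x 61 generator matrix with codon dimnames;
#'   \code{attr(,"mu")} carries the pre-scaling expected rate.
#' @examples
#' Q <- buildQ(2, 0.5)
#' max(abs(rowSums(Q)))  # 0
#' @export
buildQ <- function(kappa, omega, freqs = NULL, scale = TRUE) {
    cc <- .CODONS
    if (kappa <= 0) stop("kappa must be > 0")
    if (omega < 0) stop("omega must be >= 0")
    if (is.null(freqs)) freqs <- rep(1 / cc$n, cc$n)
    if (length(freqs) != cc$n)
        stop("freqs must cover the ", cc$n, " sense codons")
    if (abs(sum(freqs) - 1) > 1e-8) stop("freqs must sum to 1")
    fac <- matrix(0, cc$n, cc$n)
    fac[cc$one_diff] <- 1
    fac[cc$one_diff & cc$is_transition] <- kappa
    fac[cc$one_diff & !cc$is_syn] <-
        fac[cc$one_diff & !cc$is_syn] * omega
    Q <- fac * rep(freqs, each = cc$n)
    diag(Q) <- -rowSums(Q)
    mu <- -sum(freqs * diag(Q))
    if (scale && mu > 0) Q <- Q / mu
    dimnames(Q) <- list(cc$codons, cc$codons)
    attr(Q, "mu") <- mu
    Q
}

## Eigendecomposition of a reversible Q for fast expm:
## P(t) = A %*% diag(exp(lambda t)) %*% B
.codonEigen <- function(Q, freqs) {
    d <- sqrt(freqs)
    S <- Q * (d / rep(d, each = length(d)))
    S <- (S + t(S)) / 2
    e <- eigen(S, symmetric = TRUE)
    list(lambda = e$values,
         A = e$vectors / d,
         B = t(e$vectors) * rep(d, each = length(d)))
}

.codonP <- function(eg, t) {
    P <- eg$A %*% (exp(eg$lambda * t) * eg$B)
    P[P < 0] <- 0
    P / rowSums(P)
}

#' Empirical F3x4 codon frequencies
#'
#' Position-specific nucleotide frequencies from the alignment,
#' multiplied per codon and renormalized over the sense codons.
#'
#' @param codon_aln Named DNAStringSet of aligned coding rows (width a
#'   multiple of 3; gaps allowed).
#' @return Frequency vector over [senseCodons()].
#' @export
codonFreqsF3x4 <- function(codon_aln) {
    cc <- .CODONS
    m <- do.call(rbind, strsplit(as.character(codon_aln), ""))
    pos <- (seq_len(ncol(m)) - 1L) %% 3L + 1L
    f <- sapply(1:3, function(p) {
        v <- m[, pos == p, drop = FALSE]
        v <- v[v %in% c("A", "C", "G", "T")]
        tab <- table(factor(v, levels = c("A", "C", "G", "T")))
        as.numeric(tab) / sum(tab)
    })
    rownames(f) <- c("A", "C", "G", "T")
    fr <- f[cc$nt[, 1], 1] * f[cc$nt[, 2], 2] * f[cc$nt[, 3], 3]
    fr / sum(fr)
}

## Encode a codon alignment into an integer matrix (rows = taxa,
## columns = codon sites); NA for gap/ambiguous codons.  Sites with
## any gap are dropped (logged via attribute).
.encodeCodonAlignment <- function(codon_aln, drop_gapped = TRUE) {
    cc <- .CODONS
    chr <- as.character(codon_aln)
    w <- unique(nchar(chr))
    if (length(w) != 1L || w %% 3L != 0L)
        stop("codon alignment rows must share a width divisible by 3")
    nsite <- w / 3L
    m <- matrix(NA_integer_, length(chr), nsite,
                dimnames = list(names(codon_aln), NULL))
    for (i in seq_along(chr)) {
        cod <- substring(chr[i], seq(1L, w, 3L), seq(3L, w, 3L))
        idx <- match(cod, cc$codons)
        if (any(is.na(idx) & !grepl("-|N", cod)))
            stop("stop or invalid codon in row ", names(codon_aln)[i])
        m[i, ] <- idx
    }
    if (drop_gapped) {
        keep <- colSums(is.na(m)) == 0L
        dropped <- which(!keep)
        m <- m[, keep, drop = FALSE]
        attr(m, "dropped_sites") <- dropped
    }
    m
}

## Collapse encoded sites to unique patterns with weights.
.sitePatterns <- function(enc) {
    key <- apply(enc, 2L, paste, collapse = ",")
    u <- !duplicated(key)
    pat <- enc[, u, drop = FALSE]
    w <- as.vector(table(key)[key[u]])
    list(patterns = pat, weights = w, index = match(key, key[u]))
}

## Postorder edge traversal info for an ape tree.
.treeInfo <- function(tree) {
    tree <- ape::reorder.phylo(tree, "postorder")
    list(edge = tree$edge, len = tree$edge.length,
         ntip = length(tree$tip.label), tips = tree$tip.label,
         nnode = tree$Nnode, root = length(tree$tip.label) + 1L)
}

## Felsenstein pruning for one site class.
## Plist: list over edges (rows of ti$edge) of 61x61 P matrices.
## Returns list(loglik = per-pattern log-likelihood under pi).
.pruneClass <- function(ti, Plist, pat, freqs) {
    n <- .CODONS$n
    npat <- ncol(pat)
    nnodes <- ti$ntip + ti$nnode
    partial <- vector("list", nnodes)
    scalelog <- matrix(0, nnodes, npat)
    for (tip in seq_len(ti$ntip)) {
        L <- matrix(0, n, npat)
        idx <- pat[match(ti$tips[tip], rownames(pat)), ]
        ok <- !is.na(idx)
        L[cbind(idx[ok], which(ok))] <- 1
        if (any(!ok)) L[, !ok] <- 1
        partial[[tip]] <- L
    }
    for (e in seq_len(nrow(ti$edge))) {
        parent <- ti$edge[e, 1L]; child <- ti$edge[e, 2L]
        contrib <- Plist[[e]] %*% partial[[child]]
        scalelog[parent, ] <- scalelog[parent, ] + scalelog[child, ]
        if (is.null(partial[[parent]])) {
            partial[[parent]] <- contrib
        } else {
            partial[[parent]] <- partial[[parent]] * contrib
            ## rescale to guard against underflow (column-sum scaling)
            cs <- .colSums(partial[[parent]], n, npat)
            cs[cs == 0] <- 1
            partial[[parent]] <- partial[[parent]] / rep(cs, each = n)
            scalelog[parent, ] <- scalelog[parent, ] + log(cs)
        }
    }
    root <- ti$root
    lik <- colSums(partial[[root]] * freqs)
    log(lik) + scalelog[root, ]
}

## Site-class table for each model; p are the free parameters on the
## natural scale.  Returns data.frame(proportion, omega) for site
## models; for branch-site models columns (proportion, omega_bg,
## omega_fg).
.betaClassOmegas <- function(p_shape, q_shape, K = 10L) {
    qs <- qbeta(seq(0, 1, length.out = K + 1L), p_shape, q_shape)
    ## mean of the beta within each equal-probability bin
    upper <- pbeta(qs[-1L], p_shape + 1, q_shape)
    lower <- pbeta(qs[-(K + 1L)], p_shape + 1, q_shape)
    m <- (upper - lower) * (p_shape / (p_shape + q_shape)) * K
    pmin(pmax(m, 1e-8), 1)
}

## Parameter packing: every model maps a named free-parameter vector
## (optimizer scale) to (kappa, class table).  Stick-breaking keeps
## proportions in the simplex.
.modelSpec <- function(model, k_m3 = 3L, K_m7 = 10L) {
    logit <- function(x) log(x / (1 - x))
    expit <- function(x) 1 / (1 + exp(-x))
    switch(model,
    M0 = list(
        init = c(lkappa = log(2), lomega = log(0.3)),
        classes = function(par) data.frame(
            proportion = 1, omega = exp(par["lomega"]))),
    M3 = list(
        init = c(lkappa = log(2),
                 setNames(rep(0, k_m3 - 1L), paste0("q", seq_len(k_m3 - 1L))),
                 setNames(log(c(0.05, 0.4, 1.2))[seq_len(k_m3)],
                          paste0("lomega", seq_len(k_m3)))),
        classes = function(par) {
            pr <- .stickBreak(par[grep("^q", names(par))])
            data.frame(proportion = pr,
                       omega = exp(par[grep("^lomega", names(par))]))
        }),
    M1a = list(
        init = c(lkappa = log(2), q1 = logit(0.7), lomega0 = log(0.2)),
        classes = function(par) {
            p0 <- expit(par["q1"])
            data.frame(proportion = c(p0, 1 - p0),
                       omega = c(min(exp(par["lomega0"]), 1 - 1e-6), 1))
        }),
    M2a = list(
        init = c(lkappa = log(2), q1 = logit(0.6), q2 = logit(0.7),
                 lomega0 = log(0.2), lomega2m1 = log(1)),
        classes = function(par) {
            pr <- .stickBreak(par[c("q1", "q2")])
            data.frame(proportion = pr,
                       omega = c(min(exp(par["lomega0"]), 1 - 1e-6), 1,
                                 1 + exp(par["lomega2m1"])))
        }),
    M7 = list(
        init = c(lkappa = log(2), lp = log(0.5), lq = log(1.5)),
        classes = function(par) data.frame(
            proportion = rep(1 / K_m7, K_m7),
            omega = .betaClassOmegas(exp(par["lp"]), exp(par["lq"]), K_m7))),
    M8 = list(
        init = c(lkappa = log(2), lp = log(0.5), lq = log(1.5),
                 q1 = logit(0.9), lomegasm1 = log(0.5)),
        classes = function(par) {
            p0 <- expit(par["q1"])
            data.frame(
                proportion = c(rep(p0 / K_m7, K_m7), 1 - p0),
                omega = c(.betaClassOmegas(exp(par["lp"]), exp(par["lq"]),
                                           K_m7),
                          1 + exp(par["lomegasm1"])))
        }),
    stop("unknown site model: ", model))
}

.stickBreak <- function(q) {
    expit <- function(x) 1 / (1 + exp(-x))
    k <- length(q) + 1L
    pr <- numeric(k)
    rest <- 1
    for (i in seq_along(q)) {
        pr[i] <- rest * expit(q[i])
        rest <- rest - pr[i]
    }
    pr[k] <- rest
    pr
}

## Branch-site model A class table: 4 classes.
.branchSiteClasses <- function(par, null = FALSE) {
    pr2 <- .stickBreak(par[c("q1", "q2")])  # p0, p1, p2
    p0 <- pr2[1]; p1 <- pr2[2]; p2 <- pr2[3]
    w0 <- min(exp(par["lomega0"]), 1 - 1e-6)
    w2 <- if (null) 1 else 1 + exp(par["lomega2m1"])
    data.frame(
        proportion = c(p0, p1, p2 * p0 / (p0 + p1), p2 * p1 / (p0 + p1)),
        omega_bg = c(w0, 1, w0, 1),
        omega_fg = c(w0, 1, w2, w2))
}

## Mixture log-likelihood over classes; returns total lnL and, if
## wanted, the per-site per-class likelihood matrix for posteriors.
.mixtureLnL <- function(ti, pat, wts, freqs, kappa, class_tab,
                        branch_lengths, foreground_edges = NULL,
                        site_lik = FALSE) {
    ncl <- nrow(class_tab)
    loglik_k <- matrix(0, ncl, ncol(pat))
    has_fg <- !is.null(foreground_edges) && "omega_fg" %in% names(class_tab)
    eg_cache <- new.env(parent = emptyenv())
    getQE <- function(omega) {
        key <- sprintf("%.12g", omega)
        qe <- get0(key, envir = eg_cache)
        if (is.null(qe)) {
            Q <- buildQ(kappa, omega, freqs, scale = FALSE)
            qe <- list(eg = .codonEigen(Q, freqs), mu = attr(Q, "mu"))
            assign(key, qe, envir = eg_cache)
        }
        qe
    }
    ## one common rate scale across classes: the mixture's expected
    ## substitution rate (background omegas for branch-site models)
    om_bg <- if (has_fg) class_tab$omega_bg else class_tab$omega
    S <- sum(class_tab$proportion *
             vapply(om_bg, function(w) getQE(w)$mu, numeric(1L)))
    if (S <= 0) S <- 1
    for (k in seq_len(ncl)) {
        Plist <- vector("list", nrow(ti$edge))
        for (e in seq_len(nrow(ti$edge))) {
            om <- if (has_fg && e %in% foreground_edges)
                class_tab$omega_fg[k]
            else if (has_fg) class_tab$omega_bg[k]
            else class_tab$omega[k]
            Plist[[e]] <- .codonP(getQE(om)$eg, branch_lengths[e] / S)
        }
        loglik_k[k, ] <- .pruneClass(ti, Plist, pat, freqs)
    }
    mx <- apply(loglik_k, 2L, max)
    lik <- class_tab$proportion %*% exp(sweep(loglik_k, 2L, mx))
    total <- sum(wts * (log(as.vector(lik)) + mx))
    if (!site_lik) return(total)
    list(lnL = total, loglik_k = loglik_k)
}
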