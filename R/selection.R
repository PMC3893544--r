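## ML fitting of codon site models and branch-site model A, LRTs and
## NEB site posteriors.  Branch lengths are estimated under M0 and
## then held fixed for the other models (documented simplification;
## see the package vignette).

#' Codon log-likelihood by Felsenstein pruning
#'
#' Computes the log-likelihood of a gap-free codon alignment on a tree
#' under a (possibly mixture) GY94 model.  Codon sites containing a
#' gap or ambiguity in any row are excluded (their indices are
#' attached as \code{attr(,"dropped_sites")}).
#'
#' @param codon_aln Named DNAStringSet of aligned coding sequences.
#' @param tree \code{phylo} tree whose tip labels match the alignment
#'   names.  Non-binary trees are resolved arbitrarily with
#'   zero-length branches (a message is emitted).
#' @param branch_lengths Numeric vector of edge lengths in the order
#'   of \code{tree$edge} after postorder reordering, or NULL to use
#'   \code{tree$edge.length}.
#' @param kappa,omega M0 parameters, used when \code{classes} is NULL.
#' @param classes Optional site-class data.frame with columns
#'   \code{proportion} and \code{omega} (site mixture) or
#'   \code{omega_bg}/\code{omega_fg} (branch-site).
#' @param freqs Codon frequencies (default F3x4 from the alignment).
#' @param foreground Character vector of tip labels defining the
#'   foreground clade for branch-site classes.
#' @return Total log-likelihood (numeric scalar) with attribute
#'   \code{site_loglik} (per-site log-likelihoods).
#' @export
codonLogLik <- function(codon_aln, tree, branch_lengths = NULL,
                        kappa = 2, omega = 0.5, classes = NULL,
                        freqs = NULL, foreground = NULL) {
    prep <- .prepCodonData(codon_aln, tree, freqs)
    bl <- if (is.null(branch_lengths)) prep$ti$len else branch_lengths
    if (is.null(bl)) stop("tree has no branch lengths")
    if (is.null(classes))
        classes <- data.frame(proportion = 1, omega = omega)
    fg <- if (is.null(foreground)) NULL
          else .foregroundEdges(prep$ti, foreground)
    r <- .mixtureLnL(prep$ti, prep$pat, prep$wts, prep$freqs, kappa,
                     classes, bl, fg, site_lik = TRUE)
    mx <- apply(r$loglik_k, 2L, max)
    site_pat <- log(as.vector(
        classes$proportion %*% exp(sweep(r$loglik_k, 2L, mx)))) + mx
    out <- r$lnL
    attr(out, "site_loglik") <- site_pat[prep$index]
    attr(out, "dropped_sites") <- prep$dropped
    out
}

.prepCodonData <- function(codon_aln, tree, freqs = NULL) {
    if (!ape::is.binary.phylo(tree)) {
        message("tree is not binary; resolving with zero-length branches")
        tree <- ape::multi2di(tree)
        if (!is.null(tree$edge.length))
            tree$edge.length[is.na(tree$edge.length)] <- 0
    }
    if (!setequal(tree$tip.label, names(codon_aln)))
        stop("tree tips and alignment names differ")
    enc <- .encodeCodonAlignment(codon_aln)
    if (ncol(enc) == 0L) stop("no gap-free codon sites left")
    sp <- .sitePatterns(enc)
    if (is.null(freqs)) freqs <- codonFreqsF3x4(codon_aln)
    ti <- .treeInfo(tree)
    list(ti = ti, pat = sp$patterns, wts = sp$weights, index = sp$index,
         freqs = freqs, dropped = attr(enc, "dropped_sites"))
}

## Edges whose child subtree is contained in the foreground tip set
## (covers the clade's stem branch and all branches inside it).
.foregroundEdges <- function(ti, foreground) {
    ntip <- ti$ntip
    tipsets <- vector("list", ntip + ti$nnode)
    for (i in seq_len(ntip)) tipsets[[i]] <- ti$tips[i]
    for (e in seq_len(nrow(ti$edge)))  # postorder: children first
        tipsets[[ti$edge[e, 1L]]] <- c(tipsets[[ti$edge[e, 1L]]],
                                       tipsets[[ti$edge[e, 2L]]])
    which(vapply(seq_len(nrow(ti$edge)), function(e)
        all(tipsets[[ti$edge[e, 2L]]] %in% foreground), logical(1L)))
}

#' Fit a codon substitution model by maximum likelihood
#'
#' Supported models: \code{M0} (single omega; also estimates branch
#' lengths unless supplied), \code{M3} (k discrete omega classes),
#' \code{M1a}/\code{M2a} (nearly-neutral / positive selection),
#' \code{M7}/\code{M8} (beta / beta + omega > 1; the beta is
#' discretized into K = 10 equal-probability categories by bin means),
#' and \code{branch-site-A} / \code{branch-site-A-null} (omega2 free
#' / fixed at 1 on the foreground).  For every model except M0 branch
#' lengths must be supplied (normally from a prior M0 fit) and only
#' the model parameters are optimized, by bounded quasi-Newton with
#' multi-start.
#'
#' @param codon_aln Named DNAStringSet of aligned coding rows.
#' @param tree \code{phylo} with tip labels matching the rows.
#' @param model Model name (see above).
#' @param branch_lengths Edge lengths (postorder edge order) to hold
#'   fixed; NULL for M0 means estimate them.
#' @param freqs Codon frequency vector, or \code{"F3x4"} (default) /
#'   \code{"equal"}.
#' @param foreground Tip labels of the foreground clade (branch-site
#'   models only).
#' @param k_m3 Number of M3 classes (default 3).
#' @param n_starts Number of optimizer starts (default 2).
#' @param control List passed to [stats::nlminb()].
#' @return A [CodonFit-class] object.
#' @seealso [codonLRT()], [sitePosteriors()]
#' @export
fitCodonModel <- function(codon_aln, tree, model = "M0",
                          branch_lengths = NULL, freqs = "F3x4",
                          foreground = NULL, k_m3 = 3L, n_starts = 2L,
                          control = list(rel.tol = 1e-8, iter.max = 400L,
                                         eval.max = 1000L)) {
    model <- match.arg(model, c("M0", "M3", "M1a", "M2a", "M7", "M8",
                                "branch-site-A", "branch-site-A-null"))
    prep <- .prepCodonData(codon_aln, tree,
        freqs = if (is.character(freqs)) NULL else freqs)
    if (is.character(freqs) && freqs == "equal")
        prep$freqs <- rep(1 / .CODONS$n, .CODONS$n)
    is_bs <- startsWith(model, "branch-site")
    fg <- NULL
    if (is_bs) {
        if (is.null(foreground))
            stop("branch-site models need a foreground clade")
        fg <- .foregroundEdges(prep$ti, foreground)
        if (!length(fg)) stop("foreground clade not found in tree")
    }
    nedge <- nrow(prep$ti$edge)
    estimate_bl <- is.null(branch_lengths)
    if (estimate_bl && model != "M0")
        stop("supply branch_lengths (e.g. from an M0 fit) for ", model)
    if (!estimate_bl && length(branch_lengths) != nedge)
        stop("branch_lengths must have one entry per edge (", nedge, ")")

    if (is_bs) {
        null_model <- model == "branch-site-A-null"
        init <- c(q1 = log(0.7 / 0.3), q2 = 0, lomega0 = log(0.2))
        if (!null_model) init <- c(init, lomega2m1 = log(1))
        class_fun <- function(par) .branchSiteClasses(par, null_model)
    } else {
        spec <- .modelSpec(model, k_m3 = k_m3)
        init <- spec$init[setdiff(names(spec$init), "lkappa")]
        class_fun <- spec$classes
    }
    init <- c(lkappa = log(2), init)

    obj <- function(par) {
        bl <- if (estimate_bl)
            exp(par[grep("^lbl", names(par))]) else branch_lengths
        kappa <- exp(par[["lkappa"]])
        if (kappa > 99 || kappa < 1e-4) return(1e10)
        cls <- class_fun(par)
        om <- unlist(cls[grep("omega", names(cls))])
        if (any(om > 99)) return(1e10)
        ll <- tryCatch(.mixtureLnL(prep$ti, prep$pat, prep$wts,
                                   prep$freqs, kappa, cls, bl, fg),
                       error = function(e) -Inf)
        if (!is.finite(ll)) return(1e10)
        -ll
    }
    if (estimate_bl) {
        bl0 <- .startingBranchLengths(codon_aln, prep$ti)
        init <- c(init, setNames(log(bl0), paste0("lbl", seq_len(nedge))))
    }

    best <- NULL
    set_jitter <- c(0, 0.5, 1, 1.5)
    for (s in seq_len(n_starts)) {
        start <- init + if (s == 1L) 0 else
            stats::rnorm(length(init), 0, set_jitter[min(s, 4L)])
        fit <- tryCatch(
            nlminb(start, obj, control = control),
            error = function(e) NULL)
        if (!is.null(fit) &&
            (is.null(best) || fit$objective < best$objective))
            best <- fit
    }
    if (is.null(best)) stop("codon model optimization failed: ", model)
    par <- best$par
    cls <- class_fun(par)
    bl <- if (estimate_bl) exp(par[grep("^lbl", names(par))])
          else branch_lengths
    mle <- c(kappa = exp(par[["lkappa"]]))
    if (!is_bs && model == "M0") mle["omega"] <- cls$omega[1L]
    if (model == "M1a") mle <- c(mle, p0 = cls$proportion[1L],
                                 omega0 = cls$omega[1L])
    if (model == "M2a") mle <- c(mle, p0 = cls$proportion[1L],
                                 p1 = cls$proportion[2L],
                                 omega0 = cls$omega[1L],
                                 omega2 = cls$omega[3L])
    if (model == "M3") mle <- c(mle,
        setNames(cls$proportion, paste0("p", seq_len(nrow(cls)) - 1L)),
        setNames(cls$omega, paste0("omega", seq_len(nrow(cls)) - 1L)))
    if (model %in% c("M7", "M8")) {
        mle <- c(mle, p_beta = exp(par[["lp"]]), q_beta = exp(par[["lq"]]))
        if (model == "M8") mle <- c(mle,
            p0 = 1 / (1 + exp(-par[["q1"]])),
            omega_s = cls$omega[nrow(cls)])
    }
    if (is_bs) mle <- c(mle, p0 = cls$proportion[1L],
                        p1 = cls$proportion[2L],
                        omega0 = cls$omega_bg[1L],
                        omega2 = cls$omega_fg[3L])
    ## per-site class likelihoods for posteriors
    r <- .mixtureLnL(prep$ti, prep$pat, prep$wts, prep$freqs,
                     exp(par[["lkappa"]]), cls, bl, fg, site_lik = TRUE)
    post <- if (nrow(cls) > 1L) {
        lk <- exp(sweep(r$loglik_k, 2L,
                        apply(r$loglik_k, 2L, max)))
        w <- cls$proportion * lk
        pp <- t(w) / colSums(w)
        pp[prep$index, , drop = FALSE]
    } else matrix(numeric(0), 0L, 0L)
    new("CodonFit", model = model, lnL = -best$objective, mle = mle,
        classes = cls, posteriors = post,
        branch_lengths = setNames(bl, paste0("e", seq_len(nedge))),
        converged = best$convergence == 0L)
}

## Starting branch lengths from pairwise codon mismatch fractions:
## total expected tree length spread equally over edges.
.startingBranchLengths <- function(codon_aln, ti) {
    chr <- strsplit(as.character(codon_aln), "")
    n <- length(chr)
    pbar <- 0; cnt <- 0
    for (i in seq_len(min(n - 1L, 5L))) {
        j <- i + 1L
        ok <- chr[[i]] != "-" & chr[[j]] != "-"
        pbar <- pbar + mean(chr[[i]][ok] != chr[[j]][ok]); cnt <- cnt + 1
    }
    pbar <- pbar / cnt
    total <- max(3 * pbar, 0.05) * 2
    rep(max(total / nrow(ti$edge), 0.02), nrow(ti$edge))
}

#' Likelihood-ratio test between nested codon model fits
#'
#' @param fit_null,fit_alt [CodonFit-class] objects for the nested and
#'   the more general model.
#' @param df Degrees of freedom.  Defaults follow the standard ladder:
#'   M0-M3(k=3) 4, M1a-M2a 2, M7-M8 2, branch-site A vs its null 1;
#'   pass \code{df} explicitly to override.
#' @return data.frame with \code{statistic}, \code{df}, \code{p_value}.
#' @export
codonLRT <- function(fit_null, fit_alt, df = NULL) {
    if (is.null(df)) {
        key <- paste(fit_null@model, fit_alt@model, sep = "-")
        df <- switch(key,
            "M0-M3" = 2L * nrow(fit_alt@classes) - 2L,
            "M1a-M2a" = 2L, "M7-M8" = 2L,
            "branch-site-A-null-branch-site-A" = 1L,
            stop("no default df for ", key, "; pass df explicitly"))
    }
    if (df < 1L) stop("df must be >= 1")
    delta <- fit_alt@lnL - fit_null@lnL
    if (delta < -1e-4)
        warning("alternative lnL below null lnL by ", -delta,
                "; optimizer artefact")
    stat <- max(2 * delta, 0)
    data.frame(statistic = stat, df = df,
               p_value = pchisq(stat, df, lower.tail = FALSE))
}

#' Naive empirical Bayes site posteriors and selected-site calls
#'
#' Posterior class probabilities at the MLEs (NEB).  Sites whose
#' posterior mass on positively selected classes (omega > 1 on the
#' foreground for branch-site models) exceeds the threshold are
#' flagged.
#'
#' @param fit A [CodonFit-class] from a mixture or branch-site model.
#' @param threshold Posterior probability threshold (default 0.75).
#' @return List with \code{posteriors} (sites x classes matrix),
#'   \code{p_positive} (per-site mass on positive classes) and
#'   \code{flagged} (site indices with p_positive > threshold).
#' @export
sitePosteriors <- function(fit, threshold = 0.75) {
    if (nrow(fit@posteriors) == 0L)
        stop("fit has no site classes (M0); posteriors undefined")
    cls <- fit@classes
    om <- if ("omega_fg" %in% names(cls)) cls$omega_fg else cls$omega
    pos <- which(om > 1)
    p_pos <- if (length(pos))
        rowSums(fit@posteriors[, pos, drop = FALSE]) else
        rep(0, nrow(fit@posteriors))
    list(posteriors = fit@posteriors, p_positive = p_pos,
         flagged = which(p_pos > threshold))
}
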