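## Type-I functional divergence between two duplicate clusters:
## per-site substitution counts by Fitch parsimony, ML estimation of
## the divergence coefficient theta1 under a Poisson-gamma rate
## mixture, LRT, and per-site posteriors.

#' Per-site Fitch parsimony substitution counts
#'
#' Minimum substitution count per alignment column on a cluster's
#' tree topology (Fitch's set method on a rooted resolution;
#' branch lengths ignored).
#'
#' @param aln Named AAStringSet containing the cluster's rows.
#' @param tree \code{phylo} whose tips are a subset of the row names.
#' @return Integer vector, one minimum count per column; columns that
#'   are entirely gaps in the cluster are NA.
#' @export
fitchCounts <- function(aln, tree) {
    tips <- tree$tip.label
    miss <- setdiff(tips, names(aln))
    if (length(miss)) stop("rows missing: ", paste(miss, collapse = ", "))
    tr <- tree
    if (!ape::is.rooted(tr)) tr <- ape::root(tr, tips[1L],
                                             resolve.root = TRUE)
    if (!ape::is.binary.phylo(tr)) tr <- ape::multi2di(tr)
    ti <- .treeInfo(tr)
    m <- do.call(rbind, strsplit(as.character(aln[tips]), ""))
    rownames(m) <- tips
    nsite <- ncol(m)
    counts <- integer(nsite)
    for (s in seq_len(nsite)) {
        col <- m[, s]
        obs <- col[col != "-" & col != "X"]
        if (!length(obs)) { counts[s] <- NA_integer_; next }
        sets <- vector("list", ti$ntip + ti$nnode)
        for (t in seq_len(ti$ntip)) {
            ch <- col[ti$tips[t]]
            sets[[t]] <- if (ch %in% c("-", "X")) NULL else ch
        }
        nsub <- 0L
        ## postorder edges: child sets are complete when their edge is
        ## reached; merge each child into its parent Fitch-style
        for (e in seq_len(nrow(ti$edge))) {
            p <- ti$edge[e, 1L]
            cset <- sets[[ti$edge[e, 2L]]]
            if (is.null(cset)) next          # all-gap child subtree
            if (is.null(sets[[p]])) {
                sets[[p]] <- cset
            } else {
                inter <- intersect(sets[[p]], cset)
                if (length(inter)) {
                    sets[[p]] <- inter
                } else {
                    sets[[p]] <- union(sets[[p]], cset)
                    nsub <- nsub + 1L
                }
            }
        }
        counts[s] <- nsub
    }
    counts
}

## Marginal likelihoods of a site's count pair under the shared-rate
## and independent-rate components (gamma(alpha, alpha) rates, counts
## Poisson(rate * t_c)): negative-binomial closed forms.
.sharedLik <- function(x1, x2, alpha, t1, t2) {
    exp(lgamma(alpha + x1 + x2) - lgamma(alpha) - lgamma(x1 + 1) -
        lgamma(x2 + 1) + x1 * log(t1) + x2 * log(t2) +
        alpha * log(alpha) -
        (alpha + x1 + x2) * log(alpha + t1 + t2))
}

.indepLik <- function(x, alpha, t) {
    exp(lgamma(alpha + x) - lgamma(alpha) - lgamma(x + 1) +
        alpha * log(alpha / (alpha + t)) + x * log(t / (alpha + t)))
}

.theta1LnL <- function(theta, alpha, t1, t2, x1, x2) {
    p0 <- .sharedLik(x1, x2, alpha, t1, t2)
    p1 <- .indepLik(x1, alpha, t1) * .indepLik(x2, alpha, t2)
    sum(log(pmax((1 - theta) * p0 + theta * p1, 1e-300)))
}

#' Estimate type-I functional divergence (theta1)
#'
#' Fits by ML the two-cluster rate mixture: with probability
#' 1 - theta1 a site's substitution rate is shared between the
#' clusters (rate ~ gamma(alpha), counts Poisson with cluster-specific
#' exposures), with probability theta1 the two clusters draw
#' independent rates.  The LRT compares the free-theta1 fit with the
#' theta1 = 0 null on 1 degree of freedom (the field's convention; a
#' boundary-corrected p-value is also reported).  Site posteriors of
#' rate divergence follow by Bayes' rule at the MLE.
#'
#' @param x1,x2 Integer vectors of per-site substitution counts in
#'   cluster 1 / cluster 2 (e.g. from [fitchCounts()]); sites with NA
#'   in either cluster are dropped.
#' @param n_starts Optimizer multi-starts (default 4).
#' @return A [DivergenceFit-class] object.
#' @export
estimateTheta1 <- function(x1, x2, n_starts = 4L) {
    ok <- is.finite(x1) & is.finite(x2)
    x1 <- x1[ok]; x2 <- x2[ok]
    n <- length(x1)
    if (n < 50L) warning("fewer than 50 usable sites (", n,
                         "); estimates will be unstable")
    ## parameters on optimizer scale: logit(theta), log(alpha),
    ## log(t1), log(t2)
    expit <- function(z) 1 / (1 + exp(-z))
    nll <- function(par, fix_theta0 = FALSE) {
        theta <- if (fix_theta0) 0 else expit(par[1L])
        k <- if (fix_theta0) 0L else 1L
        alpha <- exp(par[k + 1L]); t1 <- exp(par[k + 2L])
        t2 <- exp(par[k + 3L])
        if (alpha > 1e3 || alpha < 1e-4) return(1e10)
        v <- -.theta1LnL(theta, alpha, t1, t2, x1, x2)
        if (!is.finite(v)) 1e10 else v
    }
    t1_0 <- log(max(mean(x1), 0.05)); t2_0 <- log(max(mean(x2), 0.05))
    starts <- list(c(0, 0, t1_0, t2_0), c(-2, log(0.5), t1_0, t2_0),
                   c(2, log(2), t1_0, t2_0), c(-1, log(5), t1_0, t2_0))
    best <- NULL
    for (s in seq_len(min(n_starts, length(starts)))) {
        f <- tryCatch(optim(starts[[s]], nll, method = "BFGS",
                            control = list(maxit = 500)),
                      error = function(e) NULL)
        if (!is.null(f) && (is.null(best) || f$value < best$value))
            best <- f
    }
    if (is.null(best)) stop("theta1 optimization failed to converge")
    ## null fit (theta = 0)
    best0 <- NULL
    for (s in seq_len(2L)) {
        f <- tryCatch(optim(starts[[s]][-1L], nll, fix_theta0 = TRUE,
                            method = "BFGS",
                            control = list(maxit = 500)),
                      error = function(e) NULL)
        if (!is.null(f) && (is.null(best0) || f$value < best0$value))
            best0 <- f
    }
    lnL1 <- -best$value; lnL0 <- -best0$value
    if (lnL1 < lnL0) {   # theta = 0 boundary optimum
        lnL1 <- lnL0
        best$par <- c(-20, best0$par)
    }
    theta <- expit(best$par[1L]); alpha <- exp(best$par[2L])
    t1 <- exp(best$par[3L]); t2 <- exp(best$par[4L])
    lrt <- max(2 * (lnL1 - lnL0), 0)
    ## SE of theta via observed information on the natural scale
    h <- 1e-4
    f2 <- function(th) .theta1LnL(min(max(th, 1e-8), 1 - 1e-8),
                                  alpha, t1, t2, x1, x2)
    th <- min(max(theta, h * 2), 1 - h * 2)
    d2 <- (f2(th + h) - 2 * f2(th) + f2(th - h)) / h^2
    se <- if (is.finite(d2) && d2 < 0) sqrt(-1 / d2) else NA_real_
    p0 <- .sharedLik(x1, x2, alpha, t1, t2)
    p1 <- .indepLik(x1, alpha, t1) * .indepLik(x2, alpha, t2)
    post <- theta * p1 / pmax((1 - theta) * p0 + theta * p1, 1e-300)
    new("DivergenceFit", theta1 = theta, se = se, alpha = alpha,
        lnL0 = lnL0, lnL1 = lnL1, lrt = lrt,
        p_value = pchisq(lrt, 1L, lower.tail = FALSE),
        p_value_mixture = 0.5 * pchisq(lrt, 1L, lower.tail = FALSE),
        posterior = post,
        mle = c(theta1 = theta, alpha = alpha, t1 = t1, t2 = t2))
}

#' @describeIn estimateTheta1 Convenience wrapper: Fitch counts per
#'   cluster from a [GroupedAlignment-class] with groups "cluster1"
#'   and "cluster2" (or the two group names given), then
#'   [estimateTheta1()].
#' @param aln GroupedAlignment with the two clusters as groups.
#' @param tree1,tree2 Cluster trees.
#' @param groups Names of the two groups (default the first two).
#' @export
estimateTheta1FromAlignment <- function(aln, tree1, tree2,
                                        groups = NULL) {
    gs <- alnGroups(aln)
    if (is.null(groups)) groups <- names(gs)[1:2]
    seqs <- alnSeqs(aln)
    x1 <- fitchCounts(seqs[gs[[groups[1L]]]], tree1)
    x2 <- fitchCounts(seqs[gs[[groups[2L]]]], tree2)
    estimateTheta1(x1, x2)
}

#' Sites with high posterior probability of rate divergence
#'
#' @param fit A [DivergenceFit-class].
#' @param cutoff Posterior cutoff (strict >; default 0.7, the
#'   conventional reporting threshold).
#' @return data.frame of site indices and posteriors, sorted by
#'   descending posterior.
#' @export
divergentSites <- function(fit, cutoff = 0.7) {
    idx <- which(fit@posterior > cutoff)
    out <- data.frame(site = idx, posterior = fit@posterior[idx])
    out[order(-out$posterior), , drop = FALSE]
}
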