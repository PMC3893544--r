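## Independent oracles used by the unit and acceptance tests.  Each
## is a deliberately naive implementation kept separate from the
## package's code paths.

## Exhaustive affine-gap global alignment score by enumerating every
## monotone alignment path (gap of length L costs open + L * extend).
bruteAlignScore <- function(a, b, match = 2, mismatch = -3,
                            open = 5, extend = 2) {
    av <- strsplit(a, "")[[1L]]; bv <- strsplit(b, "")[[1L]]
    best <- -Inf
    rec <- function(i, j, score, prev) {
        if (i > length(av) && j > length(bv)) {
            best <<- max(best, score)
            return(invisible())
        }
        if (i <= length(av) && j <= length(bv)) {
            s <- if (av[i] == bv[j]) match else mismatch
            rec(i + 1L, j + 1L, score + s, "m")
        }
        if (i <= length(av)) {   # a[i] against gap
            pen <- extend + if (prev == "a") 0 else open
            rec(i + 1L, j, score - pen, "a")
        }
        if (j <= length(bv)) {   # b[j] against gap
            pen <- extend + if (prev == "b") 0 else open
            rec(i, j + 1L, score - pen, "b")
        }
        invisible()
    }
    rec(1L, 1L, 0, "m")
    best
}

## Exhaustive Fitch minimum: minimize substitutions over all
## labelings of internal nodes with the observed state set.
bruteFitchMin <- function(tree, tip_states) {
    tr <- if (ape::is.rooted(tree)) tree else
        ape::root(tree, tree$tip.label[1L], resolve.root = TRUE)
    tr <- ape::multi2di(tr)
    ntip <- length(tr$tip.label)
    nint <- tr$Nnode
    states <- unique(unname(tip_states))
    grid <- do.call(expand.grid,
                    c(rep(list(states), nint),
                      list(stringsAsFactors = FALSE)))
    best <- Inf
    for (g in seq_len(nrow(grid))) {
        lab <- c(unname(tip_states[tr$tip.label]),
                 unlist(grid[g, ], use.names = FALSE))
        cost <- sum(lab[tr$edge[, 1L]] != lab[tr$edge[, 2L]])
        best <- min(best, cost)
    }
    best
}

## Codon log-likelihood on a rooted 4-leaf tree ((a,b)u,(c,d)v)root
## by explicit summation over the two internal states, with P(t)
## from Matrix::expm (independent of the package's eigensystem).
bruteCodonLnL4 <- function(enc, bl, kappa, omega, freqs) {
    Q <- buildQ(kappa, omega, freqs)   # generator is shared by design
    P <- lapply(bl, function(t) as.matrix(Matrix::expm(Q * t)))
    total <- 0
    for (s in seq_len(ncol(enc))) {
        a <- enc["a", s]; b <- enc["b", s]
        cc <- enc["c", s]; d <- enc["d", s]
        Avec <- numeric(61); Bvec <- numeric(61)
        for (u in 1:61)
            Avec[u] <- P[["a"]][u, a] * P[["b"]][u, b]
        for (v in 1:61)
            Bvec[v] <- P[["c"]][v, cc] * P[["d"]][v, d]
        lik <- 0
        for (r in 1:61)
            lik <- lik + freqs[r] *
                sum(P[["u"]][r, ] * Avec) * sum(P[["v"]][r, ] * Bvec)
        total <- total + log(lik)
    }
    total
}

## Ordinary-least-squares fit of a distance matrix on a fixed
## topology; returns the residual sum of squares.
olsTreeRSS <- function(tree, d) {
    labs <- rownames(d)
    n <- length(labs)
    pairs <- t(combn(n, 2L))
    nedge <- nrow(tree$edge)
    A <- matrix(0, nrow(pairs), nedge)
    ## edge incidence on each tip-pair path
    tr <- ape::unroot(tree)
    nedge <- nrow(tr$edge)
    A <- matrix(0, nrow(pairs), nedge)
    for (k in seq_len(nrow(pairs))) {
        t1 <- which(tr$tip.label == labs[pairs[k, 1L]])
        t2 <- which(tr$tip.label == labs[pairs[k, 2L]])
        ## path via node ancestors
        anc <- function(x) {
            out <- x
            repeat {
                p <- tr$edge[tr$edge[, 2L] == x, 1L]
                if (!length(p)) break
                out <- c(out, p); x <- p
            }
            out
        }
        a1 <- anc(t1); a2 <- anc(t2)
        mrca <- intersect(a1, a2)[1L]
        path_nodes <- c(a1[seq_len(which(a1 == mrca))],
                        a2[seq_len(which(a2 == mrca) - 1L)])
        on_path <- function(e)
            tr$edge[e, 1L] %in% path_nodes &&
            tr$edge[e, 2L] %in% path_nodes
        A[k, ] <- vapply(seq_len(nedge), on_path, logical(1L))
    }
    y <- d[pairs]
    fit <- lm.fit(A, y)
    sum(fit$residuals^2)
}

## Random additive distance matrix from a random topology.
randomAdditiveMatrix <- function(n, seed) {
    set.seed(seed)
    tr <- ape::rtree(n, rooted = FALSE,
                     br = function(k) runif(k, 0.1, 1))
    tr$tip.label <- paste0("t", seq_len(n))
    list(tree = tr, d = cophenetic(tr))
}

## Character-level reference implementation of adapter + quality
## trimming for one read.
naiveTrim <- function(seq, qual, floor, adapters) {
    for (ad in adapters) {
        p <- regexpr(ad, seq, fixed = TRUE)
        if (p != -1L) {
            seq <- substr(seq, 1L, p - 1L)
            qual <- substr(qual, 1L, p - 1L)
        }
    }
    q <- utf8ToInt(qual) - 33L
    keep <- 0L
    for (i in seq_along(q)) {
        if (q[i] < floor) break
        keep <- i
    }
    list(seq = substr(seq, 1L, keep), qual = substr(qual, 1L, keep))
}

## Small fixed test tree with labelled tips.
toyTree <- function(n = 6L, seed = 1L, scale = 1) {
    set.seed(seed)
    tr <- ape::rtree(n, br = function(k) runif(k, 0.1, 0.4) * scale)
    tr$tip.label <- paste0("s", seq_len(n))
    tr
}
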