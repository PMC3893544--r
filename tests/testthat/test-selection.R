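test_that("the GY94 generator has the required structure", {
    pi61 <- rep(1 / 61, 61)
    Q <- buildQ(1, 1, pi61)
    expect_equal(max(abs(rowSums(Q))), 0, tolerance = 1e-12)
    ## omega = kappa = 1, equal freqs: all allowed changes share a rate
    off <- Q[Q > 0]
    expect_equal(max(off), min(off))
    ## detailed balance for a non-trivial parameter set
    f <- runif(61); f <- f / sum(f)
    Q2 <- buildQ(2.5, 0.4, f)
    expect_equal(max(abs(f * Q2 - t(f * Q2))), 0, tolerance = 1e-12)
    ## unit expected substitution rate
    expect_equal(-sum(f * diag(Q2)), 1, tolerance = 1e-12)
    ## P(t) rows sum to 1
    eg <- hgtscreen:::.codonEigen(Q2, f)
    for (t in c(0.01, 0.1, 1)) {
        P <- hgtscreen:::.codonP(eg, t)
        expect_equal(range(rowSums(P)), c(1, 1), tolerance = 1e-9)
        expect_true(all(P >= 0))
    }
    expect_error(buildQ(-1, 0.5), "kappa")
    expect_error(buildQ(2, -0.1), "omega")
})

test_that("pruning equals explicit state enumeration on small trees", {
    pi61 <- rep(1 / 61, 61)
    ## 3-leaf tree against full internal-state summation
    tr3 <- ape::read.tree(text = "((a:0.2,b:0.3):0.15,c:0.4);")
    sim <- simulateCodonAlignment(tr3, 2, 0.5, 1, 3, seed = 3)
    enc <- hgtscreen:::.encodeCodonAlignment(sim$alignment)
    Q <- buildQ(2, 0.5, pi61)
    P <- lapply(c(0.2, 0.3, 0.15, 0.4),
                function(t) as.matrix(Matrix::expm(Q * t)))
    brute <- 0
    for (s in seq_len(ncol(enc))) {
        tot <- 0
        for (r in 1:61) for (u in 1:61)
            tot <- tot + pi61[r] * P[[3]][r, u] *
                P[[1]][u, enc["a", s]] * P[[2]][u, enc["b", s]] *
                P[[4]][r, enc["c", s]]
        brute <- brute + log(tot)
    }
    got <- codonLogLik(sim$alignment, tr3, kappa = 2, omega = 0.5,
                       freqs = pi61)
    expect_equal(as.numeric(got), brute, tolerance = 1e-8)

    ## pulley principle: unrooted re-rooting leaves lnL unchanged
    got_u <- suppressMessages(codonLogLik(sim$alignment,
        ape::unroot(tr3), kappa = 2, omega = 0.5, freqs = pi61))
    expect_equal(as.numeric(got_u), brute, tolerance = 1e-8)
})

test_that("t -> 0 with identical sequences gives the stationary log-density", {
    pi61 <- rep(1 / 61, 61)
    row <- paste(rep("ATGAAA", 5), collapse = "")
    aln <- Biostrings::DNAStringSet(c(a = row, b = row, c = row))
    tr <- ape::read.tree(text = "((a:1e-9,b:1e-9):1e-9,c:1e-9);")
    ll <- codonLogLik(aln, tr, kappa = 2, omega = 0.5, freqs = pi61)
    enc <- hgtscreen:::.encodeCodonAlignment(aln)
    expect_equal(as.numeric(ll), sum(log(pi61[enc["a", ]])),
                 tolerance = 1e-6)
})

test_that("nested site models respect the likelihood ordering", {
    tr <- toyTree(5, seed = 2, scale = 1.2)
    sim <- simulateCodonAlignment(tr, kappa = 2,
                                  omegas = c(0.1, 0.8),
                                  proportions = c(0.6, 0.4),
                                  n_codons = 120, seed = 5)
    bl <- hgtscreen:::.treeInfo(tr)$len
    f0 <- fitCodonModel(sim$alignment, tr, "M0", branch_lengths = bl,
                        n_starts = 1)
    f3 <- fitCodonModel(sim$alignment, tr, "M3", branch_lengths = bl,
                        n_starts = 1)
    f1a <- fitCodonModel(sim$alignment, tr, "M1a", branch_lengths = bl,
                         n_starts = 1)
    f2a <- fitCodonModel(sim$alignment, tr, "M2a", branch_lengths = bl,
                         n_starts = 1)
    expect_lte(f0@lnL, f3@lnL + 1e-4)
    expect_lte(f1a@lnL, f2a@lnL + 1e-4)
    ## LRT basics
    lrt <- codonLRT(f1a, f2a)
    expect_gte(lrt$statistic, 0)
    expect_equal(lrt$df, 2)
    lrt0 <- codonLRT(f0, f0, df = 1)
    expect_equal(lrt0$statistic, 0)
    expect_equal(lrt0$p_value, 1)
    expect_equal(codonLRT(f0, f3)$df, 4)
    expect_error(codonLRT(f0, f3, df = 0), "df")
    ## posteriors: rows sum to 1; M0 has none
    expect_error(sitePosteriors(f0), "M0")
    sp <- sitePosteriors(f2a)
    expect_equal(unname(rowSums(sp$posteriors)),
                 rep(1, nrow(sp$posteriors)), tolerance = 1e-9)
})

test_that("M7/M8 discretization is a valid beta approximation", {
    w <- hgtscreen:::.betaClassOmegas(0.5, 1.5, 10)
    expect_length(w, 10)
    expect_true(all(w > 0 & w < 1))
    expect_true(!is.unsorted(w))
    ## category means average to the beta mean
    expect_equal(mean(w), 0.5 / (0.5 + 1.5), tolerance = 1e-6)
})

test_that("branch-site model A detects foreground positive selection", {
    tr <- toyTree(6, seed = 7, scale = 1)
    fg <- c("s1", "s2")
    ## make s1+s2 a clade
    tr <- ape::read.tree(text = paste0(
        "((s1:0.15,s2:0.15):0.2,((s3:0.2,s4:0.2):0.1,",
        "(s5:0.2,s6:0.2):0.1):0.1);"))
    sim <- simulateCodonAlignment(tr, kappa = 2,
                                  omegas = c(0.1, 1, 0.1),
                                  proportions = c(0.5, 0.2, 0.3),
                                  foreground = fg, omega_fg = 6,
                                  n_codons = 250, seed = 9)
    bl <- hgtscreen:::.treeInfo(tr)$len
    fnull <- fitCodonModel(sim$alignment, tr, "branch-site-A-null",
                           branch_lengths = bl, foreground = fg,
                           n_starts = 1)
    falt <- fitCodonModel(sim$alignment, tr, "branch-site-A",
                          branch_lengths = bl, foreground = fg,
                          n_starts = 1)
    expect_lte(fnull@lnL, falt@lnL + 1e-4)
    lrt <- codonLRT(fnull, falt)
    expect_equal(lrt$df, 1)
    expect_lt(lrt$p_value, 0.05)
    ## flagged sites are enriched for the truly selected class
    sp <- sitePosteriors(falt, threshold = 0.75)
    if (length(sp$flagged)) {
        prec <- mean(sim$site_class[sp$flagged] == 3)
        expect_gte(prec, 0.5)
    }
})

test_that("simulation under M0 is recovered by the M0 fit", {
    tr <- toyTree(6, seed = 11, scale = 1)
    sim <- simulateCodonAlignment(tr, kappa = 2, omegas = 0.2,
                                  proportions = 1, n_codons = 300,
                                  seed = 13)
    fit <- fitCodonModel(sim$alignment, tr, "M0", n_starts = 1)
    expect_true(fit@converged)
    expect_gt(fit@mle["omega"], 0.13)
    expect_lt(fit@mle["omega"], 0.28)
    ## deterministic given data
    fit2 <- fitCodonModel(sim$alignment, tr, "M0", n_starts = 1)
    expect_identical(fit@lnL, fit2@lnL)
})

test_that("branch lengths of zero collapse rows to the root state", {
    tr <- ape::read.tree(text = "((a:0,b:0):0,c:0);")
    sim <- simulateCodonAlignment(tr, 2, 0.5, 1, 20, seed = 2)
    chr <- as.character(sim$alignment)
    expect_equal(unname(chr[1]), unname(chr[2]))
    expect_equal(unname(chr[1]), unname(chr[3]))
})
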