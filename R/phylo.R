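## Distance-based tree building with bootstrap clade support, and the
## clade-placement test that turns a tree into an HGT verdict.

#' Pairwise distances from a protein alignment
#'
#' p-distance (mismatches over compared columns, pairwise deletion of
#' gap positions) or its Poisson correction -ln(1 - p).
#'
#' @param aln Named AAStringSet or [GroupedAlignment-class] (trimmed).
#' @param correction "p" or "poisson".
#' @return Symmetric distance matrix with zero diagonal.
#' @export
proteinDistance <- function(aln, correction = c("p", "poisson")) {
    correction <- match.arg(correction)
    if (methods::is(aln, "GroupedAlignment")) aln <- alnSeqs(aln)
    if (length(aln) < 2L) stop("need at least 2 rows")
    m <- do.call(rbind, strsplit(as.character(aln), ""))
    rownames(m) <- names(aln)
    n <- nrow(m)
    d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        ok <- m[i, ] != "-" & m[j, ] != "-"
        if (!any(ok))
            stop("no comparable columns between ", rownames(m)[i],
                 " and ", rownames(m)[j])
        p <- mean(m[i, ok] != m[j, ok])
        if (correction == "poisson") {
            if (p >= 1)
                stop("p-distance 1 between ", rownames(m)[i], " and ",
                     rownames(m)[j], ": Poisson correction undefined")
            p <- -log(1 - p)
        }
        d[i, j] <- d[j, i] <- p
    }
    d
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining via [ape::nj()]; negative branch
#' lengths are clamped to zero (the clamped total is reported in
#' \code{attr(,"negative_length_clamped")}).
#'
#' @param d Symmetric distance matrix (labels as dimnames).
#' @return Unrooted \code{phylo} tree with branch lengths.
#' @export
njTree <- function(d) {
    d <- as.matrix(d)
    if (nrow(d) < 3L) stop("need at least 3 taxa")
    if (max(abs(d - t(d))) > 1e-9) stop("distance matrix not symmetric")
    tr <- ape::nj(as.dist(d))
    deficit <- -sum(tr$edge.length[tr$edge.length < 0])
    tr$edge.length[tr$edge.length < 0] <- 0
    attr(tr, "negative_length_clamped") <- deficit
    tr
}

#' NJ tree with bootstrap support values
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree
#' per pseudo-replicate, and reports for each internal edge of the
#' original tree the percentage of replicates containing the same
#' bipartition.  Supports are stored as internal node labels.
#'
#' @param aln Named AAStringSet (trimmed protein alignment).
#' @param n_replicates Number of pseudo-replicates (default 100).
#' @param correction Distance correction for [proteinDistance()].
#' @param seed Integer seed (reproducible supports).
#' @return \code{phylo} tree with \code{node.label} percentages; a
#'   degenerate alignment (all rows identical) returns the tree with
#'   an attribute \code{degenerate = TRUE} and no supports.
#' @export
bootstrapSupport <- function(aln, n_replicates = 100L,
                             correction = "poisson", seed = 1L) {
    if (n_replicates < 1L) stop("n_replicates must be >= 1")
    m <- do.call(rbind, strsplit(as.character(aln), ""))
    rownames(m) <- names(aln)
    build <- function(mm) {
        chr <- apply(mm, 1L, paste, collapse = "")
        a <- Biostrings::AAStringSet(setNames(chr, rownames(mm)))
        njTree(proteinDistance(a, correction))
    }
    if (max(proteinDistance(aln, "p")) == 0) {
        warning("all rows identical: no phylogenetic signal")
        tr <- ape::stree(nrow(m), tip.label = rownames(m))
        attr(tr, "degenerate") <- TRUE
        return(tr)
    }
    tr <- build(m)
    set.seed(seed)
    reps <- vector("list", n_replicates)
    for (b in seq_len(n_replicates)) {
        cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
        reps[[b]] <- tryCatch(build(m[, cols, drop = FALSE]),
                              error = function(e) NULL)
    }
    reps <- Filter(Negate(is.null), reps)
    cnt <- ape::prop.clades(tr, reps, rooted = FALSE)
    cnt[is.na(cnt)] <- 0
    tr$node.label <- round(100 * cnt / length(reps))
    tr
}

#' Clade-placement test for HGT support
#'
#' Walks up from the query leaf to its smallest enclosing clade that
#' contains at least one donor-group member.  The query's placement
#' is \code{hgt_supported} when that clade excludes every
#' recipient-group member and its support is at least
#' \code{min_support}; \code{native} when the smallest enclosing
#' clade containing a recipient member excludes all donor members;
#' \code{unresolved} otherwise.
#'
#' @param tree \code{phylo} with \code{node.label} support values
#'   (e.g. from [bootstrapSupport()]).
#' @param query_id Query leaf name.
#' @param donor_group,recipient_group Leaf-name vectors.
#' @param min_support Minimum clade support (default 75).
#' @return List with \code{verdict}, \code{clade_support} and
#'   \code{clade_members}.
#' @export
placementTest <- function(tree, query_id, donor_group,
                          recipient_group, min_support = 75) {
    if (!query_id %in% tree$tip.label) stop("query not in tree")
    ntip <- length(tree$tip.label)
    ## root the tree away from the groups if unrooted
    tr <- if (ape::is.rooted(tree)) tree else {
        out <- setdiff(tree$tip.label,
                       c(query_id, donor_group, recipient_group))
        if (length(out)) ape::root(tree, outgroup = out[1L],
                                   resolve.root = TRUE)
        else ape::root(tree, outgroup = donor_group[1L],
                       resolve.root = TRUE)
    }
    ntip <- length(tr$tip.label)
    node_support <- function(node) {
        if (is.null(tr$node.label)) return(NA_real_)
        v <- suppressWarnings(as.numeric(
            tr$node.label[node - ntip]))
        v
    }
    ## walk from the query tip upward
    node <- which(tr$tip.label == query_id)
    repeat {
        parent <- tr$edge[tr$edge[, 2L] == node, 1L]
        if (!length(parent)) break
        members <- ape::extract.clade(tr, parent)$tip.label
        has_donor <- any(donor_group %in% members)
        has_recip <- any(recipient_group %in% members)
        if (has_donor || has_recip) {
            sup <- node_support(parent)
            if (has_donor && !has_recip) {
                verdict <- if (!is.na(sup) && sup >= min_support)
                    "hgt_supported" else "unresolved"
                return(list(verdict = verdict, clade_support = sup,
                            clade_members = members))
            }
            if (has_recip && !has_donor)
                return(list(verdict = "native", clade_support = sup,
                            clade_members = members))
            return(list(verdict = "unresolved", clade_support = sup,
                        clade_members = members))
        }
        node <- parent
    }
    list(verdict = "unresolved", clade_support = NA_real_,
         clade_members = tr$tip.label)
}
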