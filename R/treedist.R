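# Non-trivial splits of a tree as a 0/1 membership matrix over a fixed tip
# order, canonicalized (the side not containing the first tip) and
# deduplicated (the two root edges of a rooted tree induce the same
# unrooted split).
splitsMatrix <- function(tree, tipOrder = tree$tip.label) {
    stopIfNotPhylo(tree)
    if (!setequal(tree$tip.label, tipOrder))
        stop("tipOrder must be a permutation of the tree's tips",
             call. = FALSE)
    n <- length(tipOrder)
    pp <- ape::prop.part(tree)
    labs <- attr(pp, "labels")
    rows <- list()
    for (cl in pp) {
        k <- length(cl)
        if (k < 2 || k > n - 2) next
        memb <- integer(n)
        memb[match(labs[cl], tipOrder)] <- 1L
        if (memb[1] == 1L) memb <- 1L - memb
        rows[[length(rows) + 1L]] <- memb
    }
    if (!length(rows)) return(matrix(0L, 0, n))
    m <- do.call(rbind, rows)
    unique(m)
}

checkSameLeaves <- function(t1, t2) {
    d1 <- setdiff(t1$tip.label, t2$tip.label)
    d2 <- setdiff(t2$tip.label, t1$tip.label)
    if (length(d1) || length(d2))
        stop(sprintf("trees have different leaf sets; only in first: %s; only in second: %s",
                     paste(d1, collapse = ", "), paste(d2, collapse = ", ")),
             call. = FALSE)
    invisible(TRUE)
}

#' Clustering information distance between two trees (bits)
#'
#' Information-based generalization of the Robinson-Foulds distance. Each
#' non-trivial split contributes the entropy of its bipartition; splits of
#' the two trees are matched one-to-one by an exact maximum-weight
#' assignment on their mutual clustering information (computed from the 2x2
#' leaf-membership table), and the distance is H(t1) + H(t2) minus twice the
#' matched information. Zero if and only if the (unrooted) topologies agree;
#' similar-but-unequal splits earn partial credit, unlike plain RF.
#'
#' @param t1,t2 trees (`phylo`) on identical leaf sets.
#' @return distance in bits (>= 0; small means congruent).
#' @export
clusteringInfoDistance <- function(t1, t2) {
    checkSameLeaves(t1, t2)
    ord <- t1$tip.label
    cpp_split_stat(splitsMatrix(t1, ord), splitsMatrix(t2, ord), 0L)
}

#' Nye branch-alignment similarity between two trees
#'
#' Each pair of splits A|A' and B|B' is scored by the best of the two
#' side-pairings of the Jaccard overlaps, `max(min(J(A,B), J(A',B')),
#' min(J(A,B'), J(A',B)))`; the splits are then matched one-to-one by an
#' exact maximum-weight assignment and the matched scores summed. Identical
#' topologies with k non-trivial splits score k (normalized: 1).
#'
#' @param t1,t2 trees (`phylo`) on identical leaf sets.
#' @param normalize divide by `max(#splits t1, #splits t2)` so the score
#'   lies between 0 and 1.
#' @return similarity score (large means congruent).
#' @export
nyeSimilarity <- function(t1, t2, normalize = FALSE) {
    checkSameLeaves(t1, t2)
    ord <- t1$tip.label
    A <- splitsMatrix(t1, ord); B <- splitsMatrix(t2, ord)
    raw <- cpp_split_stat(A, B, 1L)
    if (!normalize) return(raw)
    k <- max(nrow(A), nrow(B))
    if (k == 0) 1 else raw / k
}
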