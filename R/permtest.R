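#' Permutation congruence test with host-tip splitting
#'
#' Tests tree congruence with the clustering information distance or the Nye
#' similarity when several symbionts occupy one host. The host tree is
#' expanded with [splitHostTips()] (one zero-length tip per link) and the
#' observed statistic is computed between the expanded host tree and the
#' symbiont tree under the leaf correspondence `host_id/symbiont_id` <->
#' symbiont tip. The null distribution shuffles which symbiont tips map to
#' which hosts (permuting the symbiont column of the association link list),
#' which preserves both tree shapes and tests only the mapping; the expanded
#' host topology is unchanged by the shuffle, so only the correspondence is
#' recomputed. The p-value uses the +1-corrected estimator with ties counted
#' as extreme, oriented by the method (cid: small congruent; nye: large
#' congruent).
#'
#' @param host,symb rooted `phylo` trees with branch lengths.
#' @param assoc binary association matrix; each symbiont must map to exactly
#'   one host (marker-gene sequences come from a single metagenome) and at
#'   least 4 links are required for a meaningful null.
#' @param method `"cid"` or `"nye"`.
#' @param nPerm number of permutations (default 10000).
#' @param seed integer seed.
#' @return a [CongruenceResult-class].
#' @export
permutationCongruenceTest <- function(host, symb, assoc,
                                      method = c("cid", "nye"),
                                      nPerm = 10000, seed = NULL) {
    method <- match.arg(method)
    pr <- pruneToAssociation(host, symb, assoc)
    L <- sum(pr$assoc)
    if (L < 4)
        stop("need at least 4 links for a meaningful null", call. = FALSE)
    if (any(colSums(pr$assoc) != 1L))
        stop("each symbiont must map to exactly one host", call. = FALSE)
    expanded <- splitHostTips(pr$host, pr$assoc)
    links <- linksFromAssociation(pr$assoc)
    expLab <- paste0(links$host_id, "/", links$symbiont_id)
    if (!setequal(expanded$tip.label, expLab))
        stop("internal error: expanded tip labels do not match links")
    expanded$tip.label <-
        links$symbiont_id[match(expanded$tip.label, expLab)]
    ord <- colnames(pr$assoc)
    A <- splitsMatrix(expanded, ord)
    B <- splitsMatrix(pr$symb, ord)
    methodInt <- if (method == "cid") 0L else 1L
    res <- withSeed(seed, cpp_perm_test_splits(A, B, as.integer(nPerm),
                                               methodInt, method == "nye"))
    new("CongruenceResult", method = method, statistic = res$observed,
        pValue = permPValue(res$extreme, nPerm), nPerm = as.integer(nPerm),
        seed = seedOrNA(seed),
        orientation = if (method == "nye") "large" else "small",
        nLinks = as.integer(L))
}
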