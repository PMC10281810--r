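#' Procrustes residual m2 of a host-symbiont configuration
#'
#' Builds the link-expanded coordinate matrices (one host row and one
#' symbiont row per association link), centers both, and least-squares
#' superimposes the symbiont configuration onto the host configuration
#' (translation, orthogonal map -- rotations and reflections -- and
#' one-directional scaling, solved by singular value decomposition). The
#' residual sum of squares m2 >= 0 measures cophylogenetic incongruence:
#' small values mean congruence.
#'
#' @param hostCoords,symbCoords principal-coordinate matrices (from
#'   [pcoa()] of the patristic matrices), rows named by host/symbiont ids.
#'   Unequal axis counts are zero-padded to a common dimension.
#' @param assoc binary association matrix; every row and column must have at
#'   least one link (prune first) and the total link count must be >= 3.
#' @return the residual m2 (numeric scalar).
#' @export
pacoM2 <- function(hostCoords, symbCoords, assoc) {
    validateAssociation(assoc)
    L <- sum(assoc)
    if (L < 3) stop("need at least 3 links", call. = FALSE)
    missH <- setdiff(rownames(assoc), rownames(hostCoords))
    missS <- setdiff(colnames(assoc), rownames(symbCoords))
    if (length(missH) || length(missS))
        stop(sprintf("coordinates missing for: %s",
                     paste(c(missH, missS), collapse = ", ")), call. = FALSE)
    k <- max(ncol(hostCoords), ncol(symbCoords), 1L)
    pad <- function(m) cbind(m, matrix(0, nrow(m), k - ncol(m)))
    H0 <- pad(hostCoords); S0 <- pad(symbCoords)
    rownames(H0) <- rownames(hostCoords); rownames(S0) <- rownames(symbCoords)
    links <- linksFromAssociation(assoc)
    cpp_paco_m2(H0[links$host_id, , drop = FALSE],
                S0[links$symbiont_id, , drop = FALSE])
}

#' Procrustean cophylogeny (PACo-style) permutation test
#'
#' Converts both trees to patristic distance matrices, embeds them by
#' principal coordinates (negative axes truncated), computes the observed
#' Procrustes residual m2 on the link-expanded configurations, and compares
#' it with m2 under `nPerm` randomized associations generated by a
#' backtracking fill that conserves the row and column totals of the
#' association (the overall degree of interactions). The p-value uses the
#' +1-corrected estimator, counting permutations with m2 at most the
#' observed value (ties as extreme).
#'
#' @param host,symb rooted `phylo` trees with branch lengths.
#' @param assoc binary association matrix (host tips x symbiont tips);
#'   unlinked tips are pruned before testing.
#' @param nPerm number of permutations (default 10000).
#' @param seed integer seed for the permutation stream.
#' @param maxRestarts restart budget for each backtracking fill.
#' @return a [CongruenceResult-class] (`method = "paco"`, orientation
#'   "small").
#' @export
pacoTest <- function(host, symb, assoc, nPerm = 10000, seed = NULL,
                     maxRestarts = 1000) {
    pr <- pruneToAssociation(host, symb, assoc)
    L <- sum(pr$assoc)
    if (L < 3) stop("need at least 3 links", call. = FALSE)
    hc <- pcoa(patristicMatrix(pr$host))$points
    sc <- pcoa(patristicMatrix(pr$symb))$points
    obs <- pacoM2(hc, sc, pr$assoc)
    k <- max(ncol(hc), ncol(sc), 1L)
    pad <- function(m) cbind(m, matrix(0, nrow(m), k - ncol(m)))
    H0 <- pad(hc); S0 <- pad(sc)
    res <- withSeed(seed, cpp_paco_perm(H0, S0,
                                        as.integer(rowSums(pr$assoc)),
                                        as.integer(colSums(pr$assoc)),
                                        obs, as.integer(nPerm),
                                        as.integer(maxRestarts)))
    new("CongruenceResult", method = "paco", statistic = obs,
        pValue = permPValue(res$extreme, nPerm), nPerm = as.integer(nPerm),
        seed = seedOrNA(seed), orientation = "small", nLinks = as.integer(L))
}
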