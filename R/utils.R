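# internal helpers

#' @importFrom withr with_seed
withSeed <- function(seed, expr) {
    if (is.null(seed) || is.na(seed)) return(force(expr))
    withr::with_seed(as.integer(seed), expr)
}

seedOrNA <- function(seed) {
    if (is.null(seed)) NA_integer_ else as.integer(seed)
}

stopIfNotPhylo <- function(tree, arg = "tree") {
    if (!inherits(tree, "phylo"))
        stop(sprintf("'%s' must be a 'phylo' object", arg), call. = FALSE)
}

requireBranchLengths <- function(tree, arg = "tree") {
    stopIfNotPhylo(tree, arg)
    if (is.null(tree$edge.length) || anyNA(tree$edge.length))
        stop(sprintf("'%s' has missing branch lengths", arg), call. = FALSE)
}

# children lists indexed by node number (tips 1..n, internals n+1..)
nodeChildren <- function(tree) {
    n <- ape::Ntip(tree) + tree$Nnode
    ch <- vector("list", n)
    for (i in seq_len(nrow(tree$edge)))
        ch[[tree$edge[i, 1]]] <- c(ch[[tree$edge[i, 1]]], tree$edge[i, 2])
    ch
}

# permutation p-value with the +1 correction, ties counted as extreme
permPValue <- function(nExtreme, nPerm) {
    (1 + nExtreme) / (nPerm + 1)
}
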