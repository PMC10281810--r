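#' Read a rooted tree from Newick text or a file
#'
#' Thin, validating wrapper around [ape::read.tree()]. The tree must be
#' rooted with unique tip labels; branch lengths, when present, must be
#' non-negative (zero is allowed). Writing with [writeNewick()] and reading
#' back reproduces the tree up to whitespace.
#'
#' @param x path to a Newick file, or a Newick string (recognized by the
#'   presence of a parenthesis or terminating semicolon).
#' @return an object of class `phylo`.
#' @examples
#' tr <- readNewick("((A:1,B:1):1,C:2);")
#' patristicMatrix(tr)["A", "C"]  # 4
#' @export
readNewick <- function(x) {
    stopifnot(is.character(x), length(x) == 1L)
    isText <- grepl("[(;]", x)
    if (!isText && !file.exists(x))
        stop(sprintf("file not found: %s", x), call. = FALSE)
    tree <- tryCatch(
        suppressWarnings(
            if (isText) ape::read.tree(text = x) else ape::read.tree(x)),
        error = function(e) NULL)
    if (is.null(tree) || !inherits(tree, "phylo"))
        stop("Newick parse error: malformed tree (check parentheses and ';')",
             call. = FALSE)
    dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
    if (length(dup))
        stop(sprintf("Newick parse error: duplicate tip labels: %s",
                     paste(dup, collapse = ", ")), call. = FALSE)
    if (!is.null(tree$edge.length)) {
        neg <- which(tree$edge.length < 0)
        if (length(neg))
            stop(sprintf(
                "Newick parse error: negative branch length on edge to '%s'",
                nodeLabelFor(tree, tree$edge[neg[1], 2])), call. = FALSE)
    }
    tree
}

nodeLabelFor <- function(tree, node) {
    n <- ape::Ntip(tree)
    if (node <= n) tree$tip.label[node] else paste0("node#", node)
}

#' Write a tree as Newick
#'
#' Branch lengths are serialized with 10 significant digits so that a
#' write-read round trip is an identity for all practical purposes.
#'
#' @param tree a `phylo` object.
#' @param file optional output path; when missing the Newick string is
#'   returned.
#' @return the Newick string, invisibly when written to a file.
#' @export
writeNewick <- function(tree, file = NULL) {
    stopIfNotPhylo(tree)
    txt <- ape::write.tree(tree, digits = 10)
    if (is.null(file)) return(txt)
    writeLines(txt, file)
    invisible(txt)
}

#' Patristic (cophenetic) distance matrix
#'
#' Sum of branch lengths along the path between every pair of tips; the
#' standard distance input of the Procrustean congruence test.
#'
#' @param tree a `phylo` object with branch lengths on all edges.
#' @return a symmetric matrix with zero diagonal, dimnames = tip labels.
#' @export
patristicMatrix <- function(tree) {
    requireBranchLengths(tree)
    d <- ape::cophenetic.phylo(tree)
    d[tree$tip.label, tree$tip.label, drop = FALSE]
}
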