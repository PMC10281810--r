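#' Split host tips into one zero-length tip per symbiont link
#'
#' Split-based tree distances require a one-to-one leaf correspondence, but a
#' host commonly harbours several symbionts. Each host tip is therefore
#' replaced by a multifurcation of zero-branch-length tips, one per symbiont
#' linked to that host, named `host_id/symbiont_id`. Hosts with no links in
#' the association are pruned first. Two tips derived from the same host are
#' at patristic distance zero; the zero-length fan is kept as a
#' multifurcation rather than an arbitrary resolution so that no artificial
#' splits enter split-based metrics.
#'
#' @param host rooted host `phylo` with branch lengths.
#' @param assoc binary host x symbiont association matrix (dimnames
#'   required); rows must be host tip labels.
#' @return a `phylo` with exactly `sum(assoc)` tips.
#' @examples
#' h <- readNewick("((A:1,B:1):1,C:2);")
#' A <- associationFromLinks(data.frame(host_id = c("A", "A", "C"),
#'                                      symbiont_id = c("s1", "s2", "s3")))
#' tr <- splitHostTips(h, A)  # tips A/s1, A/s2, C/s3; B pruned
#' @export
splitHostTips <- function(host, assoc) {
    requireBranchLengths(host, "host")
    validateAssociation(assoc, requireLinks = FALSE)
    missing <- setdiff(rownames(assoc), host$tip.label)
    if (length(missing))
        stop(sprintf("association references unknown host tips: %s",
                     paste(missing, collapse = ", ")), call. = FALSE)
    assoc <- assoc[rowSums(assoc) > 0, , drop = FALSE]
    if (nrow(assoc) < 2)
        stop("need at least two linked hosts", call. = FALSE)
    pruned <- ape::keep.tip(host, rownames(assoc))
    txt <- ape::write.tree(pruned, digits = 10)
    for (h in pruned$tip.label) {
        symb <- colnames(assoc)[assoc[h, ] == 1L]
        newTips <- paste0(h, "/", symb)
        repl <- if (length(symb) == 1L) newTips else
            paste0("(", paste0(newTips, ":0", collapse = ","), ")")
        # a tip label occurs exactly once, preceded by '(' or ',' and
        # followed by ':' (branch lengths are required above)
        done <- FALSE
        for (pre in c("(", ",")) {
            pat <- paste0(pre, h, ":")
            if (grepl(pat, txt, fixed = TRUE)) {
                txt <- sub(pat, paste0(pre, repl, ":"), txt, fixed = TRUE)
                done <- TRUE
                break
            }
        }
        if (!done)
            stop(sprintf("could not locate host tip '%s' in Newick text", h),
                 call. = FALSE)
    }
    readNewick(txt)
}
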