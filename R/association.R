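#' Build a binary host x symbiont association matrix from a link list
#'
#' @param links data.frame with columns `host_id` and `symbiont_id` (one row
#'   per link), or a two-column character matrix.
#' @param hosts,symbionts optional orderings of the row/column ids; defaults
#'   to first appearance in the link list.
#' @return a binary matrix with hosts as rows, symbionts as columns.
#' @export
associationFromLinks <- function(links, hosts = NULL, symbionts = NULL) {
    links <- as.data.frame(links)
    if (ncol(links) < 2)
        stop("'links' needs columns host_id and symbiont_id", call. = FALSE)
    h <- as.character(links[[1]]); s <- as.character(links[[2]])
    if (is.null(hosts)) hosts <- unique(h)
    if (is.null(symbionts)) symbionts <- unique(s)
    if (!all(h %in% hosts) || !all(s %in% symbionts))
        stop("link ids missing from the supplied orderings", call. = FALSE)
    A <- matrix(0L, length(hosts), length(symbionts),
                dimnames = list(hosts, symbionts))
    A[cbind(h, s)] <- 1L
    A
}

#' Long-format links of an association matrix
#'
#' @param assoc binary association matrix with dimnames.
#' @return data.frame with columns `host_id`, `symbiont_id`, ordered by host
#'   then symbiont (deterministic).
#' @export
linksFromAssociation <- function(assoc) {
    validateAssociation(assoc)
    idx <- which(t(assoc) == 1L, arr.ind = TRUE)  # order by host, then symbiont
    data.frame(host_id = rownames(assoc)[idx[, 2]],
               symbiont_id = colnames(assoc)[idx[, 1]],
               stringsAsFactors = FALSE)
}

#' Read / write an association table (long TSV: host_id, symbiont_id)
#'
#' @param file TSV path with header columns `host_id` and `symbiont_id`.
#' @return `readAssociation`: a binary association matrix.
#' @export
readAssociation <- function(file) {
    tab <- read.delim(file, stringsAsFactors = FALSE)
    need <- c("host_id", "symbiont_id")
    if (!all(need %in% names(tab)))
        stop("association TSV must have columns host_id, symbiont_id",
             call. = FALSE)
    associationFromLinks(tab[, need])
}

#' @rdname readAssociation
#' @param assoc binary association matrix.
#' @export
writeAssociation <- function(assoc, file) {
    write.table(linksFromAssociation(assoc), file, sep = "\t",
                quote = FALSE, row.names = FALSE)
    invisible(file)
}

validateAssociation <- function(assoc, requireLinks = TRUE) {
    if (!is.matrix(assoc) || is.null(rownames(assoc)) ||
        is.null(colnames(assoc)))
        stop("association must be a matrix with host/symbiont dimnames",
             call. = FALSE)
    if (!all(assoc %in% c(0L, 1L)))
        stop("association must be binary", call. = FALSE)
    if (requireLinks) {
        if (any(rowSums(assoc) == 0))
            stop(sprintf("hosts without links: %s (prune first)",
                         paste(rownames(assoc)[rowSums(assoc) == 0],
                               collapse = ", ")), call. = FALSE)
        if (any(colSums(assoc) == 0))
            stop(sprintf("symbionts without links: %s (prune first)",
                         paste(colnames(assoc)[colSums(assoc) == 0],
                               collapse = ", ")), call. = FALSE)
    }
    invisible(TRUE)
}

# Restrict trees and association to their common ids, pruning hosts with no
# links for this symbiont set (and vice versa).
pruneToAssociation <- function(host, symb, assoc) {
    validateAssociation(assoc, requireLinks = FALSE)
    missingH <- setdiff(rownames(assoc), host$tip.label)
    if (length(missingH))
        stop(sprintf("association references unknown host tips: %s",
                     paste(missingH, collapse = ", ")), call. = FALSE)
    missingS <- setdiff(colnames(assoc), symb$tip.label)
    if (length(missingS))
        stop(sprintf("association references unknown symbiont tips: %s",
                     paste(missingS, collapse = ", ")), call. = FALSE)
    assoc <- assoc[rowSums(assoc) > 0, colSums(assoc) > 0, drop = FALSE]
    host <- ape::keep.tip(host, rownames(assoc))
    symb <- ape::keep.tip(symb, colnames(assoc))
    list(host = host, symb = symb,
         assoc = assoc[host$tip.label, symb$tip.label, drop = FALSE])
}
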