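#' Read tip metadata for habitat-specific clade extraction
#'
#' @param file TSV with columns `seq_id`, `host_species`, `environment`,
#'   `contig_id`, `marker_gene`.
#' @return a validated data.frame.
#' @export
readTipMetadata <- function(file) {
    meta <- read.delim(file, stringsAsFactors = FALSE)
    validateTipMetadata(meta)
    meta
}

validateTipMetadata <- function(meta) {
    need <- c("seq_id", "host_species", "environment", "contig_id",
              "marker_gene")
    miss <- setdiff(need, names(meta))
    if (length(miss))
        stop(sprintf("tip metadata missing columns: %s",
                     paste(miss, collapse = ", ")), call. = FALSE)
    bad <- setdiff(unique(meta$environment), c("termite_gut", "other"))
    if (length(bad))
        stop(sprintf("environment labels must be 'termite_gut' or 'other'; found: %s",
                     paste(bad, collapse = ", ")), call. = FALSE)
    for (m in unique(meta$marker_gene)) {
        ids <- meta$seq_id[meta$marker_gene == m]
        if (anyDuplicated(ids))
            stop(sprintf("duplicate seq_id within marker gene '%s'", m),
                 call. = FALSE)
    }
    invisible(TRUE)
}

#' Extract termite-specific clades (TSCs) from an annotated marker-gene tree
#'
#' A TSC is a maximal clade whose tips are all labelled with the focal
#' environment (termite gut) and that spans at least `minSpecies` distinct
#' host species. Maximality is enforced top-down: a clade is reported only
#' when no ancestor qualifies, so the returned clades are the whole
#' habitat-exclusive subtrees. Host species are counted as distinct host
#' species ids, not samples.
#'
#' @param tree rooted marker-gene `phylo`.
#' @param meta tip metadata data.frame (see [readTipMetadata()]); every tip
#'   of `tree` must appear in `meta$seq_id`.
#' @param minSpecies minimum number of distinct host species (inclusive,
#'   default 10).
#' @param environment the focal environment label.
#' @return list of [TSC-class] objects, in tree (preorder) traversal order
#'   with stable ids `TSC1`, `TSC2`, ...
#' @export
extractTscs <- function(tree, meta, minSpecies = 10,
                        environment = "termite_gut") {
    stopIfNotPhylo(tree)
    validateTipMetadata(meta)
    stopifnot(minSpecies >= 1)
    missing <- setdiff(tree$tip.label, meta$seq_id)
    if (length(missing))
        stop(sprintf("tips missing from metadata: %s",
                     paste(missing, collapse = ", ")), call. = FALSE)
    idx <- match(tree$tip.label, meta$seq_id)
    tipGut <- meta$environment[idx] == environment
    tipSpecies <- meta$host_species[idx]
    marker <- unique(meta$marker_gene[idx])
    marker <- if (length(marker) == 1L) marker else NA_character_

    nTip <- ape::Ntip(tree)
    ch <- nodeChildren(tree)
    nNode <- nTip + tree$Nnode
    gutOnly <- logical(nNode)
    speciesOf <- vector("list", nNode)
    postorder <- rev(unique(ape::reorder.phylo(tree, "cladewise")$edge[, 1]))
    gutOnly[seq_len(nTip)] <- tipGut
    for (i in seq_len(nTip)) speciesOf[[i]] <- tipSpecies[i]
    for (v in postorder) {
        kids <- ch[[v]]
        gutOnly[v] <- all(gutOnly[kids])
        speciesOf[[v]] <- unique(unlist(speciesOf[kids]))
    }
    qualifies <- function(v)
        gutOnly[v] && length(unique(speciesOf[[v]])) >= minSpecies

    tipsBelow <- function(v) {
        if (v <= nTip) return(v)
        unlist(lapply(ch[[v]], tipsBelow))
    }
    out <- list()
    visit <- function(v) {
        if (qualifies(v)) {
            tips <- tipsBelow(v)
            out[[length(out) + 1L]] <<- new(
                "TSC", id = paste0("TSC", length(out) + 1L),
                node = as.integer(v),
                members = tree$tip.label[tips],
                hostSpecies = sort(unique(tipSpecies[tips])),
                marker = marker)
            return(invisible())
        }
        if (v > nTip) for (k in ch[[v]]) visit(k)
    }
    visit(nTip + 1L)
    out
}

#' Match clades across marker genes via contig co-occurrence
#'
#' Two clades from different marker-gene trees describe the same organisms
#' when assembled contigs carry member sequences of both. Each other-marker
#' clade is assigned to the reference clade with the most supporting contigs;
#' a tie between reference clades leaves the clade unmatched with a conflict
#' flag.
#'
#' @param ref list of [TSC-class] from the reference marker tree.
#' @param other list of [TSC-class] from another marker tree.
#' @param metaRef,metaOther tip metadata for the two markers (contig ids
#'   must be populated).
#' @return data.frame with one row per other-marker clade: `other_tsc`,
#'   `ref_tsc` (NA when unmatched), `contigs` (supporting contig count) and
#'   `status` (`matched`, `conflict` or `unmatched`). The attribute
#'   `unmatched_ref` lists reference clades that attracted no match.
#' @export
matchTscs <- function(ref, other, metaRef, metaOther) {
    validateTipMetadata(metaRef)
    validateTipMetadata(metaOther)
    tscOfSeq <- function(tscs, meta) {
        m <- setNames(rep(NA_character_, nrow(meta)), meta$seq_id)
        for (t in tscs) m[t@members] <- t@id
        m
    }
    refOf <- tscOfSeq(ref, metaRef)
    othOf <- tscOfSeq(other, metaOther)
    refContig <- split(unname(refOf[metaRef$seq_id]), metaRef$contig_id)
    othContig <- split(unname(othOf[metaOther$seq_id]), metaOther$contig_id)
    votes <- list()
    for (ctg in intersect(names(refContig), names(othContig))) {
        rt <- unique(refContig[[ctg]]); rt <- rt[!is.na(rt)]
        ot <- unique(othContig[[ctg]]); ot <- ot[!is.na(ot)]
        for (r in rt) for (o in ot) {
            key <- paste(r, o, sep = "\r")
            votes[[key]] <- (votes[[key]] %||% 0L) + 1L
        }
    }
    othIds <- vapply(other, function(t) t@id, character(1))
    rows <- lapply(othIds, function(o) {
        keys <- if (length(votes))
            names(votes)[endsWith(names(votes), paste0("\r", o))]
        else character()
        if (!length(keys))
            return(data.frame(other_tsc = o, ref_tsc = NA_character_,
                              contigs = 0L, status = "unmatched",
                              stringsAsFactors = FALSE))
        cnt <- vapply(keys, function(k) votes[[k]], integer(1))
        best <- which(cnt == max(cnt))
        if (length(best) > 1L)
            return(data.frame(other_tsc = o, ref_tsc = NA_character_,
                              contigs = max(cnt), status = "conflict",
                              stringsAsFactors = FALSE))
        data.frame(other_tsc = o,
                   ref_tsc = sub("\r.*$", "", keys[best]),
                   contigs = max(cnt), status = "matched",
                   stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    refIds <- vapply(ref, function(t) t@id, character(1))
    attr(tab, "unmatched_ref") <- setdiff(refIds, tab$ref_tsc)
    tab
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a list of TSCs as JSON
#'
#' @param tscs list of [TSC-class].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeTscJson <- function(tscs, file) {
    jsonlite::write_json(lapply(tscs, function(t) list(
        id = t@id, marker = t@marker, size = length(t@members),
        members = t@members, host_species = t@hostSpecies)),
        file, auto_unbox = TRUE, pretty = TRUE)
    invisible(file)
}
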