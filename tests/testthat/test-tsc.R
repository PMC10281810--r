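# build a metadata table for a tree from per-tip species / environment
makeMeta <- function(tree, species, environment, contig = NA,
                     marker = "COG0552") {
    data.frame(seq_id = tree$tip.label, host_species = species,
               environment = environment,
               contig_id = if (all(is.na(contig)))
                   paste0("ctg_", seq_along(tree$tip.label)) else contig,
               marker_gene = marker, stringsAsFactors = FALSE)
}

# independent recursive scan: all maximal all-gut clades meeting the species
# threshold, found by plain depth-first search over the edge matrix
scanTscs <- function(tree, meta, minSpecies) {
    n <- ape::Ntip(tree)
    kids <- function(v) tree$edge[tree$edge[, 1] == v, 2]
    tipsOf <- function(v) if (v <= n) v else unlist(lapply(kids(v), tipsOf))
    info <- function(v) {
        tl <- tree$tip.label[tipsOf(v)]
        m <- meta[match(tl, meta$seq_id), ]
        list(ok = all(m$environment == "termite_gut") &&
                 length(unique(m$host_species)) >= minSpecies,
             members = tl)
    }
    out <- list()
    walk <- function(v) {
        i <- info(v)
        if (i$ok) { out[[length(out) + 1L]] <<- sort(i$members); return() }
        if (v > n) for (k in kids(v)) walk(k)
    }
    walk(n + 1L)
    out
}

test_that("a fully gut-exclusive tree is one TSC rooted at the root", {
    tr <- rtreeLabeled(15)
    meta <- makeMeta(tr, paste0("sp", rep(1:12, length.out = 15)),
                     "termite_gut")
    tscs <- extractTscs(tr, meta, minSpecies = 10)
    expect_length(tscs, 1)
    expect_setequal(tscMembers(tscs[[1]]), tr$tip.label)
    expect_equal(length(tscHostSpecies(tscs[[1]])), 12)
})

test_that("planted gut-only clades are recovered exactly", {
    # two gut-only clades of 11 and 13 species separated by environmental tips
    cladeA <- paste0("(", paste0("a", 1:13, ":1", collapse = ","), ")")
    cladeB <- paste0("(", paste0("b", 1:11, ":1", collapse = ","), ")")
    env <- paste0("(", paste0("e", 1:6, ":1", collapse = ","), ")")
    tr <- readNewick(paste0("((", cladeA, ":1,", env, ":1):1,",
                            cladeB, ":1);"))
    species <- c(paste0("spA", 1:13), paste0("spE", 1:6), paste0("spB", 1:11))
    environment <- rep(c("termite_gut", "other", "termite_gut"),
                       c(13, 6, 11))
    meta <- makeMeta(tr, species, environment)
    tscs <- extractTscs(tr, meta, minSpecies = 10)
    expect_length(tscs, 2)
    got <- lapply(tscs, function(t) sort(tscMembers(t)))
    expect_setequal(got, list(sort(paste0("a", 1:13)),
                              sort(paste0("b", 1:11))))
    expect_equal(got, scanTscs(tr, meta, 10), ignore_attr = TRUE)
})

test_that("clades below the species threshold are not reported", {
    tr <- rtreeLabeled(9)
    meta <- makeMeta(tr, paste0("sp", 1:9), "termite_gut")
    expect_length(extractTscs(tr, meta, minSpecies = 10), 0)
    expect_length(extractTscs(tr, meta, minSpecies = 9), 1)
})

test_that("extraction agrees with the recursive scan on random trees and is maximal", {
    set.seed(17)
    for (i in 1:100) {
        tr <- rtreeLabeled(sample(8:25, 1))
        n <- ape::Ntip(tr)
        meta <- makeMeta(tr, paste0("sp", sample(1:8, n, replace = TRUE)),
                         sample(c("termite_gut", "other"), n, replace = TRUE,
                                prob = c(.8, .2)))
        thr <- sample(2:5, 1)
        tscs <- extractTscs(tr, meta, minSpecies = thr)
        got <- lapply(tscs, function(t) sort(tscMembers(t)))
        expect_setequal(got, scanTscs(tr, meta, thr))
    }
})

test_that("raising the species threshold never adds TSCs", {
    set.seed(19)
    for (i in 1:100) {
        tr <- rtreeLabeled(sample(8:20, 1))
        n <- ape::Ntip(tr)
        meta <- makeMeta(tr, paste0("sp", sample(1:6, n, replace = TRUE)),
                         sample(c("termite_gut", "other"), n, replace = TRUE,
                                prob = c(.85, .15)))
        counts <- vapply(1:6, function(thr)
            length(extractTscs(tr, meta, minSpecies = thr)), integer(1))
        expect_true(all(diff(counts) <= 0))
    }
})

test_that("extraction is deterministic and validates its inputs", {
    tr <- rtreeLabeled(12)
    meta <- makeMeta(tr, paste0("sp", 1:12), "termite_gut")
    a <- extractTscs(tr, meta, minSpecies = 5)
    b <- extractTscs(tr, meta, minSpecies = 5)
    expect_identical(vapply(a, function(t) t@id, character(1)),
                     vapply(b, function(t) t@id, character(1)))
    expect_error(extractTscs(tr, meta[-1, ], minSpecies = 5),
                 "missing from metadata.*t1")
})

test_that("contig matching follows the majority rule with tie conflicts", {
    mkTsc <- function(id, members, marker)
        new("TSC", id = id, node = 1L, members = members,
            hostSpecies = "sp1", marker = marker)
    ref <- list(mkTsc("refTSC1", c("r1", "r2"), "mk1"),
                mkTsc("refTSC2", c("r3", "r4"), "mk1"))
    oth <- list(mkTsc("othTSC3", c("o1", "o2", "o3"), "mk2"),
                mkTsc("othTSC4", c("o4"), "mk2"))
    metaRef <- data.frame(seq_id = paste0("r", 1:4),
                          host_species = "sp1", environment = "termite_gut",
                          contig_id = c("c1", "c2", "c3", "c9"),
                          marker_gene = "mk1")
    metaOth <- data.frame(seq_id = paste0("o", 1:4),
                          host_species = "sp1", environment = "termite_gut",
                          contig_id = c("c1", "c2", "c3", "cX"),
                          marker_gene = "mk2")
    # c1, c2 vote refTSC1 <-> othTSC3; stray c3 votes refTSC2 <-> othTSC3
    tab <- matchTscs(ref, oth, metaRef, metaOth)
    row3 <- tab[tab$other_tsc == "othTSC3", ]
    expect_equal(row3$ref_tsc, "refTSC1")
    expect_equal(row3$contigs, 2L)
    expect_equal(row3$status, "matched")
    expect_equal(tab[tab$other_tsc == "othTSC4", "status"], "unmatched")

    # one contig to each of two reference TSCs: tie -> conflict
    metaOth2 <- metaOth
    metaOth2$contig_id <- c("c1", "c3", "cZ", "cX")
    tab2 <- matchTscs(ref, oth, metaRef, metaOth2)
    expect_equal(tab2[tab2$other_tsc == "othTSC3", "status"], "conflict")
    expect_true(is.na(tab2[tab2$other_tsc == "othTSC3", "ref_tsc"]))

    # disjoint contigs: everything unmatched
    metaOth3 <- metaOth
    metaOth3$contig_id <- paste0("zz", 1:4)
    tab3 <- matchTscs(ref, oth, metaRef, metaOth3)
    expect_true(all(tab3$status == "unmatched"))
    expect_setequal(attr(tab3, "unmatched_ref"), c("refTSC1", "refTSC2"))
})
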