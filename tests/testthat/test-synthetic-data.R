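test_that("host tree simulator returns conditioned ultrametric trees", {
    expect_equal(ape::Ntip(simulateHostTree(2, seed = 1)), 2L)
    tr <- simulateHostTree(50, birth = 1, death = 0, seed = 2)
    expect_equal(ape::Ntip(tr), 50L)
    expect_true(ape::is.ultrametric(tr))
    # fixed seed: byte-identical Newick
    expect_identical(writeNewick(simulateHostTree(20, seed = 9)),
                     writeNewick(simulateHostTree(20, seed = 9)))
    expect_error(simulateHostTree(10, birth = 1, death = 2),
                 "death rate")
    h1 <- simulateHostTree(10, seed = 3, height = 1)
    expect_equal(max(ape::node.depth.edgelength(h1)), 1, tolerance = 1e-12)
})

test_that("pure cospeciation reproduces the host tree exactly", {
    h <- simulateHostTree(12, seed = 5)
    sim <- simulateCophylogeny(h, cophyloParams(0, 0, 0, codivergence = 1,
                                                sampling = 1, seed = 6))
    expect_false(sim@empty)
    expect_equal(unname(eventCounts(sim)["switch"]), 0L)
    A <- association(sim)
    expect_true(all(rowSums(A) == 1) && all(colSums(A) == 1))
    s <- symbiontTree(sim)
    relabeled <- s
    relabeled$tip.label <- rownames(A)[apply(A[, s$tip.label], 2, which.max)]
    expect_equal(phangorn::RF.dist(ape::unroot(h), ape::unroot(relabeled)), 0)
    # branch lengths track host time exactly
    expect_equal(sort(patristicMatrix(relabeled)[h$tip.label, h$tip.label]),
                 sort(patristicMatrix(h)), tolerance = 1e-8,
                 ignore_attr = TRUE)
})

test_that("symbiont tips equal association links for every record", {
    set.seed(21)
    for (i in 1:40) {
        h <- simulateHostTree(sample(5:15, 1), seed = 100 + i, height = 1)
        sim <- simulateCophylogeny(h, cophyloParams(
            duplication = runif(1, 0, .4), loss = runif(1, 0, .4),
            hostSwitch = runif(1, 0, .4), codivergence = runif(1, .5, 1),
            sampling = runif(1, .5, 1), seed = 200 + i))
        if (sim@empty) next
        expect_equal(ape::Ntip(symbiontTree(sim)), sum(association(sim)))
        expect_true(all(colSums(association(sim)) == 1))
    }
})

test_that("event bookkeeping matches the genealogy's internal nodes", {
    set.seed(31)
    for (i in 1:25) {
        h <- simulateHostTree(sample(5:12, 1), seed = 300 + i, height = 1)
        sim <- simulateCophylogeny(h, cophyloParams(.3, .3, .3,
                                                    codivergence = .8,
                                                    sampling = 1,
                                                    seed = 400 + i))
        if (is.null(sim@genealogy)) next
        ev <- eventCounts(sim)
        expect_equal(sim@genealogy$Nnode,
                     unname(ev["codivergence"] + ev["duplication"] +
                                ev["switch"]))
    }
})

test_that("switch counts follow the Poisson expectation over lineage time", {
    h <- simulateHostTree(8, seed = 41, height = 1)
    tau <- 0.5
    nRep <- 400
    sims <- withr::with_seed(42, lapply(seq_len(nRep), function(i)
        simulateCophylogeny(h, cophyloParams(0, 0, tau, codivergence = .9,
                                             sampling = 1))))
    switches <- sum(vapply(sims, function(s) eventCounts(s)[["switch"]],
                           numeric(1)))
    expected <- tau * sum(vapply(sims, function(s) s@lineageTime, numeric(1)))
    se <- sqrt(expected)  # Poisson
    expect_lt(abs(switches - expected), 3 * se)
})

test_that("sampling dropout thins extant tips binomially", {
    h <- simulateHostTree(10, seed = 51, height = 1)
    nFull <- 0; nHalf <- 0
    for (i in 1:200) {
        p1 <- cophyloParams(0.2, 0, 0, codivergence = 1, sampling = 1,
                            seed = 1000 + i)
        p2 <- cophyloParams(0.2, 0, 0, codivergence = 1, sampling = 0.5,
                            seed = 1000 + i)
        s1 <- simulateCophylogeny(h, p1)   # same seed: identical genealogy
        s2 <- simulateCophylogeny(h, p2)
        nFull <- nFull + sum(association(s1))
        nHalf <- nHalf + if (s2@empty) 0 else sum(association(s2))
    }
    se <- sqrt(nFull * 0.5 * 0.5)
    expect_lt(abs(nHalf - 0.5 * nFull), 4 * se)
})

test_that("all-extinct simulations come back flagged, not as errors", {
    h <- simulateHostTree(5, seed = 61, height = 1)
    sim <- simulateCophylogeny(h, cophyloParams(0, 50, 0, codivergence = 1,
                                                sampling = 1, seed = 62))
    expect_true(sim@empty)
    expect_null(symbiontTree(sim))
})

test_that("perturbTree is the identity at zero noise and preserves leaves", {
    tr <- rtreeLabeled(12)
    expect_identical(writeNewick(perturbTree(tr, 0, 0)), writeNewick(tr))
    set.seed(71)
    for (i in 1:20) {
        out <- perturbTree(tr, nNni = sample(0:4, 1),
                           blSigma = runif(1, 0, .5))
        expect_setequal(out$tip.label, tr$tip.label)
        expect_true(all(out$edge.length >= 0))
    }
    expect_error(perturbTree(readNewick("(A:1,B:1);"), nNni = 1),
                 "no internal edges")
})

test_that("a single NNI changes at most one split", {
    set.seed(81)
    for (i in 1:40) {
        tr <- rtreeLabeled(sample(5:15, 1))
        out <- perturbTree(tr, nNni = 1, blSigma = 0)
        expect_true(phangorn::RF.dist(ape::unroot(tr), ape::unroot(out))
                    %in% c(0, 2))
    }
})

test_that("baseline replicates share the true history up to noise", {
    tr <- rtreeLabeled(10)
    same <- makeBaselineReplicates(tr, k = 15, nNni = 0, blSigma = 0,
                                   seed = 1)
    expect_length(same, 15)
    for (g in same) expect_identical(writeNewick(g), writeNewick(tr))
    noisy <- makeBaselineReplicates(tr, k = 15, nNni = 2, blSigma = 0.1,
                                    seed = 2)
    for (g in noisy)
        expect_lte(phangorn::RF.dist(ape::unroot(tr), ape::unroot(g)), 4)
    again <- makeBaselineReplicates(tr, k = 15, nNni = 2, blSigma = 0.1,
                                    seed = 2)
    expect_identical(vapply(noisy, writeNewick, character(1)),
                     vapply(again, writeNewick, character(1)))
})

test_that("simulation records serialize to disk", {
    h <- simulateHostTree(8, seed = 91, height = 1)
    sim <- simulateCophylogeny(h, cophyloParams(.1, .1, .1, seed = 92))
    d <- file.path(tempdir(), "simrec")
    writeSimulation(sim, d)
    expect_true(file.exists(file.path(d, "host.nwk")))
    expect_true(file.exists(file.path(d, "truth.json")))
    if (!sim@empty) {
        expect_true(file.exists(file.path(d, "association.tsv")))
        A <- readAssociation(file.path(d, "association.tsv"))
        expect_equal(sum(A), sum(association(sim)))
    }
})
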