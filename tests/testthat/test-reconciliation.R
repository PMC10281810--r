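test_that("a congruent gene tree reconciles at zero cost with speciations only", {
    sp <- rtreeLabeled(8, "S")
    lm <- setNames(sp$tip.label, sp$tip.label)
    out <- reconcileMP(sp, sp, lm, costs = c(dup = 2.3, transfer = 4.1,
                                             loss = 0.7))
    expect_equal(out$cost, 0)
    expect_equal(unname(out$events["speciation"]), 7L)
    expect_equal(sum(out$events[c("duplication", "transfer", "loss")]), 0L)
})

test_that("the worked 3-leaf transfer example matches exhaustive enumeration", {
    sp <- readNewick("((A:1,B:1):1,C:2);")
    gn <- readNewick("((a:1,c:1):1,b:2);")
    lm <- c(a = "A", b = "B", c = "C")
    costs <- c(dup = 2, transfer = 3, loss = 1)
    dp <- reconcileMP(sp, gn, lm, costs)
    expect_equal(dp$cost, oracleReconcileMP(sp, gn, lm, costs))
})

test_that("the DTL likelihood is a log probability with model symmetries", {
    sp <- readNewick("((A:1,B:1):1,(C:1,D:1):1);")
    gn <- readNewick("((a:1,b:1):1,(c:1,d:1):1);")
    lm <- c(a = "A", b = "B", c = "C", d = "D")
    ll <- dtlLikelihood(sp, gn, lm, c(.1, .1, .1))
    expect_lt(ll, 0)
    # consistent relabeling of species leaves leaves the likelihood alone
    sp2 <- sp; sp2$tip.label <- paste0(sp$tip.label, "_x")
    lm2 <- setNames(paste0(lm, "_x"), names(lm))
    expect_equal(dtlLikelihood(sp2, gn, lm2, c(.1, .1, .1)), ll,
                 tolerance = 1e-12)
})

test_that("the likelihood matches truncated event-history enumeration", {
    cases <- list(
        list(sp = "(A:1,B:1);", gn = "(a:1,b:1);", lm = c(a = "A", b = "B")),
        list(sp = "(A:1,B:1);", gn = "(a1:1,a2:1);",
             lm = c(a1 = "A", a2 = "A")),
        list(sp = "((A:1,B:1):1,C:2);", gn = "((a:1,c:1):1,b:2);",
             lm = c(a = "A", b = "B", c = "C")))
    for (cs in cases) {
        sp <- readNewick(cs$sp); gn <- readNewick(cs$gn)
        rates <- c(.01, .01, .01)
        full <- exp(dtlLikelihood(sp, gn, cs$lm, rates))
        tr <- oracleDtlTruncated(sp, gn, cs$lm, rates, kmax = 3)
        # the enumeration misses histories with > kmax extra events; its
        # shells shrink geometrically, bounding the truncation remainder
        ratio <- tr$byShell[4] / max(tr$byShell[3], 1e-300)
        bound <- tr$lastShell * ratio / max(1 - ratio, 0.5)
        expect_lt(abs(full - tr$likelihood), 1e-6)
        expect_lt(bound, 1e-6)
    }
})

test_that("raising the loss rate penalizes a lossless congruent history", {
    sp <- readNewick("((A:1,B:1):1,(C:1,D:1):1);")
    gn <- readNewick("((a:1,b:1):1,(c:1,d:1):1);")
    lm <- c(a = "A", b = "B", c = "C", d = "D")
    lls <- vapply(c(0.01, 0.1, 0.5), function(l)
        dtlLikelihood(sp, gn, lm, c(0.01, 0.01, l)), numeric(1))
    expect_true(all(diff(lls) < 0))
})

test_that("rate estimation is deterministic and noise raises apparent transfer", {
    sp <- simulateHostTree(15, seed = 83, height = 1)
    lm <- setNames(sp$tip.label, sp$tip.label)
    a <- estimateRatesML(sp, sp, lm, seed = 4)
    b <- estimateRatesML(sp, sp, lm, seed = 4)
    expect_identical(dtlRates(a), dtlRates(b))
    expect_lte(logLik(a), 0)
    wins <- 0L
    for (i in 1:50) {
        noisy <- perturbTree(sp, nNni = 3, blSigma = 0, seed = 900 + i)
        tClean <- transferRate(estimateRatesML(sp, sp, lm, seed = i,
                                               nRestarts = 2))
        tNoisy <- transferRate(estimateRatesML(sp, noisy, lm, seed = i,
                                               nRestarts = 2))
        if (tClean <= tNoisy + 1e-12) wins <- wins + 1L
    }
    expect_gte(wins, 45L)
})

test_that("the ML event assignment agrees with parsimony in the low-rate limit", {
    # map the fitted event probabilities to parsimony costs
    # (-log odds against speciation) and compare event multisets
    mlCosts <- function(fit) {
        r <- dtlRates(fit)
        r <- pmax(r, 1e-4)
        c(dup = log(1 / r[["duplication"]]),
          transfer = log(1 / r[["transfer"]]),
          loss = log(1 / r[["loss"]]))
    }
    sp <- rtreeLabeled(6, "S")
    lm <- setNames(sp$tip.label, sp$tip.label)
    fit <- estimateRatesML(sp, sp, lm, seed = 1)
    expect_equal(reconcileMP(sp, sp, lm, mlCosts(fit))$events,
                 reconcileMP(sp, sp, lm)$events)
    # single-transfer fixture: congruent backbone plus one transferred copy
    sp2 <- readNewick("((A:1,B:1):1,(C:1,D:1):1);")
    gn2 <- readNewick("(((a:1,cx:1):1,b:2):1,(c:1,d:1):2);")
    lm2 <- c(a = "A", b = "B", c = "C", d = "D", cx = "C")
    fit2 <- estimateRatesML(sp2, gn2, lm2, seed = 2)
    expect_equal(reconcileMP(sp2, gn2, lm2, mlCosts(fit2))$events,
                 reconcileMP(sp2, gn2, lm2)$events)
})

test_that("baselines summarize replicate rates and classify boundaries", {
    sp <- simulateHostTree(12, seed = 87, height = 1)
    same <- makeBaselineReplicates(sp, k = 3, nNni = 0, blSigma = 0, seed = 1)
    b0 <- computeBaseline(sp, same, seed = 5, nRestarts = 2)
    expect_equal(baselineMin(b0), baselineMax(b0), tolerance = 1e-9)
    expect_lt(baselineMax(b0), 1e-4)   # at the lower optimization bound
    noisy <- makeBaselineReplicates(sp, k = 4, nNni = 2, blSigma = 0.1,
                                    seed = 2)
    b1 <- computeBaseline(sp, noisy, seed = 6, nRestarts = 2)
    expect_length(replicateRates(b1), 4)
    expect_gte(baselineMax(b1), baselineMin(b1))
    expect_gte(baselineMin(b1), 0)

    expect_equal(classifyTsc(baselineMax(b1), b1), "vertical_dominant")
    expect_equal(classifyTsc(baselineMax(b1) + 1e-9, b1),
                 "transfer_elevated")
    expect_equal(classifyTsc(0, b1), "vertical_dominant")
    expect_error(classifyTsc(-0.1, b1), "non-negative")
})

test_that("stronger reconstruction noise widens the baseline", {
    sp <- simulateHostTree(12, seed = 89, height = 1)
    wins <- 0L
    for (i in 1:20) {
        soft <- computeBaseline(sp, makeBaselineReplicates(
            sp, k = 4, nNni = 1, blSigma = 0.05, seed = 30 + i),
            seed = i, nRestarts = 2)
        hard <- computeBaseline(sp, makeBaselineReplicates(
            sp, k = 4, nNni = 4, blSigma = 0.05, seed = 60 + i),
            seed = i, nRestarts = 2)
        if (baselineMax(hard) >= baselineMax(soft) - 1e-12) wins <- wins + 1L
    }
    expect_gte(wins, 16L)
})
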