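test_that("pcoa reproduces Euclidean-embeddable distances", {
    d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3)  # right triangle
    out <- pcoa(d)
    expect_equal(as.matrix(dist(out$points)), d, ignore_attr = TRUE,
                 tolerance = 1e-9)
    expect_equal(out$negative, 0)
})

test_that("pcoa orders eigenvalues and validates its input", {
    tr <- rtreeLabeled(10)
    out <- pcoa(patristicMatrix(tr))
    expect_true(all(diff(out$eigenvalues) <= 1e-9))
    bad <- matrix(c(0, 1, 2, 0), 2)
    expect_error(pcoa(bad), "symmetric")
    expect_error(pcoa(matrix(c(1, 0, 0, 1), 2)), "zero diagonal")
})

test_that("non-Euclidean input yields negative eigenvalues that are dropped", {
    # 4-cycle graph distances: b and d would both need to sit at the
    # midpoint of the a-c segment, so no Euclidean embedding exists
    d <- matrix(c(0, 1, 2, 1,
                  1, 0, 1, 2,
                  2, 1, 0, 1,
                  1, 2, 1, 0), 4)
    # independent witness of the negative spectrum: a centered direction
    # with a negative quadratic form on the Gower matrix
    n <- 4; J <- diag(n) - 1 / n
    B <- -0.5 * J %*% (d * d) %*% J
    v <- c(1, -1, 1, -1)
    expect_lt(drop(t(v) %*% B %*% v), -1e-9)
    out <- pcoa(d)
    expect_gte(out$negative, 1)
    expect_true(min(out$eigenvalues) < 0)
    expect_lt(ncol(out$points), n - 1)
})

test_that("m2 vanishes for identical and rigidly transformed configurations", {
    set.seed(23)
    for (k in c(2, 3, 5)) {
        X <- matrix(rnorm(8 * k), 8)
        rownames(X) <- paste0("H", 1:8)
        A <- diag(8); dimnames(A) <- list(paste0("H", 1:8), paste0("H", 1:8))
        expect_lt(pacoM2(X, X, A), 1e-9)
        # random rotation/reflection + scale + translation
        Q <- qr.Q(qr(matrix(rnorm(k * k), k)))
        if (runif(1) < .5) Q[, 1] <- -Q[, 1]
        Y <- 2.7 * X %*% Q + matrix(rnorm(k), 8, k, byrow = TRUE)
        rownames(Y) <- rownames(X)
        expect_lt(pacoM2(X, Y, A), 1e-9)
    }
})

test_that("m2 equals a direct numerical rotation optimization", {
    set.seed(29)
    for (i in 1:20) {
        L <- sample(5:9, 1)
        H <- matrix(rnorm(L * 2), L); S <- matrix(rnorm(L * 2), L)
        rownames(H) <- paste0("H", 1:L); rownames(S) <- paste0("s", 1:L)
        A <- diag(L); dimnames(A) <- list(rownames(H), rownames(S))
        expect_equal(pacoM2(H, S, A), oracleM2Planar(H, S),
                     tolerance = 1e-6)
    }
})

test_that("m2 agrees with an independent Procrustes implementation", {
    set.seed(31)
    for (i in 1:10) {
        L <- 8; k <- sample(2:4, 1)
        H <- matrix(rnorm(L * k), L); S <- matrix(rnorm(L * k), L)
        rownames(H) <- paste0("H", 1:L); rownames(S) <- paste0("s", 1:L)
        A <- diag(L); dimnames(A) <- list(rownames(H), rownames(S))
        ref <- vegan::procrustes(scale(H, scale = FALSE),
                                 scale(S, scale = FALSE), symmetric = FALSE)
        expect_equal(pacoM2(H, S, A), ref$ss, tolerance = 1e-8)
    }
})

test_that("m2 is invariant to rigid motions and to rescaling the symbionts", {
    set.seed(37)
    L <- 9; k <- 3
    H <- matrix(rnorm(L * k), L); S <- matrix(rnorm(L * k), L)
    rownames(H) <- paste0("H", 1:L); rownames(S) <- paste0("s", 1:L)
    A <- diag(L); dimnames(A) <- list(rownames(H), rownames(S))
    base <- pacoM2(H, S, A)
    Q <- qr.Q(qr(matrix(rnorm(k * k), k)))
    S2 <- 5.1 * S %*% Q + matrix(rnorm(k), L, k, byrow = TRUE)
    rownames(S2) <- rownames(S)
    expect_equal(pacoM2(H, S2, A), base, tolerance = 1e-8)
    H2 <- H %*% Q + matrix(rnorm(k), L, k, byrow = TRUE)
    rownames(H2) <- rownames(H)
    expect_equal(pacoM2(H2, S, A), base, tolerance = 1e-8)
})

test_that("pacoM2 validates associations and link counts", {
    H <- matrix(rnorm(6), 3, dimnames = list(paste0("H", 1:3), NULL))
    S <- matrix(rnorm(6), 3, dimnames = list(paste0("s", 1:3), NULL))
    A <- diag(3); dimnames(A) <- list(rownames(H), rownames(S))
    A0 <- A; A0[2, ] <- 0
    expect_error(pacoM2(H, S, A0), "without links")
    expect_error(pacoM2(H[1:2, ], S[1:2, ], A[1:2, 1:2]), "at least 3 links")
})

test_that("pacoTest respects the permutation p-value floor and determinism", {
    h <- simulateHostTree(8, seed = 43)
    sim <- simulateCophylogeny(h, cophyloParams(0, 0, 0, codivergence = 1,
                                                sampling = 1, seed = 44))
    r1 <- pacoTest(h, symbiontTree(sim), association(sim), nPerm = 99,
                   seed = 7)
    expect_gte(pValue(r1), 1 / 100)
    r2 <- pacoTest(h, symbiontTree(sim), association(sim), nPerm = 99,
                   seed = 7)
    expect_identical(pValue(r1), pValue(r2))
    expect_equal(orientation(r1), "small")
})
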