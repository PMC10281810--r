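# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (no splitsMatrix, no Hungarian solver, no DP): patristic
# distances by explicit path walking, split statistics by exhaustive
# assignment enumeration, parsimony reconciliation by enumerating all
# placements of the internal gene nodes, and the undated DTL likelihood by
# summing event histories in order of their exact non-speciation event count.

rtreeLabeled <- function(n, prefix = "t") {
    tr <- ape::rtree(n)
    tr$tip.label <- paste0(prefix, seq_len(n))
    tr
}

# ---- patristic distances by path walking ----------------------------------

oraclePatristic <- function(tree) {
    n <- ape::Ntip(tree)
    N <- n + tree$Nnode
    parent <- integer(N); parent[tree$edge[, 2]] <- tree$edge[, 1]
    elen <- numeric(N);   elen[tree$edge[, 2]] <- tree$edge.length
    pathToRoot <- function(v) {
        p <- v
        while (parent[v] != 0L) { v <- parent[v]; p <- c(p, v) }
        p
    }
    D <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
    for (i in seq_len(n)) for (j in seq_len(n)) if (i < j) {
        pi <- pathToRoot(i); pj <- pathToRoot(j)
        common <- intersect(pi, pj)
        mrca <- common[which.min(match(common, pi))]
        di <- sum(elen[pi[seq_len(match(mrca, pi)) - 1]])
        dj <- sum(elen[pj[seq_len(match(mrca, pj)) - 1]])
        D[i, j] <- D[j, i] <- di + dj
    }
    D
}

# ---- split statistics by exhaustive matching ------------------------------

# non-trivial splits as logical membership over 'ord', canonicalized to the
# side not containing ord[1], collected by explicit descent through the edge
# matrix (no prop.part)
oracleSplits <- function(tree, ord = tree$tip.label) {
    n <- length(ord)
    tipsBelow <- function(v) {
        if (v <= ape::Ntip(tree)) return(tree$tip.label[v])
        unlist(lapply(tree$edge[tree$edge[, 1] == v, 2], tipsBelow))
    }
    internal <- setdiff(unique(tree$edge[, 2]), seq_len(ape::Ntip(tree)))
    rows <- list()
    for (v in internal) {
        memb <- ord %in% tipsBelow(v)
        k <- sum(memb)
        if (k < 2 || k > n - 2) next
        if (memb[1]) memb <- !memb
        rows[[length(rows) + 1L]] <- memb
    }
    if (!length(rows)) return(matrix(FALSE, 0, n))
    unique(do.call(rbind, rows))
}

bruteAssignMax <- function(W) {
    nr <- nrow(W); nc <- ncol(W)
    if (nr == 0 || nc == 0) return(0)
    rec <- function(r, used) {
        if (r > nr) return(0)
        best <- rec(r + 1L, used)     # row r left unmatched
        for (cc in seq_len(nc)) if (!used[cc]) {
            used[cc] <- TRUE
            best <- max(best, W[r, cc] + rec(r + 1L, used))
            used[cc] <- FALSE
        }
        best
    }
    rec(1L, logical(nc))
}

oracleEntropy <- function(a, n) {
    p <- a / n
    f <- function(x) ifelse(x > 0, x * log2(x), 0)
    -f(p) - f(1 - p)
}

oracleMutualInfo <- function(a, b) {
    n <- length(a)
    mi <- 0
    for (va in c(TRUE, FALSE)) for (vb in c(TRUE, FALSE)) {
        nij <- sum(a == va & b == vb)
        if (nij == 0) next
        mi <- mi + (nij / n) * log2(nij * n / (sum(a == va) * sum(b == vb)))
    }
    mi
}

oracleNyePair <- function(a, b) {
    jac <- function(x, y) {
        u <- sum(x | y)
        if (u == 0) 0 else sum(x & y) / u
    }
    max(min(jac(a, b), jac(!a, !b)), min(jac(a, !b), jac(!a, b)))
}

oracleSplitStat <- function(t1, t2, method = c("cid", "nye")) {
    method <- match.arg(method)
    ord <- t1$tip.label
    A <- oracleSplits(t1, ord); B <- oracleSplits(t2, ord)
    k1 <- nrow(A); k2 <- nrow(B)
    W <- matrix(0, k1, k2)
    for (r in seq_len(k1)) for (q in seq_len(k2))
        W[r, q] <- if (method == "cid") oracleMutualInfo(A[r, ], B[q, ])
                   else oracleNyePair(A[r, ], B[q, ])
    matched <- bruteAssignMax(W)
    if (method == "nye") return(matched)
    n <- length(ord)
    H1 <- sum(vapply(seq_len(k1), function(r) oracleEntropy(sum(A[r, ]), n),
                     numeric(1)))
    H2 <- sum(vapply(seq_len(k2), function(q) oracleEntropy(sum(B[q, ]), n),
                     numeric(1)))
    max(H1 + H2 - 2 * matched, 0)
}

# ---- parsimony DTL by placement enumeration -------------------------------

# flat arrays shared by the reconciliation oracles
oracleArrays <- function(tree) {
    n <- ape::Ntip(tree); N <- n + tree$Nnode
    parent <- integer(N); parent[tree$edge[, 2]] <- tree$edge[, 1]
    kids <- vector("list", N)
    for (i in seq_len(nrow(tree$edge)))
        kids[[tree$edge[i, 1]]] <- c(kids[[tree$edge[i, 1]]],
                                     tree$edge[i, 2])
    depth <- integer(N)
    order <- c(n + 1L)
    while (length(order)) {
        v <- order[1]; order <- order[-1]
        for (k in kids[[v]]) { depth[k] <- depth[v] + 1L; order <- c(order, k) }
    }
    anc <- lapply(seq_len(N), function(v) {
        p <- integer(); a <- parent[v]
        while (a != 0L) { p <- c(p, a); a <- parent[a] }
        p
    })
    isDesc <- matrix(FALSE, N, N)   # isDesc[x, y]: y inside subtree of x
    for (y in seq_len(N)) { isDesc[y, y] <- TRUE; isDesc[anc[[y]], y] <- TRUE }
    list(n = n, N = N, parent = parent, kids = kids, depth = depth,
         anc = anc, isDesc = isDesc, labels = tree$tip.label)
}

oracleReconcileMP <- function(species, gene, leafMap,
                              costs = c(dup = 2, transfer = 3, loss = 1)) {
    sA <- oracleArrays(species); gA <- oracleArrays(gene)
    D <- costs[["dup"]]; TT <- costs[["transfer"]]; LL <- costs[["loss"]]
    S <- sA$N
    # cost of descending (with losses) from branch p to branch x
    descC <- matrix(Inf, S, S)
    for (p in seq_len(S)) for (x in seq_len(S))
        if (sA$isDesc[p, x]) descC[p, x] <- LL * (sA$depth[x] - sA$depth[p])
    # best transfer arrival: min over recipients r (not ancestral to p,
    # not p) of descC[r, x]
    tmin <- matrix(Inf, S, S)
    for (p in seq_len(S)) {
        allowed <- setdiff(seq_len(S), c(p, sA$anc[[p]]))
        for (x in seq_len(S))
            if (length(allowed)) tmin[p, x] <- min(descC[allowed, x])
    }
    nodeCost <- function(p, a, b) {
        v <- D + descC[p, a] + descC[p, b]
        kidsP <- sA$kids[[p]]
        if (length(kidsP) == 2) {
            f <- kidsP[1]; g <- kidsP[2]
            v <- min(v, descC[f, a] + descC[g, b], descC[g, a] + descC[f, b])
        }
        min(v, TT + descC[p, a] + tmin[p, b], TT + descC[p, b] + tmin[p, a])
    }
    gInternal <- which(vapply(seq_len(gA$N),
                              function(v) length(gA$kids[[v]]) == 2,
                              logical(1)))
    place <- integer(gA$N)
    for (i in seq_len(gA$n))
        place[i] <- match(leafMap[[gA$labels[i]]], sA$labels)
    grid <- as.matrix(do.call(expand.grid,
                              rep(list(seq_len(S)), length(gInternal))))
    best <- Inf
    for (r in seq_len(nrow(grid))) {
        place[gInternal] <- grid[r, ]
        total <- 0
        for (u in gInternal) {
            ab <- gA$kids[[u]]
            total <- total + nodeCost(place[u], place[ab[1]], place[ab[2]])
            if (total >= best) break
        }
        if (total < best) best <- total
    }
    best
}

# ---- undated DTL likelihood by truncated event-history enumeration -------

# Sums the probabilities of all event histories with exactly k
# non-speciation events (duplication, transfer or loss draws), k = 0..kmax,
# by convolution recursions memoized on (node, branch, k). Returns the
# truncated likelihood and the k = kmax shell (to bound the remainder).
oracleDtlTruncated <- function(species, gene, leafMap, rates, kmax = 4) {
    sA <- oracleArrays(species); gA <- oracleArrays(gene)
    S <- sA$N
    delta <- rates[1]; tau <- rates[2]; lambda <- rates[3]
    q <- 1 + delta + tau + lambda
    pS <- 1 / q; pD <- delta / q; pT <- tau / q; pL <- lambda / q
    recip <- lapply(seq_len(S), function(e)
        setdiff(seq_len(S), c(e, sA$anc[[e]])))
    placeOfLeaf <- integer(gA$N)
    for (i in seq_len(gA$n))
        placeOfLeaf[i] <- match(leafMap[[gA$labels[i]]], sA$labels)

    Ememo <- new.env(parent = emptyenv())
    Pmemo <- new.env(parent = emptyenv())
    Eex <- function(e, k) {
        if (k < 1) return(0)
        key <- paste(e, k)
        if (!is.null(Ememo[[key]])) return(Ememo[[key]])
        v <- if (k == 1) pL else 0
        kidsE <- sA$kids[[e]]
        if (length(kidsE) == 2 && k >= 2) {
            f <- kidsE[1]; g <- kidsE[2]
            for (i in 1:(k - 1)) v <- v + pS * Eex(f, i) * Eex(g, k - i)
        }
        if (k >= 3)   # D/T need the event plus >= 1 loss on each copy
            for (i in 1:(k - 2)) {
                v <- v + pD * Eex(e, i) * Eex(e, k - 1 - i)
                rr <- recip[[e]]
                if (length(rr))
                    v <- v + pT * Eex(e, i) *
                        mean(vapply(rr, function(h) Eex(h, k - 1 - i),
                                    numeric(1)))
            }
        Ememo[[key]] <- v
        v
    }
    Pex <- function(u, e, k) {
        if (k < 0) return(0)
        key <- paste(u, e, k)
        if (!is.null(Pmemo[[key]])) return(Pmemo[[key]])
        v <- 0
        uKids <- gA$kids[[u]]
        eKids <- sA$kids[[e]]
        isGLeaf <- length(uKids) == 0
        if (isGLeaf && length(eKids) == 0 && placeOfLeaf[u] == e && k == 0)
            v <- v + pS
        if (length(eKids) == 2) {
            f <- eKids[1]; g <- eKids[2]
            if (!isGLeaf) {
                a <- uKids[1]; b <- uKids[2]
                for (i in 0:k)
                    v <- v + pS * (Pex(a, f, i) * Pex(b, g, k - i) +
                                   Pex(a, g, i) * Pex(b, f, k - i))
            }
            # speciation-loss
            if (k >= 1)
                for (i in 0:(k - 1))
                    v <- v + pS * (Pex(u, f, i) * Eex(g, k - i) +
                                   Pex(u, g, i) * Eex(f, k - i))
        }
        if (k >= 1) {
            rr <- recip[[e]]
            if (!isGLeaf) {
                a <- uKids[1]; b <- uKids[2]
                for (i in 0:(k - 1)) {
                    v <- v + 2 * pD * Pex(a, e, i) * Pex(b, e, k - 1 - i)
                    if (length(rr)) {
                        pbarB <- mean(vapply(rr, function(h)
                            Pex(b, h, k - 1 - i), numeric(1)))
                        pbarA <- mean(vapply(rr, function(h)
                            Pex(a, h, k - 1 - i), numeric(1)))
                        v <- v + pT * (Pex(a, e, i) * pbarB +
                                       Pex(b, e, i) * pbarA)
                    }
                }
            }
            # duplication-loss and transfer-loss
            if (k >= 2) for (i in 0:(k - 2)) {
                v <- v + 2 * pD * Pex(u, e, i) * Eex(e, k - 1 - i)
                if (length(rr)) {
                    ebar <- mean(vapply(rr, function(h) Eex(h, k - 1 - i),
                                        numeric(1)))
                    pbarU <- mean(vapply(rr, function(h) Pex(u, h, i),
                                         numeric(1)))
                    v <- v + pT * (Pex(u, e, i) * ebar +
                                   pbarU * Eex(e, k - 1 - i))
                }
            }
        }
        Pmemo[[key]] <- v
        v
    }
    groot <- gA$n + 1L
    byShell <- vapply(0:kmax, function(k)
        sum(vapply(seq_len(S), function(e) Pex(groot, e, k),
                   numeric(1))) / S, numeric(1))
    list(likelihood = sum(byShell), lastShell = byShell[kmax + 1],
         byShell = byShell)
}

# ---- Procrustes residual by direct 2-D rotation optimization --------------

oracleM2Planar <- function(H, S) {
    Hc <- scale(H, scale = FALSE); Sc <- scale(S, scale = FALSE)
    obj <- function(par, refl) {
        th <- par[1]; cc <- exp(par[2])
        Q <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
        if (refl) Q <- Q %*% diag(c(1, -1))
        sum((Hc - cc * Sc %*% Q)^2)
    }
    best <- Inf
    for (refl in c(FALSE, TRUE))
        for (th0 in seq(0, 2 * pi, length.out = 9)[-9]) {
            fit <- optim(c(th0, 0), obj, refl = refl,
                         method = "Nelder-Mead",
                         control = list(reltol = 1e-14, maxit = 5000))
            best <- min(best, fit$value)
        }
    best
}

# ---- small random problem generators --------------------------------------

randomAssociation <- function(host, nSymb, prefix = "s") {
    pick <- sample(host$tip.label, nSymb, replace = TRUE)
    links <- data.frame(host_id = pick,
                        symbiont_id = paste0(prefix, seq_len(nSymb)))
    associationFromLinks(links,
                         hosts = host$tip.label[host$tip.label %in% pick])
}

leafMapFromAssociation <- function(assoc) {
    links <- linksFromAssociation(assoc)
    setNames(links$host_id, links$symbiont_id)
}
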