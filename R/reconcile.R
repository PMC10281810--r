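# flat array view of a rooted binary phylo for the reconciliation DPs:
# nodes 1..n are tips, root = n+1; one "branch" per node (the root carries
# the stem branch)
phyloArraysR <- function(tree, arg = "tree") {
    stopIfNotPhylo(tree, arg)
    nTip <- ape::Ntip(tree)
    S <- nTip + tree$Nnode
    left <- integer(S); right <- integer(S)
    for (v in (nTip + 1L):S) {
        kids <- tree$edge[tree$edge[, 1] == v, 2]
        if (length(kids) != 2L)
            stop(sprintf("'%s' must be binary (node %d has %d children)",
                         arg, v, length(kids)), call. = FALSE)
        left[v] <- kids[1]; right[v] <- kids[2]
    }
    parent <- integer(S)
    parent[tree$edge[, 2]] <- tree$edge[, 1]
    po <- ape::reorder.phylo(tree, "postorder")
    postorder <- c(po$edge[, 2][!duplicated(po$edge[, 2])], nTip + 1L)
    postorder <- postorder[!duplicated(postorder)]
    anc <- vector("list", S)
    for (v in seq_len(S)) {
        a <- parent[v]; path <- integer()
        while (a != 0L) { path <- c(path, a); a <- parent[a] }
        anc[[v]] <- path
    }
    list(n = S, nTip = nTip, parent = parent, left = left, right = right,
         postorder = postorder, anc = anc, labels = tree$tip.label)
}

geneLeafMapIdx <- function(gA, sA, leafMap) {
    if (is.null(names(leafMap)))
        stop("leafMap must be named: gene tip -> species tip", call. = FALSE)
    idx <- rep(-1L, gA$n)
    for (i in seq_len(gA$nTip)) {
        g <- gA$labels[i]
        if (!g %in% names(leafMap))
            stop(sprintf("unmapped gene tip: %s", g), call. = FALSE)
        s <- match(leafMap[[g]], sA$labels)
        if (is.na(s))
            stop(sprintf("leafMap sends '%s' to unknown species tip '%s'",
                         g, leafMap[[g]]), call. = FALSE)
        idx[i] <- s
    }
    idx
}

#' Undated duplication-transfer-loss log-likelihood
#'
#' Probability of a gene (symbiont) tree given a species (host) tree under
#' the undated DTL model: on each species branch a gene lineage draws one
#' event with probabilities `pS = 1/q`, `pD = delta/q`, `pT = tau/q`,
#' `pL = lambda/q` where `q = 1 + delta + tau + lambda`. A transfer copies
#' the lineage to a branch drawn uniformly among branches not ancestral to
#' the donor (self excluded). Extinction probabilities are solved by
#' fixed-point iteration to `extTol`; the self-referential
#' speciation-loss/duplication-loss/transfer-loss propagation terms of the
#' inside probabilities are resolved with `insideRounds` Gauss-Seidel
#' sweeps. The gene root placement is summed over species branches under a
#' uniform prior, so the returned value is a log probability (<= 0).
#'
#' @param species,gene rooted binary `phylo` trees.
#' @param leafMap named character vector: gene tip -> species tip
#'   (many-to-one allowed).
#' @param rates numeric of length 3: duplication (delta), transfer (tau),
#'   loss (lambda); all >= 0.
#' @param insideRounds fixed-point sweeps for the propagation terms.
#' @param extTol,extMaxIter absolute tolerance and cap for the extinction
#'   fixed point (an error reports the residual if the cap is hit).
#' @return log-likelihood (numeric scalar; `-Inf` outside the numerically
#'   valid regime of the fixed number of sweeps).
#' @export
dtlLikelihood <- function(species, gene, leafMap, rates,
                          insideRounds = 5, extTol = 1e-12,
                          extMaxIter = 100) {
    stopifnot(length(rates) == 3, all(rates >= 0))
    sA <- phyloArraysR(species, "species")
    gA <- phyloArraysR(gene, "gene")
    idx <- geneLeafMapIdx(gA, sA, leafMap)
    res <- cpp_dtl_loglik(sA$parent - 1L, sA$left - 1L, sA$right - 1L,
                          sA$postorder - 1L, gA$left - 1L, gA$right - 1L,
                          gA$postorder - 1L, idx - 1L,
                          rates[1], rates[2], rates[3],
                          as.integer(insideRounds), extTol,
                          as.integer(extMaxIter))
    if (!res$converged)
        stop(sprintf("extinction fixed point did not converge (residual %.3g after %d iterations)",
                     res$residual, extMaxIter), call. = FALSE)
    res$loglik
}

#' Maximum-likelihood DTL rate estimation
#'
#' Maximizes [dtlLikelihood()] over (duplication, transfer, loss) with
#' derivative-free Nelder-Mead simplex searches on a logistic-log transform
#' that enforces the rate bounds, restarted from seeded jittered initial
#' points. The transfer rate of the best restart is the package's
#' horizontal-transfer rate estimate for the gene tree.
#'
#' @inheritParams dtlLikelihood
#' @param init initial rates (duplication, transfer, loss).
#' @param bounds lower and upper bound applied to each rate.
#' @param nRestarts number of optimizer restarts (the first starts at
#'   `init`, the rest at jittered points).
#' @param seed integer seed controlling the jitter.
#' @return a [DTLRates-class] object.
#' @export
estimateRatesML <- function(species, gene, leafMap,
                            init = c(0.1, 0.1, 0.1), bounds = c(1e-6, 10),
                            nRestarts = 4, seed = NULL, insideRounds = 5) {
    stopifnot(length(init) == 3, length(bounds) == 2, bounds[1] > 0,
              bounds[2] > bounds[1], nRestarts >= 1)
    sA <- phyloArraysR(species, "species")
    gA <- phyloArraysR(gene, "gene")
    idx <- geneLeafMapIdx(gA, sA, leafMap)
    lb <- log(bounds[1]); ub <- log(bounds[2])
    toRates <- function(u) exp(lb + (ub - lb) * plogis(u))
    toU <- function(r) qlogis((log(pmin(pmax(r, bounds[1] * 1.0001),
                                        bounds[2] * 0.9999)) - lb) / (ub - lb))
    negLL <- function(u) {
        r <- toRates(u)
        res <- cpp_dtl_loglik(sA$parent - 1L, sA$left - 1L, sA$right - 1L,
                              sA$postorder - 1L, gA$left - 1L, gA$right - 1L,
                              gA$postorder - 1L, idx - 1L,
                              r[1], r[2], r[3], as.integer(insideRounds),
                              1e-12, 100L)
        if (!res$converged || !is.finite(res$loglik)) return(1e10)
        -res$loglik
    }
    u0 <- toU(init)
    fits <- withSeed(seed, lapply(seq_len(nRestarts), function(r) {
        start <- if (r == 1) u0 else u0 + stats::rnorm(3, 0, 1.5)
        tryCatch(optim(start, negLL, method = "Nelder-Mead",
                       control = list(maxit = 1000, reltol = 1e-10)),
                 error = function(e) NULL)
    }))
    fits <- Filter(function(f) !is.null(f) && is.finite(f$value) &&
                       f$value < 1e9, fits)
    if (!length(fits))
        stop("DTL rate optimization failed in all restarts", call. = FALSE)
    vals <- vapply(fits, function(f) f$value, numeric(1))
    best <- fits[[which.min(vals)]]
    converged <- best$convergence == 0
    if (!any(vapply(fits, function(f) f$convergence == 0, logical(1))))
        stop(sprintf("optimizer did not converge in any restart; best point: %s (logLik %.4f)",
                     paste(signif(toRates(best$par), 4), collapse = ", "),
                     -best$value), call. = FALSE)
    rates <- toRates(best$par)
    names(rates) <- c("duplication", "transfer", "loss")
    new("DTLRates", rates = rates, logLik = -best$value,
        converged = converged, nRestarts = as.integer(nRestarts),
        seed = seedOrNA(seed))
}

#' Most parsimonious DTL reconciliation
#'
#' Dynamic program over (gene node x species branch): a gene node is
#' explained by a speciation (its children descend into the two species
#' daughters, in either order), a duplication (both children stay on the
#' branch, cost D), or a transfer (one child stays, the other moves to a
#' branch not ancestral to the donor and distinct from it, cost T), with
#' loss-augmented descent charging L per skipped branch. Returns the global
#' minimum cost and the event counts of one optimal history (ties broken in
#' a fixed order: speciation, duplication, transfer).
#'
#' @inheritParams dtlLikelihood
#' @param costs positive costs, named `dup`, `transfer`, `loss`.
#' @return list with `cost` and `events` (named counts: speciation,
#'   duplication, transfer, loss).
#' @export
reconcileMP <- function(species, gene, leafMap,
                        costs = c(dup = 2, transfer = 3, loss = 1)) {
    stopifnot(all(costs > 0), all(c("dup", "transfer", "loss") %in%
                                      names(costs)))
    sA <- phyloArraysR(species, "species")
    gA <- phyloArraysR(gene, "gene")
    idx <- geneLeafMapIdx(gA, sA, leafMap)
    S <- sA$n; G <- gA$n
    D <- costs[["dup"]]; TT <- costs[["transfer"]]; LL <- costs[["loss"]]
    cM <- matrix(Inf, G, S)
    inM <- matrix(Inf, G, S)
    bestRecv <- function(row) vapply(seq_len(S), function(x) {
        excl <- c(x, sA$anc[[x]])
        v <- row[-excl]
        if (length(v)) min(v) else Inf
    }, numeric(1))
    recvRows <- vector("list", G)
    for (u in gA$postorder) {
        if (gA$left[u] == 0L) {
            cM[u, idx[u]] <- 0
        } else {
            a <- gA$left[u]; b <- gA$right[u]
            rA <- bestRecv(inM[a, ]); rB <- bestRecv(inM[b, ])
            for (x in seq_len(S)) {
                v <- D + inM[a, x] + inM[b, x]
                if (sA$left[x] > 0L) {
                    f <- sA$left[x]; g <- sA$right[x]
                    v <- min(v, inM[a, f] + inM[b, g],
                             inM[a, g] + inM[b, f])
                }
                v <- min(v, TT + inM[a, x] + rB[x], TT + inM[b, x] + rA[x])
                cM[u, x] <- v
            }
        }
        for (x in sA$postorder) {
            v <- cM[u, x]
            if (sA$left[x] > 0L)
                v <- min(v, inM[u, sA$left[x]] + LL,
                         inM[u, sA$right[x]] + LL)
            inM[u, x] <- v
        }
    }
    groot <- gA$postorder[length(gA$postorder)]
    cost <- min(cM[groot, ])
    rootX <- which.min(cM[groot, ])

    eps <- 1e-9
    counts <- c(speciation = 0L, duplication = 0L, transfer = 0L, loss = 0L)
    resolveIn <- function(u, x) {
        repeat {
            if (is.finite(cM[u, x]) && cM[u, x] <= inM[u, x] + eps) {
                resolveC(u, x); return(invisible())
            }
            stopifnot(sA$left[x] > 0L)
            f <- sA$left[x]; g <- sA$right[x]
            counts["loss"] <<- counts["loss"] + 1L
            x <- if (inM[u, f] + LL <= inM[u, x] + eps) f else g
        }
    }
    resolveC <- function(u, x) {
        if (gA$left[u] == 0L) return(invisible())
        a <- gA$left[u]; b <- gA$right[u]
        target <- cM[u, x]
        if (sA$left[x] > 0L) {
            f <- sA$left[x]; g <- sA$right[x]
            if (inM[a, f] + inM[b, g] <= target + eps) {
                counts["speciation"] <<- counts["speciation"] + 1L
                resolveIn(a, f); resolveIn(b, g); return(invisible())
            }
            if (inM[a, g] + inM[b, f] <= target + eps) {
                counts["speciation"] <<- counts["speciation"] + 1L
                resolveIn(a, g); resolveIn(b, f); return(invisible())
            }
        }
        if (D + inM[a, x] + inM[b, x] <= target + eps) {
            counts["duplication"] <<- counts["duplication"] + 1L
            resolveIn(a, x); resolveIn(b, x); return(invisible())
        }
        allowed <- setdiff(seq_len(S), c(x, sA$anc[[x]]))
        for (h in allowed) {
            if (TT + inM[a, x] + inM[b, h] <= target + eps) {
                counts["transfer"] <<- counts["transfer"] + 1L
                resolveIn(a, x); resolveIn(b, h); return(invisible())
            }
            if (TT + inM[b, x] + inM[a, h] <= target + eps) {
                counts["transfer"] <<- counts["transfer"] + 1L
                resolveIn(b, x); resolveIn(a, h); return(invisible())
            }
        }
        stop("internal error: no event reproduces the optimal cost")
    }
    if (is.finite(cost)) resolveIn(groot, rootX)
    list(cost = cost, events = counts)
}

#' Transfer-rate baseline from replicate gene trees
#'
#' Estimates the DTL transfer rate for each replicate gene tree (trees that
#' share one true history and therefore experienced no transfer, e.g.
#' mitochondrial genes or [makeBaselineReplicates()] output) and returns the
#' per-replicate rates with their range. Positive rates here reflect
#' reconstruction noise alone.
#'
#' @param species the host `phylo`.
#' @param replicates list of replicate gene `phylo` trees (>= 2).
#' @param leafMaps optional list of leaf maps; defaults to identity maps
#'   (replicate tips are host tips).
#' @param seed integer seed; replicate i uses `seed + i`.
#' @param ... passed to [estimateRatesML()].
#' @return a [BaselineRange-class] object.
#' @export
computeBaseline <- function(species, replicates, leafMaps = NULL,
                            seed = NULL, ...) {
    stopifnot(length(replicates) >= 2)
    rates <- numeric(length(replicates))
    failures <- character()
    for (i in seq_along(replicates)) {
        gene <- replicates[[i]]
        lm <- if (is.null(leafMaps))
            setNames(gene$tip.label, gene$tip.label) else leafMaps[[i]]
        subSeed <- if (is.null(seed)) NULL else
            (as.integer(seed) + i) %% .Machine$integer.max
        fit <- tryCatch(
            estimateRatesML(species, gene, lm, seed = subSeed, ...),
            error = function(e) e)
        if (inherits(fit, "error")) {
            failures <- c(failures,
                          sprintf("replicate %d: %s", i, conditionMessage(fit)))
            rates[i] <- NA_real_
        } else rates[i] <- transferRate(fit)
    }
    if (length(failures)) {
        cond <- structure(
            class = c("cophylotrace_baseline_error", "error", "condition"),
            list(message = paste0("baseline estimation failed for some replicates:\n",
                                  paste(failures, collapse = "\n")),
                 call = sys.call(-1), partialRates = rates))
        stop(cond)
    }
    new("BaselineRange", rates = rates, min = min(rates), max = max(rates))
}

#' Classify a clade's transfer rate against the no-transfer baseline
#'
#' A clade's history is called vertically dominated when its estimated
#' transfer rate does not exceed the largest rate observed for replicate
#' gene trees that share one true history (boundary inclusive): anything the
#' baseline can produce is attributable to reconstruction noise rather than
#' genuine horizontal transfer.
#'
#' @param rate estimated transfer rate of the clade (>= 0).
#' @param baseline a [BaselineRange-class].
#' @return `"vertical_dominant"` or `"transfer_elevated"`.
#' @export
classifyTsc <- function(rate, baseline) {
    stopifnot(is(baseline, "BaselineRange"))
    if (!is.finite(rate) || rate < 0)
        stop("rate must be a non-negative number", call. = FALSE)
    if (rate <= baselineMax(baseline)) "vertical_dominant"
    else "transfer_elevated"
}
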