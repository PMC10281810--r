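#' Simulate an ultrametric host tree
#'
#' Birth-death tree conditioned on the number of extant tips, the stand-in
#' for a dated host phylogeny. With `death = 0` the tree is a pure-birth
#' (Yule) tree. Tips are labelled `H1..Hn`; all root-to-tip path lengths are
#' equal (the tree is ultrametric, as the cophylogeny simulator requires).
#'
#' @param n number of extant tips (>= 2).
#' @param birth per-lineage speciation rate (> 0).
#' @param death per-lineage extinction rate (>= 0, < `birth`; conditioning
#'   on n survivors is handled internally by the sampler).
#' @param seed integer seed for reproducibility (optional).
#' @param height optional total tree height to rescale to; simulator event
#'   rates are per unit host-tree time, so fixing `height = 1` makes rates
#'   comparable across replicate host trees.
#' @return an ultrametric `phylo` with `n` tips.
#' @export
simulateHostTree <- function(n, birth = 1, death = 0, seed = NULL,
                             height = NULL) {
    stopifnot(n >= 2, birth > 0, death >= 0)
    if (death >= birth)
        stop("death rate must be smaller than birth rate to condition on ",
             "n surviving tips", call. = FALSE)
    tree <- withSeed(seed, ape::rphylo(n, birth = birth, death = death,
                                       fossils = FALSE))
    tree$tip.label <- paste0("H", seq_len(n))
    if (!is.null(height)) {
        stopifnot(height > 0)
        tree$edge.length <- tree$edge.length * height /
            max(ape::node.depth.edgelength(tree))
    }
    tree
}

#' Parameters of the cophylogeny simulator
#'
#' Defaults describe a symbiont clade that mostly tracks its host
#' (codivergence probability 0.9) with occasional independent duplication,
#' loss and host switching (0.1 events per lineage per unit host-tree time
#' each) and realistic incomplete recovery of symbionts from metagenomes
#' (sampling probability 0.8 per extant tip).
#'
#' @param duplication within-host symbiont speciation rate (per lineage per
#'   time).
#' @param loss symbiont extinction rate; metagenomic non-detection is
#'   indistinguishable from true loss and is modelled separately via
#'   `sampling`.
#' @param hostSwitch horizontal transfer rate; a switch copies the lineage
#'   onto a contemporaneous host branch chosen uniformly among branches not
#'   ancestral to the donor (the donor itself excluded), leaving a
#'   bifurcation in the symbiont tree.
#' @param codivergence probability that a resident lineage divides with its
#'   host at a host speciation (otherwise it follows one daughter chosen
#'   uniformly).
#' @param sampling probability that an extant symbiont tip is recovered.
#' @param seed integer seed (optional).
#' @return a named list of validated parameters.
#' @export
cophyloParams <- function(duplication = 0.1, loss = 0.1, hostSwitch = 0.1,
                          codivergence = 0.9, sampling = 0.8, seed = NULL) {
    stopifnot(duplication >= 0, loss >= 0, hostSwitch >= 0,
              codivergence >= 0, codivergence <= 1,
              sampling > 0, sampling <= 1)
    list(duplication = duplication, loss = loss, hostSwitch = hostSwitch,
         codivergence = codivergence, sampling = sampling, seed = seed)
}

#' Simulate symbiont evolution along a host tree
#'
#' One symbiont lineage enters at the host root and traverses host branches.
#' At each host speciation every resident lineage codiverges with probability
#' `codivergence` (a node in the symbiont tree) or follows one daughter
#' branch chosen uniformly. Along branches, duplication, loss and host-switch
#' events fire as independent Poisson processes (Gillespie next-event
#' sampling); a switch moves a copy to a contemporaneous host branch chosen
#' uniformly among non-ancestral branches and leaves a bifurcation (the
#' donor copy stays), which is how a transfer is visible to reconciliation.
#' Extant tips are then thinned with the sampling probability; the returned
#' symbiont tree is the pruned genealogy of the sampled tips.
#'
#' @param host ultrametric `phylo` (time-calibrated).
#' @param params list from [cophyloParams()].
#' @param maxTips guard against runaway radiations (duplication + switching
#'   above the loss rate grows exponentially in tree height): the simulation
#'   errors out beyond this many symbiont tree leaves.
#' @return a [CophyloSimulation-class] object. When no sampled extant
#'   symbiont survives, `empty` is TRUE and the symbiont tree is NULL (this
#'   is a flagged outcome, not an error).
#' @export
simulateCophylogeny <- function(host, params = cophyloParams(),
                                maxTips = 10000) {
    requireBranchLengths(host, "host")
    depths <- ape::node.depth.edgelength(host)
    nTip <- ape::Ntip(host)
    tipDepths <- depths[seq_len(nTip)]
    if (diff(range(tipDepths)) > 1e-8 * max(tipDepths))
        stop("host tree must be ultrametric (time-calibrated)", call. = FALSE)
    root <- nTip + 1L
    ch <- nodeChildren(host)
    edgeStart <- depths[host$edge[, 1]]
    edgeEnd <- depths[host$edge[, 2]]
    edgeOf <- integer(nTip + host$Nnode)
    edgeOf[host$edge[, 2]] <- seq_len(nrow(host$edge))

    totalRate <- params$duplication + params$loss + params$hostSwitch
    env <- new.env(parent = emptyenv())
    env$codiv <- 0L; env$dup <- 0L; env$loss <- 0L; env$switch <- 0L
    env$ltime <- 0; env$tipN <- 0L
    env$tipHost <- character()

    fmt <- function(x) sprintf("%.10g", max(x, 0))

    simFromNode <- function(v, tArr) {
        if (env$tipN > maxTips)
            stop(sprintf("symbiont radiation exceeded %d tips; lower the event rates or the host-tree height", maxTips),
                 call. = FALSE)
        if (v <= nTip) {
            env$tipN <- env$tipN + 1L
            lab <- paste0("s", env$tipN)
            env$tipHost[lab] <- host$tip.label[v]
            return(list(leaf = TRUE, label = lab, time = depths[v]))
        }
        kids <- ch[[v]]
        if (runif(1) < params$codivergence) {
            env$codiv <- env$codiv + 1L
            left <- simEdge(kids[1], depths[v])
            right <- simEdge(kids[2], depths[v])
            list(leaf = FALSE, time = depths[v], children = list(left, right))
        } else {
            simEdge(kids[sample.int(length(kids), 1)], depths[v])
        }
    }

    simEdge <- function(v, t0) {
        tEnd <- depths[v]
        repeat {
            dt <- if (totalRate > 0) rexp(1, totalRate) else Inf
            if (t0 + dt >= tEnd) {
                env$ltime <- env$ltime + (tEnd - t0)
                return(simFromNode(v, tEnd))
            }
            t1 <- t0 + dt
            env$ltime <- env$ltime + dt
            u <- runif(1) * totalRate
            if (u < params$duplication) {
                env$dup <- env$dup + 1L
                return(list(leaf = FALSE, time = t1,
                            children = list(simEdge(v, t1), simEdge(v, t1))))
            } else if (u < params$duplication + params$loss) {
                env$loss <- env$loss + 1L
                env$tipN <- env$tipN + 1L
                return(list(leaf = TRUE, dead = TRUE,
                            label = paste0("x", env$tipN), time = t1))
            } else {
                # host switch: contemporaneous branches; branches ancestral
                # to the donor ended before t1, so only the donor needs
                # excluding explicitly
                alive <- which(edgeStart <= t1 & t1 < edgeEnd)
                alive <- setdiff(alive, edgeOf[v])
                if (length(alive) == 0) { t0 <- t1; next }
                env$switch <- env$switch + 1L
                w <- host$edge[alive[sample.int(length(alive), 1)], 2]
                return(list(leaf = FALSE, time = t1,
                            children = list(simEdge(v, t1), simEdge(w, t1))))
            }
        }
    }

    toNewick <- function(node, tParent) {
        len <- fmt(node$time - tParent)
        if (node$leaf) return(paste0(node$label, ":", len))
        paste0("(", toNewick(node$children[[1]], node$time), ",",
               toNewick(node$children[[2]], node$time), "):", len)
    }

    run <- function() {
        tree0 <- simFromNode(root, depths[root])
        extant <- names(env$tipHost)
        sampled <- extant[runif(length(extant)) < params$sampling]
        list(tree0 = tree0, sampled = sampled)
    }
    out <- withSeed(params$seed, run())

    events <- c(codivergence = env$codiv, duplication = env$dup,
                loss = env$loss, switch = env$switch)
    genealogy <- if (!out$tree0$leaf)
        readNewick(paste0(toNewick(out$tree0, 0), ";")) else NULL

    if (length(out$sampled) < 2) {
        return(new("CophyloSimulation", hostTree = host, symbiontTree = NULL,
                   genealogy = genealogy,
                   association = matrix(0L, 0, 0,
                                        dimnames = list(NULL, NULL)),
                   events = events, lineageTime = env$ltime,
                   params = params, seed = seedOrNA(params$seed),
                   empty = TRUE))
    }
    symb <- ape::keep.tip(genealogy, out$sampled)
    links <- data.frame(host_id = unname(env$tipHost[symb$tip.label]),
                        symbiont_id = symb$tip.label,
                        stringsAsFactors = FALSE)
    hostOrder <- host$tip.label[host$tip.label %in% links$host_id]
    assoc <- associationFromLinks(links, hosts = hostOrder,
                                  symbionts = symb$tip.label)
    new("CophyloSimulation", hostTree = host, symbiontTree = symb,
        genealogy = genealogy, association = assoc, events = events,
        lineageTime = env$ltime, params = params,
        seed = seedOrNA(params$seed), empty = FALSE)
}

#' Perturb a tree to emulate phylogenetic reconstruction noise
#'
#' Applies `nNni` random nearest-neighbour interchanges on internal edges
#' (each alters at most one split) and multiplies every branch length by an
#' independent lognormal factor with median 1 and log-sd `blSigma`. The leaf
#' set is unchanged.
#'
#' @param tree a `phylo` with >= 4 tips when `nNni > 0`.
#' @param nNni number of NNI moves (>= 0).
#' @param blSigma log-sd of the branch-length jitter (>= 0).
#' @param seed integer seed (optional).
#' @return the perturbed `phylo`.
#' @export
perturbTree <- function(tree, nNni = 0, blSigma = 0, seed = NULL) {
    requireBranchLengths(tree)
    stopifnot(nNni >= 0, blSigma >= 0)
    internal <- which(tree$edge[, 2] > ape::Ntip(tree))
    if (nNni > 0 && length(internal) == 0)
        stop("tree has no internal edges: cannot apply NNI", call. = FALSE)
    withSeed(seed, {
        out <- tree
        for (i in seq_len(nNni)) out <- nniOnce(out)
        if (blSigma > 0)
            out$edge.length <- out$edge.length *
                rlnorm(length(out$edge.length), 0, blSigma)
        out
    })
}

# one random nearest-neighbour interchange; branch lengths stay attached to
# the subtree they subtend
nniOnce <- function(tree) {
    nTip <- ape::Ntip(tree)
    internal <- which(tree$edge[, 2] > nTip)
    e <- internal[sample.int(length(internal), 1)]
    u <- tree$edge[e, 1]; v <- tree$edge[e, 2]
    kidsV <- tree$edge[tree$edge[, 1] == v, 2]
    kidsU <- setdiff(tree$edge[tree$edge[, 1] == u, 2], v)
    x <- kidsV[sample.int(length(kidsV), 1)]
    y <- kidsU[sample.int(length(kidsU), 1)]
    rowX <- which(tree$edge[, 1] == v & tree$edge[, 2] == x)
    rowY <- which(tree$edge[, 1] == u & tree$edge[, 2] == y)
    tree$edge[rowX, 1] <- u
    tree$edge[rowY, 1] <- v
    # normalize the edge ordering so downstream ape code sees a clean object
    readNewick(ape::write.tree(tree, digits = 10))
}

#' Replicate gene trees sharing one true history
#'
#' Generates `k` independently perturbed copies of a single true tree: the
#' synthetic analogue of a set of non-recombining (mitochondrial) gene trees,
#' whose estimated transfer rates bound what reconstruction noise alone can
#' produce.
#'
#' @param trueTree the shared true `phylo`.
#' @param k number of replicates (>= 2).
#' @inheritParams perturbTree
#' @return list of `k` `phylo` objects.
#' @export
makeBaselineReplicates <- function(trueTree, k = 15, nNni = 0, blSigma = 0,
                                   seed = NULL) {
    stopifnot(k >= 2)
    withSeed(seed, lapply(seq_len(k), function(i)
        perturbTree(trueTree, nNni = nNni, blSigma = blSigma)))
}

#' Write a simulation record to disk
#'
#' Writes `host.nwk`, `symbiont.nwk`, `association.tsv` and `truth.json`
#' (event counts, parameters, seed) under `dir`.
#'
#' @param sim a [CophyloSimulation-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
    stopifnot(is(sim, "CophyloSimulation"))
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    writeNewick(sim@hostTree, file.path(dir, "host.nwk"))
    if (!sim@empty) {
        writeNewick(sim@symbiontTree, file.path(dir, "symbiont.nwk"))
        writeAssociation(sim@association, file.path(dir, "association.tsv"))
    }
    truth <- list(events = as.list(sim@events),
                  lineage_time = sim@lineageTime,
                  params = sim@params[setdiff(names(sim@params), "seed")],
                  seed = sim@seed, empty = sim@empty)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
    invisible(dir)
}
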