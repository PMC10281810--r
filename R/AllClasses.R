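setOldClass("phylo")

#' Result of a congruence test between a host and a symbiont tree
#'
#' Holds the observed statistic of one of the three congruence methods
#' together with its permutation p-value. The orientation slot records
#' whether small or large values of the statistic indicate congruence
#' (`"small"` for the Procrustes residual m2 and the clustering-information
#' distance, `"large"` for the Nye similarity).
#'
#' @slot method one of `"paco"`, `"cid"`, `"nye"`.
#' @slot statistic observed statistic (m2, bits, or matched-score sum).
#' @slot pValue permutation p-value with the +1 correction, in (0, 1].
#' @slot nPerm number of permutations used.
#' @slot seed integer seed used for the permutation stream (NA if none).
#' @slot orientation `"small"` or `"large"`: which end means congruence.
#' @slot nLinks number of host-symbiont links tested.
#' @exportClass CongruenceResult
setClass("CongruenceResult",
         representation(method = "character", statistic = "numeric",
                        pValue = "numeric", nPerm = "integer",
                        seed = "integer", orientation = "character",
                        nLinks = "integer"))

setValidity("CongruenceResult", function(object) {
    msg <- character()
    if (!object@method %in% c("paco", "cid", "nye"))
        msg <- c(msg, "method must be 'paco', 'cid' or 'nye'")
    if (!object@orientation %in% c("small", "large"))
        msg <- c(msg, "orientation must be 'small' or 'large'")
    if (!is.finite(object@statistic))
        msg <- c(msg, "statistic must be finite")
    if (object@pValue <= 0 || object@pValue > 1)
        msg <- c(msg, "pValue must lie in (0, 1]")
    if (object@pValue < 1 / (object@nPerm + 1) - 1e-12)
        msg <- c(msg, "pValue below the permutation floor 1/(nPerm+1)")
    if (length(msg)) msg else TRUE
})

#' Maximum-likelihood duplication-transfer-loss rates
#'
#' Estimated event rates of the undated DTL model for one gene (symbiont)
#' tree reconciled with a species (host) tree, with the maximized
#' log-likelihood and optimizer diagnostics.
#'
#' @slot rates named numeric: `duplication`, `transfer`, `loss`.
#' @slot logLik maximized log-likelihood (finite, <= 0).
#' @slot converged logical: did the best restart converge.
#' @slot nRestarts number of optimizer restarts performed.
#' @slot seed integer seed (NA if none).
#' @exportClass DTLRates
setClass("DTLRates",
         representation(rates = "numeric", logLik = "numeric",
                        converged = "logical", nRestarts = "integer",
                        seed = "integer"))

setValidity("DTLRates", function(object) {
    msg <- character()
    if (!identical(names(object@rates),
                   c("duplication", "transfer", "loss")))
        msg <- c(msg, "rates must be named duplication, transfer, loss")
    if (any(object@rates < 0)) msg <- c(msg, "rates must be non-negative")
    if (!is.finite(object@logLik))
        msg <- c(msg, "log-likelihood must be finite at the optimum")
    if (length(msg)) msg else TRUE
})

#' No-transfer baseline from replicate gene trees
#'
#' Transfer rates estimated for a set of replicate gene trees that share one
#' true history (the analogue of non-recombining mitochondrial genes): any
#' positive rate reflects reconstruction noise alone, so the observed range
#' bounds what noise can produce without horizontal transfer.
#'
#' @slot rates per-replicate estimated transfer rates.
#' @slot min,max range of the per-replicate rates.
#' @exportClass BaselineRange
setClass("BaselineRange",
         representation(rates = "numeric", min = "numeric", max = "numeric"))

setValidity("BaselineRange", function(object) {
    msg <- character()
    if (length(object@rates) < 2)
        msg <- c(msg, "baseline needs at least 2 replicates")
    if (object@min > object@max) msg <- c(msg, "min must be <= max")
    if (length(msg)) msg else TRUE
})

#' A simulated host-symbiont cophylogeny with its true event history
#'
#' @slot hostTree host phylogeny the symbionts evolved along.
#' @slot symbiontTree pruned, sampled symbiont tree (NULL if all lineages
#'   died or were dropped: see `empty`).
#' @slot genealogy complete symbiont event genealogy including extinct
#'   lineages (internal nodes are codivergence/duplication/switch events).
#' @slot association binary host x symbiont incidence matrix.
#' @slot events named integer counts: codivergences, duplications, losses,
#'   switches.
#' @slot lineageTime total symbiont lineage-time simulated (host-tree time
#'   units), the exposure for the Poisson event rates.
#' @slot params the `CophyloParams`-style parameter list used.
#' @slot seed integer seed (NA if none).
#' @slot empty TRUE when no sampled extant symbiont survived.
#' @exportClass CophyloSimulation
setClass("CophyloSimulation",
         representation(hostTree = "ANY", symbiontTree = "ANY",
                        genealogy = "ANY", association = "matrix",
                        events = "integer", lineageTime = "numeric",
                        params = "list", seed = "integer",
                        empty = "logical"))

setValidity("CophyloSimulation", function(object) {
    msg <- character()
    if (!identical(names(object@events),
                   c("codivergence", "duplication", "loss", "switch")))
        msg <- c(msg, "events must be codivergence, duplication, loss, switch")
    if (any(object@events < 0)) msg <- c(msg, "event counts must be >= 0")
    if (!object@empty) {
        if (any(colSums(object@association) != 1L))
            msg <- c(msg, "every symbiont tip must map to exactly one host")
    }
    if (length(msg)) msg else TRUE
})

#' A habitat-specific clade extracted from a marker-gene tree
#'
#' A maximal clade whose member sequences all carry the focal environment
#' label (e.g. termite gut) and that spans at least a minimum number of
#' distinct host species.
#'
#' @slot id stable identifier, assigned in tree traversal order.
#' @slot node internal node number of the clade root in the source tree.
#' @slot members tip labels (sequence ids) of the clade.
#' @slot hostSpecies sorted unique host species ids represented.
#' @slot marker marker gene id the source tree was built from.
#' @exportClass TSC
setClass("TSC",
         representation(id = "character", node = "integer",
                        members = "character", hostSpecies = "character",
                        marker = "character"))

setValidity("TSC", function(object) {
    if (anyDuplicated(object@members))
        "member sequence ids must be unique" else TRUE
})
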