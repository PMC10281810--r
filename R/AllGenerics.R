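#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @export
setGeneric("testStatistic", function(x) standardGeneric("testStatistic"))

#' @export
setGeneric("orientation", function(x) standardGeneric("orientation"))

#' @export
setGeneric("nLinks", function(x) standardGeneric("nLinks"))

#' @export
setGeneric("dtlRates", function(x) standardGeneric("dtlRates"))

#' @export
setGeneric("transferRate", function(x) standardGeneric("transferRate"))

#' @export
setGeneric("replicateRates", function(x) standardGeneric("replicateRates"))

#' @export
setGeneric("baselineMin", function(x) standardGeneric("baselineMin"))

#' @export
setGeneric("baselineMax", function(x) standardGeneric("baselineMax"))

#' @export
setGeneric("hostTree", function(x) standardGeneric("hostTree"))

#' @export
setGeneric("symbiontTree", function(x) standardGeneric("symbiontTree"))

#' @export
setGeneric("association", function(x) standardGeneric("association"))

#' @export
setGeneric("eventCounts", function(x) standardGeneric("eventCounts"))

#' @export
setGeneric("tscMembers", function(x) standardGeneric("tscMembers"))

#' @export
setGeneric("tscHostSpecies", function(x) standardGeneric("tscHostSpecies"))

#' Accessors for result and simulation objects
#'
#' `pValue`, `testStatistic`, `orientation` and `nLinks` read
#' [CongruenceResult-class] objects; `dtlRates`, `transferRate` and
#' `logLik` read [DTLRates-class]; `replicateRates`, `baselineMin` and
#' `baselineMax` read [BaselineRange-class]; `hostTree`, `symbiontTree`,
#' `association` and `eventCounts` read [CophyloSimulation-class];
#' `tscMembers` and `tscHostSpecies` read [TSC-class].
#'
#' @param x the object.
#' @return the corresponding slot value.
#' @name accessors
#' @aliases pValue testStatistic orientation nLinks dtlRates transferRate
#'   replicateRates baselineMin baselineMax hostTree symbiontTree
#'   association eventCounts tscMembers tscHostSpecies
NULL

#' @rdname accessors
#' @exportMethod pValue
setMethod("pValue", "CongruenceResult", function(x) x@pValue)

#' @rdname accessors
#' @exportMethod testStatistic
setMethod("testStatistic", "CongruenceResult", function(x) x@statistic)

#' @rdname accessors
#' @exportMethod orientation
setMethod("orientation", "CongruenceResult", function(x) x@orientation)

#' @rdname accessors
#' @exportMethod nLinks
setMethod("nLinks", "CongruenceResult", function(x) x@nLinks)

#' @rdname accessors
#' @exportMethod dtlRates
setMethod("dtlRates", "DTLRates", function(x) x@rates)

#' @rdname accessors
#' @exportMethod transferRate
setMethod("transferRate", "DTLRates", function(x) unname(x@rates["transfer"]))

#' @importFrom stats logLik
#' @exportMethod logLik
setMethod("logLik", "DTLRates", function(object, ...) object@logLik)

#' @rdname accessors
#' @exportMethod replicateRates
setMethod("replicateRates", "BaselineRange", function(x) x@rates)

#' @rdname accessors
#' @exportMethod baselineMin
setMethod("baselineMin", "BaselineRange", function(x) x@min)

#' @rdname accessors
#' @exportMethod baselineMax
setMethod("baselineMax", "BaselineRange", function(x) x@max)

#' @rdname accessors
#' @exportMethod hostTree
setMethod("hostTree", "CophyloSimulation", function(x) x@hostTree)

#' @rdname accessors
#' @exportMethod symbiontTree
setMethod("symbiontTree", "CophyloSimulation", function(x) x@symbiontTree)

#' @rdname accessors
#' @exportMethod association
setMethod("association", "CophyloSimulation", function(x) x@association)

#' @rdname accessors
#' @exportMethod eventCounts
setMethod("eventCounts", "CophyloSimulation", function(x) x@events)

#' @rdname accessors
#' @exportMethod tscMembers
setMethod("tscMembers", "TSC", function(x) x@members)

#' @rdname accessors
#' @exportMethod tscHostSpecies
setMethod("tscHostSpecies", "TSC", function(x) x@hostSpecies)

setMethod("show", "CongruenceResult", function(object) {
    cat(sprintf("CongruenceResult [%s]\n", object@method))
    cat(sprintf("  statistic: %.6g (%s values indicate congruence)\n",
                object@statistic, object@orientation))
    cat(sprintf("  p-value  : %.4g (%d permutations, %d links)\n",
                object@pValue, object@nPerm, object@nLinks))
})

setMethod("show", "DTLRates", function(object) {
    cat("DTLRates (undated DTL maximum likelihood)\n")
    cat(sprintf("  duplication: %.4g  transfer: %.4g  loss: %.4g\n",
                object@rates["duplication"], object@rates["transfer"],
                object@rates["loss"]))
    cat(sprintf("  logLik: %.4f  converged: %s (%d restarts)\n",
                object@logLik, object@converged, object@nRestarts))
})

setMethod("show", "BaselineRange", function(object) {
    cat(sprintf("BaselineRange over %d replicate gene trees\n",
                length(object@rates)))
    cat(sprintf("  transfer rate range: [%.4g, %.4g]\n",
                object@min, object@max))
})

setMethod("show", "CophyloSimulation", function(object) {
    cat("CophyloSimulation\n")
    if (object@empty) {
        cat("  <empty: no sampled extant symbiont>\n")
    } else {
        cat(sprintf("  hosts: %d  symbionts: %d  links: %d\n",
                    nrow(object@association), ncol(object@association),
                    sum(object@association)))
    }
    cat(sprintf("  events: %s\n",
                paste(names(object@events), object@events,
                      sep = "=", collapse = " ")))
})

setMethod("show", "TSC", function(object) {
    cat(sprintf("TSC %s (marker %s): %d sequences, %d host species\n",
                object@id, object@marker, length(object@members),
                length(object@hostSpecies)))
})
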