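#' Read and validate a pipeline run configuration
#'
#' The configuration is a single YAML file (or an equivalent named list)
#' with top-level fields `seed`, `n_perm`, `alpha` (default 0.05), `methods`
#' (default all three), `bh` (optional Benjamini-Hochberg column, default
#' off) and exactly one of `simulate` (simulator parameters) or `input`
#' (paths to trees and association tables). All seeds are explicit; nothing
#' is wall-clock derived.
#'
#' @param x path to a YAML file, or a named list.
#' @return the validated configuration list.
#' @export
readRunConfig <- function(x) {
    cfg <- if (is.character(x)) yaml::read_yaml(x) else x
    if (!is.list(cfg)) stop("config must be a list or YAML path",
                            call. = FALSE)
    for (field in c("seed", "n_perm"))
        if (is.null(cfg[[field]]))
            stop(sprintf("config validation error: missing field '%s'",
                         field), call. = FALSE)
    if (is.null(cfg$alpha)) cfg$alpha <- 0.05
    if (cfg$alpha <= 0 || cfg$alpha >= 1)
        stop("config validation error: 'alpha' must lie in (0,1)",
             call. = FALSE)
    if (is.null(cfg$methods)) cfg$methods <- c("paco", "cid", "nye")
    if (is.null(cfg$bh)) cfg$bh <- FALSE
    hasSim <- !is.null(cfg$simulate); hasInput <- !is.null(cfg$input)
    if (hasSim == hasInput)
        stop("config validation error: exactly one of 'simulate' or 'input' must be present",
             call. = FALSE)
    if (hasSim) {
        sim <- cfg$simulate
        defaults <- list(n_hosts = 50, birth = 1, death = 0, n_tsc = 3,
                         duplication = 0.1, loss = 0.1, host_switch = 0.1,
                         codivergence = 0.9, sampling = 0.8,
                         noise_nni = 2, noise_bl_sigma = 0.1,
                         baseline_replicates = 15)
        for (f in names(defaults))
            if (is.null(sim[[f]])) sim[[f]] <- defaults[[f]]
        cfg$simulate <- sim
    }
    cfg
}

#' Run the full cophylogeny pipeline
#'
#' Orchestrates simulate (or load) -> congruence tests -> transfer-rate
#' estimation -> baseline classification into one reproducible run. Each
#' clade is tested with all requested methods; it is flagged as carrying a
#' cophylogenetic signal only when every method gives p <= alpha. The
#' transfer rate is classified against the baseline built from replicate
#' gene trees. Writes `report.tsv`, `report.json` and `run.log` under
#' `outdir`; the same config and seed regenerate the report byte-
#' identically. A stage failure aborts with the stage name and leaves
#' partial outputs under a `failed/` marker.
#'
#' @param config path to a YAML config or a named list (see
#'   [readRunConfig()]).
#' @param outdir output directory (default `config$output_dir`, falling
#'   back to `"cophylotrace_run"`).
#' @return the report, a list with elements `table` (per-clade data.frame),
#'   `baseline`, `config` and `version`, invisibly classed
#'   `cophyloReport`.
#' @export
runPipeline <- function(config, outdir = NULL) {
    cfg <- readRunConfig(config)
    if (is.null(outdir)) outdir <- cfg$output_dir %||% "cophylotrace_run"
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    logFile <- file.path(outdir, "run.log")
    cat(NULL, file = logFile)
    logLine <- function(stage, ...) {
        cat(sprintf("stage=%s %s\n", stage, paste(..., collapse = " ")),
            file = logFile, append = TRUE)
    }
    failed <- function(stage, e) {
        dir.create(file.path(outdir, "failed"), showWarnings = FALSE)
        writeLines(sprintf("stage: %s\nerror: %s", stage,
                           conditionMessage(e)),
                   file.path(outdir, "failed", "MARKER"))
        stop(sprintf("pipeline stage '%s' failed: %s", stage,
                     conditionMessage(e)), call. = FALSE)
    }
    seed <- as.integer(cfg$seed)

    inputs <- tryCatch(pipelineInputs(cfg, seed), error = function(e)
        failed("inputs", e))
    host <- inputs$host
    hostFile <- file.path(outdir, "host.nwk")
    writeNewick(host, hostFile)
    logLine("inputs", sprintf("n_tsc=%d host_md5=%s", length(inputs$tscs),
                              unname(tools::md5sum(hostFile))))

    baseline <- tryCatch(
        computeBaseline(host, inputs$baselineTrees, seed = seed + 4000L),
        error = function(e) failed("baseline", e))
    logLine("baseline", sprintf("min=%.6g max=%.6g",
                                baselineMin(baseline), baselineMax(baseline)))

    rows <- vector("list", length(inputs$tscs))
    for (i in seq_along(inputs$tscs)) {
        tsc <- inputs$tscs[[i]]
        row <- tryCatch(
            analyzeTsc(tsc$id, host, tsc$tree, tsc$assoc, baseline, cfg,
                       seed + 100L * i),
            error = function(e) failed(sprintf("tsc:%s", tsc$id), e))
        rows[[i]] <- row
        logLine("tsc", sprintf("id=%s signal_all3=%s", tsc$id,
                               row$signal_all3))
    }
    table <- do.call(rbind, rows)
    if (isTRUE(cfg$bh))
        for (m in cfg$methods)
            table[[paste0(m, "_p_bh")]] <-
                stats::p.adjust(table[[paste0(m, "_p")]], "BH")

    report <- list(table = table,
                   baseline = list(rates = replicateRates(baseline),
                                   min = baselineMin(baseline),
                                   max = baselineMax(baseline)),
                   config = cfg,
                   version = as.character(utils::packageVersion("cophylotrace")))
    class(report) <- "cophyloReport"
    write.table(table, file.path(outdir, "report.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(unclass(report), file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE,
                         dataframe = "rows")
    logLine("report", sprintf("report_md5=%s",
                              unname(tools::md5sum(file.path(outdir, "report.json")))))
    invisible(report)
}

# assemble host tree, per-clade trees/associations, and baseline replicate
# trees either from the simulator or from input paths
pipelineInputs <- function(cfg, seed) {
    if (!is.null(cfg$simulate)) {
        s <- cfg$simulate
        host <- simulateHostTree(s$n_hosts, s$birth, s$death, seed)
        tscs <- list()
        i <- 0L; tries <- 0L
        while (length(tscs) < s$n_tsc && tries < 20L * s$n_tsc) {
            tries <- tries + 1L
            sim <- simulateCophylogeny(host, cophyloParams(
                duplication = s$duplication, loss = s$loss,
                hostSwitch = s$host_switch, codivergence = s$codivergence,
                sampling = s$sampling, seed = seed + 10L * tries))
            if (sim@empty || sum(sim@association) < 4) next
            i <- i + 1L
            tree <- perturbTree(symbiontTree(sim), nNni = s$noise_nni,
                                blSigma = s$noise_bl_sigma,
                                seed = seed + 10L * tries + 1L)
            tscs[[i]] <- list(id = paste0("TSC", i), tree = tree,
                              assoc = association(sim))
        }
        if (length(tscs) < s$n_tsc)
            stop("simulator produced too many empty records", call. = FALSE)
        baseline <- makeBaselineReplicates(host, k = s$baseline_replicates,
                                           nNni = s$noise_nni,
                                           blSigma = s$noise_bl_sigma,
                                           seed = seed + 3000L)
        list(host = host, tscs = tscs, baselineTrees = baseline)
    } else {
        inp <- cfg$input
        for (f in c("host_tree", "tsc_dir", "baseline_dir"))
            if (is.null(inp[[f]]))
                stop(sprintf("config validation error: missing field 'input.%s'", f),
                     call. = FALSE)
        host <- readNewick(inp$host_tree)
        nwk <- sort(list.files(inp$tsc_dir, "\\.nwk$", full.names = TRUE))
        tscs <- lapply(nwk, function(p) {
            id <- sub("\\.nwk$", "", basename(p))
            assocPath <- file.path(inp$tsc_dir, paste0(id, ".assoc.tsv"))
            if (!file.exists(assocPath))
                stop(sprintf("missing association table for clade '%s'", id),
                     call. = FALSE)
            list(id = id, tree = readNewick(p),
                 assoc = readAssociation(assocPath))
        })
        baseline <- lapply(sort(list.files(inp$baseline_dir, "\\.nwk$",
                                           full.names = TRUE)), readNewick)
        list(host = host, tscs = tscs, baselineTrees = baseline)
    }
}

analyzeTsc <- function(id, host, tree, assoc, baseline, cfg, seed) {
    res <- list()
    if ("paco" %in% cfg$methods)
        res$paco <- pacoTest(host, tree, assoc, nPerm = cfg$n_perm,
                             seed = seed + 1L)
    if ("cid" %in% cfg$methods)
        res$cid <- permutationCongruenceTest(host, tree, assoc, "cid",
                                             nPerm = cfg$n_perm,
                                             seed = seed + 2L)
    if ("nye" %in% cfg$methods)
        res$nye <- permutationCongruenceTest(host, tree, assoc, "nye",
                                             nPerm = cfg$n_perm,
                                             seed = seed + 3L)
    links <- linksFromAssociation(assoc)
    leafMap <- setNames(links$host_id, links$symbiont_id)
    fit <- estimateRatesML(host, tree, leafMap, seed = seed + 4L)
    rate <- transferRate(fit)
    pvals <- vapply(res, pValue, numeric(1))
    out <- data.frame(tsc_id = id, n_links = sum(assoc),
                      stringsAsFactors = FALSE)
    for (m in names(res)) {
        out[[if (m == "paco") "paco_m2" else m]] <- testStatistic(res[[m]])
        out[[paste0(m, "_p")]] <- pValue(res[[m]])
    }
    out$transfer_rate <- rate
    out$baseline_min <- baselineMin(baseline)
    out$baseline_max <- baselineMax(baseline)
    out$classification <- classifyTsc(rate, baseline)
    out$signal_all3 <- length(pvals) == length(cfg$methods) &&
        all(pvals <= cfg$alpha)
    out
}

#' Draw a tanglegram of a host tree, a symbiont tree and their links
#'
#' Face-to-face plot of the two phylogenies with one connecting line per
#' association link; layout is deterministic given the input order.
#'
#' @param host,symb `phylo` trees.
#' @param assoc binary association matrix with at least one link.
#' @param file output file (PDF).
#' @return invisibly, a list with `file` and `nLinks` (the number of
#'   association lines drawn).
#' @export
renderTanglegram <- function(host, symb, assoc, file) {
    validateAssociation(assoc, requireLinks = FALSE)
    if (sum(assoc) == 0) stop("no links", call. = FALSE)
    links <- linksFromAssociation(
        assoc[rowSums(assoc) > 0, colSums(assoc) > 0, drop = FALSE])
    pdf(file, width = 9, height = 6)
    on.exit(dev.off())
    ape::cophyloplot(host, symb, assoc = as.matrix(links),
                     space = 60, gap = 2)
    invisible(list(file = file, nLinks = nrow(links)))
}
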