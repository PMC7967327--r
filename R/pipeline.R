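#' Pipeline run configuration
#'
#' Collects every knob of the end-to-end run. Defaults are the canonical
#' analysis settings: support >= 0.05, confidence >= 0.80, rule lengths up
#' to 5, 5000 bootstrap resamples, family-wise alpha 0.05, adjustment for
#' the first 3 substructure coordinates, deterministic mode imputation.
#'
#' @param simulate a [syntheticCohortConfig()] to simulate the cohort, or
#'   `NULL` to read genotypes from files.
#' @param genotypes,format,variantSpec,phenotypeFile input files when not
#'   simulating: genotype path and dialect, variant spec TSV, and a
#'   phenotype TSV (`subject_id`, `phenotype`).
#' @param phenotypeItem name of the phenotype item.
#' @param imputation `"mode"` or `"iterative_forest"`.
#' @param minSupport,minConfidence,maxRuleLength mining thresholds.
#' @param nBoot bootstrap resamples per rule.
#' @param alpha family-wise error rate.
#' @param nCovariates substructure coordinates to adjust for (0 disables
#'   adjustment).
#' @param assocTop bootstrap-characterize at most this many rules, taken
#'   from the top of the confidence ranking (`Inf` for all); the
#'   Bonferroni family is the set of rules actually tested.
#' @param interactTop decompose interactions for this many top rules by
#'   confidence (3-variant LHS only).
#' @param topK network / item-frequency top-rule count.
#' @param seed master seed for every source of randomness.
#' @return a validated `run_config` list.
#' @export
runConfig <- function(simulate = syntheticCohortConfig(),
                      genotypes = NULL, format = "tsv",
                      variantSpec = NULL, phenotypeFile = NULL,
                      phenotypeItem = "MS",
                      imputation = c("mode", "iterative_forest"),
                      minSupport = 0.05, minConfidence = 0.80,
                      maxRuleLength = 5L, nBoot = 5000L, alpha = 0.05,
                      nCovariates = 3L, assocTop = 50L, interactTop = 1L,
                      topK = 15L, seed = 1L) {
  imputation <- match.arg(imputation)
  if (minSupport <= 0 || minSupport > 1)
    stop("invalid config: minSupport must be in (0, 1]")
  if (minConfidence <= 0 || minConfidence > 1)
    stop("invalid config: minConfidence must be in (0, 1]")
  if (maxRuleLength < 2L) stop("invalid config: maxRuleLength < 2")
  if (nBoot < 2L) stop("invalid config: nBoot < 2")
  if (alpha <= 0 || alpha >= 1) stop("invalid config: alpha")
  if (is.null(simulate) && is.null(genotypes))
    stop("invalid config: either a simulation config or genotype input is required")
  structure(list(simulate = simulate, genotypes = genotypes,
                 format = format, variantSpec = variantSpec,
                 phenotypeFile = phenotypeFile,
                 phenotypeItem = phenotypeItem, imputation = imputation,
                 minSupport = minSupport, minConfidence = minConfidence,
                 maxRuleLength = as.integer(maxRuleLength),
                 nBoot = as.integer(nBoot), alpha = alpha,
                 nCovariates = as.integer(nCovariates),
                 assocTop = if (is.finite(assocTop)) as.integer(assocTop) else Inf,
                 interactTop = as.integer(interactTop),
                 topK = as.integer(topK), seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Scalar fields map 1:1 onto [runConfig()] arguments; a `simulate` block
#' maps onto [syntheticCohortConfig()], with `patterns` given as a list of
#' `{items, jointOddsRatio, marginalOddsRatios}` entries.
#'
#' @param path YAML file.
#' @return a `run_config` list.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(y$simulate)) {
    s <- y$simulate
    pats <- lapply(s$patterns, function(p)
      plantedPattern(p$items, p$jointOddsRatio,
                     if (is.null(p$marginalOddsRatios)) 1.1
                     else p$marginalOddsRatios))
    args <- s[setdiff(names(s), "patterns")]
    args$patterns <- pats
    if (!is.null(args$mafRange)) args$mafRange <- unlist(args$mafRange)
    sim <- do.call(syntheticCohortConfig, args)
  }
  args <- y[setdiff(names(y), "simulate")]
  args$simulate <- sim
  do.call(runConfig, args)
}

.write_manifest <- function(outDir, files, complete, failedStage = NULL) {
  jsonlite::write_json(
    list(complete = complete, failed_stage = failedStage,
         files = as.list(files)),
    file.path(outDir, "MANIFEST.json"), auto_unbox = TRUE)
}

#' Run the full mining pipeline
#'
#' Executes simulate-or-read, imputation, incidence encoding, rule mining,
#' bootstrap association with Bonferroni correction, interaction
#' decomposition of the top rule(s), and rule-set summaries, writing every
#' artifact plus a JSON run report into `outDir`. Any stage failure aborts
#' with the stage name and cause; partial outputs are retained with a
#' MANIFEST marking incompleteness.
#'
#' @param config a `run_config` from [runConfig()] / [readRunConfig()].
#' @param outDir output directory.
#' @param quiet suppress progress messages.
#' @return the run report, invisibly (also written as `report.json`).
#' @export
runPipeline <- function(config, outDir, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  files <- character()
  report <- list(package_version = as.character(utils::packageVersion("genoRules")),
                 seed = config$seed,
                 thresholds = list(minSupport = config$minSupport,
                                   minConfidence = config$minConfidence,
                                   maxRuleLength = config$maxRuleLength,
                                   nBoot = config$nBoot,
                                   alpha = config$alpha,
                                   nCovariates = config$nCovariates))
  say <- function(...) if (!quiet) message("[genoRules] ", ...)
  stage <- "init"
  run_stage <- function(name, expr) {
    stage <<- name
    say("stage: ", name)
    tryCatch(expr, error = function(e) {
      .write_manifest(outDir, files, complete = FALSE, failedStage = name)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  gm <- run_stage("input", {
    if (!is.null(config$simulate)) {
      sim <- config$simulate
      sim$seed <- config$seed
      g <- simulateCohort(sim)
      p <- writeCohort(g, file.path(outDir, "cohort"))
      files <- c(files, p)
      g
    } else {
      spec <- readVariantSpec(config$variantSpec)
      g <- readGenotypes(config$genotypes, config$format, spec)
      ph <- utils::read.delim(config$phenotypeFile)
      y <- ph$phenotype[match(rownames(genotypeCounts(g)), ph$subject_id)]
      SummarizedExperiment::colData(g)$phenotype <- as.integer(y)
      g
    }
  })
  report$n_subjects <- nSubjects(gm)
  report$n_variants <- nrow(gm)
  report$n_cases <- sum(phenotype(gm) == 1L)
  report$n_controls <- sum(phenotype(gm) == 0L)

  gm <- run_stage("impute", {
    report$n_missing <- sum(is.na(SummarizedExperiment::assay(gm, "counts")))
    imputeMissing(gm, method = config$imputation, seed = config$seed)
  })

  covs <- run_stage("substructure", {
    if (config$nCovariates > 0L) {
      cv <- covariates(gm)
      if (is.null(cv) || ncol(cv) < config$nCovariates)
        cv <- computeSubstructure(gm, k = config$nCovariates)
      cv[, seq_len(config$nCovariates), drop = FALSE]
    } else NULL
  })

  I <- run_stage("encode", {
    inc <- encodeIncidence(gm, phenotypeItem = config$phenotypeItem)
    f <- file.path(outDir, "incidence.tsv")
    writeIncidence(inc, f)
    files <- c(files, incidence = f)
    inc
  })

  rs <- run_stage("mine", {
    r <- mineRules(I, minSupport = config$minSupport,
                   minConfidence = config$minConfidence,
                   maxRuleLength = config$maxRuleLength)
    f <- file.path(outDir, "rules.tsv")
    writeRules(r, f)
    files <- c(files, rules = f)
    r
  })
  report$n_rules <- length(rs)

  assoc <- run_stage("associate", {
    if (length(rs)) {
      tested <- rs
      if (length(rs) > config$assocTop) {
        top_rules <- rankRules(rs, "confidence", topK = config$assocTop)
        tested <- RuleSet(top_rules, rs@nSubjects, rs@consequent,
                          rs@params)
      }
      a <- associateRules(I, tested, covariates = covs,
                          nBoot = config$nBoot,
                          seed = config$seed, alpha = config$alpha)
      f <- file.path(outDir, "associations.tsv")
      writeAssociations(a, f)
      files <- c(files, associations = f)
      a
    } else NULL
  })
  if (!is.null(assoc)) {
    report$bonferroni_threshold <- attr(assoc, "bonferroni_threshold")
    report$n_significant <- sum(assoc$significant_bonferroni)
  }

  run_stage("interact", {
    if (length(rs) && config$interactTop > 0L) {
      ranked <- rankRules(rs, "confidence")
      ranked <- ranked[ranked$length == 4L, , drop = FALSE]  # 3-variant LHS
      top <- utils::head(ranked, config$interactTop)
      ints <- lapply(seq_len(nrow(top)), function(i) {
        lhs <- strsplit(top$lhs[i], ";")[[1L]]
        ai <- additiveInteraction(I, lhs, nBoot = min(config$nBoot, 2000L),
                                  seed = config$seed + i)
        mi <- multiplicativeInteraction(I, lhs, covariates = covs,
                                        firth = TRUE)
        list(rule = top$lhs[i],
             stratified_ors = as.list(ai$ors$or),
             reri3 = ai$reri3, ap3 = ai$ap3, ap_p = ai$ap_p,
             mult_or3 = mi$mult_or3, mult_p = mi$mult_p,
             mult_method = mi$method)
      })
      ints <- Filter(Negate(is.null), ints)
      f <- file.path(outDir, "interactions.json")
      jsonlite::write_json(ints, f, auto_unbox = TRUE, digits = NA)
      files <- c(files, interactions = f)
    }
  })

  run_stage("summarize", {
    if (length(rs)) {
      freq <- itemFrequency(rs, topK = config$topK,
                            spec = if (!is.null(config$simulate) ||
                                       is.null(config$variantSpec))
                              variantSpec(gm) else NULL)
      f1 <- file.path(outDir, "item_frequency.tsv")
      utils::write.table(freq, f1, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      g <- rulesNetwork(rs, topK = config$topK)
      p <- writeRulesNetwork(g, file.path(outDir, "network.graphml"),
                             file.path(outDir, "network_edges.tsv"))
      files <- c(files, item_frequency = f1, p)
    }
  })

  report$wall_time_sec <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  f <- file.path(outDir, "report.json")
  jsonlite::write_json(report, f, auto_unbox = TRUE, digits = NA)
  files <- c(files, report = f)
  .write_manifest(outDir, files, complete = TRUE)
  say("done in ", round(report$wall_time_sec, 1), "s; ",
      report$n_rules, " rules")
  invisible(report)
}
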