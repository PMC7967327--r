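#' Planted multi-variant risk pattern
#'
#' Describes a pattern of 2-4 variants whose joint dominant carriers (at
#' least one risk allele at every item) receive an extra odds multiplier
#' for disease, on top of weak per-item marginal effects. This emulates the
#' mined high-risk triads, e.g. a three-variant pattern with joint odds
#' ratio around 20 and near-null marginal effects.
#'
#' @param items character vector of 2-4 distinct variant ids.
#' @param jointOddsRatio positive odds multiplier applied to subjects who
#'   carry at least one risk allele at every item.
#' @param marginalOddsRatios per-item positive odds multipliers for
#'   dominant carriage of each single item (recycled; default 1.1).
#' @return a `planted_pattern` list.
#' @export
plantedPattern <- function(items, jointOddsRatio,
                           marginalOddsRatios = 1.1) {
  items <- as.character(items)
  if (anyDuplicated(items)) stop("pattern items must be distinct")
  if (length(items) < 2L || length(items) > 4L)
    stop("pattern must contain 2-4 items")
  if (!is.numeric(jointOddsRatio) || jointOddsRatio <= 0)
    stop("jointOddsRatio must be a positive real")
  marginalOddsRatios <- rep_len(marginalOddsRatios, length(items))
  if (any(marginalOddsRatios <= 0))
    stop("marginalOddsRatios must be positive")
  structure(list(items = items, jointOddsRatio = jointOddsRatio,
                 marginalOddsRatios = marginalOddsRatios),
            class = "planted_pattern")
}

#' Synthetic case-control cohort configuration
#'
#' Defaults reproduce the structure of a modestly sized MS case-control
#' study: 207 cases and 179 controls, 196 common biallelic risk variants
#' with MAF drawn uniformly from `mafRange`, one planted three-variant
#' pattern with joint odds ratio 20 and weak (1.1) marginal effects, mild
#' two-group population substructure, and ~1.3% missingness confined to a
#' handful of variants.
#'
#' @param nCases,nControls positive integers; sampled exactly.
#' @param nVariants number of biallelic variants.
#' @param mafRange interval in (0, 0.5] from which per-variant minor
#'   (risk) allele frequencies are drawn uniformly.
#' @param baselinePrevalence baseline disease probability for a
#'   non-carrier in the reference substructure group.
#' @param patterns list of [plantedPattern()] objects (may be empty).
#' @param nSubstructureDims number of MDS-like covariate columns returned.
#' @param substructureEffect log-odds shift of disease between the two
#'   latent substructure groups.
#' @param missingRate per-genotype missing probability on the affected
#'   variants (at most 0.05).
#' @param nMissingVariants number of variants carrying missingness.
#' @param seed integer governing all randomness.
#' @return a `cohort_config` list.
#' @export
syntheticCohortConfig <- function(nCases = 207L, nControls = 179L,
                                  nVariants = 196L,
                                  mafRange = c(0.05, 0.40),
                                  baselinePrevalence = 0.30,
                                  patterns = list(
                                    plantedPattern(c("v001", "v002", "v003"),
                                                   jointOddsRatio = 20)),
                                  nSubstructureDims = 3L,
                                  substructureEffect = 0.5,
                                  missingRate = 0.013,
                                  nMissingVariants = 7L,
                                  seed = 1L) {
  stopifnot(nCases >= 1L, nControls >= 1L, nVariants >= 1L)
  if (mafRange[1] <= 0 || mafRange[2] > 0.5 || mafRange[1] > mafRange[2])
    stop("mafRange must be an interval within (0, 0.5]")
  if (baselinePrevalence <= 0 || baselinePrevalence >= 1)
    stop("baselinePrevalence must be in (0, 1)")
  if (missingRate < 0 || missingRate > 0.05)
    stop("missingRate must be in [0, 0.05]")
  ids <- sprintf("v%03d", seq_len(nVariants))
  for (p in patterns) {
    if (!inherits(p, "planted_pattern")) stop("patterns must be plantedPattern objects")
    if (!all(p$items %in% ids))
      stop("pattern items must be a subset of the cohort's variant ids")
  }
  structure(list(nCases = as.integer(nCases),
                 nControls = as.integer(nControls),
                 nVariants = as.integer(nVariants),
                 variantIds = ids, mafRange = mafRange,
                 baselinePrevalence = baselinePrevalence,
                 patterns = patterns,
                 nSubstructureDims = as.integer(nSubstructureDims),
                 substructureEffect = substructureEffect,
                 missingRate = missingRate,
                 nMissingVariants = as.integer(nMissingVariants),
                 seed = as.integer(seed)),
            class = "cohort_config")
}

.default_variant_spec <- function(ids) {
  n <- length(ids)
  data.frame(variant_id = ids,
             chromosome = as.character(1L + (seq_len(n) - 1L) %% 22L),
             position = 1e6L + 1000L * seq_len(n),
             gene = paste0("GENE", seq_len(n)),
             risk_allele = "A",
             mode = "presence",
             stringsAsFactors = FALSE)
}

#' Simulate a case-control cohort with planted risk patterns
#'
#' Genotypes are drawn per-variant from Hardy-Weinberg proportions at a MAF
#' sampled uniformly from the configured range; a latent two-group
#' substructure shifts allele frequencies on the logit scale. Disease is
#' assigned from a logistic liability: logit of the baseline prevalence,
#' plus each pattern item's marginal log-odds when the subject carries at
#' least one risk allele at that item, plus the pattern's joint log-odds
#' when the subject carries risk alleles at every item, plus the
#' substructure term. A subject pool is oversampled until both groups can
#' be filled, then exactly `nCases` cases and `nControls` controls are
#' drawn without replacement.
#'
#' The realized per-pattern carrier counts (computed before missingness is
#' injected) are stored with the configuration in `cohortTruth()`.
#'
#' @param config a [syntheticCohortConfig()] object.
#' @param maxPoolFactor oversampling cap: the pool grows to at most
#'   `maxPoolFactor * (nCases + nControls)` subjects before simulation
#'   fails with an explicit infeasibility error.
#' @return a [GenotypeMatrix-class] with phenotype and covariates in
#'   `colData` and the truth record in `metadata`.
#' @export
simulateCohort <- function(config, maxPoolFactor = 60) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n_target <- config$nCases + config$nControls
  ids <- config$variantIds
  maf <- stats::runif(config$nVariants, config$mafRange[1], config$mafRange[2])
  ## latent 2-group substructure: per-variant logit-scale frequency
  ## shifts; nSubstructureDims = 0 disables the latent group entirely
  ## (homogeneous HWE population)
  has_sub <- config$nSubstructureDims > 0L
  shift <- if (has_sub) stats::rnorm(config$nVariants, 0, 0.2) else
    numeric(config$nVariants)
  maf2 <- stats::plogis(stats::qlogis(maf) + shift)

  pat_items <- lapply(config$patterns, function(p)
    match(p$items, ids))
  marg_lor <- numeric(config$nVariants)
  for (k in seq_along(config$patterns)) {
    p <- config$patterns[[k]]
    marg_lor[pat_items[[k]]] <- marg_lor[pat_items[[k]]] +
      log(p$marginalOddsRatios)
  }
  b0 <- stats::qlogis(config$baselinePrevalence)

  draw_batch <- function(m) {
    grp <- if (has_sub) stats::rbinom(m, 1L, 0.5) else integer(m)
    f <- rbind(maf, maf2)[grp + 1L, , drop = FALSE]   # m x nVariants
    g <- matrix(stats::rbinom(m * config$nVariants, 2L, as.vector(f)),
                nrow = m)
    carrier <- g >= 1L
    lp <- b0 + carrier %*% marg_lor +
      config$substructureEffect * (grp - 0.5)
    for (k in seq_along(config$patterns)) {
      joint <- rowSums(carrier[, pat_items[[k]], drop = FALSE]) ==
        length(pat_items[[k]])
      lp <- lp + joint * log(config$patterns[[k]]$jointOddsRatio)
    }
    y <- stats::rbinom(m, 1L, stats::plogis(as.vector(lp)))
    list(g = g, y = y, grp = grp)
  }

  g_all <- NULL; y_all <- integer(); grp_all <- integer()
  batch <- max(2L * n_target, 500L)
  while (sum(y_all == 1L) < config$nCases ||
         sum(y_all == 0L) < config$nControls) {
    if (length(y_all) + batch > maxPoolFactor * n_target) {
      short <- if (sum(y_all == 1L) < config$nCases) "nCases" else "nControls"
      stop("simulateCohort: cannot satisfy ", short,
           " at the oversampling cap; baselinePrevalence = ",
           config$baselinePrevalence, " yields too few such subjects")
    }
    b <- draw_batch(batch)
    g_all <- rbind(g_all, b$g)
    y_all <- c(y_all, b$y)
    grp_all <- c(grp_all, b$grp)
  }
  take <- c(sample(which(y_all == 1L), config$nCases),
            sample(which(y_all == 0L), config$nControls))
  take <- sample(take)                       # shuffle subject order
  g <- g_all[take, , drop = FALSE]
  y <- y_all[take]
  grp <- grp_all[take]
  rownames(g) <- sprintf("S%04d", seq_len(n_target))

  # MDS-like covariates: dim 1 tracks the latent group, the rest are noise
  k <- config$nSubstructureDims
  cov <- NULL
  if (k > 0L) {
    cov <- matrix(stats::rnorm(n_target * k), n_target, k)
    cov[, 1L] <- scale(grp + stats::rnorm(n_target, 0, 0.3))[, 1L]
    colnames(cov) <- paste0("MDS", seq_len(k))
  }

  # realized pattern carrier counts from complete genotypes
  carrier <- g >= 1L
  truth_counts <- lapply(seq_along(config$patterns), function(kk) {
    joint <- rowSums(carrier[, pat_items[[kk]], drop = FALSE]) ==
      length(pat_items[[kk]])
    list(items = config$patterns[[kk]]$items,
         carriers_cases = sum(joint & y == 1L),
         carriers_controls = sum(joint & y == 0L))
  })

  gm <- GenotypeMatrix(g, .default_variant_spec(ids), phenotype = y,
                       covariates = cov)
  if (config$missingRate > 0 && config$nMissingVariants > 0L) {
    affected <- sample(config$nVariants,
                       min(config$nMissingVariants, config$nVariants))
    gm <- injectMissing(gm, config$missingRate,
                        seed = config$seed + 10000L, variants = affected)
  }
  S4Vectors::metadata(gm)$truth <- list(
    config = config, maf = maf,
    latentGroup = grp,
    patternCounts = truth_counts)
  gm
}

#' Build an exact incidence fixture from prescribed cell counts
#'
#' Constructs a deterministic [IncidenceMatrix-class] in which prescribed
#' numbers of cases and controls carry given item combinations, so that
#' itemset counts printed in published tables can be reproduced exactly
#' (e.g. a pattern carried by 21 of 386 subjects, 20 of them cases).
#'
#' @param nCases,nControls group sizes.
#' @param cells data.frame with columns `items` (semicolon-joined item ids;
#'   `""` for the no-item profile), `cases`, `controls`. Subjects not
#'   covered by any row carry no items.
#' @param items optional character vector fixing the full item vocabulary
#'   (defaults to the union of items in `cells`).
#' @param phenotypeItem name of the phenotype item appended as last column.
#' @return an [IncidenceMatrix-class].
#' @export
exactFixture <- function(nCases, nControls, cells, items = NULL,
                         phenotypeItem = "MS") {
  cells <- as.data.frame(cells, stringsAsFactors = FALSE)
  stopifnot(all(c("items", "cases", "controls") %in% colnames(cells)))
  item_lists <- strsplit(cells$items, ";", fixed = TRUE)
  if (is.null(items)) items <- sort(unique(unlist(item_lists)))
  if (phenotypeItem %in% items)
    stop("phenotypeItem must not appear among the carried items")
  for (i in seq_len(nrow(cells))) {
    bad <- setdiff(item_lists[[i]], items)
    if (length(bad))
      stop("profile '", cells$items[i], "' uses unknown item(s): ",
           paste(bad, collapse = ", "))
  }
  if (sum(cells$cases) > nCases)
    stop("prescribed case counts exceed nCases (offending total ",
         sum(cells$cases), " > ", nCases, ")")
  if (sum(cells$controls) > nControls)
    stop("prescribed control counts exceed nControls (offending total ",
         sum(cells$controls), " > ", nControls, ")")
  n <- nCases + nControls
  X <- matrix(FALSE, n, length(items) + 1L,
              dimnames = list(sprintf("S%04d", seq_len(n)),
                              c(items, phenotypeItem)))
  X[seq_len(nCases), phenotypeItem] <- TRUE
  next_case <- 1L; next_ctrl <- nCases + 1L
  for (i in seq_len(nrow(cells))) {
    prof <- item_lists[[i]]
    if (cells$cases[i] > 0L) {
      rows <- next_case:(next_case + cells$cases[i] - 1L)
      X[rows, prof] <- TRUE
      next_case <- next_case + cells$cases[i]
    }
    if (cells$controls[i] > 0L) {
      rows <- next_ctrl:(next_ctrl + cells$controls[i] - 1L)
      X[rows, prof] <- TRUE
      next_ctrl <- next_ctrl + cells$controls[i]
    }
  }
  IncidenceMatrix(X, phenotypeItem)
}

#' Inject missing genotype codes completely at random
#'
#' @param x a [GenotypeMatrix-class].
#' @param rate per-genotype missing probability in `[0, 1]`.
#' @param seed integer seed.
#' @param variants optional variant indices or ids restricting which
#'   variants receive missingness (default: all).
#' @return the GenotypeMatrix with the selected genotypes set to `NA`.
#' @export
injectMissing <- function(x, rate, seed = 1L, variants = NULL) {
  stopifnot(is(x, "GenotypeMatrix"), rate >= 0, rate <= 1)
  if (rate == 0) return(x)
  cnt <- SummarizedExperiment::assay(x, "counts")   # variants x subjects
  if (is.null(variants)) variants <- seq_len(nrow(cnt))
  if (is.character(variants)) variants <- match(variants, rownames(cnt))
  set.seed(seed)
  mask <- matrix(stats::runif(length(variants) * ncol(cnt)) < rate,
                 nrow = length(variants))
  sub <- cnt[variants, , drop = FALSE]
  sub[mask] <- NA_integer_
  cnt[variants, ] <- sub
  SummarizedExperiment::assay(x, "counts") <- cnt
  x
}

#' Write a simulated cohort to plain-text files
#'
#' Writes genotypes as both a minimal VCF (GT subfield, `./.` for missing)
#' and the TSV dialect (subjects in rows, 0/1/2/NA), the phenotype and
#' covariates as TSV, the variant spec as TSV, and the truth record as
#' JSON.
#'
#' @param x a [GenotypeMatrix-class], typically from [simulateCohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
writeCohort <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  spec <- variantSpec(x)
  g <- genotypeCounts(x)
  paths <- c(vcf = file.path(dir, "genotypes.vcf"),
             tsv = file.path(dir, "genotypes.tsv"),
             spec = file.path(dir, "variants.tsv"),
             phenotype = file.path(dir, "phenotype.tsv"),
             covariates = file.path(dir, "covariates.tsv"),
             truth = file.path(dir, "truth.json"))
  ## VCF: risk allele as ALT, reference allele "C"; GT from risk count
  gt_codes <- c("0/0", "0/1", "1/1")
  lines <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", rownames(g)), collapse = "\t"))
  body <- vapply(seq_len(nrow(spec)), function(j) {
    gj <- g[, j]
    gt <- ifelse(is.na(gj), "./.", gt_codes[gj + 1L])
    paste(c(spec$chromosome[j], spec$position[j], spec$variant_id[j],
            "C", spec$risk_allele[j], ".", "PASS", ".", "GT", gt),
          collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), paths["vcf"])
  utils::write.table(data.frame(subject_id = rownames(g), g,
                                check.names = FALSE),
                     paths["tsv"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(spec, paths["spec"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ph <- phenotype(x)
  if (!is.null(ph))
    utils::write.table(data.frame(subject_id = names(ph), phenotype = ph),
                       paths["phenotype"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  cv <- covariates(x)
  if (!is.null(cv))
    utils::write.table(data.frame(subject_id = rownames(g), cv),
                       paths["covariates"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  tr <- cohortTruth(x)
  if (!is.null(tr)) {
    tr$config$patterns <- lapply(tr$config$patterns, unclass)
    tr$config <- unclass(tr$config)
    jsonlite::write_json(tr, paths["truth"], auto_unbox = TRUE, digits = NA)
  }
  invisible(paths)
}
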