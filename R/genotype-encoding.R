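#' Read a variant specification table
#'
#' TSV with the six columns `variant_id`, `chromosome`, `position`,
#' `gene`, `risk_allele`, `mode`.
#'
#' @param path file path.
#' @return data.frame of variant specifications.
#' @export
readVariantSpec <- function(path) {
  spec <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character")
  missing_cols <- setdiff(.SPEC_COLUMNS, colnames(spec))
  if (length(missing_cols))
    stop("variant spec lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  spec$position <- as.integer(spec$position)
  if (anyDuplicated(spec$variant_id))
    stop("variant_id values must be unique in a spec table")
  if (!all(spec$mode %in% c("presence", "absence")))
    stop("mode must be 'presence' or 'absence'")
  spec[, .SPEC_COLUMNS]
}

#' Read genotypes into a GenotypeMatrix
#'
#' Supported dialects: VCF (GT subfield only; counts oriented to the
#' spec's risk allele, flipping when the risk allele is REF), PLINK `.raw`
#' additive-count export (header row with `IID` and `SNP_ALLELE` columns;
#' counts flipped to `2 - x` when the counted allele differs from the risk
#' allele), and plain TSV (first column subject id, one column per variant
#' holding risk-allele counts 0/1/2/NA).
#'
#' Spec variants absent from the file are collected into a structured
#' report stored in `metadata(x)$readReport` (never silently dropped); a
#' VCF variant whose risk allele matches neither REF nor ALT is a hard
#' error naming the variant.
#'
#' @param path input file.
#' @param format one of `"vcf"`, `"plink_raw"`, `"tsv"`.
#' @param spec variant specification data.frame (see [readVariantSpec()]).
#' @return a [GenotypeMatrix-class] covering the spec variants found, with
#'   `metadata(x)$readReport$missingVariants` listing absent ones.
#' @export
readGenotypes <- function(path, format = c("vcf", "plink_raw", "tsv"),
                          spec) {
  format <- match.arg(format)
  spec <- as.data.frame(spec, stringsAsFactors = FALSE)
  g <- switch(format,
              vcf = .read_vcf_counts(path, spec),
              plink_raw = .read_plink_raw_counts(path, spec),
              tsv = .read_tsv_counts(path, spec))
  found <- colnames(g)
  absent <- setdiff(spec$variant_id, found)
  gm <- GenotypeMatrix(g, spec[match(found, spec$variant_id), ])
  S4Vectors::metadata(gm)$readReport <-
    list(format = format, nFound = length(found),
         missingVariants = absent)
  gm
}

.read_vcf_counts <- function(path, spec) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  idx <- match(spec$variant_id, fix$ID)
  keep <- which(!is.na(idx))
  counts <- matrix(NA_integer_, ncol(gt), length(keep),
                   dimnames = list(colnames(gt), spec$variant_id[keep]))
  for (j in seq_along(keep)) {
    i <- idx[keep[j]]
    risk <- spec$risk_allele[keep[j]]
    if (risk == fix$ALT[i]) flip <- FALSE
    else if (risk == fix$REF[i]) flip <- TRUE
    else stop("risk allele '", risk, "' of variant ",
              spec$variant_id[keep[j]], " matches neither REF (",
              fix$REF[i], ") nor ALT (", fix$ALT[i], ")")
    alleles <- strsplit(gsub("\\|", "/", gt[i, ]), "/", fixed = TRUE)
    cnt <- vapply(alleles, function(a) {
      if (any(a == ".") || length(a) != 2L) return(NA_integer_)
      sum(a == "1")
    }, integer(1))
    counts[, j] <- if (flip) 2L - cnt else cnt
  }
  counts
}

.read_plink_raw_counts <- function(path, spec) {
  raw <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE)
  snp_cols <- setdiff(colnames(raw),
                      c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE"))
  ids <- sub("_[^_]*$", "", snp_cols)
  counted <- sub("^.*_", "", snp_cols)
  idx <- match(spec$variant_id, ids)
  keep <- which(!is.na(idx))
  counts <- matrix(NA_integer_, nrow(raw), length(keep),
                   dimnames = list(raw$IID, spec$variant_id[keep]))
  for (j in seq_along(keep)) {
    x <- as.integer(raw[[snp_cols[idx[keep[j]]]]])
    if (counted[idx[keep[j]]] != spec$risk_allele[keep[j]])
      x <- 2L - x
    counts[, j] <- x
  }
  counts
}

.read_tsv_counts <- function(path, spec) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  ids <- tab[[1L]]
  tab <- tab[, -1L, drop = FALSE]
  keep <- intersect(spec$variant_id, colnames(tab))
  counts <- as.matrix(tab[, keep, drop = FALSE])
  storage.mode(counts) <- "integer"
  rownames(counts) <- ids
  counts
}

#' Impute residual missing genotypes
#'
#' `method = "mode"` replaces each missing value by the variant's most
#' frequent observed code (deterministic; ties broken toward the smaller
#' code). `method = "iterative_forest"` starts from the mode fill and
#' iteratively re-predicts each incomplete variant from all other variants
#' with a random forest classifier until the imputed values stop changing
#' (in the spirit of chained random-forest single imputation).
#'
#' @param x a [GenotypeMatrix-class].
#' @param method `"mode"` or `"iterative_forest"`.
#' @param seed integer seed (forests only).
#' @param maxMissing per-variant missingness ceiling (proportion) above
#'   which imputation refuses to proceed.
#' @param maxIter maximum forest sweeps.
#' @return the GenotypeMatrix with no missing codes.
#' @export
imputeMissing <- function(x, method = c("mode", "iterative_forest"),
                          seed = 1L, maxMissing = 0.05, maxIter = 10L) {
  method <- match.arg(method)
  stopifnot(is(x, "GenotypeMatrix"))
  cnt <- SummarizedExperiment::assay(x, "counts")   # variants x subjects
  miss_frac <- rowMeans(is.na(cnt))
  if (any(miss_frac == 1))
    stop("variant(s) with all values missing: ",
         paste(rownames(cnt)[miss_frac == 1], collapse = ", "))
  if (any(miss_frac > maxMissing))
    stop("per-variant missingness exceeds ceiling (", maxMissing, ") for: ",
         paste(rownames(cnt)[miss_frac > maxMissing], collapse = ", "))
  if (!anyNA(cnt)) return(x)

  mode_fill <- function(v) {
    tab <- tabulate(v[!is.na(v)] + 1L, nbins = 3L)
    which.max(tab) - 1L       # ties -> smaller code
  }
  filled <- cnt
  for (i in which(miss_frac > 0))
    filled[i, is.na(cnt[i, ])] <- mode_fill(cnt[i, ])

  if (method == "iterative_forest") {
    set.seed(seed)
    incomplete <- which(miss_frac > 0)
    subj <- t(filled)                       # subjects x variants
    for (iter in seq_len(maxIter)) {
      changed <- 0L
      for (i in incomplete) {
        mask <- is.na(cnt[i, ])
        df <- data.frame(subj[, -i, drop = FALSE], check.names = TRUE)
        df$.y <- factor(subj[, i], levels = 0:2)
        fit <- ranger::ranger(.y ~ ., data = df[!mask, , drop = FALSE],
                              num.trees = 100L,
                              seed = seed + i,
                              respect.unordered.factors = TRUE)
        pred <- stats::predict(fit, df[mask, , drop = FALSE])$predictions
        new_vals <- as.integer(as.character(pred))
        changed <- changed + sum(new_vals != subj[mask, i])
        subj[mask, i] <- new_vals
      }
      if (changed == 0L) break
    }
    filled <- t(subj)
  }
  SummarizedExperiment::assay(x, "counts") <- filled
  x
}

#' Encode the binary incidence matrix (dominant model)
#'
#' One boolean item per variant: for presence-mode variants the item is
#' `TRUE` when the subject carries at least one risk allele (dominant
#' model); for absence-mode variants (e.g. a protective HLA allele whose
#' absence confers risk) the item is `TRUE` when the subject carries zero
#' copies. The phenotype is appended as the final item.
#'
#' @param x a complete (imputed) [GenotypeMatrix-class].
#' @param phenotype binary vector (1 = case); defaults to `phenotype(x)`.
#' @param phenotypeItem name for the phenotype item.
#' @return an [IncidenceMatrix-class].
#' @export
encodeIncidence <- function(x, phenotype = NULL, phenotypeItem = "MS") {
  stopifnot(is(x, "GenotypeMatrix"))
  g <- genotypeCounts(x)                    # subjects x variants
  if (anyNA(g))
    stop("genotypes contain missing codes; run imputeMissing() first")
  if (is.null(phenotype)) phenotype <- phenotype(x)
  if (is.null(phenotype))
    stop("no phenotype available; supply the 'phenotype' argument")
  if (length(phenotype) != nrow(g))
    stop("phenotype length must equal the number of subjects")
  spec <- variantSpec(x)
  inc <- g >= 1L
  absent <- spec$mode == "absence"
  if (any(absent)) inc[, absent] <- g[, absent] == 0L
  inc <- cbind(inc, as.logical(phenotype))
  colnames(inc) <- c(spec$variant_id, phenotypeItem)
  rownames(inc) <- rownames(g)
  IncidenceMatrix(inc, phenotypeItem)
}

#' Substructure covariates by classical multidimensional scaling
#'
#' Computes principal coordinates (classical metric MDS) of the pairwise
#' allele-sharing distance, defined as 1 minus the proportion of alleles
#' identical by state, i.e. `mean(|g_i - g_j|) / 2` over variants. The
#' sign of each coordinate is fixed so that its largest-magnitude loading
#' is positive.
#'
#' @param x a complete [GenotypeMatrix-class].
#' @param k number of coordinates to return (must be below the subject
#'   count).
#' @return numeric matrix, subjects x `k`, columns `MDS1..MDSk`.
#' @export
computeSubstructure <- function(x, k = 3L) {
  stopifnot(is(x, "GenotypeMatrix"), k >= 1L)
  g <- genotypeCounts(x)
  if (anyNA(g)) stop("genotypes contain missing codes; impute first")
  n <- nrow(g)
  if (k >= n) stop("k must be smaller than the subject count")
  d <- stats::dist(g, method = "manhattan") / (2 * ncol(g))
  mds <- stats::cmdscale(d, k = k)
  if (ncol(mds) < k) {       # degenerate geometry: pad with zeros
    mds <- cbind(mds, matrix(0, n, k - ncol(mds)))
  }
  for (j in seq_len(k)) {
    top <- which.max(abs(mds[, j]))
    if (mds[top, j] < 0) mds[, j] <- -mds[, j]
  }
  colnames(mds) <- paste0("MDS", seq_len(k))
  rownames(mds) <- rownames(g)
  mds
}

#' Write / read an incidence matrix as 0/1 TSV
#'
#' First column `subject_id`, one 0/1 column per item.
#'
#' @param x an [IncidenceMatrix-class].
#' @param path file path.
#' @return `writeIncidence` invisibly returns `path`; `readIncidence`
#'   returns the reconstructed [IncidenceMatrix-class].
#' @export
writeIncidence <- function(x, path) {
  inc <- incidence(x)
  df <- data.frame(subject_id = rownames(inc), inc * 1L,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeIncidence
#' @param phenotypeItem phenotype column name in the file.
#' @export
readIncidence <- function(path, phenotypeItem = "MS") {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  ids <- tab[[1L]]
  m <- as.matrix(tab[, -1L, drop = FALSE]) == 1
  rownames(m) <- ids
  IncidenceMatrix(m, phenotypeItem)
}
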