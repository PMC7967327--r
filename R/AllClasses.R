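#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

.SPEC_COLUMNS <- c("variant_id", "chromosome", "position", "gene",
                   "risk_allele", "mode")

#' GenotypeMatrix: subjects-by-variants risk-allele counts
#'
#' An S4 container for case-control genotype data, stored as a
#' [SummarizedExperiment::SummarizedExperiment] with variants as rows and
#' subjects as columns. The `"counts"` assay holds risk-allele counts
#' (0, 1, 2 or `NA` for missing); `rowData` carries the variant
#' specification (id, chromosome, hg19 position, gene label, risk allele,
#' and encoding mode `"presence"` or `"absence"`); `colData` may carry the
#' binary phenotype and substructure covariates.
#'
#' Positions are metadata only and never enter any computation.
#'
#' @name GenotypeMatrix-class
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix", contains = "SummarizedExperiment")

setValidity("GenotypeMatrix", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    cnt <- SummarizedExperiment::assay(object, "counts")
    bad <- !(is.na(cnt) | cnt %in% c(0L, 1L, 2L))
    if (any(bad))
      msg <- c(msg, "genotype counts must be 0, 1, 2 or NA")
  }
  rd <- SummarizedExperiment::rowData(object)
  missing_cols <- setdiff(.SPEC_COLUMNS, colnames(rd))
  if (length(missing_cols))
    msg <- c(msg, paste0("rowData lacks variant spec column(s): ",
                         paste(missing_cols, collapse = ", ")))
  else {
    if (anyDuplicated(rd$variant_id))
      msg <- c(msg, "variant_id values must be unique")
    if (!all(rd$mode %in% c("presence", "absence")))
      msg <- c(msg, "mode must be 'presence' or 'absence'")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param counts integer matrix of risk-allele counts with subjects in rows
#'   and variants in columns (the orientation of the TSV genotype dialect);
#'   values 0/1/2/NA. Stored internally with variants as rows.
#' @param variantSpec data.frame with columns `variant_id`, `chromosome`,
#'   `position`, `gene`, `risk_allele`, `mode`; one row per column of
#'   `counts`, in order.
#' @param phenotype optional binary vector (1 = case), one per subject.
#' @param covariates optional numeric matrix of substructure covariates,
#'   subjects in rows.
#' @return a [GenotypeMatrix-class] object.
#' @export
GenotypeMatrix <- function(counts, variantSpec, phenotype = NULL,
                           covariates = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("S", seq_len(nrow(counts)))
  variantSpec <- as.data.frame(variantSpec, stringsAsFactors = FALSE)
  if (nrow(variantSpec) != ncol(counts))
    stop("variantSpec must have one row per variant column of 'counts'")
  storage.mode(counts) <- "integer"
  colnames(counts) <- variantSpec$variant_id
  cd <- S4Vectors::DataFrame(row.names = rownames(counts))
  if (!is.null(phenotype)) {
    if (length(phenotype) != nrow(counts))
      stop("phenotype length must equal the number of subjects")
    cd$phenotype <- as.integer(phenotype)
  }
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != nrow(counts))
      stop("covariates must have one row per subject")
    if (is.null(colnames(covariates)))
      colnames(covariates) <- paste0("MDS", seq_len(ncol(covariates)))
    for (j in seq_len(ncol(covariates)))
      cd[[colnames(covariates)[j]]] <- covariates[, j]
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = t(counts)),
    rowData = S4Vectors::DataFrame(variantSpec, row.names = variantSpec$variant_id),
    colData = cd)
  new("GenotypeMatrix", se)
}

#' IncidenceMatrix: subjects-by-items binary transaction matrix
#'
#' Binary incidence matrix for rule mining: one boolean item per variant
#' (dominant model; `TRUE` when the subject carries at least one risk
#' allele, or zero copies for absence-mode items) plus exactly one
#' phenotype item.
#'
#' @name IncidenceMatrix-class
#' @exportClass IncidenceMatrix
setClass("IncidenceMatrix",
         slots = c(incidence = "matrix", phenotypeItem = "character"))

setValidity("IncidenceMatrix", function(object) {
  msg <- character()
  x <- object@incidence
  if (!is.logical(x)) msg <- c(msg, "incidence must be a logical matrix")
  if (is.null(colnames(x)) || anyDuplicated(colnames(x)))
    msg <- c(msg, "item ids (colnames) must be present and unique")
  if (any(is.na(x))) msg <- c(msg, "incidence cells must not be NA")
  if (length(object@phenotypeItem) != 1L ||
      !(object@phenotypeItem %in% colnames(x)))
    msg <- c(msg, "exactly one phenotype item must name a column")
  if (length(msg)) msg else TRUE
})

#' Construct an IncidenceMatrix
#'
#' @param incidence logical matrix, subjects in rows, items in columns
#'   (named); must include the phenotype item.
#' @param phenotypeItem name of the single phenotype column.
#' @return an [IncidenceMatrix-class] object.
#' @export
IncidenceMatrix <- function(incidence, phenotypeItem = "MS") {
  incidence <- as.matrix(incidence)
  if (!is.logical(incidence)) {
    stopifnot(all(incidence %in% c(0, 1)))
    storage.mode(incidence) <- "logical"
  }
  if (is.null(rownames(incidence)))
    rownames(incidence) <- paste0("S", seq_len(nrow(incidence)))
  new("IncidenceMatrix", incidence = incidence, phenotypeItem = phenotypeItem)
}

#' RuleSet: mined association rules with a fixed disease consequent
#'
#' Holds one row per rule with columns `lhs` (semicolon-joined, sorted item
#' ids), `rhs`, `length` (LHS size + 1), `lhs_count`, `joint_count`,
#' `rhs_count`, `support`, `confidence`, `lift`, together with the mining
#' parameters and cohort size.
#'
#' @name RuleSet-class
#' @exportClass RuleSet
setClass("RuleSet",
         slots = c(rules = "data.frame", nSubjects = "integer",
                   consequent = "character", params = "list"))

.RULE_COLUMNS <- c("lhs", "rhs", "length", "lhs_count", "joint_count",
                   "rhs_count", "support", "confidence", "lift")

setValidity("RuleSet", function(object) {
  msg <- character()
  if (!all(.RULE_COLUMNS %in% colnames(object@rules)))
    msg <- c(msg, paste0("rules must have columns: ",
                         paste(.RULE_COLUMNS, collapse = ", ")))
  else if (nrow(object@rules)) {
    r <- object@rules
    if (any(r$support > r$confidence + 1e-12))
      msg <- c(msg, "support must not exceed confidence")
    if (any(r$support < 0 | r$confidence > 1))
      msg <- c(msg, "support/confidence out of [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname RuleSet-class
#' @param rules rule data.frame (see above), e.g. a ranked subset.
#' @param nSubjects cohort size the metrics refer to.
#' @param consequent the RHS item.
#' @param params list of mining parameters.
#' @export
RuleSet <- function(rules, nSubjects, consequent, params = list()) {
  new("RuleSet", rules = rules, nSubjects = as.integer(nSubjects),
      consequent = consequent, params = params)
}
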