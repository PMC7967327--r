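#' @rdname GenotypeMatrix-class
#' @param x a GenotypeMatrix or IncidenceMatrix.
#' @export
setGeneric("genotypeCounts", function(x) standardGeneric("genotypeCounts"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("variantSpec", function(x) standardGeneric("variantSpec"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("phenotype", function(x) standardGeneric("phenotype"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("covariates", function(x) standardGeneric("covariates"))

#' @rdname GenotypeMatrix-class
#' @export
setGeneric("cohortTruth", function(x) standardGeneric("cohortTruth"))

#' @rdname IncidenceMatrix-class
#' @param x an IncidenceMatrix.
#' @export
setGeneric("incidence", function(x) standardGeneric("incidence"))

#' @rdname IncidenceMatrix-class
#' @export
setGeneric("itemIds", function(x) standardGeneric("itemIds"))

#' @rdname IncidenceMatrix-class
#' @export
setGeneric("phenotypeItem", function(x) standardGeneric("phenotypeItem"))

#' @rdname IncidenceMatrix-class
#' @export
setGeneric("nSubjects", function(x) standardGeneric("nSubjects"))

#' @rdname RuleSet-class
#' @param x a RuleSet.
#' @export
setGeneric("ruleTable", function(x) standardGeneric("ruleTable"))

## ---- methods ----

#' @rdname GenotypeMatrix-class
#' @export
setMethod("genotypeCounts", "GenotypeMatrix", function(x)
  t(SummarizedExperiment::assay(x, "counts")))

#' @rdname GenotypeMatrix-class
#' @export
setMethod("variantSpec", "GenotypeMatrix", function(x)
  as.data.frame(SummarizedExperiment::rowData(x))[, .SPEC_COLUMNS])

#' @rdname GenotypeMatrix-class
#' @export
setMethod("phenotype", "GenotypeMatrix", function(x) {
  cd <- SummarizedExperiment::colData(x)
  if (!"phenotype" %in% colnames(cd)) return(NULL)
  stats::setNames(cd$phenotype, rownames(cd))
})

#' @rdname GenotypeMatrix-class
#' @export
setMethod("covariates", "GenotypeMatrix", function(x) {
  cd <- SummarizedExperiment::colData(x)
  keep <- grep("^MDS", colnames(cd), value = TRUE)
  if (!length(keep)) return(NULL)
  as.matrix(as.data.frame(cd[, keep, drop = FALSE]))
})

#' @rdname GenotypeMatrix-class
#' @export
setMethod("cohortTruth", "GenotypeMatrix", function(x)
  S4Vectors::metadata(x)$truth)

#' @rdname GenotypeMatrix-class
#' @export
setMethod("nSubjects", "GenotypeMatrix", function(x) ncol(x))

setMethod("show", "GenotypeMatrix", function(object) {
  cnt <- SummarizedExperiment::assay(object, "counts")
  cat("GenotypeMatrix:", ncol(object), "subjects x", nrow(object),
      "variants\n")
  ph <- phenotype(object)
  if (!is.null(ph))
    cat("  phenotype: ", sum(ph == 1L), " cases / ", sum(ph == 0L),
        " controls\n", sep = "")
  nm <- sum(is.na(cnt))
  cat("  missing genotypes: ", nm, " (",
      format(100 * nm / length(cnt), digits = 3), "%)\n", sep = "")
})

#' @rdname IncidenceMatrix-class
#' @export
setMethod("incidence", "IncidenceMatrix", function(x) x@incidence)

#' @rdname IncidenceMatrix-class
#' @export
setMethod("itemIds", "IncidenceMatrix", function(x) colnames(x@incidence))

#' @rdname IncidenceMatrix-class
#' @export
setMethod("phenotypeItem", "IncidenceMatrix", function(x) x@phenotypeItem)

#' @rdname IncidenceMatrix-class
#' @export
setMethod("nSubjects", "IncidenceMatrix", function(x) nrow(x@incidence))

setMethod("show", "IncidenceMatrix", function(object) {
  cat("IncidenceMatrix:", nrow(object@incidence), "subjects x",
      ncol(object@incidence), "items (phenotype item: ",
      object@phenotypeItem, ")\n")
})

#' @rdname RuleSet-class
#' @export
setMethod("ruleTable", "RuleSet", function(x) x@rules)

#' @rdname RuleSet-class
#' @export
setMethod("length", "RuleSet", function(x) nrow(x@rules))

setMethod("show", "RuleSet", function(object) {
  cat("RuleSet:", nrow(object@rules), "rules with consequent '",
      object@consequent, "' over ", object@nSubjects, " subjects\n",
      sep = "")
  p <- object@params
  if (length(p))
    cat("  minSupport=", p$minSupport, " minConfidence=", p$minConfidence,
        " maxRuleLength=", p$maxRuleLength, "\n", sep = "")
  if (nrow(object@rules)) {
    top <- utils::head(object@rules[order(-object@rules$confidence), ], 3L)
    cat("  top rules by confidence:\n")
    for (i in seq_len(nrow(top)))
      cat("   {", top$lhs[i], "} -> ", top$rhs[i],
          sprintf("  supp=%.3f conf=%.2f lift=%.2f", top$support[i],
                  top$confidence[i], top$lift[i]), "\n", sep = "")
  }
})
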