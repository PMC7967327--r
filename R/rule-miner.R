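## Level-wise (apriori) frequent-itemset mining and rule generation with a
## fixed disease consequent. Counting is exact: per-item subject indicator
## vectors are conjoined and counted with integer arithmetic (implemented
## as 0/1 matrix cross-products); no sampling.

.min_count <- function(minSupport, n) as.integer(ceiling(minSupport * n - 1e-9))

.check_items <- function(I, items) {
  unknown <- setdiff(items, itemIds(I))
  if (length(unknown))
    stop("unknown item id(s): ", paste(unknown, collapse = ", "))
}

#' Count subjects carrying every item of an itemset
#'
#' The empty itemset is the vacuous conjunction and counts all subjects.
#'
#' @param I an [IncidenceMatrix-class].
#' @param items character vector of item ids (possibly empty).
#' @return integer count.
#' @export
itemsetCount <- function(I, items) {
  .check_items(I, items)
  X <- incidence(I)
  if (!length(items)) return(nrow(X))
  sum(rowSums(X[, items, drop = FALSE]) == length(items))
}

#' Mining configuration
#'
#' Defaults are the canonical thresholds: support at least 5%, confidence
#' at least 80%, rule lengths 2-5 (length counts LHS items plus the
#' consequent, so LHS sizes 1-4).
#'
#' @param minSupport,minConfidence thresholds in (0, 1].
#' @param maxRuleLength maximum rule length (LHS size + 1), at least 2.
#' @param consequent the single item allowed on the RHS.
#' @return a `mining_config` list.
#' @export
miningConfig <- function(minSupport = 0.05, minConfidence = 0.80,
                         maxRuleLength = 5L, consequent = "MS") {
  if (minSupport <= 0 || minSupport > 1 ||
      minConfidence <= 0 || minConfidence > 1)
    stop("thresholds must lie in (0, 1]")
  if (maxRuleLength < 2L) stop("maxRuleLength must be at least 2")
  structure(list(minSupport = minSupport, minConfidence = minConfidence,
                 maxRuleLength = as.integer(maxRuleLength),
                 consequent = consequent),
            class = "mining_config")
}

#' Complete frequent itemsets by level-wise apriori
#'
#' Classic apriori: size-k candidates are joined from frequent (k-1)-sets
#' sharing a (k-2)-prefix and pruned when any (k-1)-subset is infrequent,
#' then counted exactly. Returns every itemset with support at least
#' `minSupport` and size at most `maxSize`.
#'
#' @param I an [IncidenceMatrix-class].
#' @param minSupport support threshold in (0, 1].
#' @param maxSize largest itemset size to enumerate.
#' @param candidateCap refuse (with an error) if a level would generate
#'   more candidates than this, which guards `minSupport` near 0 on large
#'   vocabularies.
#' @return data.frame with columns `items` (semicolon-joined, sorted ids),
#'   `size`, `count`, `support`.
#' @export
frequentItemsets <- function(I, minSupport, maxSize = 5L,
                             candidateCap = 1e6) {
  stopifnot(minSupport > 0, minSupport <= 1)
  X <- incidence(I) * 1.0
  n <- nrow(X); p <- ncol(X)
  minCount <- .min_count(minSupport, n)
  counts1 <- colSums(X)
  keep <- which(counts1 >= minCount)
  out <- list()
  if (!length(keep)) return(.itemsets_df(out, colnames(X), n))
  sets <- matrix(keep, nrow = 1L)
  cnts <- counts1[keep]
  V <- X[, keep, drop = FALSE]
  out[[1L]] <- list(sets = sets, counts = cnts)
  k <- 2L
  while (k <= maxSize && ncol(sets) >= 2L) {
    prev_keys <- apply(sets, 2L, paste, collapse = ",")
    prefix <- if (k == 2L) rep("", ncol(sets)) else
      apply(sets[seq_len(k - 2L), , drop = FALSE], 2L, paste, collapse = ",")
    groups <- split(seq_len(ncol(sets)), prefix)
    cand_parent <- integer(); cand_ext <- integer()
    n_cand <- sum(vapply(groups, function(g) choose(length(g), 2L),
                         numeric(1)))
    if (n_cand > candidateCap)
      stop("candidate count at size ", k, " (", n_cand,
           ") exceeds candidateCap; raise minSupport or the cap")
    for (g in groups) {
      if (length(g) < 2L) next
      last <- sets[k - 1L, g]
      o <- g[order(last)]
      for (a in seq_len(length(o) - 1L)) {
        cand_parent <- c(cand_parent, rep(o[a], length(o) - a))
        cand_ext <- c(cand_ext, o[(a + 1L):length(o)])
      }
    }
    if (!length(cand_parent)) break
    cand_sets <- rbind(sets[, cand_parent, drop = FALSE],
                       sets[k - 1L, cand_ext])
    ## apriori prune: every (k-1)-subset must be frequent
    ok <- vapply(seq_len(ncol(cand_sets)), function(j) {
      s <- cand_sets[, j]
      all(vapply(seq_len(k), function(drop_i)
        paste(s[-drop_i], collapse = ",") %in% prev_keys, logical(1)))
    }, logical(1))
    if (!any(ok)) break
    cand_parent <- cand_parent[ok]; cand_ext <- cand_ext[ok]
    cand_sets <- cand_sets[, ok, drop = FALSE]
    Vc <- V[, cand_parent, drop = FALSE] *
      X[, sets[k - 1L, cand_ext], drop = FALSE]
    cc <- colSums(Vc)
    freq <- cc >= minCount
    if (!any(freq)) break
    sets <- cand_sets[, freq, drop = FALSE]
    cnts <- cc[freq]
    V <- Vc[, freq, drop = FALSE]
    out[[k]] <- list(sets = sets, counts = cnts)
    k <- k + 1L
  }
  .itemsets_df(out, colnames(X), n)
}

.itemsets_df <- function(levels, item_names, n) {
  rows <- lapply(levels, function(lv) {
    if (is.null(lv)) return(NULL)
    data.frame(
      items = vapply(seq_len(ncol(lv$sets)), function(j)
        paste(sort(item_names[lv$sets[, j]]), collapse = ";"),
        character(1)),
      size = nrow(lv$sets),
      count = as.integer(lv$counts),
      stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- data.frame(items = character(), size = integer(),
                     count = integer(), stringsAsFactors = FALSE)
  df$support <- df$count / n
  df[order(df$size, df$items), , drop = FALSE]
}

#' Generate consequent-constrained rules from frequent itemsets
#'
#' For every frequent itemset that contains the consequent and has size at
#' most `maxRuleLength`, the single rule (itemset minus consequent) ->
#' consequent is emitted when its confidence reaches the threshold. Only
#' presence-side LHS items exist in the vocabulary; complements are never
#' generated.
#'
#' @param frequent data.frame from [frequentItemsets()], computed at the
#'   same support threshold.
#' @param config a [miningConfig()].
#' @param I the [IncidenceMatrix-class] the itemsets were mined from.
#' @return a [RuleSet-class].
#' @export
generateRules <- function(frequent, config, I) {
  stopifnot(inherits(config, "mining_config"))
  .check_items(I, config$consequent)
  n <- nSubjects(I)
  rhs_count <- itemsetCount(I, config$consequent)
  key <- stats::setNames(frequent$count, frequent$items)
  items_list <- strsplit(frequent$items, ";", fixed = TRUE)
  has_cons <- vapply(items_list, function(s) config$consequent %in% s,
                     logical(1))
  sel <- which(has_cons & frequent$size >= 2L &
                 frequent$size <= config$maxRuleLength)
  rows <- lapply(sel, function(i) {
    lhs_items <- sort(setdiff(items_list[[i]], config$consequent))
    lhs_key <- paste(lhs_items, collapse = ";")
    lhs_count <- key[[lhs_key]]
    if (is.null(lhs_count))     # subset of a frequent set is frequent
      lhs_count <- itemsetCount(I, lhs_items)
    conf <- frequent$count[i] / lhs_count
    if (conf < config$minConfidence) return(NULL)
    data.frame(lhs = lhs_key, rhs = config$consequent,
               length = frequent$size[i],
               lhs_count = as.integer(lhs_count),
               joint_count = frequent$count[i],
               rhs_count = as.integer(rhs_count),
               support = frequent$count[i] / n,
               confidence = conf,
               lift = conf / (rhs_count / n),
               stringsAsFactors = FALSE)
  })
  rules <- do.call(rbind, rows)
  if (is.null(rules)) rules <- .empty_rules_df()
  rownames(rules) <- NULL
  RuleSet(rules, n, config$consequent,
          list(minSupport = config$minSupport,
               minConfidence = config$minConfidence,
               maxRuleLength = config$maxRuleLength))
}

.empty_rules_df <- function() {
  data.frame(lhs = character(), rhs = character(), length = integer(),
             lhs_count = integer(), joint_count = integer(),
             rhs_count = integer(), support = numeric(),
             confidence = numeric(), lift = numeric(),
             stringsAsFactors = FALSE)
}

#' Mine disease-consequent association rules
#'
#' End-to-end apriori mining restricted to rules with the phenotype on the
#' RHS. Because every emitted rule corresponds to a frequent itemset
#' containing the consequent, the search enumerates LHS itemsets level-wise
#' using their joint count with the consequent as the (antimonotone)
#' frequency measure, which prunes the same candidates apriori would while
#' skipping LHS-only itemsets that can never reach the rule support
#' threshold. Results are identical to exhaustive enumeration (see the
#' test suite's brute-force cross-check).
#'
#' @param I an [IncidenceMatrix-class].
#' @param minSupport rule support threshold, P(LHS and consequent).
#' @param minConfidence confidence threshold, P(consequent | LHS).
#' @param maxRuleLength maximum rule length (LHS size + 1).
#' @param consequent RHS item; defaults to the phenotype item.
#' @return a [RuleSet-class] with one row per rule.
#' @export
mineRules <- function(I, minSupport = 0.05, minConfidence = 0.80,
                      maxRuleLength = 5L,
                      consequent = phenotypeItem(I)) {
  config <- miningConfig(minSupport, minConfidence, maxRuleLength,
                         consequent)
  .check_items(I, consequent)
  Xl <- incidence(I)
  n <- nrow(Xl)
  vars <- setdiff(colnames(Xl), consequent)
  Y <- Xl[, consequent] * 1.0
  Xv <- Xl[, vars, drop = FALSE] * 1.0
  rhs_count <- sum(Y)
  minCount <- .min_count(minSupport, n)
  maxLhs <- config$maxRuleLength - 1L

  joint1 <- as.vector(crossprod(Xv, Y))
  lhs1 <- colSums(Xv)
  keep <- which(joint1 >= minCount)
  res <- list()
  emit <- function(sets, joint, lhs_cnt) {
    conf <- joint / lhs_cnt
    sel <- which(conf >= config$minConfidence)
    if (!length(sel)) return(NULL)
    data.frame(
      lhs = vapply(sel, function(j)
        paste(sort(vars[sets[, j]]), collapse = ";"), character(1)),
      rhs = consequent,
      length = nrow(sets) + 1L,
      lhs_count = as.integer(lhs_cnt[sel]),
      joint_count = as.integer(joint[sel]),
      rhs_count = as.integer(rhs_count),
      support = joint[sel] / n,
      confidence = conf[sel],
      lift = (joint[sel] / lhs_cnt[sel]) / (rhs_count / n),
      stringsAsFactors = FALSE)
  }
  if (length(keep)) {
    sets <- matrix(keep, nrow = 1L)
    res[[1L]] <- emit(sets, joint1[keep], lhs1[keep])
    ## restrict joint counting to consequent carriers: non-carriers never
    ## contribute to a joint-with-consequent count
    Xc <- Xv[Y == 1, , drop = FALSE]
    k <- 2L
    chunk <- 20000L
    while (k <= maxLhs && ncol(sets) >= 1L) {
      m <- ncol(sets)
      new_sets <- list(); new_joint <- list(); new_lhs <- list()
      for (lo in seq(1L, m, by = chunk)) {
        hi <- min(lo + chunk - 1L, m)
        cols <- lo:hi
        ## rebuild parent indicators for this chunk (k-1 items each)
        U <- Xc[, sets[1L, cols], drop = FALSE]
        V <- Xv[, sets[1L, cols], drop = FALSE]
        if (k > 2L) for (r in 2:(k - 1L)) {
          U <- U * Xc[, sets[r, cols], drop = FALSE]
          V <- V * Xv[, sets[r, cols], drop = FALSE]
        }
        M <- crossprod(Xc, U)              # p x chunk joint counts
        maxel <- sets[k - 1L, cols]
        hit <- which(M >= minCount, arr.ind = TRUE)
        if (!nrow(hit)) next
        ok <- hit[, 1L] > maxel[hit[, 2L]] # extend by higher-indexed items
        hit <- hit[ok, , drop = FALSE]
        if (!nrow(hit)) next
        M2 <- crossprod(Xv, V)             # p x chunk LHS counts
        parent <- hit[, 2L]; ext <- hit[, 1L]
        new_sets[[length(new_sets) + 1L]] <-
          rbind(sets[, cols[parent], drop = FALSE], ext)
        new_joint[[length(new_joint) + 1L]] <- M[hit]
        new_lhs[[length(new_lhs) + 1L]] <- M2[hit]
      }
      if (!length(new_sets)) break
      sets <- do.call(cbind, new_sets)
      res[[k]] <- emit(sets, unlist(new_joint), unlist(new_lhs))
      k <- k + 1L
    }
  }
  rules <- do.call(rbind, res)
  if (is.null(rules)) rules <- .empty_rules_df()
  rules <- rules[order(rules$length, rules$lhs), , drop = FALSE]
  rownames(rules) <- NULL
  RuleSet(rules, n, consequent,
          list(minSupport = minSupport, minConfidence = minConfidence,
               maxRuleLength = config$maxRuleLength))
}

#' Evaluate an arbitrary rule, bypassing thresholds
#'
#' Computes support, confidence and lift for a user-specified LHS ->
#' consequent rule (post-hoc dyad/triad evaluation).
#'
#' @param I an [IncidenceMatrix-class].
#' @param lhs character vector of LHS item ids.
#' @param consequent RHS item id (must not appear in `lhs`).
#' @return one-row data.frame with the rule metric columns.
#' @export
evaluateItemset <- function(I, lhs, consequent = phenotypeItem(I)) {
  .check_items(I, c(lhs, consequent))
  if (consequent %in% lhs) stop("lhs must not contain the consequent")
  n <- nSubjects(I)
  lhs <- sort(lhs)
  lhs_count <- itemsetCount(I, lhs)
  joint_count <- itemsetCount(I, c(lhs, consequent))
  rhs_count <- itemsetCount(I, consequent)
  conf <- if (lhs_count > 0) joint_count / lhs_count else NA_real_
  data.frame(lhs = paste(lhs, collapse = ";"), rhs = consequent,
             length = length(lhs) + 1L,
             lhs_count = lhs_count, joint_count = joint_count,
             rhs_count = rhs_count,
             support = joint_count / n, confidence = conf,
             lift = conf / (rhs_count / n),
             stringsAsFactors = FALSE)
}

#' Serialize and restore rule sets
#'
#' Rules are written as TSV (one rule per row, LHS semicolon-joined) and,
#' alongside, a JSON provenance record with the thresholds, cohort size
#' and consequent.
#'
#' @param rs a [RuleSet-class].
#' @param path TSV output path; the JSON record is written next to it with
#'   extension `.json`.
#' @return invisibly, the TSV path.
#' @export
writeRules <- function(rs, path) {
  utils::write.table(ruleTable(rs), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- c(rs@params, list(nSubjects = rs@nSubjects,
                            consequent = rs@consequent,
                            nRules = length(rs)))
  jsonlite::write_json(meta, sub("\\.tsv$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeRules
#' @param path TSV path previously written by [writeRules()].
#' @export
readRules <- function(path) {
  rules <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!nrow(rules)) rules <- .empty_rules_df()
  meta <- jsonlite::read_json(sub("\\.tsv$", ".json", path),
                              simplifyVector = TRUE)
  RuleSet(rules, meta$nSubjects, meta$consequent,
          list(minSupport = meta$minSupport,
               minConfidence = meta$minConfidence,
               maxRuleLength = meta$maxRuleLength))
}
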