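.rules_df <- function(rules) {
  if (is(rules, "RuleSet")) ruleTable(rules) else as.data.frame(rules)
}

#' Rank rules deterministically
#'
#' Descending by the chosen key (ascending for `p_value`); ties broken by
#' higher support, then lexicographic LHS, so repeated calls give
#' identical output.
#'
#' @param rules a [RuleSet-class] or rule data.frame (must contain a
#'   `p_value` column when ranking by p-value).
#' @param key `"confidence"`, `"support"` or `"p_value"`.
#' @param topK keep at most this many rules (default: all).
#' @return the ordered rule data.frame.
#' @export
rankRules <- function(rules, key = c("confidence", "support", "p_value"),
                      topK = Inf) {
  key <- match.arg(key)
  df <- .rules_df(rules)
  if (!nrow(df)) return(df)
  if (!key %in% colnames(df))
    stop("rules carry no '", key, "' column")
  v <- df[[key]]
  if (key == "p_value") v <- -v
  o <- order(-v, -df$support, df$lhs)
  out <- df[o, , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, topK)
}

#' Per-item membership frequencies across a rule set
#'
#' Counts, for every item, the rules whose LHS contains it, over all rules
#' and over the top `topK` rules by confidence, with percentages of the
#' respective denominators. Optional variant-spec annotation adds gene,
#' chromosome and position columns.
#'
#' @param rules a [RuleSet-class] or rule data.frame.
#' @param topK size of the top-by-confidence subset (default 15).
#' @param spec optional variant spec data.frame for annotation.
#' @return data.frame with columns `item_id`, (annotation), `n_rules`,
#'   `pct_rules`, `n_top_k`, `pct_top_k`, sorted by `n_rules` decreasing.
#' @export
itemFrequency <- function(rules, topK = 15L, spec = NULL) {
  df <- .rules_df(rules)
  empty <- data.frame(item_id = character(), n_rules = integer(),
                      pct_rules = numeric(), n_top_k = integer(),
                      pct_top_k = numeric(), stringsAsFactors = FALSE)
  if (!nrow(df)) return(empty)
  total <- nrow(df)
  all_items <- strsplit(df$lhs, ";", fixed = TRUE)
  tab <- table(unlist(all_items))
  top <- rankRules(df, "confidence", topK = topK)
  k <- nrow(top)
  tab_top <- table(unlist(strsplit(top$lhs, ";", fixed = TRUE)))
  out <- data.frame(item_id = names(tab),
                    n_rules = as.integer(tab),
                    stringsAsFactors = FALSE)
  out$pct_rules <- 100 * out$n_rules / total
  out$n_top_k <- as.integer(tab_top[out$item_id])
  out$n_top_k[is.na(out$n_top_k)] <- 0L
  out$pct_top_k <- 100 * out$n_top_k / k
  if (!is.null(spec)) {
    m <- match(out$item_id, spec$variant_id)
    out$gene <- spec$gene[m]
    out$chromosome <- spec$chromosome[m]
    out$position <- spec$position[m]
    out <- out[, c("item_id", "gene", "chromosome", "position",
                   "n_rules", "pct_rules", "n_top_k", "pct_top_k")]
  }
  out <- out[order(-out$n_rules, out$item_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Dyad co-occurrence across a rule set
#'
#' The conditional share of rules containing `itemA` that also contain
#' `itemB`, plus the joint share among all rules. When `itemA` occurs in
#' no rule the conditional is undefined and reported as `NA` (never 0).
#'
#' @param rules a [RuleSet-class] or rule data.frame.
#' @param itemA,itemB item ids.
#' @return list with `n_a`, `n_joint`, `conditional_pct` (possibly `NA`),
#'   `joint_pct`, `defined`.
#' @export
cooccurrence <- function(rules, itemA, itemB) {
  df <- .rules_df(rules)
  sets <- strsplit(df$lhs, ";", fixed = TRUE)
  has_a <- vapply(sets, function(s) itemA %in% s, logical(1))
  has_b <- vapply(sets, function(s) itemB %in% s, logical(1))
  n_a <- sum(has_a); n_joint <- sum(has_a & has_b)
  list(n_a = n_a, n_joint = n_joint,
       conditional_pct = if (n_a > 0) 100 * n_joint / n_a else NA_real_,
       joint_pct = if (nrow(df)) 100 * n_joint / nrow(df) else NA_real_,
       defined = n_a > 0)
}

#' Bipartite rule-item network of the top rules
#'
#' Nodes are the top `topK` rules by confidence (node size attribute =
#' support) and their LHS items; each item points to the rules it belongs
#' to. No item-item edges exist, and each rule node's in-degree equals its
#' LHS size.
#'
#' @param rules a [RuleSet-class] or rule data.frame.
#' @param topK number of top-confidence rules to include.
#' @return an [igraph::igraph] directed graph with vertex attributes
#'   `type` (`"rule"`/`"item"`) and `support` (rules only).
#' @export
rulesNetwork <- function(rules, topK = 15L) {
  df <- rankRules(rules, "confidence", topK = topK)
  if (!nrow(df)) return(igraph::make_empty_graph())
  rule_ids <- paste0("rule_", seq_len(nrow(df)))
  sets <- strsplit(df$lhs, ";", fixed = TRUE)
  items <- sort(unique(unlist(sets)))
  edges <- do.call(rbind, lapply(seq_along(sets), function(i)
    cbind(from = sets[[i]], to = rule_ids[i])))
  g <- igraph::graph_from_data_frame(
    as.data.frame(edges, stringsAsFactors = FALSE), directed = TRUE,
    vertices = data.frame(
      name = c(items, rule_ids),
      type = c(rep("item", length(items)), rep("rule", nrow(df))),
      support = c(rep(NA_real_, length(items)), df$support),
      label = c(items, df$lhs),
      stringsAsFactors = FALSE))
  g
}

#' Export a rule-item network as GraphML and edge-list TSV
#'
#' @param g graph from [rulesNetwork()].
#' @param graphmlPath,edgeTsvPath output paths (either may be `NULL`).
#' @return invisibly, the written paths.
#' @export
writeRulesNetwork <- function(g, graphmlPath = NULL, edgeTsvPath = NULL) {
  if (!is.null(graphmlPath))
    igraph::write_graph(g, graphmlPath, format = "graphml")
  if (!is.null(edgeTsvPath)) {
    e <- igraph::as_data_frame(g, what = "edges")
    utils::write.table(e, edgeTsvPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(c(graphml = graphmlPath, edges = edgeTsvPath))
}

#' Exhaustive interaction search-space size
#'
#' The number of k-way variant combinations an exhaustive interaction scan
#' would have to test: exact binomial coefficients C(n, k) per order, and
#' their total.
#'
#' @param nVariants number of variants.
#' @param orders integer vector of interaction orders (each >= 2 and <=
#'   `nVariants`).
#' @return list with `counts` (named by order) and `total`.
#' @export
interactionSearchSpace <- function(nVariants, orders = 2:4) {
  stopifnot(all(orders >= 2L), all(orders <= nVariants))
  counts <- vapply(orders, function(k) choose(nVariants, k), numeric(1))
  names(counts) <- as.character(orders)
  list(counts = counts, total = sum(counts))
}
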