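## Brute-force oracles, independent of the package's level-wise miner:
## direct enumeration over all itemsets / rules by per-subject scans.

brute_itemset_count <- function(X, items) {
  if (!length(items)) return(nrow(X))
  sum(apply(X[, items, drop = FALSE], 1L, all))
}

## All itemsets with support >= minSupport and size <= maxSize, by
## exhaustive enumeration of every non-empty subset of the vocabulary.
brute_frequent_itemsets <- function(X, minSupport, maxSize) {
  n <- nrow(X)
  items <- colnames(X)
  out <- list()
  for (k in seq_len(min(maxSize, length(items)))) {
    combs <- utils::combn(items, k, simplify = FALSE)
    for (s in combs) {
      cnt <- brute_itemset_count(X, s)
      if (cnt / n >= minSupport - 1e-12)
        out[[length(out) + 1L]] <- data.frame(
          items = paste(sort(s), collapse = ";"), size = k,
          count = cnt, stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, out)
  if (is.null(df))
    df <- data.frame(items = character(), size = integer(),
                     count = integer())
  df$support <- df$count / n
  df[order(df$size, df$items), , drop = FALSE]
}

## All rules LHS -> consequent meeting the thresholds, by exhaustive
## enumeration of every LHS subset of the non-consequent vocabulary.
brute_rules <- function(X, minSupport, minConfidence, maxRuleLength,
                        consequent) {
  n <- nrow(X)
  vars <- setdiff(colnames(X), consequent)
  rhs_count <- brute_itemset_count(X, consequent)
  out <- list()
  for (k in seq_len(min(maxRuleLength - 1L, length(vars)))) {
    for (s in utils::combn(vars, k, simplify = FALSE)) {
      joint <- brute_itemset_count(X, c(s, consequent))
      if (joint / n < minSupport - 1e-12) next
      lhs_count <- brute_itemset_count(X, s)
      conf <- joint / lhs_count
      if (conf < minConfidence - 1e-12) next
      out[[length(out) + 1L]] <- data.frame(
        lhs = paste(sort(s), collapse = ";"), rhs = consequent,
        length = k + 1L, lhs_count = lhs_count, joint_count = joint,
        rhs_count = rhs_count, support = joint / n, confidence = conf,
        lift = conf / (rhs_count / n), stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, out)
  if (is.null(df))
    df <- data.frame(lhs = character(), rhs = character(),
                     length = integer(), lhs_count = integer(),
                     joint_count = integer(), rhs_count = integer(),
                     support = numeric(), confidence = numeric(),
                     lift = numeric(), stringsAsFactors = FALSE)
  df[order(df$length, df$lhs), , drop = FALSE]
}

## Random incidence fixture with a guaranteed phenotype column.
random_incidence <- function(n, p, seed, item_prob = 0.4,
                             case_prob = 0.5) {
  set.seed(seed)
  X <- matrix(runif(n * p) < item_prob, n, p,
              dimnames = list(NULL, sprintf("i%02d", seq_len(p))))
  X <- cbind(X, MS = runif(n) < case_prob)
  IncidenceMatrix(X, "MS")
}

## The printed-counts fixture: 386 subjects (207 cases / 179 controls),
## 20 cases and 1 control carrying the three-variant pattern.
top_rule_fixture <- function() {
  exactFixture(207, 179, data.frame(
    items = "HLA-DRB1*15:01;rs56678847;rs6880809",
    cases = 20L, controls = 1L))
}

## A deterministic 114-rule fixture with prescribed item memberships:
## "hub" appears in 37 rules, "partner" joins it in 28, and fillers pad
## each LHS to three items. Confidences descend with rule index so the
## ranking is unambiguous.
fixture_rules <- function() {
  lhs <- character(114)
  fill <- function(i, k) sprintf("f%03d_%d", i, k)
  for (i in 1:114) {
    if (i <= 28) lhs[i] <- paste(sort(c("hub", "partner", fill(i, 1))),
                                 collapse = ";")
    else if (i <= 37) lhs[i] <- paste(sort(c("hub", fill(i, 1), fill(i, 2))),
                                      collapse = ";")
    else lhs[i] <- paste(sort(c(fill(i, 1), fill(i, 2), fill(i, 3))),
                         collapse = ";")
  }
  data.frame(lhs = lhs, rhs = "MS", length = 4L,
             lhs_count = 21L, joint_count = 20L, rhs_count = 207L,
             support = 20 / 386,
             confidence = seq(0.95, 0.80, length.out = 114),
             lift = (20 / 21) / (207 / 386),
             stringsAsFactors = FALSE)
}
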