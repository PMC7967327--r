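#' 2x2 contingency table for a rule's carriers against disease
#'
#' A carrier is a subject with every LHS item TRUE. Cells: `a` carriers
#' among cases, `b` carriers among controls, `c` non-carrier cases, `d`
#' non-carrier controls, plus per-group carrier frequencies.
#'
#' @param I an [IncidenceMatrix-class].
#' @param lhs character vector of LHS item ids (or a one-row rule
#'   data.frame with an `lhs` column).
#' @param phenotypeItem the phenotype column; defaults to the matrix's.
#' @return list of class `contingency_table` with fields `a`, `b`, `c`,
#'   `d`, `freq_cases`, `freq_controls`.
#' @export
ruleContingency <- function(I, lhs, phenotypeItem = NULL) {
  if (is.data.frame(lhs)) lhs <- strsplit(lhs$lhs[1L], ";")[[1L]]
  if (is.null(phenotypeItem)) phenotypeItem <- phenotypeItem(I)
  .check_items(I, c(lhs, phenotypeItem))
  X <- incidence(I)
  carrier <- rowSums(X[, lhs, drop = FALSE]) == length(lhs)
  y <- X[, phenotypeItem]
  contingencyTable(a = sum(carrier & y), b = sum(carrier & !y),
                   c = sum(!carrier & y), d = sum(!carrier & !y))
}

#' @rdname ruleContingency
#' @param a,b,c,d non-negative cell counts (carrier cases, carrier
#'   controls, non-carrier cases, non-carrier controls).
#' @export
contingencyTable <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  structure(list(a = as.integer(a), b = as.integer(b), c = as.integer(c),
                 d = as.integer(d),
                 freq_cases = a / (a + c), freq_controls = b / (b + d)),
            class = "contingency_table")
}

#' Crude odds ratio with Woolf confidence interval
#'
#' OR = ad/bc with a log-scale (Woolf) 95% CI. With `zeroCell =
#' "haldane"`, 0.5 is added to all four cells whenever any cell is zero
#' (flagged in the output); with `"none"`, degenerate tables return an
#' infinite or zero OR with an explicit flag and no silent correction.
#'
#' @param tab a `contingency_table` (see [contingencyTable()]).
#' @param zeroCell `"haldane"` or `"none"`.
#' @param conf.level CI level.
#' @return list with `or`, `ci_low`, `ci_high`, `log_or`, `se_log_or`,
#'   `corrected` (Haldane applied), `degenerate`.
#' @export
crudeOddsRatio <- function(tab, zeroCell = c("haldane", "none"),
                           conf.level = 0.95) {
  zeroCell <- match.arg(zeroCell)
  cells <- c(tab$a, tab$b, tab$c, tab$d)
  corrected <- FALSE
  degenerate <- any(cells == 0L)
  if (degenerate && zeroCell == "haldane") {
    cells <- cells + 0.5
    corrected <- TRUE
    degenerate <- FALSE
  }
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  z <- stats::qnorm(1 - (1 - conf.level) / 2)
  if (is.finite(or) && or > 0) {
    se <- sqrt(sum(1 / cells))
    ci <- exp(log(or) + c(-1, 1) * z * se)
  } else {
    se <- NA_real_; ci <- c(NA_real_, NA_real_)
  }
  list(or = or, ci_low = ci[1], ci_high = ci[2],
       log_or = log(or), se_log_or = se,
       corrected = corrected, degenerate = degenerate)
}

#' Maximum-likelihood logistic regression fit
#'
#' Fits by iteratively reweighted least squares (tolerance `1e-8`, at most
#' 100 iterations). The design is checked for full column rank first, with
#' an error naming the collinear columns. Complete or quasi-complete
#' separation is detected as a diverging coefficient magnitude (or IRLS
#' non-convergence) and flagged, never silently accepted.
#'
#' @param y binary response vector.
#' @param X design matrix (without intercept; one is prepended unless
#'   `addIntercept = FALSE`).
#' @param addIntercept prepend an intercept column.
#' @param tol,maxIter IRLS convergence controls.
#' @return list with `coef`, `vcov`, `converged`, `separated`.
#' @export
fitLogistic <- function(y, X, addIntercept = TRUE, tol = 1e-8,
                        maxIter = 100L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (addIntercept) X <- cbind(`(Intercept)` = 1, X)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  fit <- suppressWarnings(stats::glm.fit(
    X, y, family = stats::binomial(),
    control = stats::glm.control(epsilon = tol, maxit = maxIter)))
  p <- ncol(X)
  covmat <- chol2inv(fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE])
  dimnames(covmat) <- list(colnames(X), colnames(X))
  coefs <- stats::setNames(fit$coefficients, colnames(X))
  separated <- !fit$converged || any(abs(coefs[-1L]) > 10)
  list(coef = coefs, vcov = covmat, converged = fit$converged,
       separated = separated)
}

## Fast exact ML log-OR for the single-binary-predictor model, where the
## logistic MLE equals the 2x2 log cross-ratio. Returns NA on zero cells
## (separation in the corresponding fit).
.table_log_or <- function(carrier, y) {
  a <- sum(carrier & y); b <- sum(carrier & !y)
  c <- sum(!carrier & y); d <- sum(!carrier & !y)
  if (a == 0L || b == 0L || c == 0L || d == 0L) return(NA_real_)
  log(a) + log(d) - log(b) - log(c)
}

#' Bootstrap characterization of a rule's association with disease
#'
#' Fits the logistic model disease ~ carrier (+ covariates) on the full
#' data, then resamples subjects with replacement `nBoot` times and refits
#' to obtain the bias-corrected (BC) percentile 95% CI of the adjusted OR,
#' a bootstrap SE, and a two-sided normal-based p-value
#' (point log-OR / bootstrap SE). Replicates where the fit does not
#' converge or separates are dropped and counted; more than 10% dropped
#' flags the result unstable. The reported point estimate is always the
#' full-data estimate, never a replicate mean.
#'
#' @param I an [IncidenceMatrix-class].
#' @param lhs LHS item ids (or one-row rule data.frame).
#' @param covariates optional numeric covariate matrix (subjects x k).
#' @param nBoot number of resamples (canonically 5000).
#' @param seed integer seed.
#' @param stratified resample within cases and controls separately
#'   (default: unstratified subject resampling).
#' @return list with `or_crude`, `or_adjusted`, `ci_low`, `ci_high`,
#'   `log_or`, `se`, `p_value`, `n_boot`, `n_dropped`, `unstable`,
#'   `separated`.
#' @export
bootstrapAssociation <- function(I, lhs, covariates = NULL, nBoot = 5000L,
                                 seed = 1L, stratified = FALSE) {
  if (is.data.frame(lhs)) lhs <- strsplit(lhs$lhs[1L], ";")[[1L]]
  X <- incidence(I)
  ph <- phenotypeItem(I)
  .check_items(I, c(lhs, ph))
  carrier <- rowSums(X[, lhs, drop = FALSE]) == length(lhs)
  y <- X[, ph] * 1L
  n <- length(y)
  if (all(carrier) || !any(carrier))
    stop("carrier status is constant; the association model is undefined")
  tab <- ruleContingency(I, lhs)
  crude <- crudeOddsRatio(tab)

  has_cov <- !is.null(covariates)
  if (has_cov) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == n)
  }
  point_fit_logor <- function(idx) {
    cr <- carrier[idx]; yy <- y[idx]
    if (all(cr) || !any(cr)) return(NA_real_)
    if (!has_cov) return(.table_log_or(cr, yy))
    f <- try(fitLogistic(yy, cbind(carrier = cr * 1,
                                   covariates[idx, , drop = FALSE])),
             silent = TRUE)
    if (inherits(f, "try-error") || !f$converged || f$separated)
      return(NA_real_)
    unname(f$coef["carrier"])
  }

  ## Haldane-corrected crude log-OR: always finite while carriers vary
  haldane_logor <- function(idx) {
    cr <- carrier[idx]; yy <- y[idx]
    if (all(cr) || !any(cr)) return(NA_real_)
    a <- sum(cr & yy) + 0.5; b <- sum(cr & !yy) + 0.5
    c <- sum(!cr & yy) + 0.5; d <- sum(!cr & !yy) + 0.5
    log(a) + log(d) - log(b) - log(c)
  }

  ## Full-data fit. Under separation (e.g. a confidence-1 rule with no
  ## control carriers) the ML log-OR diverges, so the whole bootstrap
  ## switches consistently to the Haldane-corrected crude estimator and
  ## the result is flagged.
  separated <- FALSE
  theta <- point_fit_logor(seq_len(n))
  if (is.na(theta)) {
    separated <- TRUE
    theta <- haldane_logor(seq_len(n))
    estimator <- haldane_logor
  } else estimator <- point_fit_logor

  set.seed(seed)
  cases <- which(y == 1L); controls <- which(y == 0L)
  thetas <- rep(NA_real_, nBoot)
  for (r in seq_len(nBoot)) {
    idx <- if (stratified)
      c(sample(cases, length(cases), replace = TRUE),
        sample(controls, length(controls), replace = TRUE))
    else sample.int(n, n, replace = TRUE)
    thetas[r] <- estimator(idx)
  }
  dropped <- sum(is.na(thetas))
  thetas <- thetas[!is.na(thetas)]
  if (length(thetas) < 2L)
    stop("bootstrap failed: fewer than 2 usable replicates")
  se <- stats::sd(thetas)
  ## bias-corrected percentile interval
  prop_below <- mean(thetas < theta)
  prop_below <- min(max(prop_below, 1 / (length(thetas) + 1)),
                    1 - 1 / (length(thetas) + 1))
  z0 <- stats::qnorm(prop_below)
  probs <- stats::pnorm(2 * z0 + stats::qnorm(c(0.025, 0.975)))
  ci <- stats::quantile(thetas, probs, names = FALSE, type = 6)
  p <- 2 * stats::pnorm(-abs(theta) / se)
  list(or_crude = crude$or, or_adjusted = exp(theta),
       ci_low = exp(ci[1]), ci_high = exp(ci[2]),
       log_or = theta, se = se, p_value = max(p, .Machine$double.xmin),
       n_boot = nBoot, n_dropped = dropped,
       unstable = dropped > 0.1 * nBoot, separated = separated)
}

#' Characterize every rule of a rule set
#'
#' Runs [bootstrapAssociation()] per rule and applies the Bonferroni
#' correction across the rule family.
#'
#' @param I an [IncidenceMatrix-class].
#' @param rs a [RuleSet-class].
#' @param covariates optional covariate matrix (the canonical analysis
#'   adjusts for the first three substructure coordinates).
#' @param nBoot,seed,stratified passed to [bootstrapAssociation()].
#' @param alpha family-wise error rate for Bonferroni.
#' @return data.frame: rule columns plus association columns and
#'   `significant_bonferroni`.
#' @export
associateRules <- function(I, rs, covariates = NULL, nBoot = 5000L,
                           seed = 1L, stratified = FALSE, alpha = 0.05) {
  rules <- ruleTable(rs)
  if (!nrow(rules)) return(cbind(rules, p_value = numeric()))
  assoc <- lapply(seq_len(nrow(rules)), function(i)
    bootstrapAssociation(I, strsplit(rules$lhs[i], ";")[[1L]],
                         covariates = covariates, nBoot = nBoot,
                         seed = seed + i, stratified = stratified))
  out <- cbind(rules,
               do.call(rbind, lapply(assoc, function(a)
                 data.frame(or_crude = a$or_crude,
                            or_adjusted = a$or_adjusted,
                            ci_low = a$ci_low, ci_high = a$ci_high,
                            p_value = a$p_value,
                            n_dropped = a$n_dropped,
                            unstable = a$unstable,
                            separated = a$separated))))
  bf <- bonferroni(out$p_value, alpha = alpha)
  out$significant_bonferroni <- bf$significant
  attr(out, "bonferroni_threshold") <- bf$threshold
  out
}

#' Bonferroni correction
#'
#' @param pValues vector of p-values (length m >= 1).
#' @param alpha family-wise error rate.
#' @return list with `threshold` (= alpha/m) and logical `significant`
#'   flags (p <= threshold).
#' @export
bonferroni <- function(pValues, alpha = 0.05) {
  m <- length(pValues)
  stopifnot(m >= 1L)
  thr <- alpha / m
  list(threshold = thr, significant = pValues <= thr, m = m)
}

#' Stratified odds ratios over the 8 carrier profiles of three variants
#'
#' Subjects are cross-classified by dominant carriage of each of three
#' items (profiles `000` ... `111`, in item order); each profile's odds of
#' disease is compared with the `000` reference in a 2x2 sub-table
#' (Haldane 0.5 correction on zero cells, flagged).
#'
#' @param I an [IncidenceMatrix-class].
#' @param variants exactly three item ids.
#' @param phenotypeItem phenotype column (defaults to the matrix's).
#' @return list of class `stratified_ors`: `or` (named length-8 vector,
#'   reference = 1), `corrected` flags, `profile_counts`.
#' @export
stratifiedOrs <- function(I, variants, phenotypeItem = NULL) {
  stopifnot(length(variants) == 3L)
  if (is.null(phenotypeItem)) phenotypeItem <- phenotypeItem(I)
  .check_items(I, c(variants, phenotypeItem))
  X <- incidence(I)
  y <- X[, phenotypeItem]
  g <- X[, variants, drop = FALSE]
  prof <- paste0(g[, 1] * 1L, g[, 2] * 1L, g[, 3] * 1L)
  levels8 <- apply(expand.grid(0:1, 0:1, 0:1)[, 3:1], 1L, paste,
                   collapse = "")
  ref_cases <- sum(y[prof == "000"]); ref_ctrls <- sum(prof == "000" & !y)
  if (ref_cases + ref_ctrls == 0L)
    stop("reference profile 000 is empty; choose a different reference")
  or <- stats::setNames(rep(NA_real_, 8L), levels8)
  corrected <- stats::setNames(rep(FALSE, 8L), levels8)
  counts <- stats::setNames(rep(0L, 8L), levels8)
  or["000"] <- 1
  for (lv in levels8) {
    counts[lv] <- sum(prof == lv)
    if (lv == "000" || counts[lv] == 0L) next
    cr <- crudeOddsRatio(contingencyTable(
      a = sum(prof == lv & y), b = sum(prof == lv & !y),
      c = ref_cases, d = ref_ctrls))
    or[lv] <- cr$or
    corrected[lv] <- cr$corrected
  }
  structure(list(or = or, corrected = corrected,
                 profile_counts = counts, variants = variants),
            class = "stratified_ors")
}

#' Three-way relative excess odds due to interaction and attributable
#' proportion
#'
#' From the 8 profile odds ratios, RERI3 = OR111 - OR110 - OR101 - OR011 +
#' OR100 + OR010 + OR001 - 1 and AP3 = RERI3 / OR111: the share of the
#' joint effect attributable to additive interaction.
#'
#' @param ors named numeric vector of profile ORs (names `000` ... `111`)
#'   or a `stratified_ors` object.
#' @return list with `reri3` and `ap3`.
#' @export
reriFromOrs <- function(ors) {
  if (inherits(ors, "stratified_ors")) ors <- ors$or
  need <- c("111", "110", "101", "011", "100", "010", "001")
  if (any(is.na(ors[need])))
    stop("undefined strata: ",
         paste(need[is.na(ors[need])], collapse = ", "))
  if (ors["111"] <= 0) stop("OR(1,1,1) must be positive")
  reri <- unname(ors["111"] - ors["110"] - ors["101"] - ors["011"] +
                   ors["100"] + ors["010"] + ors["001"] - 1)
  list(reri3 = reri, ap3 = reri / unname(ors["111"]))
}

#' Additive interaction of a three-variant pattern, with bootstrap p
#'
#' Computes RERI3/AP3 from the stratified ORs and a two-sided
#' percentile-type bootstrap p-value for AP3 (subjects resampled with
#' replacement; replicates with an empty stratum dropped and counted).
#'
#' @param I an [IncidenceMatrix-class].
#' @param variants exactly three item ids.
#' @param nBoot bootstrap replicates.
#' @param seed integer seed.
#' @return list with `reri3`, `ap3`, `ap_p`, `ors` (the stratified OR
#'   object), `n_boot`, `n_dropped`.
#' @export
additiveInteraction <- function(I, variants, nBoot = 2000L, seed = 1L) {
  so <- stratifiedOrs(I, variants)
  point <- reriFromOrs(so)
  X <- incidence(I)
  n <- nrow(X)
  set.seed(seed)
  aps <- rep(NA_real_, nBoot)
  for (r in seq_len(nBoot)) {
    idx <- sample.int(n, n, replace = TRUE)
    Ib <- IncidenceMatrix(X[idx, , drop = FALSE], phenotypeItem(I))
    so_b <- try(stratifiedOrs(Ib, variants), silent = TRUE)
    if (inherits(so_b, "try-error")) next
    ap_b <- try(reriFromOrs(so_b), silent = TRUE)
    if (!inherits(ap_b, "try-error")) aps[r] <- ap_b$ap3
  }
  dropped <- sum(is.na(aps))
  aps <- aps[!is.na(aps)]
  ## two-sided percentile p for H0: AP = 0
  p_lo <- (sum(aps <= 0) + 1) / (length(aps) + 1)
  p_hi <- (sum(aps >= 0) + 1) / (length(aps) + 1)
  list(reri3 = point$reri3, ap3 = point$ap3,
       ap_p = min(1, 2 * min(p_lo, p_hi)),
       ors = so, n_boot = nBoot, n_dropped = dropped)
}

#' Multiplicative interaction of a three-variant pattern
#'
#' Fits the fully parameterized logistic model with all three main
#' effects, the three two-way products and the three-way product (plus
#' covariates) and reports the exponentiated three-way coefficient with
#' its Wald p-value. Under separation the fit is flagged and, if
#' requested, refit with Firth's penalized likelihood (labeled in the
#' output).
#'
#' @param I an [IncidenceMatrix-class].
#' @param variants exactly three item ids.
#' @param covariates optional covariate matrix.
#' @param firth use the Firth-penalized fallback when the ML fit
#'   separates.
#' @return list with `mult_or3`, `mult_p`, `coef`, `separated`, `method`.
#' @export
multiplicativeInteraction <- function(I, variants, covariates = NULL,
                                      firth = FALSE) {
  stopifnot(length(variants) == 3L)
  .check_items(I, variants)
  X <- incidence(I)
  y <- X[, phenotypeItem(I)] * 1L
  g1 <- X[, variants[1]] * 1; g2 <- X[, variants[2]] * 1
  g3 <- X[, variants[3]] * 1
  D <- cbind(g1 = g1, g2 = g2, g3 = g3,
             g1g2 = g1 * g2, g1g3 = g1 * g3, g2g3 = g2 * g3,
             g1g2g3 = g1 * g2 * g3)
  if (!is.null(covariates)) D <- cbind(D, as.matrix(covariates))
  fit <- fitLogistic(y, D)
  method <- "ml"
  if (fit$separated && firth) {
    fit <- .firth_logistic(y, cbind(`(Intercept)` = 1, D))
    method <- "firth"
  }
  est <- unname(fit$coef["g1g2g3"])
  se <- sqrt(fit$vcov["g1g2g3", "g1g2g3"])
  list(mult_or3 = exp(est), mult_p = 2 * stats::pnorm(-abs(est) / se),
       coef = fit$coef, separated = fit$separated, method = method)
}

## Firth's penalized-likelihood logistic regression: Newton iterations on
## the score modified by the hat-diagonal bias term.
.firth_logistic <- function(y, X, maxIter = 50L, tol = 1e-8) {
  p <- ncol(X)
  beta <- rep(0, p)
  for (it in seq_len(maxIter)) {
    eta <- as.vector(X %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    XW <- X * sqrt(w)
    info <- crossprod(XW)
    info_inv <- solve(info)
    h <- rowSums((XW %*% info_inv) * XW)
    U <- as.vector(crossprod(X, y - mu + h * (0.5 - mu)))
    step <- as.vector(info_inv %*% U)
    ## step-halving for stability
    while (max(abs(step)) > 5) step <- step / 2
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  eta <- as.vector(X %*% beta)
  w <- stats::plogis(eta) * (1 - stats::plogis(eta))
  vcov <- solve(crossprod(X * sqrt(w)))
  dimnames(vcov) <- list(colnames(X), colnames(X))
  list(coef = stats::setNames(beta, colnames(X)), vcov = vcov,
       converged = it < maxIter, separated = FALSE)
}

#' Write rule association results as TSV
#'
#' @param assoc data.frame from [associateRules()].
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
writeAssociations <- function(assoc, path) {
  utils::write.table(assoc, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
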