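# The lncRNA risk model: univariate Cox screen, 1:1 cohort split,
# Lasso-Cox selection (glmnet), bidirectional stepwise-AIC refinement over
# unpenalized Cox fits, the linear risk score with median-cutoff
# stratification, a from-scratch log-rank test, IPCW cumulative/dynamic
# time-dependent AUC, and a multivariate Cox (nomogram linear predictor)
# with a binned calibration table. Cox fits use the Efron tie
# approximation throughout.

# align expression columns and clinical rows on their shared samples
.align_surv <- function(expr, clin) {
  ids <- intersect(sample_ids(expr), clin$sample)
  if (length(ids) < 10L) stop("fewer than 10 shared samples", call. = FALSE)
  list(x = expr$values[, ids, drop = FALSE],
       clin = clin[match(ids, clin$sample), , drop = FALSE])
}

#' Univariate Cox screen of candidate lncRNAs
#'
#' One single-covariate Cox fit per lncRNA; lncRNAs with Wald p below
#' `p_cut` are selected. Non-convergent fits are skipped with a warning.
#'
#' @param expr an [expression_matrix()] restricted to (or containing) the
#'   candidate lncRNAs; every row is tested.
#' @param clin clinical data.frame (`sample`, `os_time`, `os_status`);
#'   needs >= 10 events.
#' @param p_cut selection threshold (0.05).
#' @return list: `fits` (data.frame lncrna, coef, hr, ci_low, ci_high,
#'   pvalue, loglik, aic) and `selected` (ids with p < p_cut).
#' @export
univariate_screen <- function(expr, clin, p_cut = 0.05) {
  al <- .align_surv(expr, clin)
  if (sum(al$clin$os_status) < 10L)
    stop("need >= 10 events for the univariate screen", call. = FALSE)
  y <- survival::Surv(al$clin$os_time, al$clin$os_status)
  rows <- lapply(rownames(al$x), function(g) {
    fit <- tryCatch(
      survival::coxph(y ~ x, data = data.frame(x = al$x[g, ]),
                      ties = "efron"),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit) || !is.finite(stats::coef(fit))) {
      warning("univariate Cox did not converge for ", g, "; skipped",
              call. = FALSE)
      return(NULL)
    }
    s <- summary(fit)
    data.frame(lncrna = g,
               coef = unname(stats::coef(fit)),
               hr = unname(s$conf.int[1L, "exp(coef)"]),
               ci_low = unname(s$conf.int[1L, "lower .95"]),
               ci_high = unname(s$conf.int[1L, "upper .95"]),
               pvalue = unname(s$coefficients[1L, "Pr(>|z|)"]),
               loglik = fit$loglik[2L],
               aic = 2 - 2 * fit$loglik[2L],
               stringsAsFactors = FALSE)
  })
  fits <- do.call(rbind, rows)
  if (is.null(fits)) fits <- data.frame()
  rownames(fits) <- NULL
  list(fits = fits,
       selected = if (nrow(fits)) fits$lncrna[fits$pvalue < p_cut]
                  else character())
}

#' Random 1:1 (or `ratio`) train/test split of a cohort
#'
#' @param clin clinical data.frame with >= 20 samples.
#' @param ratio training fraction (0.5); split sizes differ by at most 1
#'   at ratio 0.5.
#' @param seed integer seed; deterministic split.
#' @return list with character vectors `train` and `test`.
#' @export
split_cohort <- function(clin, ratio = 0.5, seed = 1L) {
  ids <- as.character(clin$sample)
  n <- length(ids)
  if (n < 20L) stop("need >= 20 samples to split", call. = FALSE)
  set.seed(seed)
  train <- sort(sample(ids, floor(n * ratio)))
  list(train = train, test = setdiff(ids, train))
}

#' Lasso-Cox feature selection
#'
#' L1-penalized Cox over glmnet's log-spaced lambda path; lambda chosen by
#' cross-validated partial-likelihood deviance (`lambda.min`); features
#' with nonzero coefficients at that lambda are returned.
#'
#' Note that `lambda.min` is deliberately liberal: it tends to carry
#' many small-coefficient passengers into the stepwise-AIC stage (which
#' is what prunes them); `s = "lambda.1se"` selects far more sparsely.
#'
#' @inheritParams univariate_screen
#' @param n_folds CV folds (10).
#' @param seed integer seed (fold assignment).
#' @param s which cross-validated lambda to use: `"lambda.min"`
#'   (default) or `"lambda.1se"`.
#' @return list: `selected` (ids), `coefs` (named nonzero lasso
#'   coefficients), `lambda_min` (the lambda actually used).
#' @export
lasso_cox_select <- function(expr, clin, n_folds = 10L, seed = 1L,
                             s = c("lambda.min", "lambda.1se")) {
  s <- match.arg(s)
  al <- .align_surv(expr, clin)
  if (nrow(al$x) < 2L) stop("need >= 2 candidate features", call. = FALSE)
  y <- survival::Surv(al$clin$os_time, al$clin$os_status)
  xm <- t(al$x)
  set.seed(seed)
  foldid <- sample(rep(seq_len(n_folds), length.out = nrow(xm)))
  cv <- glmnet::cv.glmnet(xm, y, family = "cox", foldid = foldid)
  cf <- as.numeric(stats::coef(cv, s = s))
  names(cf) <- rownames(stats::coef(cv, s = s))
  nz <- cf[cf != 0]
  if (!length(nz))
    warning("all lasso coefficients zero at ", s, call. = FALSE)
  list(selected = names(nz), coefs = nz, lambda_min = cv[[s]])
}

# AIC of a Cox fit on a fixed feature set; NULL model has loglik of the
# empty partial likelihood
.cox_aic <- function(x, y, feats) {
  if (!length(feats)) {
    fit0 <- survival::coxph(y ~ 1)
    return(list(aic = -2 * fit0$loglik[1L], fit = NULL))
  }
  fit <- tryCatch(
    survival::coxph(y ~ ., data = as.data.frame(t(x[feats, , drop = FALSE])),
                    ties = "efron"),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(fit) || any(!is.finite(stats::coef(fit)))) return(NULL)
  list(aic = 2 * length(feats) - 2 * fit$loglik[2L], fit = fit)
}

#' Bidirectional stepwise-AIC refinement of a Cox model
#'
#' Greedy search over unpenalized Cox models, starting from the full
#' candidate set: at each step every single-term removal and re-addition
#' is evaluated and the move with the largest AIC decrease is taken; the
#' search stops when no move decreases AIC. Coefficients of the final fit
#' become the risk model; the training median risk score is stored as the
#' stratification cutoff. Non-convergent moves are skipped.
#'
#' @inheritParams univariate_screen
#' @return an object of class `RiskModel`: list with `terms` (named
#'   coefficient vector), `training_median`, `aic`, `loglik`.
#' @export
stepwise_aic <- function(expr, clin) {
  al <- .align_surv(expr, clin)
  y <- survival::Surv(al$clin$os_time, al$clin$os_status)
  feats <- rownames(al$x)
  if (!length(feats)) stop("need >= 1 candidate feature", call. = FALSE)
  current <- feats
  cur <- .cox_aic(al$x, y, current)
  if (is.null(cur)) stop("full Cox model did not converge", call. = FALSE)
  repeat {
    moves <- list()
    for (f in current)
      moves[[paste0("-", f)]] <- setdiff(current, f)
    for (f in setdiff(feats, current))
      moves[[paste0("+", f)]] <- c(current, f)
    if (!length(moves)) break
    aics <- vapply(moves, function(m) {
      r <- .cox_aic(al$x, y, m)
      if (is.null(r)) Inf else r$aic
    }, numeric(1))
    best <- which.min(aics)
    if (aics[[best]] >= cur$aic - 1e-8) break
    current <- moves[[best]]
    cur <- .cox_aic(al$x, y, current)
  }
  if (!length(current))
    stop("stepwise search removed every term; no risk model", call. = FALSE)
  cf <- stats::coef(cur$fit)
  names(cf) <- current
  model <- structure(list(
    terms = cf,
    training_median = NA_real_,
    aic = cur$aic,
    loglik = cur$fit$loglik[2L]), class = "RiskModel")
  model$training_median <- stats::median(
    risk_score(model, expression_matrix(al$x,
      stats::setNames(rep("lncRNA", nrow(al$x)), rownames(al$x)))))
  model
}

#' Evaluate a risk model: the linear risk score
#'
#' \eqn{score_s = \sum_i coef_i \cdot exp_{is}}: the exact inner product
#' of the model coefficients with the sample's expression of the model
#' lncRNAs.
#'
#' @param model a `RiskModel` (from [stepwise_aic()] or
#'   [read_risk_model()]).
#' @param expr an [expression_matrix()] containing every model lncRNA.
#' @return named numeric vector of per-sample risk scores.
#' @export
risk_score <- function(model, expr) {
  stopifnot(inherits(model, "RiskModel"))
  miss <- setdiff(names(model$terms), gene_ids(expr))
  if (length(miss))
    stop("model lncRNA(s) missing from matrix: ",
         paste(miss, collapse = ", "), call. = FALSE)
  v <- expr$values[names(model$terms), , drop = FALSE]
  stats::setNames(as.numeric(crossprod(v, model$terms)), sample_ids(expr))
}

#' @export
print.RiskModel <- function(x, ...) {
  cat("RiskModel with", length(x$terms), "term(s); training median =",
      format(x$training_median, digits = 4), "\n")
  print(round(x$terms, 4))
  invisible(x)
}

#' Read / write a risk model as JSON
#'
#' The JSON exchange format holds `terms` (array of `{lncrna, coef}`) and
#' `training_median` (number or null).
#'
#' @param path file path.
#' @return [read_risk_model()]: a `RiskModel`.
#' @export
read_risk_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(j$terms) || !length(j$terms))
    stop("risk-model JSON must contain >= 1 term", call. = FALSE)
  cf <- vapply(j$terms, function(t) as.numeric(t$coef), numeric(1))
  names(cf) <- vapply(j$terms, function(t) as.character(t$lncrna),
                      character(1))
  if (any(!is.finite(cf))) stop("non-finite coefficient", call. = FALSE)
  med <- if (is.null(j$training_median)) NA_real_
         else as.numeric(j$training_median)
  structure(list(terms = cf, training_median = med,
                 aic = NA_real_, loglik = NA_real_), class = "RiskModel")
}

#' @rdname read_risk_model
#' @param model a `RiskModel`.
#' @export
write_risk_model <- function(model, path) {
  stopifnot(inherits(model, "RiskModel"))
  obj <- list(
    terms = lapply(seq_along(model$terms), function(i)
      list(lncrna = names(model$terms)[i],
           coef = unname(model$terms[i]))),
    training_median = if (is.na(model$training_median)) NULL
                      else model$training_median)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Two-group log-rank test (observed-minus-expected form)
#'
#' At each distinct event time the expected number of events in group 1
#' is allocated proportionally to the numbers at risk and the
#' hypergeometric variance accumulated; the statistic
#' \eqn{(O - E)^2 / V} is chi-square with 1 df.
#'
#' @param time,status survival times and 0/1 event indicators.
#' @param group logical or two-level vector.
#' @return list: `statistic`, `pvalue`, `observed`, `expected` (group-1
#'   quantities).
#' @export
logrank_test <- function(time, status, group) {
  g <- as.integer(factor(group))
  if (length(unique(g)) != 2L) stop("need exactly 2 groups", call. = FALSE)
  ev <- sort(unique(time[status == 1]))
  O <- E <- V <- 0
  for (t in ev) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == 1L)
    d <- sum(time == t & status == 1)
    d1 <- sum(time == t & status == 1 & g == 1L)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  stat <- if (V > 0) (O - E)^2 / V else 0
  list(statistic = stat,
       pvalue = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       observed = O, expected = E)
}

#' Stratify samples by a risk-score cutoff and log-rank test the strata
#'
#' High risk is `score > cutoff` (the training median by convention).
#'
#' @param scores named risk scores.
#' @param clin clinical data.frame covering the score names.
#' @param cutoff risk-score cutoff.
#' @return list: `labels` (named "high"/"low"), `statistic`, `pvalue`.
#' @export
stratify_and_test <- function(scores, clin, cutoff) {
  cl <- clin[match(names(scores), clin$sample), , drop = FALSE]
  if (anyNA(cl$sample)) stop("clinical rows missing for some samples",
                             call. = FALSE)
  high <- scores > cutoff
  if (!any(high) || all(high))
    stop("empty stratum at cutoff ", format(cutoff), call. = FALSE)
  lr <- logrank_test(cl$os_time, cl$os_status, high)
  list(labels = stats::setNames(ifelse(high, "high", "low"), names(scores)),
       statistic = lr$statistic, pvalue = lr$pvalue)
}

# Kaplan-Meier estimate of the censoring survival G(t) (status flipped),
# evaluated left-continuously at arbitrary times
.censor_km <- function(time, status) {
  fit <- survival::survfit(survival::Surv(time, 1 - status) ~ 1)
  step_t <- fit$time
  step_s <- fit$surv
  function(t) {
    idx <- findInterval(t - 1e-12, step_t)  # G(t-)
    ifelse(idx == 0L, 1, pmax(step_s[pmax(idx, 1L)], 1e-12))
  }
}

#' Time-dependent (cumulative/dynamic) AUC with IPCW
#'
#' Discrimination of a risk score for events occurring by each horizon:
#' cases are subjects with an observed event at or before t, controls
#' those still at risk beyond t; case contributions are weighted by the
#' inverse of the Kaplan-Meier censoring survival at their event time.
#' Horizons beyond the last observed time, or with fewer than 5 prior
#' events, are skipped with a warning.
#'
#' @param scores named risk scores.
#' @param clin clinical data.frame covering the score names.
#' @param horizons evaluation times in days (365/1095/1825).
#' @return named numeric vector of AUCs (NA for skipped horizons).
#' @export
time_dependent_auc <- function(scores, clin,
                               horizons = c(365, 1095, 1825)) {
  cl <- clin[match(names(scores), clin$sample), , drop = FALSE]
  time <- cl$os_time; status <- cl$os_status
  G <- .censor_km(time, status)
  out <- stats::setNames(rep(NA_real_, length(horizons)),
                         paste0("t", horizons))
  for (i in seq_along(horizons)) {
    h <- horizons[[i]]
    if (h > max(time)) {
      warning("horizon ", h, " beyond last observed time; skipped",
              call. = FALSE)
      next
    }
    case <- which(time <= h & status == 1)
    ctrl <- which(time > h)
    if (length(case) < 5L) {
      warning("fewer than 5 events before horizon ", h, "; skipped",
              call. = FALSE)
      next
    }
    w <- 1 / G(time[case])
    conc <- outer(scores[case], scores[ctrl], `>`) +
      0.5 * outer(scores[case], scores[ctrl], `==`)
    num <- sum(w * rowSums(conc))
    den <- sum(w) * length(ctrl)
    out[[i]] <- num / den
  }
  out
}

#' Multivariate Cox model of the risk score with clinical covariates
#'
#' Fits one Cox model on the risk score plus the named clinical columns
#' (characters become factors with the alphabetically first level as
#' reference). The linear predictor is the nomogram score; a binned
#' calibration table compares decile-mean predicted survival at each
#' horizon with the Kaplan-Meier estimate in the bin. Collinear
#' covariates (NA coefficients) are dropped with a warning.
#'
#' @param scores named risk scores.
#' @param clin clinical data.frame with the covariate columns.
#' @param covariates character vector of clinical column names (may be
#'   empty).
#' @param horizons calibration horizons in days.
#' @param n_bins calibration bins (10; reduced if the cohort is small).
#' @return list: `fit_table` (term, coef, hr, ci_low, ci_high, pvalue),
#'   `linear_predictor` (named), `calibration` (data.frame horizon, bin,
#'   n, predicted, observed), `fit` (the coxph object).
#' @export
multivariate_cox <- function(scores, clin, covariates = character(),
                             horizons = c(365, 1095, 1825),
                             n_bins = 10L) {
  cl <- clin[match(names(scores), clin$sample), , drop = FALSE]
  df <- data.frame(risk_score = unname(scores))
  for (cv in covariates) {
    col <- cl[[cv]]
    if (is.null(col)) stop("clinical column not found: ", cv, call. = FALSE)
    df[[cv]] <- if (is.character(col) || is.factor(col))
      factor(col, levels = sort(unique(as.character(col)))) else col
  }
  y <- survival::Surv(cl$os_time, cl$os_status)
  fit <- survival::coxph(y ~ ., data = df, ties = "efron")
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    warning("collinear covariate term(s) dropped: ",
            paste(names(cf)[is.na(cf)], collapse = ", "), call. = FALSE)
    keep_terms <- names(cf)[!is.na(cf)]
    cf <- cf[!is.na(cf)]
  }
  s <- summary(fit)
  ok <- !is.na(s$coefficients[, "coef"])
  fit_table <- data.frame(
    term = rownames(s$coefficients)[ok],
    coef = s$coefficients[ok, "coef"],
    hr = s$coefficients[ok, "exp(coef)"],
    ci_low = s$conf.int[ok, "lower .95"],
    ci_high = s$conf.int[ok, "upper .95"],
    pvalue = s$coefficients[ok, "Pr(>|z|)"],
    stringsAsFactors = FALSE)
  rownames(fit_table) <- NULL
  lp <- stats::setNames(unname(stats::predict(fit, type = "lp")),
                        names(scores))

  # predicted S(t | x) from the uncentered baseline cumulative hazard
  bh <- survival::basehaz(fit, centered = FALSE)
  lp_unc <- stats::predict(fit, type = "lp", reference = "zero")
  cal <- list()
  n_bins <- max(2L, min(n_bins, floor(length(scores) / 10)))
  for (h in horizons[horizons <= max(cl$os_time)]) {
    H0 <- if (any(bh$time <= h)) max(bh$hazard[bh$time <= h]) else 0
    pred <- exp(-H0 * exp(lp_unc))
    bins <- cut(rank(pred, ties.method = "first"),
                breaks = n_bins, labels = FALSE)
    for (b in seq_len(n_bins)) {
      idx <- bins == b
      km <- survival::survfit(
        survival::Surv(cl$os_time[idx], cl$os_status[idx]) ~ 1)
      obs <- if (any(km$time <= h)) min(km$surv[km$time <= h]) else 1
      cal[[length(cal) + 1L]] <- data.frame(
        horizon = h, bin = b, n = sum(idx),
        predicted = mean(pred[idx]), observed = obs)
    }
  }
  calibration <- if (length(cal)) do.call(rbind, cal) else
    data.frame(horizon = numeric(), bin = integer(), n = integer(),
               predicted = numeric(), observed = numeric())
  list(fit_table = fit_table, linear_predictor = lp,
       calibration = calibration, fit = fit)
}

#' End-to-end risk-model construction
#'
#' Convenience wrapper over the full chain: univariate screen on the
#' training half of a seeded 1:1 split, Lasso-Cox selection, stepwise-AIC
#' refinement, then evaluation (median stratification + log-rank,
#' time-dependent AUC) on train, test and the full cohort.
#'
#' @param expr an [expression_matrix()] restricted to candidate lncRNAs.
#' @param clin clinical data.frame.
#' @param seed integer seed driving the split and CV folds.
#' @param split_ratio training fraction (0.5).
#' @param p_cut univariate threshold (0.05).
#' @param horizons AUC horizons in days.
#' @return list: `model`, `split`, `univariate`, `lasso`, `scores`
#'   (full-cohort), `evaluation` (per-cohort log-rank p and AUCs).
#' @export
build_risk_model <- function(expr, clin, seed = 1L, split_ratio = 0.5,
                             p_cut = 0.05, horizons = c(365, 1095, 1825)) {
  clin <- clin[clin$sample %in% sample_ids(expr), , drop = FALSE]
  sp <- split_cohort(clin, ratio = split_ratio, seed = seed)
  train_clin <- clin[clin$sample %in% sp$train, , drop = FALSE]
  expr_train <- subset_expression(expr, samples = sp$train)
  uni <- univariate_screen(expr_train, train_clin, p_cut = p_cut)
  if (!length(uni$selected))
    stop("no lncRNA passes the univariate screen", call. = FALSE)
  cand <- subset_expression(expr_train, genes = uni$selected)
  las <- if (length(uni$selected) >= 2L)
    lasso_cox_select(cand, train_clin, seed = seed)
  else list(selected = uni$selected,
            coefs = stats::setNames(NA_real_, uni$selected),
            lambda_min = NA_real_)
  keep <- if (length(las$selected)) las$selected else uni$selected
  model <- stepwise_aic(subset_expression(expr_train, genes = keep),
                        train_clin)
  scores_all <- risk_score(model, expr)
  evaluation <- lapply(
    list(train = sp$train, test = sp$test, full = clin$sample),
    function(ids) {
      sc <- scores_all[ids]
      st <- stratify_and_test(sc, clin, model$training_median)
      list(logrank_statistic = st$statistic, logrank_pvalue = st$pvalue,
           auc = time_dependent_auc(sc, clin, horizons))
    })
  list(model = model, split = sp, univariate = uni, lasso = las,
       scores = scores_all, evaluation = evaluation)
}
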