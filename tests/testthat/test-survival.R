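# survival_risk: screen, split, lasso, stepAIC, risk score, log-rank,
# AUC, multivariate Cox

lnc_submatrix <- function(ch, genes) subset_expression(ch$expr, genes = genes)

test_that("univariate screen finds planted signal and calibrates on null", {
  ch <- generate_cohort(sim_config(seed = 21, n_samples = 200))
  lncs <- gene_ids(ch$expr)[gene_biotypes(ch$expr) == "lncRNA"][1:20]
  res <- univariate_screen(lnc_submatrix(ch, lncs), ch$clinical)
  expect_true(all(ch$truth$risk_lnc %in% res$selected))
  expect_true(all(res$fits$hr == exp(res$fits$coef)))
  expect_true(all(res$fits$aic == 2 - 2 * res$fits$loglik))

  # a lncRNA exactly proportional to the true risk: strong hazard
  one <- res$fits[res$fits$lncrna == ch$truth$risk_lnc[1], ]
  expect_gt(one$hr, 1); expect_lt(one$pvalue, 0.001)

  # null cohort: pass fraction near the nominal level
  ch0 <- generate_cohort(sim_config(seed = 22, n_samples = 200,
                                    cox_betas = rep(0, 6)))
  lncs0 <- gene_ids(ch0$expr)[gene_biotypes(ch0$expr) == "lncRNA"]
  res0 <- univariate_screen(lnc_submatrix(ch0, lncs0), ch0$clinical)
  expect_lte(length(res0$selected) / nrow(res0$fits), 0.15)
})

test_that("split_cohort is balanced, seeded and exhaustive", {
  cl <- data.frame(sample = paste0("s", 1:101),
                   os_time = 1:101, os_status = 1)
  sp <- split_cohort(cl, seed = 9)
  expect_setequal(c(sp$train, sp$test), cl$sample)
  expect_equal(sort(c(length(sp$train), length(sp$test))), c(50L, 51L))
  expect_identical(sp, split_cohort(cl, seed = 9))
  expect_error(split_cohort(cl[1:10, ]), ">= 20")
})

test_that("lasso retains planted features and drops noise", {
  for (s in 1:3) {
    ch <- generate_cohort(sim_config(
      seed = 30 + s, n_samples = 300,
      cox_betas = rep(c(0.5, -0.5), 3)))
    noise <- setdiff(gene_ids(ch$expr)[
      gene_biotypes(ch$expr) == "lncRNA"],
      ch$truth$true_assoc_lnc)[1:20]
    cand <- lnc_submatrix(ch, c(ch$truth$risk_lnc, noise))
    sel_min <- lasso_cox_select(cand, ch$clinical, seed = s)
    expect_true(all(ch$truth$risk_lnc %in% sel_min$selected),
                label = paste("seed", s))
    # sparse selection (all planted kept, >= half the noise dropped)
    # holds at lambda.1se; lambda.min is deliberately liberal
    sel <- lasso_cox_select(cand, ch$clinical, seed = s,
                            s = "lambda.1se")
    expect_true(all(ch$truth$risk_lnc %in% sel$selected),
                label = paste("seed", s))
    expect_lte(sum(noise %in% sel$selected), 10,
               label = paste("seed", s))
  }
  # strong single candidate (plus one noise column): correct sign
  ch <- generate_cohort(sim_config(seed = 41, n_samples = 300,
                                   n_risk_lnc = 1, cox_betas = 0.6))
  cand <- lnc_submatrix(ch, c(ch$truth$risk_lnc,
                              rev(gene_ids(ch$expr)[
                                gene_biotypes(ch$expr) == "lncRNA"])[1]))
  sel <- lasso_cox_select(cand, ch$clinical, seed = 1)
  expect_true(ch$truth$risk_lnc %in% sel$selected)
  expect_gt(sel$coefs[ch$truth$risk_lnc], 0)
})

test_that("stepwise_aic descends, prunes noise and nears the optimum", {
  # noise pruning across seeds
  pruned <- 0L
  for (s in 1:10) {
    ch <- generate_cohort(sim_config(
      seed = 50 + s, n_samples = 400,
      cox_betas = rep(c(0.5, -0.5), 3)))
    noise <- rev(gene_ids(ch$expr)[
      gene_biotypes(ch$expr) == "lncRNA"])[1]
    model <- stepwise_aic(
      lnc_submatrix(ch, c(ch$truth$risk_lnc, noise)), ch$clinical)
    full <- survival::coxph(
      survival::Surv(os_time, os_status) ~ ., ties = "efron",
      data = data.frame(
        ch$clinical[c("os_time", "os_status")],
        t(ch$expr$values[c(ch$truth$risk_lnc, noise),
                         ch$clinical$sample])))
    full_aic <- 2 * 7 - 2 * full$loglik[2]
    expect_lte(model$aic, full_aic + 1e-8)
    if (!noise %in% names(model$terms)) pruned <- pruned + 1L
  }
  expect_gte(pruned, 8L)

  # exhaustive-search oracle on 4 candidates
  ch <- generate_cohort(sim_config(seed = 61, n_samples = 150,
                                   n_risk_lnc = 2,
                                   cox_betas = c(0.5, -0.5)))
  cand <- c(ch$truth$risk_lnc,
            rev(gene_ids(ch$expr)[gene_biotypes(ch$expr) == "lncRNA"])[1:2])
  model <- stepwise_aic(lnc_submatrix(ch, cand), ch$clinical)
  y <- survival::Surv(ch$clinical$os_time, ch$clinical$os_status)
  xm <- t(ch$expr$values[cand, ch$clinical$sample])
  combos <- unlist(lapply(1:4, function(k)
    utils::combn(cand, k, simplify = FALSE)), recursive = FALSE)
  aics <- sort(vapply(combos, function(cc) {
    f <- survival::coxph(y ~ ., data = as.data.frame(xm[, cc, drop = FALSE]))
    2 * length(cc) - 2 * f$loglik[2]
  }, numeric(1)))
  expect_lte(model$aic, aics[2] + 1e-8)
})

test_that("risk_score is the exact inner product and is linear", {
  model <- read_risk_model(system.file("extdata",
                                       "published_risk_model.json",
                                       package = "lncpath"))
  genes <- names(model$terms)
  mk <- function(v) expression_matrix(
    matrix(v, length(genes), 1, dimnames = list(genes, "s1")),
    stats::setNames(rep("lncRNA", length(genes)), genes))
  expect_equal(unname(risk_score(model, mk(rep(0, 6)))), 0)
  expect_equal(unname(risk_score(model, mk(rep(1, 6)))),
               sum(model$terms))
  set.seed(12)
  a <- rnorm(6); b <- rnorm(6)
  expect_equal(
    unname(risk_score(model, mk(2 * a + 3 * b))),
    unname(2 * risk_score(model, mk(a)) + 3 * risk_score(model, mk(b))),
    tolerance = 1e-12)
  expect_error(risk_score(model, tiny_expr()), "missing")

  # JSON round trip
  f <- tempfile(fileext = ".json")
  m2 <- structure(list(terms = c(g1 = 0.5, g2 = -1.25),
                       training_median = 0.77,
                       aic = NA_real_, loglik = NA_real_),
                  class = "RiskModel")
  write_risk_model(m2, f)
  expect_equal(read_risk_model(f), m2)
})

test_that("log-rank test matches survdiff and guards degenerate cuts", {
  # hand-scale example plus randomized agreement with survival::survdiff
  set.seed(15)
  for (i in 1:20) {
    n <- sample(c(8, 30, 80), 1)
    time <- rexp(n, 0.01)
    status <- rbinom(n, 1, 0.7)
    grp <- rbinom(n, 1, 0.5)
    if (length(unique(grp)) < 2 || sum(status) == 0) next
    lr <- logrank_test(time, status, grp)
    sd <- survival::survdiff(survival::Surv(time, status) ~ grp)
    expect_equal(lr$statistic, sd$chisq, tolerance = 1e-10)
    expect_equal(lr$pvalue,
                 pchisq(lr$statistic, 1, lower.tail = FALSE))
  }
  sc <- stats::setNames(rnorm(30), paste0("s", 1:30))
  cl <- data.frame(sample = paste0("s", 1:30),
                   os_time = rexp(30, 0.01) + 1, os_status = 1)
  expect_error(stratify_and_test(sc, cl, min(sc) - 1), "empty stratum")
  st <- stratify_and_test(sc, cl, stats::median(sc))
  expect_setequal(unique(st$labels), c("high", "low"))
})

test_that("time-dependent AUC: antisymmetry and perfect separation", {
  set.seed(16)
  n <- 120
  time <- rexp(n, 0.002)
  status <- rbinom(n, 1, 0.8)
  cl <- data.frame(sample = paste0("s", 1:n), os_time = time,
                   os_status = status)
  sc <- stats::setNames(rnorm(n), cl$sample)
  auc <- time_dependent_auc(sc, cl, horizons = c(200, 500))
  auc_neg <- time_dependent_auc(-sc, cl, horizons = c(200, 500))
  expect_equal(unname(auc + auc_neg), c(1, 1), tolerance = 1e-10)

  # score = -time with no censoring ranks perfectly
  cl2 <- data.frame(sample = cl$sample, os_time = time, os_status = 1)
  sc2 <- stats::setNames(-time, cl$sample)
  auc2 <- time_dependent_auc(sc2, cl2, horizons = 300)
  expect_equal(unname(auc2), 1)

  expect_warning(time_dependent_auc(sc, cl, horizons = max(time) + 1),
                 "beyond")
})

test_that("multivariate Cox is specific and contrast-invariant", {
  hits <- 0L; misses <- 0L
  for (s in 1:5) {
    ch <- generate_cohort(sim_config(seed = 70 + s, n_samples = 200,
                                     cox_betas = rep(c(0.5, -0.5), 3)))
    sc <- stats::setNames(
      as.numeric(crossprod(
        ch$expr$values[ch$truth$risk_lnc, ch$clinical$sample],
        ch$truth$cox_betas)), ch$clinical$sample)
    mv <- multivariate_cox(sc, ch$clinical, covariates = "stage")
    tab <- mv$fit_table
    if (tab$pvalue[tab$term == "risk_score"] < 0.05) hits <- hits + 1L
    if (all(tab$pvalue[grepl("stage", tab$term)] > 0.05))
      misses <- misses + 1L
  }
  expect_gte(hits, 4L)   # risk score detected
  expect_gte(misses, 3L) # independent stage not implicated (majority)

  # relabeling the reference level shifts the lp by a constant only
  ch <- generate_cohort(sim_config(seed = 81, n_samples = 150))
  sc <- stats::setNames(rnorm(150), ch$clinical$sample)
  cl2 <- ch$clinical
  cl2$stage <- factor(cl2$stage, levels = c("III", "I", "II"))
  lp1 <- multivariate_cox(sc, ch$clinical,
                          covariates = "stage")$linear_predictor
  lp2 <- multivariate_cox(sc, cl2, covariates = "stage")$linear_predictor
  expect_lt(diff(range((lp1 - lp2))), 1e-8)

  # collinear covariate dropped with warning
  cl3 <- ch$clinical
  cl3$dup <- sc[cl3$sample]
  expect_warning(multivariate_cox(sc, cl3, covariates = "dup"),
                 "collinear")
})

test_that("calibration of the oracle predictor is self-consistent", {
  ch <- generate_cohort(sim_config(seed = 90, n_samples = 400,
                                   cox_betas = rep(c(0.5, -0.5), 3)))
  sc <- stats::setNames(
    as.numeric(crossprod(
      ch$expr$values[ch$truth$risk_lnc, ch$clinical$sample],
      ch$truth$cox_betas)), ch$clinical$sample)
  mv <- multivariate_cox(sc, ch$clinical, covariates = character(),
                         horizons = 1095)
  cal <- mv$calibration
  expect_gte(nrow(cal), 8)
  expect_lt(mean(abs(cal$predicted - cal$observed)), 0.12)
})

test_that("build_risk_model runs the whole chain deterministically", {
  ch <- generate_cohort(sim_config(seed = 23, n_samples = 200))
  lncs <- gene_ids(ch$expr)[gene_biotypes(ch$expr) == "lncRNA"][1:25]
  br <- build_risk_model(lnc_submatrix(ch, lncs), ch$clinical, seed = 3)
  expect_s3_class(br$model, "RiskModel")
  expect_gte(length(br$model$terms), 1L)
  expect_true(any(ch$truth$risk_lnc %in% names(br$model$terms)))
  expect_lt(br$evaluation$full$logrank_pvalue, 0.01)
  br2 <- build_risk_model(lnc_submatrix(ch, lncs), ch$clinical, seed = 3)
  expect_identical(br$model$terms, br2$model$terms)
  expect_identical(br$scores, br2$scores)
})
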