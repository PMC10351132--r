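# Synthetic cohort generator. Emulates the statistical structure the
# analysis assumes: a tumor-purity confounder loading on every gene, a
# latent pathway activity shared by a pathway mRNA block and a planted set
# of associated lncRNAs, latent sample subtypes marked by shifted lncRNAs,
# and survival drawn from a Cox model on a subset of the planted lncRNAs.

#' Simulation configuration
#'
#' Returns the default configuration for [generate_cohort()], with any
#' field overridden by name. Fields:
#' \describe{
#'   \item{n_samples}{cohort size (200).}
#'   \item{n_mrna, n_lncrna}{gene counts (1000, 120).}
#'   \item{pathway_size}{mRNAs in the planted pathway block (60).}
#'   \item{n_true_lnc}{lncRNAs planted as pathway-associated (10).}
#'   \item{assoc_strength}{target mean purity-adjusted correlation between
#'     a planted lncRNA and the pathway mRNAs (0.6).}
#'   \item{purity_load}{loading of standardized purity on every gene (0.5).}
#'   \item{n_subtypes}{latent sample subtypes (3).}
#'   \item{subtype_shift}{log2 shift of a subtype's marker lncRNAs (1.5).}
#'   \item{markers_per_subtype}{marker lncRNAs per subtype (5), disjoint
#'     from the planted associated set.}
#'   \item{n_risk_lnc}{lncRNAs driving survival, drawn from the planted
#'     associated set (6).}
#'   \item{cox_betas}{their log-hazard coefficients (default all 0.5;
#'     risk lncRNAs share the pathway activity and are therefore
#'     strongly mutually correlated, so opposing signs would cancel
#'     marginally and defeat the univariate screen).}
#'   \item{censor_rate}{target fraction censored (0.3).}
#'   \item{noise_sd}{per-gene residual SD in log2 units (1.0).}
#'   \item{baseline_hazard}{exponential baseline hazard, per day
#'     (`log(2)/1095`: median survival three years at linear predictor 0).}
#'   \item{seed}{RNG seed (1).}
#' }
#' @param ... named overrides of the defaults above.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_samples = 200L, n_mrna = 1000L, n_lncrna = 120L,
    pathway_size = 60L, n_true_lnc = 10L,
    assoc_strength = 0.6, purity_load = 0.5,
    n_subtypes = 3L, subtype_shift = 1.5, markers_per_subtype = 5L,
    n_risk_lnc = 6L, cox_betas = NULL,
    censor_rate = 0.3, noise_sd = 1.0,
    baseline_hazard = log(2) / 1095,
    seed = 1L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown sim_config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(dots)] <- dots
  if (is.null(cfg$cox_betas))
    cfg$cox_betas <- rep(0.5, cfg$n_risk_lnc)
  stopifnot(
    cfg$n_true_lnc <= cfg$n_lncrna,
    cfg$pathway_size <= cfg$n_mrna,
    cfg$n_risk_lnc <= cfg$n_true_lnc,
    cfg$assoc_strength > 0, cfg$assoc_strength < 1,
    cfg$purity_load >= 0, cfg$purity_load < 1,
    cfg$censor_rate >= 0, cfg$censor_rate < 1,
    cfg$noise_sd > 0,
    length(cfg$cox_betas) == cfg$n_risk_lnc,
    cfg$n_subtypes >= 1,
    cfg$n_true_lnc + cfg$n_subtypes * cfg$markers_per_subtype <= cfg$n_lncrna)
  class(cfg) <- "sim_config"
  cfg
}

# Calibrate the pathway-activity loading v of a planted lncRNA so that the
# mean purity-adjusted correlation with the pathway mRNAs hits `target`.
# After removing purity, a planted lncRNA is v*a + e (e ~ N(0, s^2)) and a
# pathway mRNA is w_j*a + e, so the correlation is
#   v*w_j / sqrt((v^2 + s^2) (w_j^2 + s^2)),
# which increases in v toward the ceiling mean_j w_j/sqrt(w_j^2 + s^2).
# Targets within 5% of the ceiling are clipped to 0.95*ceiling (the solve
# is ill-conditioned there); beyond ceiling + 0.05 the request is
# infeasible for this noise level.
calibrate_activity_loading <- function(target, w, noise_sd) {
  s2 <- noise_sd^2
  mean_cor <- function(v) mean(v * w / sqrt((v^2 + s2) * (w^2 + s2)))
  ceiling_cor <- mean(w / sqrt(w^2 + s2))
  if (target > ceiling_cor + 0.05)
    stop("assoc_strength = ", target, " is infeasible for noise_sd = ",
         noise_sd, " (achievable ceiling ", round(ceiling_cor, 3),
         "); lower assoc_strength or noise_sd", call. = FALSE)
  eff <- min(target, 0.95 * ceiling_cor)
  stats::uniroot(function(v) mean_cor(v) - eff,
                 lower = 1e-6, upper = 1e4, tol = 1e-10)$root
}

#' Generate a synthetic cohort with planted ground truth
#'
#' The generative model, per sample s and gene g (all on the log2 scale):
#' purity \eqn{p_s \sim Beta(5, 2)} with standardized version \eqn{z_s};
#' latent pathway activity \eqn{a_s \sim N(0, 1)}; pathway mRNA j is
#' \eqn{purity\_load \cdot z_s + w_j a_s + \epsilon} with
#' \eqn{w_j \sim U(0.5, 1)}, other mRNAs drop the activity term; a planted
#' associated lncRNA is \eqn{purity\_load \cdot z_s + v a_s + \epsilon}
#' with v calibrated to `assoc_strength` (see
#' `calibrate_activity_loading`); other lncRNAs carry purity and noise
#' only. Each subtype's marker lncRNAs (disjoint from the planted set) are
#' shifted by `subtype_shift` in that subtype; subtype sizes are as equal
#' as possible. Survival times are exponential with hazard
#' \eqn{h_0 \exp(\sum_k \beta_k y_{ks})} over the risk lncRNAs (drawn from
#' the planted set, pre-shift values), censored by an independent
#' exponential whose rate is solved to meet `censor_rate`. Finally all
#' expression is shifted by +8 toward a nonnegative log2 scale. The
#' clinical table carries an independent `stage` covariate for specificity
#' checks. Deterministic given `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return a list of class `lnc_cohort`: `expr` (an
#'   [expression_matrix()]), `purity` (named vector), `clinical`
#'   (data.frame: sample, os_time days, os_status, stage), `gene_sets`
#'   (one-element list holding the pathway mRNA set, named `"PATHWAY"`),
#'   `truth` (planted ground truth: `true_assoc_lnc`, `subtype_labels`,
#'   `marker_lnc`, `risk_lnc`, `cox_betas`, `purity`, `activity`,
#'   `activity_loading`, `linear_predictor`).
#' @export
generate_cohort <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_samples
  samples <- sprintf("S%03d", seq_len(n))
  mrna_ids <- sprintf("mRNA_%04d", seq_len(cfg$n_mrna))
  lnc_ids <- sprintf("lnc_%03d", seq_len(cfg$n_lncrna))

  purity <- stats::rbeta(n, 5, 2)
  z <- as.numeric(scale(purity))
  a <- stats::rnorm(n)

  pathway <- sort(sample(mrna_ids, cfg$pathway_size))
  w <- stats::runif(cfg$pathway_size, 0.5, 1)
  names(w) <- pathway

  mrna <- matrix(stats::rnorm(cfg$n_mrna * n, sd = cfg$noise_sd),
                 cfg$n_mrna, n, dimnames = list(mrna_ids, samples))
  mrna <- mrna + cfg$purity_load * matrix(z, cfg$n_mrna, n, byrow = TRUE)
  mrna[pathway, ] <- mrna[pathway, ] + outer(w, a)

  v <- calibrate_activity_loading(cfg$assoc_strength, w, cfg$noise_sd)
  true_lnc <- lnc_ids[seq_len(cfg$n_true_lnc)]
  lnc <- matrix(stats::rnorm(cfg$n_lncrna * n, sd = cfg$noise_sd),
                cfg$n_lncrna, n, dimnames = list(lnc_ids, samples))
  lnc <- lnc + cfg$purity_load * matrix(z, cfg$n_lncrna, n, byrow = TRUE)
  if (cfg$n_true_lnc > 0)
    lnc[true_lnc, ] <- lnc[true_lnc, ] + outer(rep(v, cfg$n_true_lnc), a)

  # latent subtypes: balanced random assignment, markers disjoint from the
  # planted associated lncRNAs
  subtype <- sample(rep(seq_len(cfg$n_subtypes), length.out = n))
  names(subtype) <- samples
  marker_pool <- setdiff(lnc_ids, true_lnc)
  marker_lnc <- split(
    marker_pool[seq_len(cfg$n_subtypes * cfg$markers_per_subtype)],
    rep(seq_len(cfg$n_subtypes), each = cfg$markers_per_subtype))
  for (k in seq_len(cfg$n_subtypes))
    lnc[marker_lnc[[k]], subtype == k] <-
      lnc[marker_lnc[[k]], subtype == k] + cfg$subtype_shift

  # survival from a Cox-exponential model on pre-shift risk lncRNAs
  risk_lnc <- true_lnc[seq_len(cfg$n_risk_lnc)]
  lp <- if (cfg$n_risk_lnc > 0)
    as.numeric(crossprod(lnc[risk_lnc, , drop = FALSE], cfg$cox_betas))
  else rep(0, n)
  hazard <- cfg$baseline_hazard * exp(lp)
  t_event <- stats::rexp(n, rate = hazard)
  if (cfg$censor_rate > 0) {
    cens_rate <- stats::uniroot(
      function(cr) mean(cr / (cr + hazard)) - cfg$censor_rate,
      lower = 1e-12, upper = 1e6, tol = 1e-12)$root
    t_cens <- stats::rexp(n, rate = cens_rate)
  } else t_cens <- rep(Inf, n)
  os_time <- pmin(t_event, t_cens)
  os_status <- as.integer(t_event <= t_cens)

  clinical <- data.frame(
    sample = samples,
    os_time = os_time,
    os_status = os_status,
    stage = sample(c("I", "II", "III"), n, replace = TRUE),
    stringsAsFactors = FALSE)

  values <- rbind(lnc, mrna) + 8  # toward a nonnegative log2 scale
  biotype <- c(stats::setNames(rep("lncRNA", cfg$n_lncrna), lnc_ids),
               stats::setNames(rep("mRNA", cfg$n_mrna), mrna_ids))
  expr <- expression_matrix(values, biotype)
  names(purity) <- samples

  structure(list(
    expr = expr,
    purity = purity,
    clinical = clinical,
    gene_sets = structure(list(PATHWAY = pathway),
                          class = c("GeneSetCollection", "list")),
    truth = list(
      true_assoc_lnc = true_lnc,
      subtype_labels = subtype,
      marker_lnc = marker_lnc,
      risk_lnc = risk_lnc,
      cox_betas = stats::setNames(cfg$cox_betas, risk_lnc),
      purity = purity,
      activity = stats::setNames(a, samples),
      activity_loading = v,
      linear_predictor = stats::setNames(lp, samples)),
    config = cfg), class = "lnc_cohort")
}

#' Write a generated cohort to disk
#'
#' Emits `expression.tsv`, `biotype.tsv`, `purity.tsv`, `clinical.tsv`,
#' `pathway.gmt` and `truth.json` under `outdir` in the formats the
#' [read_expression()] family reads back.
#'
#' @param cohort result of [generate_cohort()].
#' @param outdir output directory (created if absent).
#' @param force overwrite existing files (default `FALSE`: refuse).
#' @return invisibly, named vector of file paths.
#' @export
write_cohort <- function(cohort, outdir, force = FALSE) {
  stopifnot(inherits(cohort, "lnc_cohort"))
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  paths <- c(expression = file.path(outdir, "expression.tsv"),
             biotype = file.path(outdir, "biotype.tsv"),
             purity = file.path(outdir, "purity.tsv"),
             clinical = file.path(outdir, "clinical.tsv"),
             gmt = file.path(outdir, "pathway.gmt"),
             truth = file.path(outdir, "truth.json"))
  if (!force && any(file.exists(paths)))
    stop("output files exist in ", outdir, "; use force = TRUE to overwrite",
         call. = FALSE)
  write_expression(cohort$expr, paths[["expression"]], paths[["biotype"]])
  write_purity(cohort$purity, paths[["purity"]])
  write_clinical(cohort$clinical, paths[["clinical"]])
  write_gmt(cohort$gene_sets, paths[["gmt"]])
  truth <- cohort$truth
  truth$subtype_labels <- as.list(truth$subtype_labels)
  truth$cox_betas <- as.list(truth$cox_betas)
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
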