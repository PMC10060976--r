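# Survival analysis: Kaplan-Meier, Peto-Peto weighted log-rank, spline Cox
# per gene, ridge-regularized multi-parameter Cox, concordance comparison.

#' Kaplan-Meier product-limit estimate
#'
#' @param time Follow-up times (days, > 0).
#' @param event Event indicators (0 = censored, 1 = event).
#' @param group Optional group labels for stratified curves.
#' @return Tibble with `time`, `n_risk`, `n_event`, `n_censor`, `surv` (and
#'   `group` when stratified). A cohort without events yields a flat curve
#'   at 1 with a warning.
#' @export
kaplan_meier <- function(time, event, group = NULL) {
  stopifnot(all(time >= 0), all(event %in% c(0, 1)))
  if (sum(event) == 0) warning("no events; survival curve is flat at 1",
                               call. = FALSE)
  if (is.null(group)) {
    fit <- survfit(Surv(time, event) ~ 1)
    tibble(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
           n_censor = fit$n.censor, surv = fit$surv)
  } else {
    g <- factor(group)
    fit <- survfit(Surv(time, event) ~ g)
    grp <- rep(sub("^g=", "", names(fit$strata)), fit$strata)
    tibble(group = grp, time = fit$time, n_risk = fit$n.risk,
           n_event = fit$n.event, n_censor = fit$n.censor, surv = fit$surv)
  }
}

#' Peto-Peto weighted log-rank test
#'
#' Two-group weighted log-rank test with weights from the Peto-Peto
#' modified pooled survivor estimate `S~(t) = prod_{t_i <= t} (1 - d_i /
#' (n_i + 1))`, which emphasizes early hazard differences. With
#' `weighting = "logrank"` all weights are 1, recovering the standard
#' log-rank statistic (useful as an internal cross-check).
#'
#' @param time,event Follow-up times and 0/1 event indicators.
#' @param group Two-level group labels.
#' @param weighting `"peto"` (default) or `"logrank"`.
#' @return One-row tibble: `chisq` (1 df), `p`, `observed` and `expected`
#'   events in the first group.
#' @export
peto_peto_test <- function(time, event, group, weighting = c("peto",
                                                             "logrank")) {
  weighting <- match.arg(weighting)
  g <- factor(group)
  if (nlevels(g) != 2L) stop("exactly two groups required", call. = FALSE)
  if (any(table(g) == 0L)) stop("empty group", call. = FALSE)
  if (sum(event) == 0) stop("no events in either group", call. = FALSE)

  ord <- order(time)
  time <- time[ord]; event <- event[ord]; g <- g[ord]
  is1 <- g == levels(g)[1L]
  ev_times <- unique(time[event == 1])

  u <- 0; v <- 0; obs <- 0; expct <- 0
  s_tilde <- 1
  for (t in ev_times) {
    at_risk <- time >= t
    n_j <- sum(at_risk)
    d_j <- sum(event == 1 & time == t)
    n1_j <- sum(at_risk & is1)
    d1_j <- sum(event == 1 & time == t & is1)
    s_tilde <- s_tilde * (1 - d_j / (n_j + 1))
    w <- if (weighting == "peto") s_tilde else 1
    e1 <- d_j * n1_j / n_j
    u <- u + w * (d1_j - e1)
    if (n_j > 1) {
      v <- v + w^2 * d_j * (n_j - d_j) / (n_j - 1) *
        (n1_j / n_j) * (1 - n1_j / n_j)
    }
    obs <- obs + d1_j
    expct <- expct + e1
  }
  chisq <- if (v > 0) u^2 / v else 0
  p <- if (v > 0) pchisq(chisq, df = 1, lower.tail = FALSE) else 1
  tibble(chisq = chisq, p = p, observed = obs, expected = expct)
}

#' Uni-variable Cox model with linear and spline terms
#'
#' Fits the proportional-hazards model for one expression covariate twice:
#' with a linear term only, and with a natural cubic spline basis
#' (`splines::ns`, interior knots at quantiles; df 3 puts them at
#' terciles). The hazard ratio per 1 log2 unit comes from the linear fit;
#' `spline_p` is the likelihood-ratio test of the nonlinear spline
#' components against the nested linear model.
#'
#' @param time,event Follow-up times and 0/1 event indicators (>= 10
#'   events).
#' @param x Numeric covariate (e.g. log2 expression of one gene).
#' @param spline_df Spline degrees of freedom (default 3).
#' @return One-row tibble: `hr`, `ci_low`, `ci_high`, `p`, `spline_p`,
#'   `converged`. Non-convergence yields a flagged row, not an error.
#' @export
cox_univariable <- function(time, event, x, spline_df = 3L) {
  stopifnot(length(x) == length(time))
  if (sum(event) < 10L) stop("need at least 10 events", call. = FALSE)
  if (sd(x) == 0) stop("constant covariate", call. = FALSE)
  out <- tryCatch({
    lin <- coxph(Surv(time, event) ~ x)
    spl <- coxph(Surv(time, event) ~ splines::ns(x, df = spline_df))
    lrt <- 2 * (logLik(spl)[1L] - logLik(lin)[1L])
    spline_p <- pchisq(max(lrt, 0), df = spline_df - 1L, lower.tail = FALSE)
    beta <- unname(coef(lin)[1L])
    se <- sqrt(lin$var[1L, 1L])
    tibble(hr = exp(beta), ci_low = exp(beta - qnorm(0.975) * se),
           ci_high = exp(beta + qnorm(0.975) * se),
           p = 2 * pnorm(-abs(beta / se)), spline_p = spline_p,
           converged = TRUE)
  }, error = function(e) {
    tibble(hr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
           p = NA_real_, spline_p = NA_real_, converged = FALSE)
  }, warning = function(w) {
    tibble(hr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
           p = NA_real_, spline_p = NA_real_, converged = FALSE)
  })
  out
}

#' Per-gene Cox screen with FDR
#'
#' Runs [cox_univariable()] for each gene of a cohort and adjusts linear and
#' spline p-values across genes with BH-FDR.
#'
#' @param cohort An `expression_cohort` with `os_time`/`os_event` metadata.
#' @param genes Genes to screen.
#' @param spline_df Passed to [cox_univariable()].
#' @return Tibble with one row per gene plus `fdr` and `spline_fdr`.
#' @export
cox_gene_screen <- function(cohort, genes, spline_df = 3L) {
  stopifnot(inherits(cohort, "expression_cohort"))
  meta <- cohort$sample_meta
  ok <- !is.na(meta$os_time) & !is.na(meta$os_event)
  ids <- meta$sample_id[ok]
  idx <- match_genes(genes, rownames(cohort$values))
  rows <- lapply(seq_along(genes), function(i) {
    res <- cox_univariable(meta$os_time[ok], meta$os_event[ok],
                           cohort$values[idx[i], ids], spline_df = spline_df)
    res$gene <- genes[i]
    res
  })
  out <- dplyr::bind_rows(rows)
  out$fdr <- ifelse(is.na(out$p), NA_real_, bh_fdr(ifelse(is.na(out$p), 1, out$p)))
  out$spline_fdr <- ifelse(is.na(out$spline_p), NA_real_,
                           bh_fdr(ifelse(is.na(out$spline_p), 1, out$spline_p)))
  out[, c("gene", "hr", "ci_low", "ci_high", "p", "fdr", "spline_p",
          "spline_fdr", "converged")]
}

#' Ridge-regularized Cox model with cross-validated penalty
#'
#' L2-penalized partial likelihood (`glmnet`, `alpha = 0`); the penalty is
#' chosen by k-fold cross-validation maximizing the cross-validated partial
#' likelihood, with folds stratified by event status. Zero-variance columns
#' are dropped with a warning. When a validation set is supplied, Harrell's
#' concordance of the linear predictor on it is reported.
#'
#' @param time,event Training follow-up and 0/1 event indicators (>= 20
#'   events).
#' @param covariates Numeric matrix, samples x covariates (>= 2 columns
#'   after dropping degenerate ones).
#' @param val_time,val_event,val_covariates Optional validation cohort.
#' @param nfolds Number of CV folds (default 10).
#' @param seed Optional seed for the fold split.
#' @param lambda Optional penalty grid passed to `glmnet`.
#' @return List with `coefficients` (named, at the optimal penalty),
#'   `lambda`, `fit` (the `cv.glmnet` object), and `concordance` (validation
#'   C-index, `NA` without a validation set).
#' @export
ridge_cox <- function(time, event, covariates,
                      val_time = NULL, val_event = NULL,
                      val_covariates = NULL,
                      nfolds = 10L, seed = NULL, lambda = NULL) {
  covariates <- as.matrix(covariates)
  if (sum(event) < 20L) stop("need at least 20 events", call. = FALSE)
  sds <- apply(covariates, 2L, sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance column(s): ",
            paste(colnames(covariates)[sds == 0], collapse = ", "),
            call. = FALSE)
    covariates <- covariates[, sds > 0, drop = FALSE]
    if (!is.null(val_covariates)) {
      val_covariates <- as.matrix(val_covariates)[, sds > 0, drop = FALSE]
    }
  }
  if (ncol(covariates) < 2L) stop("need at least 2 usable covariates",
                                  call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  # event-stratified folds
  foldid <- integer(length(time))
  for (lv in c(0, 1)) {
    i <- which(event == lv)
    foldid[i] <- sample(rep(seq_len(nfolds), length.out = length(i)))
  }
  y <- Surv(time, event)
  cv <- glmnet::cv.glmnet(covariates, y, family = "cox", alpha = 0,
                          foldid = foldid, lambda = lambda)
  beta <- as.numeric(coef(cv, s = "lambda.min"))
  names(beta) <- rownames(coef(cv, s = "lambda.min"))
  cindex <- NA_real_
  if (!is.null(val_time)) {
    risk <- as.numeric(predict(cv, newx = as.matrix(val_covariates),
                               s = "lambda.min"))
    cindex <- concordance_index(risk, val_time, val_event)
  }
  list(coefficients = beta, lambda = cv$lambda.min, fit = cv,
       concordance = cindex)
}

#' Harrell's concordance index
#'
#' Probability that, of two comparable samples, the one with the higher
#' risk score fails earlier. Tied scores count 0.5; censored-censored pairs
#' are unusable. Invariant to monotone transforms of the risk score.
#'
#' @param risk Numeric risk scores (higher = worse prognosis).
#' @param time,event Follow-up times and 0/1 event indicators.
#' @return Concordance in `[0, 1]`.
#' @export
concordance_index <- function(risk, time, event) {
  stopifnot(length(risk) == length(time))
  if (sum(event) == 0) stop("no usable pairs (no events)", call. = FALSE)
  fit <- concordance(Surv(time, event) ~ risk, reverse = TRUE)
  cc <- unname(fit$concordance)
  if (!is.finite(cc)) stop("no usable pairs", call. = FALSE)
  cc
}
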