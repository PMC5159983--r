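# Group-comparison statistics: Welch t-tests with BH-FDR over feature
# families (domains, chromosomes, promoters, CGIs, gene bodies, windows,
# chromatin-state elements), chromatin-state methylation profiles,
# unit-scaled univariate regressions, and AIC model selection with
# heteroscedasticity-robust confidence intervals.

#' Welch two-sample t-test
#'
#' Unequal-variance two-sided t-test with Welch-Satterthwaite degrees of
#' freedom (the conservative default when group variances are not assumed
#' equal); `var_equal = TRUE` gives the pooled-variance variant. Degenerate
#' inputs follow explicit conventions: if both groups have zero variance the
#' p-value is 1 for equal means and 0 (flagged) for unequal means.
#'
#' @param a,b numeric vectors (NA dropped), each with at least 2 values.
#' @param var_equal use pooled variance instead of Welch.
#' @return list(t, df, p, mean_a, mean_b, degenerate).
#' @export
welch_ttest <- function(a, b, var_equal = FALSE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2)
    stop("welch_ttest: each group needs at least 2 values")
  na <- length(a); nb <- length(b)
  va <- var(a); vb <- var(b)
  ma <- mean(a); mb <- mean(b)
  if (va == 0 && vb == 0) {
    p <- if (ma == mb) 1 else 0
    return(list(t = if (ma == mb) 0 else sign(ma - mb) * Inf,
                df = NA_real_, p = p, mean_a = ma, mean_b = mb,
                degenerate = TRUE))
  }
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  t <- (ma - mb) / se
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df),
       mean_a = ma, mean_b = mb, degenerate = FALSE)
}

#' Benjamini-Hochberg FDR adjustment and rejection set
#'
#' Step-up BH q-values (via [stats::p.adjust()]) with the rejection set at
#' `q <= alpha`.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @param alpha FDR level (default 0.05).
#' @return list(q, rejected) with `rejected` logical.
#' @export
bh_fdr <- function(pvalues, alpha = 0.05) {
  if (!length(pvalues)) return(list(q = numeric(0), rejected = logical(0)))
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("bh_fdr: p-values must lie in [0, 1]")
  q <- stats::p.adjust(pvalues, method = "BH")
  list(q = q, rejected = q <= alpha)
}

# row-wise Welch statistics over a features x samples matrix (same formulas
# as welch_ttest, vectorised; NAs handled per row)
row_welch <- function(x, ia, ib, var_equal = FALSE) {
  xa <- x[, ia, drop = FALSE]; xb <- x[, ib, drop = FALSE]
  na <- rowSums(!is.na(xa)); nb <- rowSums(!is.na(xb))
  ma <- rowMeans(xa, na.rm = TRUE); mb <- rowMeans(xb, na.rm = TRUE)
  va <- rowSums((xa - ma)^2, na.rm = TRUE) / pmax(na - 1, 1)
  vb <- rowSums((xb - mb)^2, na.rm = TRUE) / pmax(nb - 1, 1)
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / pmax(na + nb - 2, 1)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / pmax(na - 1, 1) + (vb / nb)^2 / pmax(nb - 1, 1))
  }
  t <- (ma - mb) / se
  data.frame(n_a = na, n_b = nb, mean_a = ma, mean_b = mb,
             var_a = va, var_b = vb, t = t, df = df,
             p = 2 * stats::pt(-abs(t), df))
}

#' Per-feature differential methylation scan
#'
#' One Welch t-test per feature (row) between two diagnostic groups, with
#' BH-FDR within the feature class as its own family. Features with fewer
#' than 2 non-missing values in either group, or zero variance in both
#' groups, are skipped and counted rather than assigned artificial p-values.
#'
#' @param values features x samples numeric matrix (row names = feature ids).
#' @param groups vector of group labels per column (e.g. "ASD"/"TD").
#' @param feature_class label for this feature family (e.g. "HMD",
#'   "promoter", "window20kb", "chromhmm_state_element").
#' @param group_a,group_b the two labels to compare (defaults "ASD", "TD";
#'   other columns are ignored).
#' @param alpha FDR level.
#' @param var_equal pooled-variance option passed through to the t-test.
#' @return A `feature_stat_table` data.frame sorted by (q, p): feature_id,
#'   feature_class, mean per group, t, df, p, q, rejected; attributes
#'   `n_skipped` and `skipped_ids`.
#' @export
feature_scan <- function(values, groups, feature_class = "feature",
                         group_a = "ASD", group_b = "TD",
                         alpha = 0.05, var_equal = FALSE) {
  stopifnot(is.matrix(values), length(groups) == ncol(values))
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("%s_%d", feature_class, seq_len(nrow(values)))
  ia <- which(groups == group_a); ib <- which(groups == group_b)
  if (length(ia) < 2 || length(ib) < 2)
    stop("feature_scan: each group needs at least 2 samples")
  st <- row_welch(values, ia, ib, var_equal = var_equal)
  usable <- st$n_a >= 2 & st$n_b >= 2 & (st$var_a > 0 | st$var_b > 0)
  skipped <- rownames(values)[!usable]
  res <- data.frame(feature_id = rownames(values)[usable],
                    feature_class = feature_class,
                    mean_a = st$mean_a[usable], mean_b = st$mean_b[usable],
                    t = st$t[usable], df = st$df[usable], p = st$p[usable])
  names(res)[names(res) == "mean_a"] <- paste0("mean_", group_a)
  names(res)[names(res) == "mean_b"] <- paste0("mean_", group_b)
  fdr <- bh_fdr(res$p, alpha = alpha)
  res$q <- fdr$q
  res$rejected <- fdr$rejected
  res <- res[order(res$q, res$p), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_skipped") <- length(skipped)
  attr(res, "skipped_ids") <- skipped
  class(res) <- c("feature_stat_table", "data.frame")
  res
}

#' Chromatin-state methylation profile
#'
#' For each chromatin-state element, percent methylation is the mean over the
#' element's per-CpG fractions within a sample (per-CpG mean, not a count
#' pool, so deeply covered CpGs do not dominate an element), then averaged
#' across the samples of each group. State-level distributions are
#' summarized as box-plot statistics: median, quartiles, and whiskers at the
#' furthest element within 1.5 x IQR of the quartiles.
#'
#' @param tracks named list of [cpg_track()]s.
#' @param elements data.frame (chrom, start, end, state) of state elements.
#' @param groups named vector of group labels per sample.
#' @return list: `elements` (per-element per-group means) and `states`
#'   (per state x group box summaries).
#' @export
chromstate_profile <- function(tracks, elements, groups) {
  elements <- as.data.frame(elements)
  if ("name" %in% names(elements) && !"state" %in% names(elements))
    elements$state <- elements$name
  stopifnot(all(c("chrom", "start", "end", "state") %in% names(elements)))
  if (is.null(names(tracks)))
    names(tracks) <- vapply(tracks, function(t)
      as.character(attr(t, "sample_id")), character(1))
  ne <- nrow(elements)
  element_ids <- sprintf("%s:%.0f-%.0f", elements$chrom, elements$start,
                         elements$end)
  per_sample <- matrix(NA_real_, ne, length(tracks),
                       dimnames = list(element_ids, names(tracks)))
  for (s in names(tracks)) {
    tr <- tracks[[s]]
    idx <- assign_to_intervals(tr, elements)
    ok <- !is.na(idx) & tr$total > 0
    if (!any(ok)) next
    fr <- tr$meth[ok] / tr$total[ok]
    sums <- rowsum(fr, idx[ok])
    cnts <- rowsum(rep(1, sum(ok)), idx[ok])
    per_sample[as.integer(rownames(sums)), s] <- sums[, 1] / cnts[, 1]
  }
  glabs <- groups[names(tracks)]
  out <- data.frame(element_id = element_ids,
                    elements[c("chrom", "start", "end", "state")])
  for (g in unique(glabs)) {
    cols <- which(glabs == g)
    out[[paste0("mean_", g)]] <- rowMeans(per_sample[, cols, drop = FALSE],
                                          na.rm = TRUE)
  }
  box <- function(v) {
    v <- v[is.finite(v)]
    if (!length(v)) return(data.frame(median = NA_real_, q1 = NA_real_,
                                      q3 = NA_real_, whisker_lo = NA_real_,
                                      whisker_hi = NA_real_, n = 0L))
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3] - q[1]
    data.frame(median = q[2], q1 = q[1], q3 = q[3],
               whisker_lo = min(v[v >= q[1] - 1.5 * iqr]),
               whisker_hi = max(v[v <= q[3] + 1.5 * iqr]), n = length(v))
  }
  states <- do.call(rbind, lapply(unique(elements$state), function(stt) {
    do.call(rbind, lapply(unique(glabs), function(g) {
      cbind(data.frame(state = stt, group = g),
            box(out[out$state == stt, paste0("mean_", g)]))
    }))
  }))
  rownames(states) <- NULL
  list(elements = out, states = states, per_sample = per_sample)
}

#' Unit-scaled univariate regressions of global methylation metrics
#'
#' Ordinary least squares of each response on each predictor separately,
#' including declared "adjusted for" two-predictor models (e.g. PMD mean
#' adjusted for HMD mean). Responses are first rescaled by their declared
#' unit (e.g. 5 percentage points for PMD methylation, 2 for HMD, 5 for the
#' percent of windows below 60%) so a coefficient reads as "units of
#' response per unit of predictor". Factor predictors are releveled to the
#' declared reference (e.g. race/ethnicity reference "white non-Hispanic",
#' sex reference "M"). BH-FDR is applied across the whole family of
#' predictor coefficients.
#'
#' @param responses data.frame of per-sample responses, in percent.
#' @param predictors data.frame of per-sample covariates (same row order).
#' @param units named numeric vector: percentage points per unit, by response
#'   name (unnamed responses default to unit 1).
#' @param adjust named list: response -> covariate to adjust for (fits an
#'   extra model response ~ predictor + covariate for every predictor). The
#'   covariate may name a predictor column or another response column (e.g.
#'   PMD methylation adjusted for HMD methylation).
#' @param ref_levels named list: predictor column -> reference level.
#' @param alpha FDR level.
#' @return A `regression_report` data.frame: response, predictor,
#'   adjusted_for, term, estimate, se, ci_lo, ci_hi, robust_se, robust_ci_lo,
#'   robust_ci_hi, p, q, n.
#' @export
univariate_regressions <- function(responses, predictors, units = NULL,
                                   adjust = NULL, ref_levels = NULL,
                                   alpha = 0.05) {
  responses <- as.data.frame(responses)
  predictors <- as.data.frame(predictors)
  stopifnot(nrow(responses) == nrow(predictors))
  for (nm in names(ref_levels)) {
    if (nm %in% names(predictors))
      predictors[[nm]] <- stats::relevel(factor(predictors[[nm]]),
                                         ref = ref_levels[[nm]])
  }
  rows <- list()
  for (rn in names(responses)) {
    unit <- if (!is.null(units) && rn %in% names(units)) units[[rn]] else 1
    y <- responses[[rn]] / unit
    adj_for <- if (!is.null(adjust) && rn %in% names(adjust))
      adjust[[rn]] else NA_character_
    # the adjustment covariate may be another response (e.g. PMD methylation
    # adjusted for HMD methylation) or one of the predictors
    adj_vals <- if (is.na(adj_for)) NULL
      else if (adj_for %in% names(predictors)) predictors[[adj_for]]
      else if (adj_for %in% names(responses)) responses[[adj_for]]
      else stop("univariate_regressions: unknown adjustment covariate '",
                adj_for, "' for response ", rn)
    for (pn in names(predictors)) {
      specs <- list(c(pn))
      if (!is.na(adj_for) && !identical(pn, adj_for))
        specs <- c(specs, list(c(pn, adj_for)))
      for (covs in specs) {
        dat <- data.frame(.y = y, predictors[pn])
        if (length(covs) > 1) dat[[adj_for]] <- adj_vals
        dat <- dat[stats::complete.cases(dat), , drop = FALSE]
        if (nrow(dat) < 3) stop("univariate_regressions: < 3 complete samples for ",
                                rn, " ~ ", paste(covs, collapse = " + "))
        fit <- tryCatch(stats::lm(stats::reformulate(covs, ".y"), data = dat),
                        error = function(e) stop("fit error for ", rn, ": ",
                                                 conditionMessage(e)))
        if (any(is.na(stats::coef(fit))))
          stop("univariate_regressions: rank-deficient design for ", rn,
               " ~ ", paste(covs, collapse = " + "), "; collinear columns: ",
               paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
                     collapse = ", "))
        sm <- summary(fit)$coefficients
        vr <- sandwich::vcovHC(fit, type = "HC1")
        tq <- stats::qt(0.975, stats::df.residual(fit))
        terms_keep <- grep(paste0("^", pn), rownames(sm), value = TRUE)
        for (tm in terms_keep) {
          est <- sm[tm, "Estimate"]; se <- sm[tm, "Std. Error"]
          rse <- sqrt(vr[tm, tm])
          rows[[length(rows) + 1]] <- data.frame(
            response = rn, predictor = pn,
            adjusted_for = if (length(covs) > 1) covs[2] else NA_character_,
            term = tm, estimate = est, se = se,
            ci_lo = est - tq * se, ci_hi = est + tq * se,
            robust_se = rse,
            robust_ci_lo = est - tq * rse, robust_ci_hi = est + tq * rse,
            p = sm[tm, "Pr(>|t|)"], n = nrow(dat))
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  fdr <- bh_fdr(out$p, alpha = alpha)
  out$q <- fdr$q
  out$rejected <- fdr$rejected
  rownames(out) <- NULL
  class(out) <- c("regression_report", "data.frame")
  out
}

#' AIC model selection with sandwich-robust confidence intervals
#'
#' Fits every candidate OLS model on the identical sample set, selects the
#' minimum-AIC candidate (Gaussian likelihood; ties go to the model with
#' fewer parameters, then to the first declared), and reports HC1
#' heteroscedasticity-consistent 95% confidence intervals for the selected
#' model's coefficients.
#'
#' @param response numeric response vector.
#' @param data data.frame of covariates.
#' @param candidates named list of character vectors of covariate names; an
#'   empty vector is the intercept-only model.
#' @param aicc use the small-sample corrected AICc instead of AIC.
#' @return list: `aic` data.frame (model, aic, n_params, selected), `fit`
#'   (the selected lm), `coefficients` data.frame with estimate, robust_se,
#'   robust_ci_lo, robust_ci_hi, p.
#' @export
model_select_robust <- function(response, data, candidates, aicc = FALSE) {
  stopifnot(is.list(candidates), length(candidates) >= 1)
  if (is.null(names(candidates)))
    names(candidates) <- vapply(candidates, function(cv)
      if (length(cv)) paste(cv, collapse = "+") else "intercept", character(1))
  data <- as.data.frame(data)
  allc <- unique(unlist(candidates))
  cc <- stats::complete.cases(cbind(data.frame(.y = response),
                                    data[allc]))
  if (!all(cc))
    stop("model_select_robust: candidates would fit on differing sample ",
         "subsets (missing values present); supply complete cases")
  dat <- data.frame(.y = response, data)
  fits <- lapply(candidates, function(cv) {
    f <- if (length(cv)) stats::reformulate(cv, ".y") else
      stats::as.formula(".y ~ 1")
    stats::lm(f, data = dat)
  })
  aics <- vapply(fits, stats::AIC, numeric(1))
  npar <- vapply(fits, function(f) length(stats::coef(f)) + 1, numeric(1))
  if (aicc) {
    n_obs <- length(response)
    aics <- aics + 2 * npar * (npar + 1) / (n_obs - npar - 1)
  }
  # minimum AIC; ties -> fewer parameters, then first declared
  best <- order(aics, npar, seq_along(fits))[1]
  fit <- fits[[best]]
  vr <- sandwich::vcovHC(fit, type = "HC1")
  sm <- summary(fit)$coefficients
  tq <- stats::qt(0.975, stats::df.residual(fit))
  est <- stats::coef(fit)
  rse <- sqrt(diag(vr))[names(est)]
  coefs <- data.frame(term = names(est), estimate = unname(est),
                      robust_se = unname(rse),
                      robust_ci_lo = unname(est - tq * rse),
                      robust_ci_hi = unname(est + tq * rse),
                      p = sm[names(est), "Pr(>|t|)"])
  rownames(coefs) <- NULL
  list(aic = data.frame(model = names(candidates), aic = aics,
                        n_params = npar,
                        selected = seq_along(fits) == best),
       fit = fit, coefficients = coefs,
       selected = names(candidates)[best])
}
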