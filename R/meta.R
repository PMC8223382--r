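#' Weighted prevalence with Kish effective sample size
#'
#' Prevalence \eqn{\sum w y / \sum w}; the variance uses the Kish effective
#' sample size \eqn{(\sum w)^2/\sum w^2} so unequal sampling weights inflate
#' uncertainty: \eqn{var = p(1-p)/n_{eff}}.
#'
#' @param y binary outcome vector.
#' @param w positive sampling weights.
#' @return list with `prev`, `var`, `eff_n`.
#' @export
weighted_prevalence <- function(y, w) {
  if (length(y) == 0L) stop("empty subset")
  if (sum(w) <= 0) stop("zero total weight")
  prev <- wmean(y, w)
  eff_n <- kish_eff_n(w)
  list(prev = prev, var = prev * (1 - prev) / eff_n, eff_n = eff_n)
}

#' Z-test for equality of two prevalences
#'
#' Pooled-proportion two-sample z statistic on effective sample sizes;
#' two-sided p-value.
#'
#' @param p1,p2 group prevalences.
#' @param eff_n1,eff_n2 effective sample sizes.
#' @return list with `z` and `p`, or an error when the pooled proportion is
#'   degenerate (0 or 1).
#' @export
z_test_two_proportions <- function(p1, eff_n1, p2, eff_n2) {
  if (eff_n1 <= 0 || eff_n2 <= 0) stop("effective sample sizes must be positive")
  pp <- (p1 * eff_n1 + p2 * eff_n2) / (eff_n1 + eff_n2)
  if (pp <= 0 || pp >= 1) stop("degenerate pooled proportion; z undefined")
  se <- sqrt(pp * (1 - pp) * (1 / eff_n1 + 1 / eff_n2))
  z <- (p1 - p2) / se
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Weighted chi-square test of association with the outcome
#'
#' Pearson chi-square on the factor x outcome contingency table built from
#' sampling weights, rescaled so the table total equals the unweighted n
#' (which keeps the nominal test size honest under weighting).
#'
#' @param records data frame of child records.
#' @param factor_name name of the factor column tested.
#' @return list with `chi2`, `df` (= categories - 1), `p`, and
#'   `small_expected` flag (any expected cell < 1 after rescaling).
#' @export
chi_square_association <- function(records, factor_name) {
  if (!factor_name %in% names(records)) stop("factor not found: ", factor_name)
  f <- as.character(records[[factor_name]])
  y <- records$outcome
  w <- records$weight
  cats <- unique(f)
  if (length(cats) < 2L) stop("need >= 2 categories with positive weight")
  tab <- vapply(cats, function(cc) {
    c(sum(w[f == cc & y == 1]), sum(w[f == cc & y == 0]))
  }, numeric(2))                        # 2 x K weighted table
  tab <- tab * length(y) / sum(tab)     # rescale to unweighted n
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chi2 <- sum((tab - expected)^2 / expected)
  df <- length(cats) - 1L
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df, lower.tail = FALSE),
       small_expected = any(expected < 1))
}

#' Per-country inequality effects
#'
#' For every country: weighted prevalence of the outcome in each literacy
#' group, the risk difference (illiterate minus literate) with variance
#' `var_I + var_L`, and the log odds ratio with variance
#' \eqn{1/a+1/b+1/c+1/d} on Kish-effective counts. A country where one
#' group is empty yields a not-computable marker (NA effects) and is
#' excluded from downstream pooling. Zero cells in the OR receive a 0.5
#' continuity correction, flagged.
#'
#' @param records data frame of child records with `country_id`, `group`,
#'   `outcome`, `weight`.
#' @return data frame, one row per country: country_id, n_I, n_L, prev_I,
#'   prev_L, rd, var_rd, rd_per_1000, log_or, var_log_or, eff_n_I, eff_n_L,
#'   computable, continuity_corrected.
#' @export
country_effects <- function(records) {
  out <- lapply(split(records, records$country_id), function(cc) {
    i <- cc$group == "illiterate"
    res <- data.frame(
      country_id = cc$country_id[1L], n_I = sum(i), n_L = sum(!i),
      prev_I = NA_real_, prev_L = NA_real_, rd = NA_real_, var_rd = NA_real_,
      rd_per_1000 = NA_real_, log_or = NA_real_, var_log_or = NA_real_,
      eff_n_I = NA_real_, eff_n_L = NA_real_,
      computable = FALSE, continuity_corrected = FALSE,
      stringsAsFactors = FALSE
    )
    if (res$n_I == 0L || res$n_L == 0L) return(res)
    pI <- weighted_prevalence(cc$outcome[i], cc$weight[i])
    pL <- weighted_prevalence(cc$outcome[!i], cc$weight[!i])
    res$prev_I <- pI$prev; res$prev_L <- pL$prev
    res$eff_n_I <- pI$eff_n; res$eff_n_L <- pL$eff_n
    res$rd <- pI$prev - pL$prev
    res$var_rd <- pI$var + pL$var
    res$rd_per_1000 <- 1000 * res$rd
    a <- pI$prev * pI$eff_n; b <- (1 - pI$prev) * pI$eff_n
    c_ <- pL$prev * pL$eff_n; d <- (1 - pL$prev) * pL$eff_n
    if (min(a, b, c_, d) < .Machine$double.eps^0.5) {
      a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5
      res$continuity_corrected <- TRUE
    }
    res$log_or <- log(a * d / (b * c_))
    res$var_log_or <- 1 / a + 1 / b + 1 / c_ + 1 / d
    res$computable <- TRUE
    res
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Fixed- and random-effects meta-analysis
#'
#' Inverse-variance fixed effect; Cochran's Q; between-study variance by
#' DerSimonian-Laird (truncated at zero); random effect re-weighted by
#' \eqn{1/(v_k + \tau^2)}; \eqn{I^2 = \max(0, 100 (Q - df)/Q)};
#' normal-theory confidence intervals.
#'
#' @param effects data frame from [country_effects()] (or any with the
#'   needed columns); non-computable rows are dropped.
#' @param metric `"rd"` (risk difference) or `"log_or"`.
#' @param conf_level confidence level for the intervals.
#' @return object of class `meta_result`: fixed/random effects with CIs, Q,
#'   df, tau2, i2 (percent), per-study fixed weights (summing to 1), k.
#' @export
meta_fixed_random <- function(effects, metric = c("rd", "log_or"),
                              conf_level = 0.95) {
  metric <- match.arg(metric)
  eff <- effects[effects$computable, , drop = FALSE]
  if (nrow(eff) == 0L) stop("no computable effects")
  theta <- eff[[metric]]
  v <- eff[[paste0("var_", metric)]]
  if (all(v <= 0)) stop("all variances zero")
  wf <- 1 / v
  fixed <- sum(wf * theta) / sum(wf)
  q <- sum(wf * (theta - fixed)^2)
  df <- nrow(eff) - 1L
  tau2 <- if (df > 0) {
    max(0, (q - df) / (sum(wf) - sum(wf^2) / sum(wf)))
  } else {
    0
  }
  wr <- 1 / (v + tau2)
  random <- sum(wr * theta) / sum(wr)
  zc <- stats::qnorm(1 - (1 - conf_level) / 2)
  se_f <- sqrt(1 / sum(wf))
  se_r <- sqrt(1 / sum(wr))
  i2 <- if (q > 0 && df > 0) max(0, 100 * (q - df) / q) else 0
  structure(list(
    metric = metric,
    k = nrow(eff),
    fixed_effect = fixed,
    fixed_ci = c(fixed - zc * se_f, fixed + zc * se_f),
    random_effect = random,
    random_ci = c(random - zc * se_r, random + zc * se_r),
    Q = q, df = df, tau2 = tau2, i2 = i2,
    weights_fixed = stats::setNames(wf / sum(wf), eff$country_id)
  ), class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("meta-analysis of %s over %d studies\n", x$metric, x$k))
  cat(sprintf("  fixed:  %+.5f [%+.5f, %+.5f]\n", x$fixed_effect,
              x$fixed_ci[1], x$fixed_ci[2]))
  cat(sprintf("  random: %+.5f [%+.5f, %+.5f]\n", x$random_effect,
              x$random_ci[1], x$random_ci[2]))
  cat(sprintf("  Q = %.3f (df %d), tau2 = %.6f, I2 = %.1f%%\n",
              x$Q, x$df, x$tau2, x$i2))
  invisible(x)
}

#' Mantel-Haenszel pooled odds ratio over strata
#'
#' Pooled OR \eqn{\sum_k a_k d_k/n_k / \sum_k b_k c_k/n_k} with
#' Robins-Breslow-Greenland variance for the confidence interval, plus a
#' Woolf-type Q homogeneity test of the stratum log odds ratios against the
#' pooled value. Strata with an empty margin are dropped with a note; zero
#' cells in otherwise usable strata get a 0.5 continuity correction for the
#' homogeneity component only (the MH estimator itself tolerates zero
#' cells).
#'
#' @param strata list of 2x2 matrices `rbind(c(a, b), c(c, d))` with rows =
#'   exposure (illiterate / literate) and columns = outcome (case /
#'   non-case): `a` = exposed cases, `b` = exposed non-cases, `c` =
#'   unexposed cases, `d` = unexposed non-cases.
#' @param conf_level confidence level.
#' @return list with `or`, `ci`, `se_log_or`, `z`, `p` (test of OR = 1),
#'   `chi2_homogeneity`, `df`, `p_homogeneity`, `k_used`, `dropped`.
#' @export
mantel_haenszel_or <- function(strata, conf_level = 0.95) {
  ok <- vapply(strata, function(s) {
    all(dim(s) == c(2L, 2L)) && all(rowSums(s) > 0) && all(colSums(s) > 0)
  }, logical(1))
  dropped <- sum(!ok)
  if (dropped > 0) {
    message(dropped, " stratum/strata dropped (empty margin)")
  }
  strata <- strata[ok]
  if (length(strata) == 0L) stop("no usable strata")
  a <- vapply(strata, function(s) s[1, 1], numeric(1))
  b <- vapply(strata, function(s) s[1, 2], numeric(1))
  cc <- vapply(strata, function(s) s[2, 1], numeric(1))
  d <- vapply(strata, function(s) s[2, 2], numeric(1))
  n <- a + b + cc + d
  r <- a * d / n
  s <- b * cc / n
  or <- sum(r) / sum(s)
  # Robins-Breslow-Greenland variance of log(OR_MH)
  p_ <- (a + d) / n
  q_ <- (b + cc) / n
  var_log <- sum(p_ * r) / (2 * sum(r)^2) +
    sum(p_ * s + q_ * r) / (2 * sum(r) * sum(s)) +
    sum(q_ * s) / (2 * sum(s)^2)
  se <- sqrt(var_log)
  zc <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- exp(log(or) + c(-1, 1) * zc * se)
  z <- log(or) / se
  # Woolf-type homogeneity of stratum log-ORs around the pooled log-OR
  zero <- pmin(a, b, cc, d) == 0
  a2 <- a + 0.5 * zero; b2 <- b + 0.5 * zero
  c2 <- cc + 0.5 * zero; d2 <- d + 0.5 * zero
  lor <- log(a2 * d2 / (b2 * c2))
  wk <- 1 / (1 / a2 + 1 / b2 + 1 / c2 + 1 / d2)
  chi2_hom <- sum(wk * (lor - log(or))^2)
  df <- length(strata) - 1L
  list(
    or = or, ci = ci, se_log_or = se,
    z = z, p = 2 * stats::pnorm(-abs(z)),
    chi2_homogeneity = chi2_hom, df = df,
    p_homogeneity = if (df > 0) {
      stats::pchisq(chi2_hom, df, lower.tail = FALSE)
    } else {
      NA_real_
    },
    k_used = length(strata), dropped = dropped
  )
}

#' Country 2x2 tables for stratified odds ratios
#'
#' Builds per-country 2x2 tables of literacy group against outcome on
#' Kish-effective counts (so sampling weights shrink, never inflate, the
#' information in a stratum).
#'
#' @param records data frame of child records.
#' @param effective use Kish-effective counts (default) or raw unweighted
#'   counts.
#' @return named list of 2x2 matrices (rows illiterate/literate, columns
#'   case/non-case).
#' @export
country_strata <- function(records, effective = TRUE) {
  lapply(split(records, records$country_id), function(cc) {
    cell <- function(grp, out) {
      sel <- cc$group == grp & cc$outcome == out
      if (!effective) return(sum(sel))
      sub <- cc$group == grp
      if (!any(sub)) return(0)
      p <- weighted_prevalence(cc$outcome[sub], cc$weight[sub])
      if (out == 1) p$prev * p$eff_n else (1 - p$prev) * p$eff_n
    }
    rbind(c(cell("illiterate", 1), cell("illiterate", 0)),
          c(cell("literate", 1), cell("literate", 0)))
  })
}

#' Covariate-adjusted odds ratio of the literacy group
#'
#' Weighted logistic regression of the outcome on an illiterate-group
#' indicator plus the schema covariates; the exponentiated indicator
#' coefficient is the adjusted OR of the outcome for children of illiterate
#' versus literate mothers. Complements the crude per-country OR of
#' [country_effects()].
#'
#' @param records data frame of child records for one stratum (country).
#' @param schema a [covariate_schema()].
#' @param factors optional subset of adjustment factors.
#' @param conf_level confidence level.
#' @return list with `or`, `ci`, `z`, `p` and the underlying `fit`.
#' @export
adjusted_group_or <- function(records, schema, factors = NULL,
                              conf_level = 0.95) {
  d <- build_design(records, schema, factors)
  x <- cbind(d$x[, 1L, drop = FALSE],
             group_illiterate = as.numeric(records$group == "illiterate"),
             d$x[, -1L, drop = FALSE])
  blocks <- lapply(d$blocks, `+`, 1L)
  fit <- fit_weighted_logit(list(x = x, y = d$y, w = d$w, blocks = blocks))
  b <- fit$coef[["group_illiterate"]]
  se <- sqrt(fit$cov["group_illiterate", "group_illiterate"])
  zc <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(or = exp(b), ci = exp(b + c(-1, 1) * zc * se), z = b / se,
       p = 2 * stats::pnorm(-abs(b / se)), fit = fit)
}

#' Classify countries by prevalence and direction of inequality
#'
#' Labels a country pro-illiterate when the risk-difference confidence
#' interval lies strictly above zero, pro-literate when strictly below, and
#' none otherwise; crossing the label with overall prevalence above or
#' below a threshold yields the four named quadrants (labelled `none`
#' countries are `unclassified`).
#'
#' @param effects data frame from [country_effects()].
#' @param prevalence_threshold prevalence cut separating high from low
#'   (default: effective-sample-size-weighted mean country prevalence).
#' @param conf_level confidence level of the RD interval.
#' @return data frame: country_id, prevalence, rd, ci_lo, ci_hi, label,
#'   quadrant.
#' @export
classify_inequality <- function(effects, prevalence_threshold = NULL,
                                conf_level = 0.95) {
  zc <- stats::qnorm(1 - (1 - conf_level) / 2)
  eff_n <- effects$eff_n_I + effects$eff_n_L
  prevalence <- (effects$prev_I * effects$eff_n_I +
                   effects$prev_L * effects$eff_n_L) / eff_n
  if (is.null(prevalence_threshold)) {
    ok <- effects$computable
    prevalence_threshold <- sum((prevalence * eff_n)[ok]) / sum(eff_n[ok])
  }
  ci_lo <- effects$rd - zc * sqrt(effects$var_rd)
  ci_hi <- effects$rd + zc * sqrt(effects$var_rd)
  label <- ifelse(!effects$computable, "none",
                  ifelse(ci_lo > 0, "pro_illiterate",
                         ifelse(ci_hi < 0, "pro_literate", "none")))
  high <- prevalence > prevalence_threshold
  quadrant <- ifelse(label == "none", "unclassified",
    ifelse(high,
           ifelse(label == "pro_illiterate", "high_prev_pro_illiterate",
                  "high_prev_pro_literate"),
           ifelse(label == "pro_illiterate", "low_prev_pro_illiterate",
                  "low_prev_pro_literate")))
  data.frame(
    country_id = effects$country_id,
    prevalence = prevalence,
    rd = effects$rd, ci_lo = ci_lo, ci_hi = ci_hi,
    label = label, quadrant = quadrant,
    stringsAsFactors = FALSE
  )
}

#' Forest table of country effects
#'
#' The numeric content of a risk-difference forest plot: one row per
#' country with prevalences, RD per 1000 with its CI, fixed-effect weight
#' (percent) and inequality label.
#'
#' @param effects data frame from [country_effects()].
#' @param meta a `meta_result` for the RD metric.
#' @param classes data frame from [classify_inequality()].
#' @return data frame ready to write as CSV.
#' @export
forest_table <- function(effects, meta, classes) {
  zc <- stats::qnorm(0.975)
  wt <- rep(NA_real_, nrow(effects))
  idx <- match(names(meta$weights_fixed), effects$country_id)
  wt[idx] <- 100 * as.numeric(meta$weights_fixed)
  data.frame(
    country = effects$country_id,
    n = effects$n_I + effects$n_L,
    prev_I = effects$prev_I,
    prev_L = effects$prev_L,
    rd_per_1000 = effects$rd_per_1000,
    ci_lo = 1000 * (effects$rd - zc * sqrt(effects$var_rd)),
    ci_hi = 1000 * (effects$rd + zc * sqrt(effects$var_rd)),
    weight_fixed_pct = wt,
    label = classes$label[match(effects$country_id, classes$country_id)],
    stringsAsFactors = FALSE
  )
}
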