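#' Build aligned group samples for decomposition
#'
#' Builds one design matrix over all records, so both literacy groups share
#' identical columns and factor blocks, then splits it by group. Alignment
#' is what makes block-wise covariate replacement meaningful.
#'
#' @param records data frame of child records.
#' @param schema a [covariate_schema()].
#' @param factors optional subset of schema factors to decompose over.
#' @return list with `sample_I` (illiterate), `sample_L` (literate), both of
#'   class `group_sample`.
#' @export
fairlie_samples <- function(records, schema, factors = NULL) {
  d <- build_design(records, schema, factors)
  grp <- records$group
  if (!all(grp %in% c("illiterate", "literate"))) {
    stop("group must be 'illiterate' or 'literate'")
  }
  subset_design <- function(keep) {
    list(x = d$x[keep, , drop = FALSE], y = d$y[keep], w = d$w[keep],
         blocks = d$blocks)
  }
  list(
    sample_I = group_sample(subset_design(grp == "illiterate"), "I"),
    sample_L = group_sample(subset_design(grp == "literate"), "L")
  )
}

#' Group sample
#'
#' Wraps one group's design matrix with its size, weighted mean outcome and
#' weighted covariate means.
#'
#' @param design list with `x`, `y`, `w`, `blocks` (see [build_design()]).
#' @param label group label, `"I"` or `"L"`.
#' @return object of class `group_sample`.
#' @export
group_sample <- function(design, label = c("I", "L")) {
  label <- match.arg(label)
  n <- nrow(design$x)
  if (n == 0L) stop("empty group")
  structure(list(
    design = design,
    group_label = label,
    n = n,
    ybar = wmean(design$y, design$w),
    xbar = apply(design$x, 2L, wmean, w = design$w)
  ), class = "group_sample")
}

#' Total outcome gap between groups
#'
#' Weighted mean outcome of the illiterate group minus that of the literate
#' group. A positive gap means the outcome is more prevalent among children
#' of illiterate mothers (pro-illiterate inequality).
#'
#' @param sample_I,sample_L `group_sample` objects.
#' @return real gap on the probability scale.
#' @export
total_gap <- function(sample_I, sample_L) {
  if (sample_I$n == 0L || sample_L$n == 0L) stop("empty group")
  sample_I$ybar - sample_L$ybar
}

#' Decomposition settings
#'
#' @param n_replications number of decomposition replications (default
#'   10000, the recommended scale for stable random-ordering averages).
#' @param seed master seed; every replication derives an independent
#'   substream from it.
#' @param ordering `"random"` draws a fresh factor ordering per replication;
#'   `"fixed"` uses the declaration order.
#' @param coefficient_source coefficients used to evaluate predicted
#'   probabilities: `"pooled"` (both groups combined; the default),
#'   `"group_I"` or `"group_L"`.
#' @param include_group_indicator add a group dummy to the pooled fit
#'   (coefficient shifts only the unexplained part; default off).
#' @param link `"logit"` for the nonlinear engine; `"identity"` evaluates a
#'   weighted linear-probability fit instead, the linear Blinder-Oaxaca
#'   limit.
#' @return object of class `decomposition_spec`.
#' @export
decomposition_spec <- function(n_replications = 10000L, seed = 1L,
                               ordering = c("random", "fixed"),
                               coefficient_source = c("pooled", "group_I", "group_L"),
                               include_group_indicator = FALSE,
                               link = c("logit", "identity")) {
  if (n_replications < 1) stop("n_replications must be >= 1")
  structure(list(
    n_replications = as.integer(n_replications),
    seed = as.integer(seed),
    ordering = match.arg(ordering),
    coefficient_source = match.arg(coefficient_source),
    include_group_indicator = isTRUE(include_group_indicator),
    link = match.arg(link)
  ), class = "decomposition_spec")
}

# Fit the coefficient vector the sequential replacement evaluates.
fit_decomposition_coefficients <- function(sample_I, sample_L, spec) {
  dI <- sample_I$design
  dL <- sample_L$design
  design <- switch(spec$coefficient_source,
    pooled = {
      x <- rbind(dI$x, dL$x)
      blocks <- dI$blocks
      if (spec$include_group_indicator) {
        x <- cbind(x, group_I = c(rep(1, sample_I$n), rep(0, sample_L$n)))
      }
      list(x = x, y = c(dI$y, dL$y), w = c(dI$w, dL$w), blocks = blocks)
    },
    group_I = dI,
    group_L = dL
  )
  if (spec$link == "logit") fit_weighted_logit(design) else fit_weighted_linear(design)
}

mean_link <- function(eta, w, link) {
  if (link == "logit") wmean(stats::plogis(eta), w) else wmean(eta, w)
}

#' Match the larger group to the smaller by predicted-probability rank
#'
#' Draws a random subsample of the larger group of the target size, then
#' sorts the subsample by predicted probability under the supplied fit so
#' that sequential replacement pairs observations of like rank (the smaller
#' group is sorted the same way by the caller).
#'
#' @param larger a `group_sample`.
#' @param target_n subsample size (the smaller group's n).
#' @param fit a fitted model whose `coef` aligns with the design columns.
#' @param seed integer seed for the subsample draw; `NULL` uses the current
#'   RNG state.
#' @return a `group_sample` of size `target_n`, rows sorted by predicted
#'   probability.
#' @export
match_subsample <- function(larger, target_n, fit, seed = NULL) {
  if (target_n > larger$n) stop("target_n exceeds group size")
  draw <- function() {
    if (target_n == larger$n) seq_len(larger$n) else
      sample.int(larger$n, target_n, replace = FALSE)
  }
  idx <- if (is.null(seed)) draw() else with_local_seed(seed, draw())
  d <- larger$design
  x <- d$x[idx, , drop = FALSE]
  eta <- drop(x %*% fit$coef[colnames(x)])
  ord <- order(eta, seq_along(eta))
  group_sample(list(x = x[ord, , drop = FALSE], y = d$y[idx][ord],
                    w = d$w[idx][ord], blocks = d$blocks),
               larger$group_label)
}

sort_by_prediction <- function(sample, fit) {
  d <- sample$design
  eta <- drop(d$x %*% fit$coef[colnames(d$x)])
  ord <- order(eta, seq_along(eta))
  group_sample(list(x = d$x[ord, , drop = FALSE], y = d$y[ord], w = d$w[ord],
                    blocks = d$blocks), sample$group_label)
}

#' One decomposition replication
#'
#' Performs a single sequential-replacement pass: the larger group is
#' subsampled to the smaller's size, both sides are sorted by predicted
#' probability so replacement pairs like ranks, and then — starting from the
#' literate group's covariate rows — each factor's dummy block is replaced
#' in the given order by the matched illiterate rows' values. A factor's
#' contribution is the change in weighted mean predicted probability at its
#' replacement step; the per-replication explained term is their sum, which
#' telescopes exactly to the full-replacement mean minus the no-replacement
#' mean.
#'
#' @param sample_I,sample_L `group_sample` objects with aligned designs.
#' @param fit coefficient fit (pooled by default upstream).
#' @param ordering character vector: a permutation of the factor names.
#' @param seed optional seed for the subsample draw.
#' @param link `"logit"` or `"identity"`.
#' @return list with `explained` and named `contributions`.
#' @export
decompose_once <- function(sample_I, sample_L, fit, ordering, seed = NULL,
                           link = "logit") {
  blocks <- sample_L$design$blocks
  if (!identical(names(blocks), names(sample_I$design$blocks))) {
    stop("factor blocks differ between groups")
  }
  if (!setequal(ordering, names(blocks))) {
    stop("ordering must be a permutation of the factor names")
  }
  n_target <- min(sample_I$n, sample_L$n)
  if (sample_I$n > n_target) {
    sI <- match_subsample(sample_I, n_target, fit, seed)
    sL <- sort_by_prediction(sample_L, fit)
  } else if (sample_L$n > n_target) {
    sI <- sort_by_prediction(sample_I, fit)
    sL <- match_subsample(sample_L, n_target, fit, seed)
  } else {
    sI <- sort_by_prediction(sample_I, fit)
    sL <- sort_by_prediction(sample_L, fit)
  }
  xI <- sI$design$x
  xL <- sL$design$x
  w <- sL$design$w                    # base rows are group L's; weights ride along
  coefs <- fit$coef[colnames(xL)]
  eta <- drop(xL %*% coefs)
  # linear predictor shift from swapping one whole factor block
  deltas <- lapply(blocks, function(cols) {
    drop((xI[, cols, drop = FALSE] - xL[, cols, drop = FALSE]) %*% coefs[cols])
  })
  contributions <- stats::setNames(numeric(length(ordering)), ordering)
  m_prev <- mean_link(eta, w, link)
  m0 <- m_prev
  for (f in ordering) {
    eta <- eta + deltas[[f]]
    m <- mean_link(eta, w, link)
    contributions[[f]] <- m - m_prev
    m_prev <- m
  }
  list(explained = m_prev - m0, contributions = contributions)
}

#' Nonlinear (Fairlie) decomposition of the outcome gap
#'
#' Decomposes the illiterate-literate gap in outcome prevalence into a part
#' explained by group differences in covariate distributions and an
#' unexplained remainder, with per-factor contributions averaged over
#' replications. Each replication draws a fresh matched subsample of the
#' larger group and (with `ordering = "random"`) a fresh factor ordering,
#' removing the path dependence of sequential replacement.
#'
#' @param sample_I,sample_L `group_sample` objects with aligned designs
#'   (see [fairlie_samples()]).
#' @param spec a [decomposition_spec()].
#' @return object of class `decomposition_result`: `total_gap`, `explained`,
#'   `unexplained`, `contributions` (data frame: factor, mean_contribution,
#'   se, percent_of_gap), `rep_contributions` (replications x factors),
#'   `rep_explained`, `n_replications_used`, `seed`, `fit`.
#' @export
decompose <- function(sample_I, sample_L, spec = decomposition_spec()) {
  stopifnot(inherits(spec, "decomposition_spec"))
  gap <- total_gap(sample_I, sample_L)
  fit <- fit_decomposition_coefficients(sample_I, sample_L, spec)
  factors <- names(sample_L$design$blocks)
  k <- length(factors)
  if (k == 0L) stop("no factors to decompose over")
  reps <- spec$n_replications
  sub_seeds <- derive_substream_seeds(spec$seed, 2L * reps)
  rep_contributions <- matrix(NA_real_, nrow = reps, ncol = k,
                              dimnames = list(NULL, factors))
  rep_explained <- numeric(reps)
  needs_subsample <- sample_I$n != sample_L$n
  for (r in seq_len(reps)) {
    ordering <- if (spec$ordering == "random") {
      with_local_seed(sub_seeds[2L * r - 1L], sample(factors))
    } else {
      factors
    }
    one <- decompose_once(sample_I, sample_L, fit, ordering,
                          seed = if (needs_subsample) sub_seeds[2L * r] else NULL,
                          link = spec$link)
    rep_contributions[r, ] <- one$contributions[factors]
    rep_explained[r] <- one$explained
  }
  mean_contrib <- colMeans(rep_contributions)
  se <- apply(rep_contributions, 2L, stats::sd)
  if (reps == 1L) se[] <- NA_real_
  explained <- mean(rep_explained)
  contributions <- data.frame(
    factor = factors,
    mean_contribution = unname(mean_contrib),
    se = unname(se),
    percent_of_gap = if (gap != 0) 100 * unname(mean_contrib) / gap else NA_real_,
    stringsAsFactors = FALSE
  )
  structure(list(
    total_gap = gap,
    explained = explained,
    unexplained = gap - explained,
    contributions = contributions,
    rep_contributions = rep_contributions,
    rep_explained = rep_explained,
    n_replications_used = reps,
    seed = spec$seed,
    fit = fit
  ), class = "decomposition_result")
}

#' @export
print.decomposition_result <- function(x, ...) {
  cat(sprintf("gap decomposition over %d replication(s), seed %d\n",
              x$n_replications_used, x$seed))
  cat(sprintf("  total gap:   %+.5f\n  explained:   %+.5f (%.1f%%)\n  unexplained: %+.5f\n",
              x$total_gap, x$explained,
              if (x$total_gap != 0) 100 * x$explained / x$total_gap else NA,
              x$unexplained))
  print(x$contributions, row.names = FALSE)
  invisible(x)
}

#' Linear Blinder-Oaxaca decomposition
#'
#' Fits a weighted linear-probability model per group and splits the gap
#' into the endowment (explained) term \eqn{(\bar X^I - \bar X^L)\hat\beta^I}
#' and the coefficient (unexplained) term
#' \eqn{\bar X^L(\hat\beta^I - \hat\beta^L)}, with the explained term
#' partitioned over factor blocks. The two terms sum to the gap exactly.
#'
#' @param sample_I,sample_L `group_sample` objects with aligned designs.
#' @return list with `explained`, `unexplained`, `total_gap`, and
#'   `endowment_terms` (named per factor).
#' @export
linear_boda <- function(sample_I, sample_L) {
  fit_I <- fit_weighted_linear(sample_I$design)
  fit_L <- fit_weighted_linear(sample_L$design)
  dx <- sample_I$xbar - sample_L$xbar
  explained <- sum(dx * fit_I$coef)
  unexplained <- sum(sample_L$xbar * (fit_I$coef - fit_L$coef))
  endowment <- vapply(sample_I$design$blocks, function(cols) {
    sum(dx[cols] * fit_I$coef[cols])
  }, numeric(1))
  list(
    total_gap = total_gap(sample_I, sample_L),
    explained = explained,
    unexplained = unexplained,
    endowment_terms = endowment
  )
}

#' Write a decomposition report as CSV
#'
#' Header rows carry the totals (total_gap, explained, unexplained,
#' n_replications, seed) followed by one row per factor with its mean
#' contribution, replication SE and percent of the gap.
#'
#' @param result a `decomposition_result`.
#' @param path output CSV path.
#' @export
write_decomposition_csv <- function(result, path) {
  header <- data.frame(
    factor = c(".total_gap", ".explained", ".unexplained",
               ".n_replications", ".seed"),
    mean_contribution = c(result$total_gap, result$explained,
                          result$unexplained, result$n_replications_used,
                          result$seed),
    se = NA_real_,
    percent_of_gap = NA_real_,
    stringsAsFactors = FALSE
  )
  utils::write.csv(rbind(header, result$contributions), path, row.names = FALSE)
  invisible(path)
}
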