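#' Synthetic survey configuration
#'
#' Describes a clustered, weighted child-level survey generator with a
#' country -> cluster -> child hierarchy, categorical covariates, a
#' logistic outcome model with known coefficients, and literacy driven by
#' household wealth (the empirical pattern: illiteracy concentrates in the
#' poorest quintiles). Defaults emulate the scale of DHS-style under-five
#' diarrhoea data: a baseline outcome prevalence near 14.2%, about a third
#' of mothers illiterate, illiteracy ranging from roughly half in the
#' poorest wealth quintile to near one-eighth in the richest.
#'
#' @param n_countries,clusters_per_country,children_per_cluster hierarchy
#'   sizes.
#' @param seed master seed for generation.
#' @param target_prevalence overall outcome prevalence the country
#'   intercepts are calibrated to (plug-in expectation, solved once at
#'   configuration time).
#' @param country_intercept_spread half-range (logit scale) of evenly
#'   spaced deterministic country offsets around the calibrated base
#'   intercept; creates between-country heterogeneity.
#' @param outcome_coefficients named list: factor -> named numeric vector
#'   of logit-scale effects per category (reference 0).
#' @param literacy_model list with `base_rate` (illiteracy probability at
#'   the middle wealth quintile) and `wealth_gradient` (logit change per
#'   unit of the centered wealth score; negative = richer households less
#'   often illiterate).
#' @param covariate_distributions named list: factor -> probability vector
#'   over its categories, or a list with elements `illiterate` and
#'   `literate` for group-specific distributions. Factors and category
#'   order must match `schema`.
#' @param wealth_cluster_sd SD of the cluster-level tilt (logit-linear in
#'   the wealth score) that makes wealth composition vary by cluster; 0
#'   switches clustering of wealth off.
#' @param weight_model list with `selection_prob_range`: cluster selection
#'   probabilities are drawn uniformly in this range and the sampling
#'   weight is their reciprocal.
#' @param schema [covariate_schema()] the factors refer to.
#' @return object of class `synthetic_config`; `$country_intercepts` holds
#'   the calibrated per-country intercepts.
#' @export
synthetic_config <- function(n_countries = 6L,
                             clusters_per_country = 40L,
                             children_per_cluster = 25L,
                             seed = 1L,
                             target_prevalence = 0.142,
                             country_intercept_spread = 0.3,
                             outcome_coefficients = default_outcome_coefficients(),
                             literacy_model = list(base_rate = 0.31,
                                                   wealth_gradient = -0.53),
                             covariate_distributions = default_covariate_distributions(),
                             wealth_cluster_sd = 0.5,
                             weight_model = list(selection_prob_range = c(0.5, 1.5)),
                             schema = default_schema()) {
  for (nm in names(covariate_distributions)) {
    dists <- covariate_distributions[[nm]]
    if (!is.list(dists)) dists <- list(dists)
    for (p in dists) {
      if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
        stop("category probabilities for '", nm, "' must be nonnegative and sum to 1")
      }
      if (length(p) != length(schema[[nm]]$categories)) {
        stop("probability vector for '", nm, "' does not match its categories")
      }
    }
  }
  rng <- weight_model$selection_prob_range
  if (any(rng <= 0)) stop("selection probabilities must be strictly positive")
  cfg <- structure(list(
    n_countries = as.integer(n_countries),
    clusters_per_country = as.integer(clusters_per_country),
    children_per_cluster = as.integer(children_per_cluster),
    seed = as.integer(seed),
    target_prevalence = target_prevalence,
    country_intercept_spread = country_intercept_spread,
    outcome_coefficients = outcome_coefficients,
    literacy_model = literacy_model,
    covariate_distributions = covariate_distributions,
    wealth_cluster_sd = wealth_cluster_sd,
    weight_model = weight_model,
    schema = schema[names(covariate_distributions)]
  ), class = "synthetic_config")
  class(cfg$schema) <- "covariate_schema"
  cfg$country_intercepts <- calibrate_intercepts(cfg)
  cfg
}

#' Default outcome coefficient set
#'
#' Logit-scale effects for a compact six-factor outcome model (wealth,
#' maternal age, toilet type, residence, child age, maternal employment).
#' The `"pooled"` profile has magnitudes read off typical pooled-data
#' prevalence contrasts: richer households, older mothers, improved toilets
#' and post-infancy ages are protective; rural residence and maternal
#' unemployment carry small excesses. The `"high_inequality"` profile
#' steepens the wealth and toilet gradients to the level seen in the
#' high-inequality countries where household wealth dominates the
#' outcome gap, and is the profile the constructed gap-recovery scenarios
#' start from.
#'
#' @param profile `"pooled"` or `"high_inequality"`.
#' @return named list of named numeric vectors.
#' @export
default_outcome_coefficients <- function(profile = c("pooled", "high_inequality")) {
  profile <- match.arg(profile)
  list(
    wealth = if (profile == "pooled") {
      c(poorest = 0, poorer = -0.03, middle = -0.08,
        richer = -0.10, richest = -0.22)
    } else {
      c(poorest = 0, poorer = -0.35, middle = -0.65,
        richer = -0.95, richest = -1.25)
    },
    maternal_age = c("15-24" = 0, "25-34" = -0.26, "35-49" = -0.24),
    toilet = if (profile == "pooled") {
      c(unimproved = 0, improved = -0.19)
    } else {
      c(unimproved = 0, improved = -0.5)
    },
    residence = c(urban = 0, rural = 0.10),
    child_age = c(infant = 0, "12-59 months" = -0.31),
    employment = c(employed = 0, unemployed = 0.22)
  )
}

#' Default covariate category distributions
#'
#' Marginal category probabilities matching the pooled composition of
#' DHS-style child data (wealth quintiles mildly bottom-heavy, half of
#' households with unimproved toilets, 70% rural, four-fifths of children
#' past infancy).
#'
#' @return named list of probability vectors.
#' @export
default_covariate_distributions <- function() {
  list(
    wealth = c(0.255, 0.224, 0.199, 0.176, 0.146),
    maternal_age = c(0.295, 0.520, 0.185),
    toilet = c(0.504, 0.496),
    residence = c(0.301, 0.699),
    child_age = c(0.207, 0.793),
    employment = c(0.662, 0.338)
  )
}

# Centered ordinal score of a factor's categories (1..K minus the mean);
# drives the wealth-literacy link and cluster tilts.
category_scores <- function(categories) {
  k <- length(categories)
  stats::setNames(seq_len(k) - (k + 1) / 2, categories)
}

# Marginal wealth distribution after integrating the cluster tilt
# (Gaussian quadrature on a fixed grid; exact when sd = 0).
marginal_wealth_dist <- function(cfg) {
  p <- group_dist(cfg, "wealth", "literate")  # common unless group-specific
  sdt <- cfg$wealth_cluster_sd
  score <- category_scores(cfg$schema$wealth$categories)
  if (sdt == 0) return(p)
  tt <- seq(-4, 4, length.out = 81) * sdt
  wq <- stats::dnorm(tt, sd = sdt)
  wq <- wq / sum(wq)
  out <- numeric(length(p))
  for (j in seq_along(tt)) {
    pj <- p * exp(tt[j] * score)
    out <- out + wq[j] * pj / sum(pj)
  }
  out
}

group_dist <- function(cfg, factor_name, group) {
  d <- cfg$covariate_distributions[[factor_name]]
  if (is.list(d)) d[[group]] else d
}

has_group_specific_wealth <- function(cfg) {
  is.list(cfg$covariate_distributions$wealth)
}

# P(illiterate | wealth category) under the literacy model.
illiteracy_by_wealth <- function(cfg) {
  score <- category_scores(cfg$schema$wealth$categories)
  stats::plogis(stats::qlogis(cfg$literacy_model$base_rate) +
                  cfg$literacy_model$wealth_gradient * score)
}

# Per-group joint factor distributions implied by the config; the basis of
# every plug-in expectation.
group_factor_dists <- function(cfg, group) {
  out <- list()
  for (nm in names(cfg$covariate_distributions)) {
    if (nm == "wealth" && !has_group_specific_wealth(cfg)) {
      m <- marginal_wealth_dist(cfg)
      pi_ill <- illiteracy_by_wealth(cfg)
      joint <- if (group == "illiterate") m * pi_ill else m * (1 - pi_ill)
      out[[nm]] <- joint / sum(joint)
    } else {
      p <- group_dist(cfg, nm, group)
      if (nm == "wealth") {
        # group-specific wealth still carries the (marginalized) cluster tilt
        sdt <- cfg$wealth_cluster_sd
        if (sdt > 0) {
          tmp <- cfg
          tmp$covariate_distributions$wealth <- p
          p <- marginal_wealth_dist(tmp)
        }
      }
      out[[nm]] <- p
    }
  }
  out
}

# Expected outcome prevalence for one group: enumeration over the product
# of category combinations, averaged over country intercepts.
expected_group_prevalence <- function(cfg, group, intercepts = NULL) {
  if (is.null(intercepts)) intercepts <- cfg$country_intercepts
  dists <- group_factor_dists(cfg, group)
  enumerate_mean(dists, cfg$outcome_coefficients, intercepts)
}

enumerate_mean <- function(dists, coefs, intercepts) {
  etas <- 0
  probs <- 1
  for (nm in names(dists)) {
    b <- coefs[[nm]]
    etas <- rep(etas, each = length(b)) + rep(unname(b), times = length(etas))
    probs <- rep(probs, each = length(b)) * rep(dists[[nm]], times = length(probs))
  }
  mean(vapply(intercepts, function(a) sum(probs * stats::plogis(a + etas)),
              numeric(1)))
}

#' Plug-in expected gap and prevalences of a configuration
#'
#' Exact (enumeration-based) expected weighted prevalence per literacy
#' group, the expected illiterate-literate gap, and the expected illiteracy
#' share — all computable from the echoed truth without simulation.
#'
#' @param cfg a [synthetic_config()].
#' @return list with `prev_I`, `prev_L`, `gap`, `prev_overall`,
#'   `illiterate_share`.
#' @export
expected_gap <- function(cfg) {
  share <- expected_illiterate_share(cfg)
  pI <- expected_group_prevalence(cfg, "illiterate")
  pL <- expected_group_prevalence(cfg, "literate")
  list(prev_I = pI, prev_L = pL, gap = pI - pL,
       prev_overall = share * pI + (1 - share) * pL,
       illiterate_share = share)
}

expected_illiterate_share <- function(cfg) {
  if (has_group_specific_wealth(cfg)) return(cfg$literacy_model$base_rate)
  m <- marginal_wealth_dist(cfg)
  sum(m * illiteracy_by_wealth(cfg))
}

calibrate_intercepts <- function(cfg) {
  offsets <- if (cfg$n_countries == 1L) {
    0
  } else {
    seq(-cfg$country_intercept_spread, cfg$country_intercept_spread,
        length.out = cfg$n_countries)
  }
  share <- expected_illiterate_share(cfg)
  f <- function(a) {
    pI <- expected_group_prevalence(cfg, "illiterate", intercepts = a + offsets)
    pL <- expected_group_prevalence(cfg, "literate", intercepts = a + offsets)
    share * pI + (1 - share) * pL - cfg$target_prevalence
  }
  base <- stats::uniroot(f, c(-15, 15), tol = 1e-10)$root
  base + offsets
}

#' Generate a synthetic child-level table
#'
#' Draws the full hierarchy: per cluster a selection probability (weight =
#' its reciprocal) and a wealth-composition tilt; per child a wealth
#' quintile, literacy (from the wealth-driven logit unless group-specific
#' wealth distributions are supplied, in which case literacy is drawn first
#' at the base rate), the remaining covariates and finally the outcome from
#' the logistic model. Identical seeds give identical tables.
#'
#' @param cfg a [synthetic_config()].
#' @return list with `records` (data frame accepted by every downstream
#'   stage) and `truth` (the configuration echo plus the calibrated
#'   intercepts and plug-in expectations).
#' @export
generate_children <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_local_seed(cfg$seed, {
    rows <- vector("list", cfg$n_countries * cfg$clusters_per_country)
    idx <- 0L
    wscore <- category_scores(cfg$schema$wealth$categories)
    pi_ill <- illiteracy_by_wealth(cfg)
    rng <- cfg$weight_model$selection_prob_range
    group_specific <- has_group_specific_wealth(cfg)
    for (co in seq_len(cfg$n_countries)) {
      alpha <- cfg$country_intercepts[co]
      for (cl in seq_len(cfg$clusters_per_country)) {
        idx <- idx + 1L
        n <- cfg$children_per_cluster
        sel_p <- stats::runif(1, rng[1], rng[2])
        tilt <- if (cfg$wealth_cluster_sd > 0) {
          stats::rnorm(1, 0, cfg$wealth_cluster_sd)
        } else {
          0
        }
        wcats <- cfg$schema$wealth$categories
        if (group_specific) {
          grp <- ifelse(stats::runif(n) < cfg$literacy_model$base_rate,
                        "illiterate", "literate")
          wealth <- character(n)
          for (g in c("illiterate", "literate")) {
            k <- grp == g
            if (!any(k)) next
            p <- group_dist(cfg, "wealth", g) * exp(tilt * wscore)
            wealth[k] <- sample(wcats, sum(k), replace = TRUE, prob = p / sum(p))
          }
        } else {
          p <- group_dist(cfg, "wealth", "literate") * exp(tilt * wscore)
          wealth <- sample(wcats, n, replace = TRUE, prob = p / sum(p))
          grp <- ifelse(stats::runif(n) < pi_ill[wealth], "illiterate", "literate")
        }
        rec <- data.frame(
          country_id = sprintf("C%02d", co),
          cluster_id = sprintf("C%02d_K%03d", co, cl),
          group = grp, wealth = wealth,
          weight = 1 / sel_p,
          stringsAsFactors = FALSE
        )
        for (nm in setdiff(names(cfg$covariate_distributions), "wealth")) {
          cats <- cfg$schema[[nm]]$categories
          d <- cfg$covariate_distributions[[nm]]
          if (is.list(d)) {
            val <- character(n)
            for (g in c("illiterate", "literate")) {
              k <- grp == g
              if (any(k)) val[k] <- sample(cats, sum(k), replace = TRUE, prob = d[[g]])
            }
            rec[[nm]] <- val
          } else {
            rec[[nm]] <- sample(cats, n, replace = TRUE, prob = d)
          }
        }
        eta <- rep(alpha, n)
        for (nm in names(cfg$outcome_coefficients)) {
          eta <- eta + unname(cfg$outcome_coefficients[[nm]][rec[[nm]]])
        }
        rec$outcome <- as.integer(stats::runif(n) < stats::plogis(eta))
        rows[[idx]] <- rec
      }
    }
    records <- do.call(rbind, rows)
    rownames(records) <- NULL
    first <- c("outcome", "group", "weight", "cluster_id", "country_id")
    records <- records[c(first, setdiff(names(records), first))]
    list(records = records,
         truth = c(unclass(cfg), list(expected = expected_gap(cfg))))
  })
}

#' Exhaustive plug-in decomposition oracle
#'
#' The population-level analogue of the sequential-replacement
#' decomposition, computed exactly from a configuration's echoed truth: for
#' every subset S of factors, the expected outcome probability when factors
#' in S follow the illiterate group's distribution and the rest the
#' literate group's is evaluated by enumeration; per-factor contributions
#' are then the Shapley averages over all orderings. No simulation and no
#' estimated coefficients are involved, so this is an independent oracle
#' for the decomposition engine.
#'
#' @param cfg a [synthetic_config()] (factorial in the number of factors;
#'   intended for small factor sets).
#' @return list with `contributions` (named, probability scale),
#'   `explained` (their sum = full swap minus no swap), `gap`, and
#'   `share_of_explained`.
#' @export
expected_decomposition <- function(cfg) {
  dI <- group_factor_dists(cfg, "illiterate")
  dL <- group_factor_dists(cfg, "literate")
  factors <- names(dI)
  p <- length(factors)
  if (p > 12) stop("too many factors for exhaustive enumeration")
  a <- cfg$country_intercepts
  m_subset <- function(bits) {
    dists <- dL
    dists[factors[bits]] <- dI[factors[bits]]
    enumerate_mean(dists, cfg$outcome_coefficients, a)
  }
  subsets <- lapply(0:(2^p - 1), function(s) as.logical(bitwAnd(s, 2^(0:(p - 1)))))
  mvals <- vapply(subsets, m_subset, numeric(1))
  names(mvals) <- vapply(subsets, function(b) paste(as.integer(b), collapse = ""), "")
  contributions <- stats::setNames(numeric(p), factors)
  for (j in seq_len(p)) {
    tot <- 0
    for (s in seq_along(subsets)) {
      b <- subsets[[s]]
      if (b[j]) next
      sz <- sum(b)
      wgt <- factorial(sz) * factorial(p - sz - 1) / factorial(p)
      b2 <- b
      b2[j] <- TRUE
      key <- paste(as.integer(b2), collapse = "")
      tot <- tot + wgt * (mvals[[key]] - mvals[[s]])
    }
    contributions[j] <- tot
  }
  explained <- mvals[[length(mvals)]] - mvals[[1L]]
  eg <- expected_gap(cfg)
  list(contributions = contributions, explained = explained, gap = eg$gap,
       share_of_explained = contributions / explained)
}

#' Construct a configuration with a controlled, attributable gap
#'
#' Returns a configuration whose literacy groups differ only in the
#' distributions of household wealth (and, for intermediate shares, toilet
#' type), tilted so the expected illiterate-literate outcome gap equals
#' `target_gap` with approximately `share_from_wealth` of it attributable
#' to wealth. The tilts are found by deterministic root finding on the
#' plug-in expectation; the wealth-literacy gradient and the cluster wealth
#' tilt are switched off so the echoed truth yields exact expectations.
#'
#' @param share_from_wealth fraction of the compositional gap carried by
#'   wealth, in \[0, 1\]; the remainder is loaded on toilet type.
#' @param target_gap expected gap (probability scale) to induce.
#' @param base a [synthetic_config()] to start from.
#' @return a new `synthetic_config`.
#' @export
make_gap_scenario <- function(share_from_wealth, target_gap,
                              base = synthetic_config()) {
  stopifnot(share_from_wealth >= 0, share_from_wealth <= 1)
  if (target_gap < 0) stop("target_gap must be nonnegative")
  cfg <- base
  cfg$literacy_model$wealth_gradient <- 0
  cfg$wealth_cluster_sd <- 0
  base_dists <- lapply(cfg$covariate_distributions, function(d) {
    if (is.list(d)) d$literate else d
  })
  cfg$covariate_distributions <- lapply(base_dists, function(p) {
    list(illiterate = p, literate = p)
  })
  cfg$country_intercepts <- calibrate_intercepts(cfg)

  tilted <- function(p, cats, t) {
    # t > 0 shifts mass toward low-score (disadvantaged) categories
    q <- p * exp(-t * category_scores(cats))
    q / sum(q)
  }
  gap_with <- function(factor_name, t, cfg0) {
    cats <- cfg0$schema[[factor_name]]$categories
    cfg1 <- cfg0
    cfg1$covariate_distributions[[factor_name]]$illiterate <-
      tilted(base_dists[[factor_name]], cats, t)
    expected_gap(cfg1)$gap
  }
  solve_tilt <- function(factor_name, target, cfg0) {
    if (target == 0) return(0)
    t_max <- 12
    reach <- gap_with(factor_name, t_max, cfg0)
    if (reach < target) {
      stop(sprintf("infeasible target for '%s': achievable gap range is [0, %.4f]",
                   factor_name, reach))
    }
    stats::uniroot(function(t) gap_with(factor_name, t, cfg0) - target,
                   c(0, t_max), tol = 1e-10)$root
  }
  if (target_gap == 0) return(cfg)
  t_w <- solve_tilt("wealth", share_from_wealth * target_gap, cfg)
  t_x <- if (share_from_wealth < 1) {
    if (!"toilet" %in% names(base_dists)) {
      stop("base configuration lacks a 'toilet' factor for the residual share")
    }
    solve_tilt("toilet", (1 - share_from_wealth) * target_gap, cfg)
  } else {
    0
  }
  apply_tilts <- function(lambda) {
    cfg1 <- cfg
    cfg1$covariate_distributions$wealth$illiterate <-
      tilted(base_dists$wealth, cfg$schema$wealth$categories, lambda * t_w)
    if (t_x > 0) {
      cfg1$covariate_distributions$toilet$illiterate <-
        tilted(base_dists$toilet, cfg$schema$toilet$categories, lambda * t_x)
    }
    cfg1
  }
  lam <- stats::uniroot(function(l) expected_gap(apply_tilts(l))$gap - target_gap,
                        c(0, 1.5), tol = 1e-10, extendInt = "upX")$root
  out <- apply_tilts(lam)
  out$country_intercepts <- cfg$country_intercepts
  out
}
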