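test_that("weighted prevalence and Kish effective n match hand computations", {
  p <- weighted_prevalence(c(1, 0, 1, 0), rep(1, 4))
  expect_equal(p$prev, 0.5)
  expect_equal(p$eff_n, 4)
  expect_equal(p$var, 0.25 / 4)
  # equal non-unit weights change nothing
  p2 <- weighted_prevalence(c(1, 0, 1, 0), rep(2.7, 4))
  expect_equal(p2$prev, p$prev)
  expect_equal(p2$eff_n, p$eff_n)
  # weights (1,1,2), y = (1,0,0): prev = 1/4, eff_n = 16/6
  p3 <- weighted_prevalence(c(1, 0, 0), c(1, 1, 2))
  expect_equal(p3$prev, 0.25)
  expect_equal(p3$eff_n, 16 / 6)
  expect_error(weighted_prevalence(numeric(0), numeric(0)), "empty")
})

test_that("two-proportion z-test matches the pooled formula and flips sign on swap", {
  z0 <- z_test_two_proportions(0.3, 50, 0.3, 80)
  expect_equal(z0$z, 0)
  expect_equal(z0$p, 1)
  z1 <- z_test_two_proportions(0.6, 100, 0.4, 100)
  expect_equal(z1$z, 0.2 / sqrt(0.5 * 0.5 * 0.02), tolerance = 1e-12)
  z2 <- z_test_two_proportions(0.4, 100, 0.6, 100)
  expect_equal(z2$z, -z1$z)
  expect_equal(z2$p, z1$p)
  expect_error(z_test_two_proportions(0, 10, 0, 10), "degenerate")
})

test_that("weighted chi-square association matches the hand Pearson value and is weight-scale invariant", {
  rec <- data.frame(
    outcome = rep(c(1, 0, 1, 0), c(30, 70, 70, 30)),
    weight = 1,
    f = rep(c("a", "b"), each = 100),
    stringsAsFactors = FALSE
  )
  res <- chi_square_association(rec, "f")
  expect_equal(res$chi2, 32, tolerance = 1e-12)   # 4 cells, expected 50 each
  expect_equal(res$df, 1)
  rec2 <- rec; rec2$weight <- 2
  expect_equal(chi_square_association(rec2, "f")$chi2, 32, tolerance = 1e-12)
  # independence by construction gives chi2 = 0
  rec3 <- data.frame(outcome = rep(c(1, 0), 50), weight = 1,
                     f = rep(c("a", "b"), each = 50))
  expect_equal(chi_square_association(rec3, "f")$chi2, 0, tolerance = 1e-12)
})

test_that("country effects carry RD, log-OR and NA markers for one-group countries", {
  rec <- rbind(
    data.frame(outcome = rep(c(1, 0, 1, 0), c(30, 70, 18, 82)),
               group = rep(c("illiterate", "literate"), each = 100),
               weight = 1, cluster_id = "K", country_id = "gapland"),
    data.frame(outcome = rep(c(1, 0), c(5, 95)),
               group = "literate", weight = 1, cluster_id = "K",
               country_id = "allliterate")
  )
  eff <- country_effects(rec)
  g <- eff[eff$country_id == "gapland", ]
  expect_equal(g$rd, g$prev_I - g$prev_L, tolerance = 1e-12)
  expect_equal(g$rd_per_1000, 120)
  expect_equal(g$log_or, log((30 / 70) / (18 / 82)), tolerance = 1e-12)
  expect_equal(g$var_log_or, 1 / 30 + 1 / 70 + 1 / 18 + 1 / 82, tolerance = 1e-12)
  a <- eff[eff$country_id == "allliterate", ]
  expect_false(a$computable)
  expect_true(is.na(a$rd))
  # non-computable countries are excluded from pooling
  m <- meta_fixed_random(eff, "rd")
  expect_equal(m$k, 1)
  # zero-cell country gets a flagged continuity correction
  rec2 <- data.frame(outcome = rep(c(0, 1, 0), c(50, 10, 40)),
                     group = rep(c("illiterate", "literate"), c(50, 50)),
                     weight = 1, cluster_id = "K", country_id = "zed")
  e2 <- country_effects(rec2)
  expect_true(e2$continuity_corrected)
  expect_true(is.finite(e2$log_or))
})

test_that("fixed and random effects, Q, tau2 and I2 match hand computations and metafor", {
  # two studies: inverse-variance fixed effect by hand
  eff2 <- data.frame(country_id = c("a", "b"), rd = c(0.10, 0.20),
                     var_rd = c(4e-4, 1e-4), computable = TRUE)
  m2 <- meta_fixed_random(eff2, "rd")
  expect_equal(m2$fixed_effect, (0.10 * 2500 + 0.20 * 10000) / 12500,
               tolerance = 1e-12)
  expect_equal(m2$fixed_effect, 0.18, tolerance = 1e-12)

  # three studies: full DerSimonian-Laird chain by hand
  th <- c(0.05, 0.12, -0.02); v <- c(2e-4, 5e-4, 3e-4)
  w <- 1 / v
  fx <- sum(w * th) / sum(w)
  q <- sum(w * (th - fx)^2)
  t2 <- max(0, (q - 2) / (sum(w) - sum(w^2) / sum(w)))
  wr <- 1 / (v + t2)
  eff3 <- data.frame(country_id = c("a", "b", "c"), rd = th, var_rd = v,
                     computable = TRUE)
  m3 <- meta_fixed_random(eff3, "rd")
  expect_equal(m3$fixed_effect, fx, tolerance = 1e-10)
  expect_equal(m3$Q, q, tolerance = 1e-10)
  expect_equal(m3$tau2, t2, tolerance = 1e-10)
  expect_equal(m3$random_effect, sum(wr * th) / sum(wr), tolerance = 1e-10)
  expect_equal(m3$i2, max(0, 100 * (q - 2) / q), tolerance = 1e-10)
  expect_equal(sum(m3$weights_fixed), 1, tolerance = 1e-12)

  skip_if_not_installed("metafor")
  ref_re <- metafor::rma(yi = th, vi = v, method = "DL")
  expect_equal(m3$random_effect, as.numeric(ref_re$beta), tolerance = 1e-8)
  expect_equal(m3$tau2, ref_re$tau2, tolerance = 1e-8)
  ref_fe <- metafor::rma(yi = th, vi = v, method = "FE")
  expect_equal(m3$fixed_effect, as.numeric(ref_fe$beta), tolerance = 1e-8)
})

test_that("meta degenerate cases: single study, identical estimates, zero tau2", {
  e1 <- data.frame(country_id = "a", rd = 0.07, var_rd = 1e-4, computable = TRUE)
  m1 <- meta_fixed_random(e1, "rd")
  expect_equal(m1$fixed_effect, 0.07)
  expect_equal(m1$random_effect, 0.07)
  expect_equal(m1$Q, 0)
  eI <- data.frame(country_id = letters[1:4], rd = 0.05,
                   var_rd = c(1e-4, 2e-4, 3e-4, 4e-4), computable = TRUE)
  mI <- meta_fixed_random(eI, "rd")
  expect_equal(mI$i2, 0)
  expect_equal(mI$tau2, 0)
  expect_equal(mI$random_effect, mI$fixed_effect)
  expect_true(mI$i2 >= 0 && mI$i2 <= 100)
})

test_that("Mantel-Haenszel pooling matches closed forms, base-R reference, and is order invariant", {
  s1 <- rbind(c(10, 20), c(20, 10))
  mh1 <- mantel_haenszel_or(list(s1))
  expect_equal(mh1$or, 0.25, tolerance = 1e-12)   # single-table MH = crude OR
  expect_equal(mh1$chi2_homogeneity, 0, tolerance = 1e-12)

  # all strata at OR = 1 pool to 1 with no heterogeneity
  ones <- list(rbind(c(10, 10), c(20, 20)), rbind(c(5, 15), c(10, 30)))
  mh_ones <- mantel_haenszel_or(ones)
  expect_equal(mh_ones$or, 1, tolerance = 1e-12)
  expect_equal(mh_ones$chi2_homogeneity, 0, tolerance = 1e-10)

  strata <- list(rbind(c(12, 30), c(20, 50)), rbind(c(30, 60), c(10, 40)),
                 rbind(c(8, 40), c(15, 45)))
  a <- mantel_haenszel_or(strata)
  b <- mantel_haenszel_or(rev(strata))
  expect_equal(a$or, b$or, tolerance = 1e-12)
  expect_equal(a$chi2_homogeneity, b$chi2_homogeneity, tolerance = 1e-12)
  expect_equal(a$df, 2L)

  # independent reference: stats::mantelhaen.test point estimate and RBG CI
  arr <- array(unlist(strata), dim = c(2, 2, 3))
  ref <- stats::mantelhaen.test(arr, correct = FALSE)
  expect_equal(a$or, unname(ref$estimate), tolerance = 1e-8)
  expect_equal(unname(a$ci), as.numeric(ref$conf.int), tolerance = 1e-6,
               ignore_attr = TRUE)

  # a stratum with an empty margin is dropped with a note
  withmargin <- c(strata, list(rbind(c(0, 0), c(5, 5))))
  expect_message(mhd <- mantel_haenszel_or(withmargin), "dropped")
  expect_equal(mhd$k_used, 3)
  expect_equal(mhd$or, a$or)
})

test_that("adjusted group OR matches a reference GLM and exceeds the crude OR under negative confounding", {
  tt <- make_two_group_records(200, 200, n_factors = 2, seed = 61,
                               unit_weights = TRUE)
  rec <- tt$records
  est <- adjusted_group_or(rec, tt$schema)
  ref <- stats::glm(outcome ~ I(group == "illiterate") + f1 + f2,
                    family = stats::binomial(), data = rec)
  expect_equal(log(est$or), unname(coef(ref)[2]), tolerance = 1e-6)
  expect_true(est$ci[1] < est$or && est$or < est$ci[2])
})

test_that("inequality classification crosses CI sign with the prevalence threshold into a partition", {
  eff <- data.frame(
    country_id = c("hi_pro_ill", "hi_pro_lit", "lo_pro_ill", "lo_pro_lit", "flat"),
    prev_I = c(0.30, 0.20, 0.10, 0.02, 0.15),
    prev_L = c(0.24, 0.26, 0.06, 0.06, 0.15),
    rd = c(0.06, -0.06, 0.04, -0.04, 0),
    var_rd = c(1e-4, 1e-4, 1e-4, 1e-4, 1e-4),
    eff_n_I = 1000, eff_n_L = 1000, computable = TRUE,
    stringsAsFactors = FALSE
  )
  cls <- classify_inequality(eff, prevalence_threshold = 0.13)
  expect_equal(cls$label,
               c("pro_illiterate", "pro_literate", "pro_illiterate",
                 "pro_literate", "none"))
  expect_equal(cls$quadrant,
               c("high_prev_pro_illiterate", "high_prev_pro_literate",
                 "low_prev_pro_illiterate", "low_prev_pro_literate",
                 "unclassified"))
  # CI covering zero is never classified
  eff$var_rd <- 0.01
  cls2 <- classify_inequality(eff, prevalence_threshold = 0.13)
  expect_true(all(cls2$label == "none"))
  expect_true(all(cls2$quadrant == "unclassified"))
})
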