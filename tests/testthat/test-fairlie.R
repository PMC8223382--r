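test_that("total gap is the weighted prevalence difference, antisymmetric, and matches published-scale numbers", {
  tt <- make_two_group_records(100, 120, seed = 2)
  s <- fairlie_samples(tt$records, tt$schema)
  gI <- tt$records[tt$records$group == "illiterate", ]
  gL <- tt$records[tt$records$group == "literate", ]
  expect_equal(total_gap(s$sample_I, s$sample_L),
               weighted.mean(gI$outcome, gI$weight) -
                 weighted.mean(gL$outcome, gL$weight))
  expect_equal(total_gap(s$sample_L, s$sample_I),
               -total_gap(s$sample_I, s$sample_L))
  # prevalences 30.3% vs 18.4% give a gap of 0.119 (119 per 1000)
  sI <- group_sample(list(x = matrix(1, 1000, 1), y = rep(c(1, 0), c(303, 697)),
                          w = rep(1, 1000), blocks = list()), "I")
  sL <- group_sample(list(x = matrix(1, 1000, 1), y = rep(c(1, 0), c(184, 816)),
                          w = rep(1, 1000), blocks = list()), "L")
  expect_equal(total_gap(sI, sL), 0.119)
})

test_that("matched subsampling is deterministic per seed and pairs equal predicted-probability ranks", {
  tt <- make_two_group_records(150, 90, seed = 4)
  s <- fairlie_samples(tt$records, tt$schema)
  spec <- decomposition_spec(n_replications = 1, seed = 1)
  fit <- ineqdecomp:::fit_decomposition_coefficients(s$sample_I, s$sample_L, spec)
  a <- match_subsample(s$sample_I, 90, fit, seed = 99)
  b <- match_subsample(s$sample_I, 90, fit, seed = 99)
  expect_identical(a$design$x, b$design$x)
  expect_equal(a$n, 90)
  # full-size request returns the whole group, sorted by predicted probability
  full <- match_subsample(s$sample_I, 150, fit, seed = 1)
  expect_equal(full$n, 150)
  eta <- drop(full$design$x %*% fit$coef)
  expect_true(!is.unsorted(eta))
  # subsample rows are sorted too, so rank pairing is definitional
  eta_a <- drop(a$design$x %*% fit$coef)
  expect_true(!is.unsorted(eta_a))
  expect_error(match_subsample(s$sample_I, 151, fit), "exceeds")
})

test_that("one replication matches the literal row-loop oracle for the sequential replacement", {
  tt <- make_two_group_records(50, 50, n_factors = 2, seed = 7)
  s <- fairlie_samples(tt$records, tt$schema)
  spec <- decomposition_spec(n_replications = 1, seed = 1, ordering = "fixed")
  fit <- ineqdecomp:::fit_decomposition_coefficients(s$sample_I, s$sample_L, spec)
  one <- decompose_once(s$sample_I, s$sample_L, fit, c("f1", "f2"))

  # oracle: sort each group by predicted probability, then loop row by row
  # accumulating weighted means of F at each replacement stage
  sort_rows <- function(smp) {
    eta <- drop(smp$design$x %*% fit$coef)
    ord <- order(eta, seq_along(eta))
    list(x = smp$design$x[ord, ], w = smp$design$w[ord])
  }
  I <- sort_rows(s$sample_I); L <- sort_rows(s$sample_L)
  bl <- s$sample_L$design$blocks
  n <- 50
  m0 <- m1 <- m2 <- wtot <- 0
  for (i in seq_len(n)) {
    xl <- L$x[i, ]; wi <- L$w[i]
    x_f1 <- xl; x_f1[bl$f1] <- I$x[i, bl$f1]
    x_f12 <- x_f1; x_f12[bl$f2] <- I$x[i, bl$f2]
    m0 <- m0 + wi * plogis(sum(xl * fit$coef))
    m1 <- m1 + wi * plogis(sum(x_f1 * fit$coef))
    m2 <- m2 + wi * plogis(sum(x_f12 * fit$coef))
    wtot <- wtot + wi
  }
  expect_equal(unname(one$contributions["f1"]), (m1 - m0) / wtot, tolerance = 1e-12)
  expect_equal(unname(one$contributions["f2"]), (m2 - m1) / wtot, tolerance = 1e-12)
  expect_equal(one$explained, (m2 - m0) / wtot, tolerance = 1e-12)
})

test_that("single-factor and identical-covariate degenerate cases behave as the telescoping predicts", {
  tt <- make_two_group_records(60, 60, n_factors = 1, seed = 9)
  s <- fairlie_samples(tt$records, tt$schema)
  spec <- decomposition_spec(n_replications = 5, seed = 3)
  res <- decompose(s$sample_I, s$sample_L, spec)
  # with one factor its contribution IS the explained term, every ordering
  expect_equal(res$contributions$mean_contribution[1], res$explained,
               tolerance = 1e-12)

  # identical covariate rows in both groups: all contributions zero
  tt2 <- make_two_group_records(80, 80, n_factors = 3, seed = 10)
  rec <- tt2$records
  rec$group <- rep(c("illiterate", "literate"), each = 80)  # same covariates per pair
  recI <- rec[rec$group == "illiterate", ]
  recL <- recI; recL$group <- "literate"
  s2 <- fairlie_samples(rbind(recI, recL), tt2$schema)
  res2 <- decompose(s2$sample_I, s2$sample_L,
                    decomposition_spec(n_replications = 3, seed = 1))
  expect_equal(res2$contributions$mean_contribution, rep(0, 3), tolerance = 1e-12)
  expect_equal(res2$explained, 0, tolerance = 1e-12)
})

test_that("fixed ordering with equal group sizes has zero Monte-Carlo variance", {
  tt <- make_two_group_records(70, 70, n_factors = 3, seed = 12)
  s <- fairlie_samples(tt$records, tt$schema)
  res <- decompose(s$sample_I, s$sample_L,
                   decomposition_spec(n_replications = 10, seed = 5,
                                      ordering = "fixed"))
  expect_equal(max(apply(res$rep_contributions, 2, sd)), 0)
  expect_equal(sd(res$rep_explained), 0)
})

test_that("explained + unexplained equals the gap and contributions telescope per replication", {
  for (seed in c(21, 22)) {
    tt <- make_two_group_records(120, 90, n_factors = 4, n_cats = c(2, 3, 2, 2),
                                 seed = seed)
    s <- fairlie_samples(tt$records, tt$schema)
    res <- decompose(s$sample_I, s$sample_L,
                     decomposition_spec(n_replications = 8, seed = seed))
    expect_equal(res$explained + res$unexplained, res$total_gap,
                 tolerance = 1e-10)
    expect_lt(max(abs(rowSums(res$rep_contributions) - res$rep_explained)),
              1e-12)
    expect_equal(sum(res$contributions$mean_contribution), res$explained,
                 tolerance = 1e-12)
    expect_equal(res$contributions$percent_of_gap,
                 100 * res$contributions$mean_contribution / res$total_gap)
  }
})

test_that("random-ordering averages converge to the exhaustive permutation average", {
  tt <- make_two_group_records(100, 100, n_factors = 3, seed = 31)
  s <- fairlie_samples(tt$records, tt$schema)
  spec <- decomposition_spec(n_replications = 600, seed = 17)
  fit <- ineqdecomp:::fit_decomposition_coefficients(s$sample_I, s$sample_L, spec)
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  fnames <- c("f1", "f2", "f3")
  exact <- Reduce(`+`, lapply(perms, function(p) {
    decompose_once(s$sample_I, s$sample_L, fit, fnames[p])$contributions[fnames]
  })) / 6
  res <- decompose(s$sample_I, s$sample_L, spec)
  mc_se <- apply(res$rep_contributions, 2, sd) / sqrt(spec$n_replications)
  expect_true(all(abs(res$contributions$mean_contribution - exact) <=
                    3 * mc_se + 1e-12))
})

test_that("identity link reproduces the linear Blinder-Oaxaca terms exactly", {
  tt <- make_two_group_records(90, 90, n_factors = 3, seed = 41,
                               unit_weights = TRUE)
  s <- fairlie_samples(tt$records, tt$schema)
  lin <- linear_boda(s$sample_I, s$sample_L)
  expect_equal(lin$explained + lin$unexplained, lin$total_gap, tolerance = 1e-12)
  expect_equal(sum(lin$endowment_terms), lin$explained, tolerance = 1e-12)

  res <- decompose(s$sample_I, s$sample_L,
                   decomposition_spec(n_replications = 1, seed = 1,
                                      ordering = "fixed",
                                      coefficient_source = "group_I",
                                      link = "identity"))
  expect_equal(res$explained, lin$explained, tolerance = 1e-10)
  expect_equal(res$unexplained, lin$unexplained, tolerance = 1e-10)
  expect_equal(stats::setNames(res$contributions$mean_contribution,
                               res$contributions$factor),
               lin$endowment_terms, tolerance = 1e-10)
})

test_that("linear decomposition matches a four-number hand computation", {
  # one binary covariate: group means and slopes picked by hand
  xI <- rep(c(1, 0), c(30, 70))            # mean 0.3
  yI <- 0.2 + 0.5 * xI                      # exact linear outcome
  xL <- rep(c(1, 0), c(60, 40))            # mean 0.6
  yL <- 0.1 + 0.3 * xL
  mk <- function(x, y, lab) group_sample(
    list(x = cbind("(Intercept)" = 1, f = x), y = y, w = rep(1, 100),
         blocks = list(f = 2L)), lab)
  lin <- linear_boda(mk(xI, yI, "I"), mk(xL, yL, "L"))
  # explained = (0.3 - 0.6) * 0.5; unexplained = (0.2 - 0.1) + 0.6 * (0.5 - 0.3)
  expect_equal(lin$explained, -0.15, tolerance = 1e-10)
  expect_equal(lin$unexplained, 0.22, tolerance = 1e-10)
  expect_equal(lin$total_gap, 0.07, tolerance = 1e-10)
})

test_that("decomposition is reproducible from its seed and invariant to factor declaration order", {
  tt <- make_two_group_records(100, 80, n_factors = 3, seed = 51)
  s <- fairlie_samples(tt$records, tt$schema)
  spec <- decomposition_spec(n_replications = 40, seed = 23)
  r1 <- decompose(s$sample_I, s$sample_L, spec)
  r2 <- decompose(s$sample_I, s$sample_L, spec)
  expect_identical(r1$rep_contributions, r2$rep_contributions)

  # reversing schema declaration order: means agree within MC error
  sch_rev <- covariate_schema(rev(lapply(unclass(tt$schema), `[[`, "categories")))
  s_rev <- fairlie_samples(tt$records, sch_rev)
  r3 <- decompose(s_rev$sample_I, s_rev$sample_L,
                  decomposition_spec(n_replications = 400, seed = 77))
  r4 <- decompose(s$sample_I, s$sample_L,
                  decomposition_spec(n_replications = 400, seed = 78))
  m3 <- stats::setNames(r3$contributions$mean_contribution, r3$contributions$factor)
  m4 <- stats::setNames(r4$contributions$mean_contribution, r4$contributions$factor)
  se <- apply(r4$rep_contributions, 2, sd) / sqrt(400) +
    apply(r3$rep_contributions, 2, sd)[names(m4)] / sqrt(400)
  expect_true(all(abs(m3[names(m4)] - m4) <= 4 * se + 1e-12))
})
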