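# Fixture builders shared across test files. Everything is generated in
# code; no stored data.

random_probs <- function(k) {
  p <- stats::runif(k, 0.2, 1)
  p / sum(p)
}

# Two-group child table with random categorical factors and a logistic
# outcome; group-specific distributions unless same_dist = TRUE.
make_two_group_records <- function(n_I, n_L, n_factors = 3, n_cats = 2,
                                   seed = 1, same_dist = FALSE,
                                   unit_weights = FALSE) {
  set.seed(seed)
  if (length(n_cats) == 1L) n_cats <- rep(n_cats, n_factors)
  fnames <- paste0("f", seq_len(n_factors))
  cats <- lapply(n_cats, function(k) paste0("c", seq_len(k)))
  names(cats) <- fnames
  schema <- covariate_schema(cats)
  coefs <- lapply(cats, function(cc) {
    stats::setNames(c(0, stats::runif(length(cc) - 1, -1.2, 1.2)), cc)
  })
  draw_group <- function(n, group, dists) {
    df <- data.frame(
      group = group,
      weight = if (unit_weights) 1 else stats::runif(n, 0.5, 2),
      cluster_id = sample(sprintf("K%02d", 1:5), n, replace = TRUE),
      country_id = "X",
      stringsAsFactors = FALSE
    )
    eta <- rep(-1, n)
    for (j in seq_along(fnames)) {
      df[[fnames[j]]] <- sample(cats[[j]], n, replace = TRUE, prob = dists[[j]])
      eta <- eta + unname(coefs[[j]][df[[fnames[j]]]])
    }
    df$outcome <- as.integer(stats::runif(n) < stats::plogis(eta))
    df
  }
  dists_L <- lapply(n_cats, random_probs)
  dists_I <- if (same_dist) dists_L else lapply(n_cats, random_probs)
  records <- rbind(draw_group(n_I, "illiterate", dists_I),
                   draw_group(n_L, "literate", dists_L))
  list(records = records, schema = schema, coefs = coefs)
}

# A valid 6-row child table using a two-factor schema; basis of the I/O tests.
toy_table <- function() {
  schema <- covariate_schema(list(
    wealth = c("poor", "rich"),
    toilet = c("unimproved", "improved")
  ))
  records <- data.frame(
    outcome = c(1, 0, 0, 1, 0, 1),
    group = c("illiterate", "illiterate", "literate",
              "literate", "literate", "illiterate"),
    weight = c(1, 2, 1.5, 1, 0.5, 1),
    cluster_id = c("K1", "K1", "K2", "K2", "K1", "K2"),
    country_id = "A",
    wealth = c("poor", "poor", "rich", "rich", "poor", "rich"),
    toilet = c("unimproved", "improved", "improved",
               "unimproved", "improved", "improved"),
    stringsAsFactors = FALSE
  )
  list(records = records, schema = schema)
}
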