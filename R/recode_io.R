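#' Recode maternal education to the literacy dichotomy
#'
#' No formal education maps to "illiterate"; any completed formal schooling
#' (primary, secondary or higher) maps to "literate".
#'
#' @param raw_level character vector with values among `none`, `primary`,
#'   `secondary`, `higher`.
#' @return character vector of `"illiterate"` / `"literate"`.
#' @examples
#' recode_education(c("none", "primary", "higher"))
#' @export
recode_education <- function(raw_level) {
  map <- c(none = "illiterate", primary = "literate",
           secondary = "literate", higher = "literate")
  out <- unname(map[as.character(raw_level)])
  if (anyNA(out)) {
    bad <- unique(raw_level[is.na(out)])
    stop("unrecognized education level: ", paste(bad, collapse = ", "))
  }
  out
}

#' Read a child-level table
#'
#' Reads a delimited text file with one row per under-five child: binary
#' outcome, literacy group, one column per schema factor, sampling weight,
#' cluster and country identifiers. Rows with a missing value in any
#' mandatory column are excluded (complete-case policy) with a message
#' giving the tally.
#'
#' @param path file path of a CSV (or TSV, see `sep`) with a header row.
#' @param schema a [covariate_schema()] naming the factor columns expected.
#' @param sep field separator, default comma.
#' @param columns optional named character vector remapping the mandatory
#'   column names, e.g. `c(outcome = "diarrhoea")`.
#' @return data frame of validated child records with columns `outcome`,
#'   `group`, `weight`, `cluster_id`, `country_id` and one column per
#'   schema factor. Attribute `n_excluded` carries the incomplete-row tally.
#' @export
read_child_table <- function(path, schema, sep = ",", columns = NULL) {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           fileEncoding = "UTF-8")
  core <- c(outcome = "outcome", group = "group", weight = "weight",
            cluster_id = "cluster_id", country_id = "country_id")
  if (!is.null(columns)) core[names(columns)] <- columns
  for (std in names(core)) {
    src <- core[[std]]
    if (!src %in% names(raw)) stop("missing mandatory column: ", src)
    if (src != std) names(raw)[names(raw) == src] <- std
  }
  missing_f <- setdiff(names(schema), names(raw))
  if (length(missing_f)) {
    stop("missing mandatory column: ", paste(missing_f, collapse = ", "))
  }
  needed <- c(names(core), names(schema))
  complete <- stats::complete.cases(raw[needed]) &
    rowSums(raw[needed] == "", na.rm = TRUE) == 0
  n_excluded <- sum(!complete)
  if (n_excluded > 0) {
    message(n_excluded, " incomplete row(s) excluded (complete-case policy)")
  }
  rec <- raw[complete, needed, drop = FALSE]
  rownames(rec) <- NULL

  if (!all(rec$outcome %in% c(0, 1))) {
    stop("outcome must be 0/1; offending row ",
         which(!rec$outcome %in% c(0, 1))[1L])
  }
  if (!all(rec$group %in% c("illiterate", "literate"))) {
    stop("group must be 'illiterate' or 'literate'; offending row ",
         which(!rec$group %in% c("illiterate", "literate"))[1L])
  }
  bad_w <- which(!(is.finite(rec$weight) & rec$weight > 0))
  if (length(bad_w)) stop("nonpositive weight, row ", bad_w[1L])
  for (nm in names(schema)) {
    ok <- rec[[nm]] %in% schema[[nm]]$categories
    if (!all(ok)) {
      i <- which(!ok)[1L]
      stop("unknown category '", rec[[nm]][i], "' for factor '", nm,
           "' at row ", i)
    }
  }
  attr(rec, "n_excluded") <- n_excluded
  rec
}

#' Write a child-level table
#'
#' Writes records in the same dialect [read_child_table()] reads, so a
#' read-write-read cycle is an identity.
#'
#' @param records data frame of child records.
#' @param path output file path.
#' @param sep field separator.
#' @export
write_child_table <- function(records, path, sep = ",") {
  utils::write.table(records, path, sep = sep, row.names = FALSE,
                     quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Neighbourhood socio-economic quintile from cluster composition
#'
#' For every survey cluster (primary sampling unit) the weighted proportion
#' of children from poor households and of children whose mother is not
#' employed is computed; the two proportions are standardized over clusters
#' (weighted moments, cluster weight = total child weight) and the first
#' principal component of their correlation matrix is extracted, with the
#' sign oriented so a higher score means more poor/unemployed. Clusters are
#' then cut into five weight-balanced quintiles of the score; quintile 1 is
#' the highest-SES fifth.
#'
#' @param records data frame of child records with `wealth` and `employment`
#'   factor columns (or those named by the flags).
#' @param poor_flag name of the household-wealth factor; `poor_categories`
#'   selects which of its categories count as poor (default the bottom two
#'   quintiles).
#' @param employed_flag name of the employment factor; its first category is
#'   taken as "employed".
#' @param poor_categories categories of `poor_flag` counted as poor.
#' @param unemployed_category category of `employed_flag` meaning not
#'   currently employed.
#' @return list with `clusters` (data frame: cluster_id, prop_poor,
#'   prop_unemployed, pc1_score, quintile) and `records` (the input with a
#'   `neighbourhood_ses` column attached; every child inherits its cluster's
#'   quintile).
#' @export
compute_neighbourhood_ses <- function(records,
                                      poor_flag = "wealth",
                                      employed_flag = "employment",
                                      poor_categories = c("poorest", "poorer"),
                                      unemployed_category = "unemployed") {
  for (nm in c(poor_flag, employed_flag)) {
    if (!nm %in% names(records)) stop("factor not found: ", nm)
  }
  ids <- unique(records$cluster_id)
  if (length(ids) < 2L) stop("need at least 2 clusters")
  poor <- as.numeric(records[[poor_flag]] %in% poor_categories)
  unemp <- as.numeric(records[[employed_flag]] == unemployed_category)
  w <- records$weight
  cl <- factor(records$cluster_id, levels = ids)
  wsum <- tapply(w, cl, sum)
  if (any(wsum <= 0)) stop("cluster with zero total weight")
  prop_poor <- tapply(w * poor, cl, sum) / wsum
  prop_unemp <- tapply(w * unemp, cl, sum) / wsum

  cw <- as.numeric(wsum) / sum(wsum)        # cluster weights
  std <- function(p) {
    m <- sum(cw * p)
    v <- sum(cw * (p - m)^2)
    if (v <= 0) return(rep(0, length(p)))
    (p - m) / sqrt(v)
  }
  z1 <- std(as.numeric(prop_poor))
  z2 <- std(as.numeric(prop_unemp))
  if (all(z1 == 0) && all(z2 == 0)) stop("degenerate SES inputs")
  z <- cbind(z1, z2)
  cmat <- crossprod(z * sqrt(cw))           # weighted correlation matrix
  eig <- eigen(cmat, symmetric = TRUE)
  v1 <- eig$vectors[, 1L]
  if (sum(v1) < 0) v1 <- -v1                # higher score = more poor/unemployed
  score <- as.numeric(z %*% v1)

  # weighted quintiles of the cluster scores, ties broken by input order
  ord <- order(score, seq_along(score))
  cum <- cumsum(cw[ord]) - cw[ord] / 2
  qt_sorted <- pmin(5L, pmax(1L, ceiling(cum * 5)))
  # quintile 1 = highest SES (lowest poverty score)
  quintile <- integer(length(score))
  quintile[ord] <- qt_sorted
  clusters <- data.frame(
    cluster_id = ids,
    prop_poor = as.numeric(prop_poor),
    prop_unemployed = as.numeric(prop_unemp),
    pc1_score = score,
    quintile = quintile,
    stringsAsFactors = FALSE
  )
  records$neighbourhood_ses <-
    as.character(clusters$quintile[match(records$cluster_id, clusters$cluster_id)])
  list(clusters = clusters, records = records)
}
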