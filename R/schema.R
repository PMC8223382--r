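#' Covariate schema
#'
#' An ordered list of categorical factors, each with its ordered category
#' labels and a reference category (dropped in dummy coding). The order of
#' categories fixes the dummy coding; the first category is the reference
#' unless stated otherwise.
#'
#' @param factors named list; each element a character vector of category
#'   labels (first = reference) or a list with elements `categories` and
#'   `reference`.
#' @return an object of class `covariate_schema`.
#' @examples
#' sch <- covariate_schema(list(
#'   wealth = c("poorest", "poorer", "middle", "richer", "richest"),
#'   toilet = c("unimproved", "improved")
#' ))
#' @export
covariate_schema <- function(factors) {
  if (is.null(names(factors)) || any(names(factors) == "")) {
    stop("every factor must be named")
  }
  out <- lapply(factors, function(f) {
    if (is.character(f)) {
      list(categories = f, reference = f[1L])
    } else {
      stopifnot(is.list(f), !is.null(f$categories))
      ref <- if (is.null(f$reference)) f$categories[1L] else f$reference
      if (!ref %in% f$categories) stop("reference category not among categories")
      list(categories = f$categories, reference = ref)
    }
  })
  for (nm in names(out)) {
    if (anyDuplicated(out[[nm]]$categories)) {
      stop("duplicate category labels in factor '", nm, "'")
    }
  }
  structure(out, class = "covariate_schema")
}

#' Default child-level covariate schema
#'
#' The standard individual-, household- and neighbourhood-level factor set
#' used in DHS-style analyses of under-five diarrhoea: child age and sex,
#' birth weight/interval/order, maternal age (15-24, 25-34, 35-49), marital
#' and employment status, sex of household head, household wealth quintile,
#' media access, drinking-water source, toilet type (improved or
#' unimproved), cooking fuel, housing materials, urban/rural residence and
#' the neighbourhood SES quintile (1 = highest).
#'
#' @return a [covariate_schema()].
#' @export
default_schema <- function() {
  covariate_schema(list(
    child_age       = c("infant", "12-59 months"),
    child_sex       = c("female", "male"),
    household_head  = c("male", "female"),
    maternal_age    = c("15-24", "25-34", "35-49"),
    wealth          = c("poorest", "poorer", "middle", "richer", "richest"),
    employment      = c("employed", "unemployed"),
    media_access    = c("no", "yes"),
    water_source    = c("unimproved", "improved"),
    toilet          = c("unimproved", "improved"),
    marital_status  = c("never married", "currently married", "formerly married"),
    cooking_fuel    = c("unclean", "clean"),
    housing         = c("unimproved", "improved"),
    birth_weight    = c("average+", "small", "very small"),
    birth_interval  = c("first birth", "<36 months", "36+ months"),
    birth_order     = c("1", "2", "3", "4+"),
    residence       = c("urban", "rural"),
    neighbourhood_ses = c("1", "2", "3", "4", "5")
  ))
}

#' @export
print.covariate_schema <- function(x, ...) {
  cat("covariate schema with", length(x), "factors:\n")
  for (nm in names(x)) {
    cat(sprintf("  %s: %s (ref: %s)\n", nm,
                paste(x[[nm]]$categories, collapse = ", "), x[[nm]]$reference))
  }
  invisible(x)
}

#' Build a weighted design matrix from child records
#'
#' Dummy-codes every schema factor (reference level dropped, first column the
#' intercept) and records which columns belong to which factor, so that a
#' factor can later be manipulated as one block. Constant non-intercept
#' columns (categories unobserved in the data) are dropped from the matrix
#' and their block.
#'
#' @param records data frame of child records (see [read_child_table()]).
#' @param schema a [covariate_schema()]; defaults to the factor columns
#'   present in `records`.
#' @param factors optional character vector restricting which schema factors
#'   enter the design.
#' @return list with elements `x` (n x p matrix, intercept first), `y`
#'   (binary outcome), `w` (weights), `blocks` (named list of column index
#'   vectors per factor).
#' @export
build_design <- function(records, schema, factors = NULL) {
  if (is.null(factors)) factors <- intersect(names(schema), names(records))
  missing_cols <- setdiff(factors, names(records))
  if (length(missing_cols)) {
    stop("records lack factor column(s): ", paste(missing_cols, collapse = ", "))
  }
  n <- nrow(records)
  x <- matrix(1, nrow = n, ncol = 1, dimnames = list(NULL, "(Intercept)"))
  blocks <- list()
  for (nm in factors) {
    sc <- schema[[nm]]
    lev <- c(sc$reference, setdiff(sc$categories, sc$reference))
    f <- factor(as.character(records[[nm]]), levels = lev)
    if (anyNA(f)) stop("unknown category in factor '", nm, "'")
    mm <- stats::model.matrix(~f)[, -1L, drop = FALSE]
    colnames(mm) <- paste0(nm, ":", lev[-1L])
    keep <- apply(mm, 2L, function(col) stats::var(col) > 0)
    mm <- mm[, keep, drop = FALSE]
    if (ncol(mm) == 0L) next
    blocks[[nm]] <- seq.int(ncol(x) + 1L, ncol(x) + ncol(mm))
    x <- cbind(x, mm)
  }
  list(
    x = x,
    y = as.numeric(records$outcome),
    w = as.numeric(records$weight),
    blocks = blocks
  )
}
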