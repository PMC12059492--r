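# Variable dictionary: the per-variable preprocessing contract.

AGG_TOKENS <- c("median", "mode", "sum", "max", "min", "last")
IMP_TOKENS <- c("locf", "linear", "none")

#' Define the preprocessing contract for one clinical variable
#'
#' A variable specification fixes, per variable, its type, the within-bin
#' aggregation rule used during hourly resampling, the imputation strategy,
#' an optional global fallback used when a stay has no observation of the
#' variable at all, and (for categorical variables) the ordered category
#' labels.
#'
#' @param name variable identifier.
#' @param vtype `"numeric"` or `"categorical"`.
#' @param aggregation one of `"median"`, `"mode"`, `"sum"`, `"max"`,
#'   `"min"`, `"last"`.
#' @param imputation one of `"locf"`, `"linear"`, `"none"`. Categorical
#'   variables may not use `"linear"`.
#' @param fallback global summary (training-set median for numeric, mode for
#'   categorical) used for stays with zero observations; usually filled in
#'   by [fit_normalization()].
#' @param categories ordered category labels; categorical only. A
#'   `"missing"` level is appended automatically if absent.
#' @return an object of class `variable_spec`.
#' @export
variable_spec <- function(name, vtype, aggregation, imputation,
                          fallback = NA, categories = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!vtype %in% c("numeric", "categorical"))
    stop("unknown vtype '", vtype, "' for variable '", name, "'")
  if (!aggregation %in% AGG_TOKENS)
    stop("unknown aggregation token '", aggregation, "' for variable '",
         name, "'")
  if (!imputation %in% IMP_TOKENS)
    stop("unknown imputation token '", imputation, "' for variable '",
         name, "'")
  if (vtype == "numeric" && !is.null(categories))
    stop("numeric variable '", name, "' must not carry categories")
  if (vtype == "categorical") {
    if (imputation == "linear")
      stop("categorical variable '", name, "' cannot use linear imputation")
    if (is.null(categories) || length(categories) == 0L)
      stop("categorical variable '", name, "' needs a categories list")
    categories <- as.character(categories)
    if (!"missing" %in% categories) categories <- c(categories, "missing")
  }
  structure(
    list(name = name, vtype = vtype, aggregation = aggregation,
         imputation = imputation, fallback = fallback,
         categories = categories),
    class = "variable_spec"
  )
}

#' @export
print.variable_spec <- function(x, ...) {
  cat(sprintf("<variable_spec> %s [%s] agg=%s imp=%s", x$name, x$vtype,
              x$aggregation, x$imputation))
  if (!is.null(x$categories))
    cat(" levels={", paste(x$categories, collapse = ","), "}", sep = "")
  cat("\n")
  invisible(x)
}

#' Build a reduced variable dictionary for simulation and testing
#'
#' Numeric variables get median aggregation with linear interpolation;
#' categorical variables get mode aggregation, carry-forward head-fill and a
#' dedicated `"missing"` level, mirroring how a clinical variable dictionary
#' assigns rules by variable type.
#'
#' @param n_numeric number of numeric variables (`num_01`, ...).
#' @param n_categorical number of categorical variables (`cat_01`, ...),
#'   each with levels `low`, `mid`, `high` plus `missing`.
#' @return named list of [variable_spec()] objects.
#' @export
make_fixture_dictionary <- function(n_numeric, n_categorical) {
  stopifnot(n_numeric >= 0, n_categorical >= 0)
  specs <- list()
  if (n_numeric > 0) {
    for (i in seq_len(n_numeric)) {
      nm <- sprintf("num_%02d", i)
      specs[[nm]] <- variable_spec(nm, "numeric", "median", "linear")
    }
  }
  if (n_categorical > 0) {
    for (i in seq_len(n_categorical)) {
      nm <- sprintf("cat_%02d", i)
      specs[[nm]] <- variable_spec(nm, "categorical", "mode", "locf",
                                   categories = c("low", "mid", "high"))
    }
  }
  specs
}

#' Read / write a variable dictionary file
#'
#' Delimited text with columns `name`, `vtype`, `aggregation`, `imputation`,
#' `fallback`, `categories` (pipe-separated labels, empty for numeric).
#'
#' @param path file path.
#' @return `read_dictionary`: named list of [variable_spec()].
#' @export
read_dictionary <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("name", "vtype", "aggregation", "imputation", "fallback",
            "categories")
  if (!all(need %in% names(df)))
    stop("dictionary file missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  specs <- list()
  for (i in seq_len(nrow(df))) {
    cats <- if (nzchar(df$categories[i]))
      strsplit(df$categories[i], "|", fixed = TRUE)[[1]] else NULL
    fb <- df$fallback[i]
    fb <- if (!nzchar(fb)) NA
          else if (df$vtype[i] == "numeric") as.numeric(fb) else fb
    specs[[df$name[i]]] <- variable_spec(
      df$name[i], df$vtype[i], df$aggregation[i], df$imputation[i],
      fallback = fb, categories = cats)
  }
  specs
}

#' @rdname read_dictionary
#' @param specs named list of [variable_spec()].
#' @export
write_dictionary <- function(specs, path) {
  df <- data.frame(
    name = vapply(specs, `[[`, "", "name"),
    vtype = vapply(specs, `[[`, "", "vtype"),
    aggregation = vapply(specs, `[[`, "", "aggregation"),
    imputation = vapply(specs, `[[`, "", "imputation"),
    fallback = vapply(specs, function(s)
      if (is.na(s$fallback)) "" else as.character(s$fallback), ""),
    categories = vapply(specs, function(s)
      if (is.null(s$categories)) "" else
        paste(s$categories, collapse = "|"), ""),
    stringsAsFactors = FALSE
  )
  df <- df[order(df$name), , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
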