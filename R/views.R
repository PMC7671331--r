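#' Construct a view
#'
#' A view is one sample-by-feature data matrix with a declared distribution
#' family.  Compositional sequence count views (`family = "count"`) must
#' hold non-negative integers where observed; gaussian views hold real
#' intensities and may be log-transformed on construction.  Missing cells
#' are encoded as `NA` and are excluded from all estimating equations.
#'
#' @param x numeric matrix, samples in rows, features in columns.  Row and
#'   column names are used as sample and feature identifiers (defaults are
#'   generated when absent).
#' @param family `"count"` for compositional sequence counts, `"gaussian"`
#'   for (approximately log-normal) intensity data.
#' @param log_transform for gaussian views only: take `log(x)` on load.
#'   Entries must then be strictly positive where observed.
#' @param name optional label used in printing and multiplots.
#' @return an object of class `view_data`.
#' @export
view_data <- function(x, family = c("count", "gaussian"),
                      log_transform = FALSE, name = NULL) {
  family <- match.arg(family)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(rownames(x))) rownames(x) <- paste0("sample", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  obs <- is.finite(x)
  x[!obs] <- NA_real_
  if (family == "count") {
    v <- x[obs]
    if (any(v < 0) || any(v != round(v)))
      stop("count views must contain non-negative integers where observed")
    if (log_transform)
      stop("'log_transform' applies to gaussian views only")
  } else if (log_transform) {
    if (any(x[obs] <= 0))
      stop("cannot log-transform non-positive values")
    x[obs] <- log(x[obs])
  }
  structure(
    list(x = x, family = family, log_transformed = isTRUE(log_transform),
         name = name %||% family),
    class = "view_data")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.view_data <- function(x, ...) {
  cat(sprintf("view '%s' (%s): %d samples x %d features, %.1f%% missing\n",
              x$name, x$family, nrow(x$x), ncol(x$x),
              100 * mean(is.na(x$x))))
  invisible(x)
}

#' Drop features too sparse to be identifiable
#'
#' Features with zero total observed count have an unidentifiable clr
#' parameter and must be removed before fitting; features observed in fewer
#' than two samples cannot contribute a variance estimate.  This helper
#' applies both rules.
#'
#' @param view a [view_data()] object.
#' @param min_total minimum total observed value (counts) to keep a feature.
#' @param min_obs minimum number of observed cells per feature.
#' @return the filtered `view_data`.
#' @export
filter_features <- function(view, min_total = 1, min_obs = 2L) {
  stopifnot(inherits(view, "view_data"))
  nobs <- colSums(!is.na(view$x))
  keep <- nobs >= min_obs
  if (view$family == "count")
    keep <- keep & colSums(view$x, na.rm = TRUE) >= min_total
  view$x <- view$x[, keep, drop = FALSE]
  view
}

#' Read a view from a delimited file
#'
#' Expects a header of feature identifiers and a first column of sample
#' identifiers; empty cells are read as missing.
#'
#' @param file path to a TSV (default) or CSV matrix.
#' @param sep field separator.
#' @inheritParams view_data
#' @return a [view_data()] object.
#' @export
read_view <- function(file, family = c("count", "gaussian"), sep = "\t",
                      log_transform = FALSE, name = NULL) {
  d <- utils::read.table(file, header = TRUE, sep = sep, row.names = 1L,
                         check.names = FALSE, na.strings = c("", "NA"))
  view_data(as.matrix(d), family = match.arg(family),
            log_transform = log_transform,
            name = name %||% sub("\\.[^.]*$", "", basename(file)))
}

#' Write a view to a delimited file
#'
#' @param view a [view_data()] object.
#' @param file output path.
#' @param sep field separator.
#' @export
write_view <- function(view, file, sep = "\t") {
  m <- view$x
  df <- data.frame(sample = rownames(m), m, check.names = FALSE)
  utils::write.table(df, file, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(file)
}

# Align a list of views on the union of their sample ids: rows are reordered
# to a common id vector; a sample absent from a view becomes an all-missing
# row there.  Samples missing from every view are dropped with a warning.
align_views <- function(views) {
  ids <- unique(unlist(lapply(views, function(v) rownames(v$x))))
  views <- lapply(views, function(v) {
    m <- matrix(NA_real_, length(ids), ncol(v$x),
                dimnames = list(ids, colnames(v$x)))
    m[rownames(v$x), ] <- v$x
    v$x <- m
    v
  })
  some_obs <- Reduce(`|`, lapply(views, function(v) rowSums(!is.na(v$x)) > 0))
  if (!any(some_obs)) stop("views share no observed samples")
  if (!all(some_obs)) {
    warning(sum(!some_obs), " sample(s) unobserved in every view dropped")
    views <- lapply(views, function(v) {
      v$x <- v$x[some_obs, , drop = FALSE]; v })
  }
  views
}

#' Encode sample variables into a constrained/confounder design matrix
#'
#' Categorical variables expand to one indicator column per level with no
#' reference level dropped; the zero-sum restriction on the corresponding
#' gradient entries (recorded in `blocks`) removes the resulting redundancy
#' and keeps the display symmetric in the levels.  Continuous variables are
#' centered and scaled to standard deviation one, so gradient entries are
#' comparable across variables.
#'
#' @param metadata data.frame of sample variables, rows named by sample id.
#' @param variables character vector of column names to encode.
#' @return list with `design` (n-by-d numeric matrix) and `blocks` (named
#'   list mapping each categorical variable to its column indices).
#' @export
encode_design <- function(metadata, variables) {
  stopifnot(is.data.frame(metadata), length(variables) >= 1L)
  missing_vars <- setdiff(variables, names(metadata))
  if (length(missing_vars))
    stop("variables not in metadata: ", paste(missing_vars, collapse = ", "))
  cols <- list(); blocks <- list()
  for (v in variables) {
    val <- metadata[[v]]
    if (anyNA(val)) stop("missing metadata values for '", v, "'")
    if (is.numeric(val)) {
      s <- stats::sd(val)
      if (s == 0) stop("continuous variable '", v, "' is constant")
      cols[[v]] <- matrix((val - mean(val)) / s, ncol = 1L,
                          dimnames = list(NULL, v))
    } else {
      f <- factor(val)
      if (nlevels(f) < 2L)
        stop("categorical variable '", v, "' has a single level")
      ind <- stats::model.matrix(~ 0 + f)
      colnames(ind) <- paste(v, levels(f), sep = "_")
      cols[[v]] <- ind
    }
  }
  design <- do.call(cbind, cols)
  rownames(design) <- rownames(metadata)
  at <- 0L
  for (v in variables) {
    k <- ncol(cols[[v]])
    if (!is.numeric(metadata[[v]])) blocks[[v]] <- at + seq_len(k)
    at <- at + k
  }
  list(design = design, blocks = blocks)
}
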