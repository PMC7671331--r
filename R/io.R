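# Matrices are exchanged as TSV with full double precision (%.17g) so that
# an export/import round trip is bit-exact.
write_matrix_tsv <- function(m, file, row_label = "id") {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste(c(row_label, colnames(m)), collapse = "\t"), con)
  body <- apply(m, 1L, function(r)
    paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(paste(rownames(m), body, sep = "\t"), con)
  invisible(file)
}

read_matrix_tsv <- function(file) {
  d <- utils::read.table(file, header = TRUE, sep = "\t", row.names = 1L,
                         check.names = FALSE, colClasses = "character")
  m <- vapply(d, as.numeric, numeric(nrow(d)))
  if (nrow(d) == 1L) m <- matrix(m, 1L, dimnames = list(NULL, names(d)))
  rownames(m) <- rownames(d)
  m
}

#' Serialize a fitted integration to a directory
#'
#' Writes the fit as plain text: a JSON file with scalars, restrictions
#' echo and convergence diagnostics, plus one TSV per matrix (scores,
#' per-view loadings and offsets, gradient).  The raw data matrices are not
#' serialized; operations needing them (influence, quasi-scores) require
#' the in-memory fit.
#'
#' @param fit a [compint()] fit.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @seealso [read_fit()]
#' @export
write_fit <- function(fit, dir) {
  stopifnot(inherits(fit, "compint"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(
    package = "compint", M = fit$M, tol = fit$tol, psi = fit$psi,
    constrained = !is.null(fit$gradient),
    views = lapply(fit$views, function(vf)
      list(name = vf$name, family = vf$family, p = vf$p,
           depths = vf$indep$depths)),
    convergence = fit$convergence)
  jsonlite::write_json(meta, file.path(dir, "fit.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  write_matrix_tsv(fit$scores, file.path(dir, "scores.tsv"), "sample")
  for (k in seq_along(fit$views)) {
    vf <- fit$views[[k]]
    L <- vf$loadings
    rownames(L) <- paste0("dim", seq_len(nrow(L)))
    write_matrix_tsv(L, file.path(dir, sprintf("loadings_%s.tsv", vf$name)),
                     "dimension")
    om <- rbind(offset = vf$indep$offset, omega = vf$omega)
    colnames(om) <- vf$feature_ids
    write_matrix_tsv(om, file.path(dir, sprintf("offset_%s.tsv", vf$name)))
  }
  if (!is.null(fit$gradient))
    write_matrix_tsv(fit$gradient$Lambda, file.path(dir, "gradient.tsv"),
                     "variable")
  invisible(dir)
}

#' Read back a serialized fit
#'
#' Restores the components written by [write_fit()]: scores, loadings,
#' offsets, weights, gradient and metadata.  The result supports
#' coordinate and evaluation operations but not data-dependent ones.
#'
#' @param dir directory written by [write_fit()].
#' @return a list of class `compint_export`.
#' @export
read_fit <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "fit.json"),
                              simplifyVector = TRUE)
  scores <- read_matrix_tsv(file.path(dir, "scores.tsv"))
  views <- lapply(meta$views, function(v) {
    L <- read_matrix_tsv(file.path(dir, sprintf("loadings_%s.tsv", v$name)))
    om <- read_matrix_tsv(file.path(dir, sprintf("offset_%s.tsv", v$name)))
    list(name = v$name, family = v$family, p = v$p,
         loadings = L, offset = om["offset", ], omega = om["omega", ],
         depths = v$depths, feature_ids = colnames(L))
  })
  gradient <- if (isTRUE(meta$constrained))
    read_matrix_tsv(file.path(dir, "gradient.tsv"))
  structure(list(meta = meta, scores = scores, views = views,
                 gradient = gradient),
            class = "compint_export")
}

#' Export multiplot coordinates as TSV
#'
#' One file per layer (`samples.tsv`, `features_<view>.tsv`,
#' `gradient.tsv`), numeric columns at full precision so re-importing
#' reproduces coordinates bit-exactly.
#'
#' @param mp a [multiplot_coordinates()] object.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_multiplot <- function(mp, dir) {
  stopifnot(inherits(mp, "multiplot"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wdf <- function(df, file) {
    num <- vapply(df, is.numeric, logical(1L))
    df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
    utils::write.table(df, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wdf(mp$samples, file.path(dir, "samples.tsv"))
  for (nm in names(mp$features))
    wdf(mp$features[[nm]], file.path(dir, sprintf("features_%s.tsv", nm)))
  if (!is.null(mp$gradient)) wdf(mp$gradient, file.path(dir, "gradient.tsv"))
  writeLines(sprintf("%d", mp$dims), file.path(dir, "dims.txt"))
  invisible(dir)
}

#' Re-import multiplot coordinates
#'
#' @param dir directory written by [write_multiplot()].
#' @return a `multiplot` object.
#' @export
read_multiplot <- function(dir) {
  rdf <- function(file, num_cols) {
    d <- utils::read.table(file, header = TRUE, sep = "\t",
                           colClasses = "character")
    for (cn in intersect(num_cols, names(d))) d[[cn]] <- as.numeric(d[[cn]])
    if ("shown" %in% names(d)) d$shown <- d$shown == "TRUE"
    d
  }
  files <- list.files(dir, pattern = "^features_.*\\.tsv$")
  features <- lapply(files, function(f)
    rdf(file.path(dir, f), c("x", "y", "norm")))
  names(features) <- sub("^features_(.*)\\.tsv$", "\\1", files)
  gradient <- if (file.exists(file.path(dir, "gradient.tsv")))
    rdf(file.path(dir, "gradient.tsv"), c("x", "y"))
  structure(list(
    samples = rdf(file.path(dir, "samples.tsv"), c("x", "y")),
    features = features, gradient = gradient,
    dims = as.integer(readLines(file.path(dir, "dims.txt")))),
    class = "multiplot")
}
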