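#' Standardize a feature matrix
#'
#' Centers every column to sample mean zero and scales it to unit sample
#' variance (divisor \code{n - 1}). All downstream reflection and knockoff
#' algebra assumes this standardization, and the same \code{n - 1} divisor is
#' used for every sample covariance in the package.
#'
#' @param raw Numeric matrix, samples in rows and features in columns, or an
#'   object coercible to one. Must have at least two rows and two columns,
#'   finite entries, and no constant column.
#' @param names Optional character vector of feature names; defaults to the
#'   column names of \code{raw} (or \code{V1..Vp}).
#' @return An object of class \code{"feature_matrix"}: a list with elements
#'   \code{values} (the standardized matrix), \code{feature_names}, \code{n},
#'   \code{p}, \code{standardized}, \code{col_means} and \code{col_scales}
#'   (the standard deviations removed), so the transform can be inverted.
#' @examples
#' X <- standardize(matrix(rnorm(40), 10, 4))
#' colMeans(X$values)          # ~ 0
#' apply(X$values, 2, var)     # ~ 1
#' @export
standardize <- function(raw, names = NULL) {
  raw <- as.matrix(raw)
  if (!is.numeric(raw)) stop("feature matrix must be numeric")
  if (nrow(raw) < 2L) stop("need at least 2 samples (rows)")
  if (ncol(raw) < 2L) stop("need at least 2 features (columns); reflection is undefined for p = 1")
  if (any(!is.finite(raw))) {
    bad <- which(!is.finite(raw), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite entry at row %d, column %d", bad[1L], bad[2L]))
  }
  if (is.null(names)) names <- colnames(raw)
  if (is.null(names)) names <- paste0("V", seq_len(ncol(raw)))
  if (anyDuplicated(names)) stop("duplicate feature names: ",
                                 paste(unique(names[duplicated(names)]), collapse = ", "))

  mu <- colMeans(raw)
  sdv <- apply(raw, 2L, stats::sd)
  zero <- sdv <= 0 | !is.finite(sdv)
  if (any(zero)) {
    stop("constant (zero-variance) column(s): ", paste(names[zero], collapse = ", "))
  }
  vals <- sweep(sweep(raw, 2L, mu, "-"), 2L, sdv, "/")
  dimnames(vals) <- list(NULL, names)
  structure(list(values = vals,
                 feature_names = names,
                 n = nrow(vals), p = ncol(vals),
                 standardized = TRUE,
                 col_means = mu, col_scales = sdv),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("Standardized feature matrix: %d samples x %d features\n", x$n, x$p))
  invisible(x)
}

# Accept either a feature_matrix or a plain matrix (standardizing it if its
# columns are not already mean-0 / variance-1 to tight tolerance).
as_feature_matrix <- function(X) {
  if (inherits(X, "feature_matrix")) return(X)
  X <- as.matrix(X)
  mu <- colMeans(X)
  v <- apply(X, 2L, stats::var)
  if (max(abs(mu)) <= 1e-10 && max(abs(v - 1)) <= 1e-10) {
    nm <- colnames(X)
    if (is.null(nm)) nm <- paste0("V", seq_len(ncol(X)))
    structure(list(values = `dimnames<-`(X, list(NULL, nm)),
                   feature_names = nm, n = nrow(X), p = ncol(X),
                   standardized = TRUE,
                   col_means = rep(0, ncol(X)), col_scales = rep(1, ncol(X))),
              class = "feature_matrix")
  } else {
    standardize(X)
  }
}

#' Read a delimited feature matrix
#'
#' Reads a TSV or CSV file with a header row of feature names and a numeric
#' body (samples in rows), and standardizes it. The delimiter is inferred
#' from the file extension (\code{.csv} = comma, anything else = tab) unless
#' overridden.
#'
#' @param path File path.
#' @param sep Field delimiter; \code{NULL} (default) sniffs from the extension.
#' @return A \code{"feature_matrix"} (see [standardize()]).
#' @export
read_feature_matrix <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = "character", comment.char = "")
  m <- suppressWarnings(matrix(as.numeric(as.matrix(df)), nrow(df), ncol(df)))
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing or non-numeric value at data row %d, column '%s' in %s",
                 bad[1L], colnames(df)[bad[2L]], path))
  }
  standardize(m, names = colnames(df))
}

#' Write a numeric matrix as delimited text
#'
#' @param path Output path; extension picks the delimiter as in
#'   [read_feature_matrix()].
#' @param m Numeric matrix (column names written as the header row).
#' @param sep Optional delimiter override.
#' @export
write_feature_matrix <- function(path, m, sep = NULL) {
  if (inherits(m, "feature_matrix")) m <- m$values
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(format(m, digits = 17, trim = TRUE, scientific = TRUE),
                     path, sep = sep, quote = FALSE, row.names = FALSE,
                     col.names = !is.null(colnames(m)))
  invisible(path)
}

#' Read a single-column phenotype vector
#'
#' Plain-text file with one numeric value per line (no header).
#' @param path File path.
#' @return Numeric vector.
#' @export
read_phenotype <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ln <- readLines(path)
  ln <- ln[nzchar(trimws(ln))]
  y <- suppressWarnings(as.numeric(ln))
  if (anyNA(y)) stop("non-numeric or missing value at line ", which(is.na(y))[1L], " of ", path)
  y
}

# sample covariance with the package-wide n-1 convention
sample_cov <- function(A, B = NULL) {
  if (is.null(B)) stats::cov(A) else stats::cov(A, B)
}
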