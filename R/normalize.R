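## Per-organism quantile normalization with explicit missing-value handling,
## and the limit of quantitation.

## Quantile-normalize one matrix (proteins x samples) containing NAs.
## Per-sample ranks are computed on observed values only; the reference is
## the mean quantile function over samples, evaluated by linear interpolation
## at each sample's own quantile grid. On complete data this reduces to the
## classic substitute-by-rank-wise-means algorithm. Tied values receive the
## mean of the reference values for their tied ranks.
.quantileNormalizeMatrix <- function(X) {
  use <- which(colSums(!is.na(X)) > 0L)
  if (length(use) < 2L) {
    stop("quantile normalization needs at least 2 samples with data", call. = FALSE)
  }
  sorted <- lapply(use, function(j) sort(X[, j]))
  grids <- lapply(sorted, function(s) {
    if (length(s) == 1L) 0.5 else seq(0, 1, length.out = length(s))
  })
  refAt <- function(p) {
    acc <- numeric(length(p))
    for (i in seq_along(sorted)) {
      s <- sorted[[i]]
      acc <- acc + if (length(s) == 1L) rep(s, length(p)) else {
        stats::approx(grids[[i]], s, xout = p, rule = 2)$y
      }
    }
    acc / length(sorted)
  }
  for (j in use) {
    idx <- which(!is.na(X[, j]))
    n <- length(idx)
    p <- if (n == 1L) 0.5 else seq(0, 1, length.out = n)
    ref <- refAt(p)
    ord <- order(X[idx, j])
    new_vals <- numeric(n)
    new_vals[ord] <- ref
    new_vals <- stats::ave(new_vals, X[idx, j], FUN = mean)
    X[idx, j] <- new_vals
  }
  X
}

#' Per-organism quantile normalization
#'
#' Within each organism's submatrix, each sample's observed values are
#' replaced by rank-wise means across the organism's samples (extended to
#' missing data as described under Details). Missing entries stay missing,
#' within-sample rank order is preserved, and samples with no observed value
#' for an organism are left untouched. The two organisms are never
#' normalized against each other: their abundance distributions differ by
#' construction of the biomass ratio.
#'
#' @details With complete data the procedure is the standard algorithm:
#' sort each sample, average across samples rank by rank, substitute. With
#' missing values each sample's observed values are mapped onto the mean
#' empirical quantile function (linear interpolation between order
#' statistics) at the sample's own quantile grid; ties receive the mean of
#' their reference values.
#'
#' @param x a [ProteinQuantMatrix-class].
#' @return `x` with the `log2` assay replaced by its normalized values;
#'   `metadata(x)$quantile_normalized` is set to `TRUE`.
#' @export
quantileNormalizeByOrganism <- function(x) {
  stopifnot(is(x, "ProteinQuantMatrix"))
  X <- log2Abundance(x)
  org <- as.character(rowData(x)$organism)
  for (o in unique(org)) {
    rows <- org == o
    X[rows, ] <- .quantileNormalizeMatrix(X[rows, , drop = FALSE])
  }
  assay(x, "log2") <- X
  metadata(x)$quantile_normalized <- TRUE
  x
}

#' Limit of quantitation
#'
#' Two sample standard deviations below the mean of all non-missing log2
#' values in scope. By default the LOQ is computed per organism, consistent
#' with per-organism normalization; `scope = "experiment"` pools both
#' organisms.
#'
#' @param x a [ProteinQuantMatrix-class], or a numeric vector of log2
#'   values.
#' @param scope `"organism"` (default) or `"experiment"`.
#' @return Named numeric vector of LOQ values (one per organism, or one
#'   named `"experiment"`).
#' @examples
#' computeLoq(c(18, 20, 22))   # mean 20, sd 2 -> 16
#' @export
computeLoq <- function(x, scope = c("organism", "experiment")) {
  scope <- match.arg(scope)
  loq1 <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2L) stop("LOQ needs at least 2 values", call. = FALSE)
    mean(v) - 2 * stats::sd(v)
  }
  if (is.numeric(x)) return(setNames(loq1(x), "experiment"))
  stopifnot(is(x, "ProteinQuantMatrix"))
  X <- log2Abundance(x)
  if (scope == "experiment") {
    return(setNames(loq1(as.numeric(X)), "experiment"))
  }
  org <- as.character(rowData(x)$organism)
  vapply(sort(unique(org)), function(o) loq1(as.numeric(X[org == o, , drop = FALSE])),
         numeric(1))
}
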