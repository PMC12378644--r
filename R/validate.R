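#' @importFrom stats cor sd lm coef cmdscale aggregate
NULL

#' Paired comparison of two abundance series
#'
#' The comparison reported between quantification methods: Pearson
#' correlation plus a slope under one of three models — ordinary least
#' squares through the origin (default; a slope near 1 then means numeric
#' equivalence of the two counts), OLS with intercept, or standardized
#' major axis.  Optionally computed on log10-transformed pairs.
#'
#' @param x Reference series (e.g. flow-cytometry cells per liter, or
#'   ground truth), or a data.frame with columns `x` and `y`.
#' @param y Metagenomic estimates, same unit and pairing as `x`.
#' @param transform `"linear"` (default) or `"log10"` (requires positive
#'   values).
#' @param slope_model `"origin"`, `"ols"`, `"sma"` or `"all"`.
#' @return data.frame with one row per model: `model`, `slope`,
#'   `intercept`, `pearson_r`, `n`.
#' @export
paired_comparison <- function(x, y = NULL,
                              transform = c("linear", "log10"),
                              slope_model = c("origin", "ols", "sma",
                                              "all")) {
  if (is.data.frame(x)) { y <- x$y; x <- x$x }
  transform <- match.arg(transform)
  slope_model <- match.arg(slope_model)
  if (length(x) != length(y)) stop("series must be paired (equal lengths)")
  if (length(x) < 3L) stop("need n >= 3 pairs")
  if (transform == "log10") {
    if (any(x <= 0) || any(y <= 0)) stop("log10 requires positive values")
    x <- log10(x); y <- log10(y)
  }
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance in x or y")
  r <- cor(x, y)
  models <- if (slope_model == "all") c("origin", "ols", "sma")
            else slope_model
  rows <- lapply(models, function(m) {
    switch(m,
      origin = data.frame(model = "origin", slope = sum(x * y) / sum(x^2),
                          intercept = 0, pearson_r = r, n = length(x)),
      ols = {
        cf <- coef(lm(y ~ x))
        data.frame(model = "ols", slope = unname(cf[2L]),
                   intercept = unname(cf[1L]), pearson_r = r, n = length(x))
      },
      sma = {
        sl <- sign(r) * sd(y) / sd(x)
        data.frame(model = "sma", slope = sl,
                   intercept = mean(y) - sl * mean(x), pearson_r = r,
                   n = length(x))
      })
  })
  out <- do.call(rbind, rows)
  out$transform <- transform
  out
}

#' Fold range of a positive series
#'
#' @param values Positive numeric vector.
#' @return `max(values) / min(values)`.
#' @export
fold_range <- function(values) {
  if (!length(values)) stop("empty series")
  if (any(values <= 0)) stop("fold range undefined: non-positive values")
  max(values) / min(values)
}

#' Convert filament counts to cell counts
#'
#' Microscopy counts of filamentous cyanobacteria are per filament; the
#' conversion multiplies by an average number of cells per filament
#' (default 100).
#'
#' @param filaments_per_liter Filament density (`>= 0`).
#' @param cells_per_filament Average cells per filament (`>= 0`).
#' @return Cells per liter (vectorized).
#' @export
filaments_to_cells <- function(filaments_per_liter, cells_per_filament = 100) {
  if (any(filaments_per_liter < 0) || any(cells_per_filament < 0))
    stop("inputs must be >= 0")
  filaments_per_liter * cells_per_filament
}

#' Relative abundance from an absolute abundance matrix
#'
#' @param mat Numeric matrix or data.frame, samples in rows, taxa in
#'   columns; row sums must be positive.
#' @return Matrix of the same shape with rows summing to 1.
#' @export
relative_from_absolute <- function(mat) {
  m <- as.matrix(mat)
  rs <- rowSums(m)
  if (any(rs <= 0)) stop("zero or negative row sum at row ",
                         paste(which(rs <= 0), collapse = ", "))
  sweep(m, 1L, rs, "/")
}

#' Bray-Curtis dissimilarity and PCoA variance explained
#'
#' Computes the pairwise Bray-Curtis dissimilarity
#' `sum(|x_i - y_i|) / sum(x_i + y_i)` of community profiles (optionally
#' converted to relative abundance first) and a classical metric
#' multidimensional scaling (PCoA).  Bray-Curtis is not Euclidean, so
#' negative eigenvalues can occur; by default they are clipped at zero
#' when computing the fraction of variance on the first two axes, or a
#' Cailliez correction can be applied instead.
#'
#' @param mat Non-negative matrix, samples in rows (`>= 3` samples).
#' @param mode `"relative"` (rows normalized first) or `"absolute"`.
#' @param correction `"clip"` (default) or `"cailliez"`.
#' @return List: `dissimilarity` (full symmetric matrix), `points` (PCoA
#'   coordinates), `eig`, `variance_explained` (fraction of positive
#'   eigenvalue mass on axes 1-2).
#' @export
braycurtis_pcoa <- function(mat, mode = c("relative", "absolute"),
                            correction = c("clip", "cailliez")) {
  mode <- match.arg(mode)
  correction <- match.arg(correction)
  m <- as.matrix(mat)
  if (nrow(m) < 3L) stop("need >= 3 samples")
  if (any(m < 0)) stop("matrix must be non-negative")
  if (any(rowSums(m) == 0)) stop("all-zero sample row")
  if (mode == "relative") m <- relative_from_absolute(m)
  d <- vegan::vegdist(m, method = "bray")
  k <- nrow(m) - 1L
  mds <- cmdscale(d, k = k, eig = TRUE, add = (correction == "cailliez"))
  pos <- pmax(mds$eig, 0)
  ve <- sum(pos[1:2]) / sum(pos)
  list(dissimilarity = as.matrix(d), points = mds$points, eig = mds$eig,
       variance_explained = ve)
}
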