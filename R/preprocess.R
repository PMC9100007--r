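#' Per-gene mean and standard deviation
#'
#' Summarises each gene across samples. The population convention
#' (divide by n) is the default so that constant genes have exactly zero
#' standard deviation; the sample convention (n - 1) is available.
#'
#' @param expr samples x genes matrix
#' @param convention `"population"` or `"sample"`
#' @return data.frame with columns `gene`, `mean`, `std`
#' @export
geneStats <- function(expr, convention = c("population", "sample")) {
  convention <- match.arg(convention)
  expr <- expressionMatrix(expr)
  n <- nrow(expr)
  if (n < 2L) stop("gene statistics need at least 2 samples")
  mu <- colMeans(expr)
  ss <- colMeans(expr^2) - mu^2
  ss[ss < 0] <- 0  # guard tiny negative from cancellation
  std <- if (convention == "population") sqrt(ss)
         else sqrt(ss * n / (n - 1))
  data.frame(gene = colnames(expr), mean = unname(mu), std = unname(std),
             stringsAsFactors = FALSE)
}

#' Filter thresholds for noise and empty genes
#'
#' Log-scale expression shows a valley in the per-gene standard-deviation
#' distribution around 0.4 and a mass of near-zero genes below mean 0.8;
#' genes under either threshold carry no usable signal. Lower bounds are
#' closed so zero-variance genes are always removed.
#'
#' @param stdHigh,meanHigh upper (exclusive) removal thresholds
#' @param stdLow,meanLow lower (inclusive) bounds, normally 0
#' @return classed list of thresholds
#' @export
filterSpec <- function(stdHigh = 0.4, meanHigh = 0.8,
                       stdLow = 0, meanLow = 0) {
  if (stdLow > stdHigh || meanLow > meanHigh)
    stop("filter bounds must satisfy low <= high")
  structure(list(stdLow = stdLow, stdHigh = stdHigh,
                 meanLow = meanLow, meanHigh = meanHigh),
            class = "savae_filter_spec")
}

#' Remove noise and empty genes
#'
#' A gene is removed when its standard deviation lies in
#' `[stdLow, stdHigh)` (a "noise gene") or its mean lies in
#' `[meanLow, meanHigh)` (an "empty gene"). Kept genes preserve their
#' input order.
#'
#' @param expr samples x genes matrix
#' @param spec thresholds from [filterSpec()]
#' @param convention standard-deviation convention, see [geneStats()]
#' @return list: `expr` (filtered matrix), `removed` (gene ids),
#'   `stats` (the gene statistics used), `empty` (TRUE when everything
#'   was removed; also raises a warning)
#' @export
filterNoiseGenes <- function(expr, spec = filterSpec(),
                             convention = "population") {
  st <- geneStats(expr, convention = convention)
  noise <- st$std >= spec$stdLow & st$std < spec$stdHigh
  empty <- st$mean >= spec$meanLow & st$mean < spec$meanHigh
  drop <- noise | empty
  kept <- expr[, !drop, drop = FALSE]
  if (ncol(kept) == 0L)
    warning("all genes removed by the noise/empty filters")
  list(expr = kept, removed = st$gene[drop], stats = st,
       empty = ncol(kept) == 0L)
}

#' Feature-wise min-max normalization
#'
#' Maps each gene to `(x - min) / (max - min)` using its own column range,
#' or a previously fitted reference range when applying a training-fold
#' fit to held-out samples (values outside the reference range then fall
#' outside [0, 1] and are deliberately not clipped). Constant genes map
#' to 0.
#'
#' @param expr samples x genes matrix
#' @param reference optional data.frame with columns `gene`, `min`, `max`
#'   (as returned in `$range`) to apply instead of fitting
#' @return list: `expr` (normalized matrix), `range` (per-gene min/max
#'   used)
#' @export
minmaxNormalize <- function(expr, reference = NULL) {
  expr <- expressionMatrix(expr)
  if (is.null(reference)) {
    lo <- apply(expr, 2L, min)
    hi <- apply(expr, 2L, max)
  } else {
    if (!all(colnames(expr) %in% reference$gene))
      stop("reference range does not cover all genes")
    idx <- match(colnames(expr), reference$gene)
    lo <- reference$min[idx]
    hi <- reference$max[idx]
  }
  span <- hi - lo
  out <- sweep(expr, 2L, lo, "-")
  const <- span <= 0
  span[const] <- 1
  out <- sweep(out, 2L, span, "/")
  out[, const] <- 0
  list(expr = out,
       range = data.frame(gene = colnames(expr), min = unname(lo),
                          max = unname(hi), stringsAsFactors = FALSE))
}

#' Filter then normalize in one call
#'
#' Convenience wrapper running [filterNoiseGenes()] followed by
#' [minmaxNormalize()], the standard preparation before pretraining.
#'
#' @inheritParams filterNoiseGenes
#' @return list: `expr`, `removed`, `range`, `stats`
#' @export
preprocessExpression <- function(expr, spec = filterSpec(),
                                 convention = "population") {
  f <- filterNoiseGenes(expr, spec, convention)
  if (f$empty) stop("no genes survive filtering; nothing to normalize")
  n <- minmaxNormalize(f$expr)
  list(expr = n$expr, removed = f$removed, range = n$range, stats = f$stats)
}
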