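#' Genome-wide class fractions from a decoding
#'
#' The genome-wide probability of each class: the unweighted mean of the
#' per-marker posterior class probabilities over all autosomal markers
#' (`weighted = TRUE` weights each marker by the genetic interval it
#' represents instead).
#'
#' @param decoding An `"hbd_decoding"` from [forward_backward()], or a
#'   bare posterior matrix.
#' @param map Required for `weighted = TRUE` when a bare matrix is given.
#' @param weighted Weight markers by inter-marker distance.
#' @return Numeric vector of per-class fractions (sums to 1).
#' @export
genomewide_class_fractions <- function(decoding, map = NULL,
                                       weighted = FALSE) {
  post <- if (inherits(decoding, "hbd_decoding")) decoding$posteriors
          else as.matrix(decoding)
  if (!weighted) return(colMeans(post))
  if (is.null(map) && inherits(decoding, "hbd_decoding")) map <- decoding$map
  if (is.null(map)) stop("'map' required for distance-weighted averaging")
  cs <- c(TRUE, map$chrom[-1L] != map$chrom[-nrow(map)])
  d <- c(0, diff(map$morgans)); d[cs] <- 0
  w <- (c(d[-1L], 0) + d) / 2  # half the flanking intervals
  w[w == 0] <- min(w[w > 0])
  colSums(post * w) / sum(w)
}

#' Threshold inbreeding coefficient F_G-T
#'
#' The probability of belonging to any HBD class with rate `R_k <= T`,
#' averaged over the genome: class fractions summed over the qualifying
#' HBD classes.  `T` defines the base population (about `T / 2`
#' generations back); the largest `T` gives total F_G.
#'
#' @param x An `"hbd_decoding"`, a posterior matrix, or a per-class
#'   fraction vector.
#' @param model The [hbd_model()] providing the class rates.
#' @param T Rate threshold (> 0).
#' @return A single coefficient.
#' @export
inbreeding_f_t <- function(x, model, T = NULL) {
  fractions <- if (inherits(x, "hbd_decoding"))
    genomewide_class_fractions(x)
  else if (is.matrix(x)) colMeans(x)
  else x
  f_g_threshold(fractions, model, T)
}

#' Segment-length distribution table
#'
#' Counts segments per length bin.  The default bins follow the usual
#' reporting grid from under 1 kb up to 100 Mb; bins are half-open
#' `[low, high)` with the lowest bin closed at 0.
#'
#' @param segments A `data.frame` with a `length_bp` column.
#' @param breaks Bin boundaries in bp (ascending).
#' @return A `data.frame` with `bin` labels and `count`, partitioning the
#'   segment list.
#' @export
segment_length_table <- function(segments,
                                 breaks = c(0, 1e3, 5e3, 1e4, 5e4, 1e5,
                                            5e5, 1e6, 5e6, 1e7, 5e7, 1e8)) {
  stopifnot(!is.unsorted(breaks))
  lens <- segments$length_bp
  if (any(lens >= breaks[length(breaks)] | lens < breaks[1L]))
    stop("segment length outside the binning range")
  bin <- cut(lens, breaks, right = FALSE, include.lowest = FALSE)
  labels <- paste0(fmt_bp(breaks[-length(breaks)]), "-",
                   fmt_bp(breaks[-1L]))
  data.frame(bin = labels, count = as.integer(table(bin)),
             stringsAsFactors = FALSE)
}

fmt_bp <- function(x) {
  ifelse(x >= 1e6, paste0(x / 1e6, " Mb"),
         ifelse(x >= 1e3, paste0(x / 1e3, " kb"), paste0(x, " bp")))
}

#' Compare inbreeding estimators across individuals
#'
#' Pairwise correlations and per-estimator summaries over the individuals
#' present in every input column.
#'
#' @param estimates A `data.frame` with an `id` column and one numeric
#'   column per estimator (e.g. [f_estimates()] merged with HMM-based
#'   F_G values).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A list with `correlations` (symmetric matrix, unit diagonal),
#'   `summary` (mean/min/max per estimator) and `n` (individuals used).
#' @export
estimator_comparison <- function(estimates, method = c("pearson",
                                                       "spearman")) {
  method <- match.arg(method)
  num <- estimates[, setdiff(names(estimates), "id"), drop = FALSE]
  complete <- stats::complete.cases(num)
  num <- num[complete, , drop = FALSE]
  list(correlations = stats::cor(num, method = method),
       summary = data.frame(estimator = names(num),
                            mean = vapply(num, mean, 0),
                            min = vapply(num, min, 0),
                            max = vapply(num, max, 0),
                            row.names = NULL, stringsAsFactors = FALSE),
       n = sum(complete))
}

#' Trend of a coefficient against metadata
#'
#' Ordinary least-squares slope of individual values on a covariate
#' (typically birth year), with per-level means.
#'
#' @param values Named numeric vector (names = individual IDs) or plain
#'   vector aligned with `covariate`.
#' @param covariate Numeric covariate, e.g. birth years.
#' @return A list with `slope`, `intercept` and `means` (per unique
#'   covariate value).
#' @export
trend_by_metadata <- function(values, covariate) {
  stopifnot(length(values) == length(covariate))
  ok <- !is.na(values) & !is.na(covariate)
  fit <- stats::lm(values[ok] ~ covariate[ok])
  means <- tapply(values[ok], covariate[ok], mean)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       means = means)
}
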