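# Shared per-individual HMM preparation: emission matrix, interval survival
# probabilities and chromosome-start flags aligned to the marker map.
# Marker-indexed matrices are laid out K x N (classes contiguous per
# marker) to match the C++ recursions.
hmm_inputs <- function(model, codes, map, freqs, genoprobs = NULL) {
  stopifnot(length(freqs) == nrow(map))
  emis <- t(emission_matrix(model, codes, freqs, genoprobs))
  chrom_start <- c(TRUE, map$chrom[-1L] != map$chrom[-nrow(map)])
  d <- c(0, diff(map$morgans))
  d[chrom_start] <- 0
  if (any(d < 0)) stop("genetic positions decrease within a chromosome")
  surv <- exp(-outer(model$rates, d))
  list(emis = emis, surv = surv, chrom_start = chrom_start, d = d)
}

#' Posterior HBD decoding by the forward-backward algorithm
#'
#' Computes, for one individual, the per-marker posterior probability of
#' each model class, the total log-likelihood, and (internally) the
#' expected-count accumulators used by EM.  Chromosomes are treated as
#' independent chains, each restarting from the mixing proportions.
#' Per-marker scaling keeps the recursion stable on hundreds of thousands
#' of markers.
#'
#' @param model An [hbd_model()].
#' @param geno A [geno_data()] object, or a plain integer code vector for a
#'   single individual.
#' @param map A [marker_map()] aligned with the genotypes.
#' @param freqs Allele-A frequencies (defaults to `geno$freqs`).
#' @param id Individual to decode when `geno` holds several.
#' @return A list of class `"hbd_decoding"`: `posteriors` (markers x K),
#'   `loglik`, `n_obs` (non-missing markers), `model`, plus the marker map
#'   reference.
#' @export
forward_backward <- function(model, geno, map, freqs = NULL, id = NULL) {
  x <- resolve_individual(geno, freqs, id)
  inp <- hmm_inputs(model, x$codes, map, x$freqs, x$genoprobs)
  fb <- fb_hmm(inp$emis, inp$surv, model$mixing, inp$chrom_start,
               TRUE, FALSE)
  structure(list(posteriors = t(fb$gamma), loglik = fb$loglik,
                 n_obs = sum(!is.na(x$codes)), model = model, map = map),
            class = "hbd_decoding")
}

#' @exportS3Method base::print
print.hbd_decoding <- function(x, ...) {
  cat(sprintf("hbd_decoding: %d markers x %d classes, log-likelihood %.2f\n",
              nrow(x$posteriors), ncol(x$posteriors), x$loglik))
  invisible(x)
}

#' Most likely class sequence (Viterbi) and HBD segments
#'
#' `viterbi()` returns the jointly most probable class path for one
#' individual; ties are broken toward the lowest class index.
#' `decode_segments()` converts a path into maximal runs of a single HBD
#' class; physical bounds are the first and last marker positions of the
#' run.
#'
#' @inheritParams forward_backward
#' @return `viterbi()`: an integer vector of class indices per marker.
#' @export
viterbi <- function(model, geno, map, freqs = NULL, id = NULL) {
  x <- resolve_individual(geno, freqs, id)
  inp <- hmm_inputs(model, x$codes, map, x$freqs, x$genoprobs)
  path <- integer(nrow(map))
  for (ch in unique(map$chrom)) {
    i <- which(map$chrom == ch)
    cs <- inp$chrom_start[i]
    cs[1L] <- TRUE
    path[i] <- viterbi_hmm(inp$emis[, i, drop = FALSE],
                           inp$surv[, i, drop = FALSE],
                           model$mixing, cs)
  }
  path
}

#' @rdname viterbi
#' @param path Integer class path as returned by `viterbi()`.
#' @return `decode_segments()`: a `data.frame` with one row per HBD
#'   segment: `chrom`, `start_bp`, `end_bp`, `start_idx`, `end_idx`,
#'   `class`, `rate`, `n_markers`, `length_bp`, `length_morgans`.
#' @export
decode_segments <- function(path, map, model) {
  stopifnot(length(path) == nrow(map))
  r <- rle(paste(map$chrom, path, sep = "\r"))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cls <- path[starts]
  keep <- cls != model$nonhbd
  starts <- starts[keep]; ends <- ends[keep]; cls <- cls[keep]
  data.frame(chrom = map$chrom[starts],
             start_bp = map$bp[starts], end_bp = map$bp[ends],
             start_idx = starts, end_idx = ends,
             class = cls, rate = model$rates[cls],
             n_markers = ends - starts + 1L,
             length_bp = map$bp[ends] - map$bp[starts] + 1,
             length_morgans = map$morgans[ends] - map$morgans[starts],
             stringsAsFactors = FALSE)
}

# Normalize the (geno, freqs, id) triple into a single individual's codes,
# genoprobs and frequencies.
resolve_individual <- function(geno, freqs, id) {
  if (inherits(geno, "geno_data")) {
    if (is.null(id)) {
      if (length(geno$ids) != 1L)
        stop("'geno' holds several individuals; supply 'id'")
      id <- geno$ids[1L]
    }
    codes <- individual_codes(geno, id)
    gp <- individual_genoprobs(geno, id)
    if (is.null(freqs)) freqs <- geno$freqs
  } else {
    codes <- geno
    gp <- NULL
  }
  if (is.null(freqs))
    stop("allele frequencies are required (attach to geno or pass 'freqs')")
  list(codes = codes, genoprobs = gp, freqs = freqs)
}
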