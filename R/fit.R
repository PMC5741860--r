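#' Fit the multiple HBD-class model by constrained EM
#'
#' Fits the mosaic model to each individual separately with
#' expectation-maximization (Baum-Welch).  Mixing proportions are updated
#' from the expected number of segment entries per class (chromosome
#' starts count as entries); free rates are re-estimated each iteration by
#' one-dimensional bounded maximization of the expected complete-data
#' log-likelihood and clamped to `rate_bounds` (default `[1, 8192]`).
#' Iteration stops after `n_iter` iterations or when the log-likelihood
#' improves by less than `tol`.
#'
#' @param model An [hbd_model()] giving the parameterization and starting
#'   values; it is refitted independently for every individual.
#' @param geno A [geno_data()] object.
#' @param map A [marker_map()] aligned with the genotype columns.
#' @param freqs Allele-A frequencies (defaults to `geno$freqs`).
#' @param ids Individuals to fit (default: all in `geno`).
#' @param n_iter Maximum EM iterations (default 1000).
#' @param tol Stop when the log-likelihood gain per iteration falls below
#'   this value; set to 0 to always run `n_iter` iterations.
#' @param warm_start Keep the rates stored in `model` as starting values
#'   instead of the default initialization (free rates at geometrically
#'   spaced interior points of the bounds).
#' @param verbose Print per-individual progress.
#' @return An object of class `"hbd_fit"` with one fitted parameter set
#'   per individual, per-individual log-likelihood, BIC and genome-wide
#'   class fractions.  Supports `print`, `summary`, `coef`, `logLik`,
#'   `predict` and `plot`.
#' @seealso [predict.hbd_fit()], [bic_select()], [simulate.hbd_model()]
#' @export
hbd_fit <- function(model, geno, map, freqs = NULL, ids = NULL,
                    n_iter = 1000L, tol = 1e-3, warm_start = FALSE,
                    verbose = FALSE) {
  stopifnot(inherits(model, "hbd_model"), inherits(geno, "geno_data"))
  validate_marker_map(map)
  if (is.null(freqs)) freqs <- geno$freqs
  if (is.null(freqs)) stop("allele frequencies are required")
  stopifnot(length(freqs) == nrow(map), ncol(geno$codes) == nrow(map))
  if (is.null(ids)) ids <- geno$ids
  if (!n_free_parameters(model))
    stop("the model has no free parameter to fit")

  if (!warm_start) model <- init_free_rates(model)
  fits <- lapply(ids, function(id) {
    f <- em_one(model, individual_codes(geno, id), map, freqs,
                individual_genoprobs(geno, id), n_iter, tol)
    if (verbose)
      message(sprintf("%s: logLik %.2f after %d iterations", id,
                      f$loglik, f$n_iter))
    f
  })
  names(fits) <- ids
  structure(list(model = model, fits = fits, ids = ids,
                 geno = geno, map = map, freqs = freqs,
                 fingerprint = geno_fingerprint(geno, ids),
                 call = match.call()),
            class = "hbd_fit")
}

# Free rates start at geometrically spaced interior points of the bounds so
# that same-emission HBD classes are not initialized symmetrically (EM
# cannot break an exact permutation symmetry).
init_free_rates <- function(model) {
  free <- which(model$free_rates)
  if (!length(free)) return(model)
  lb <- log(model$rate_bounds[1]); ub <- log(model$rate_bounds[2])
  if (model$shared_rate) {
    model$rates[] <- exp((lb + ub) / 2)
  } else {
    q <- seq_along(free) / (length(free) + 1)
    model$rates[free] <- exp(lb + q * (ub - lb))
  }
  model
}

em_one <- function(model, codes, map, freqs, genoprobs, n_iter, tol) {
  inp <- hmm_inputs(model, codes, map, freqs, genoprobs)
  d <- inp$d
  want_rates <- any(model$free_rates)
  # aggregate E-step weights over intervals sharing the same distance
  if (want_rates) {
    informative <- !inp$chrom_start & d > 0
    dgrp <- signif(d[informative], 12)
  }
  surv <- inp$surv
  trace <- numeric(0)
  mixing <- model$mixing
  rates <- model$rates
  prev <- -Inf
  iter <- 0L
  repeat {
    iter <- iter + 1L
    fb <- fb_hmm(inp$emis, surv, mixing, inp$chrom_start, FALSE,
                 want_rates)
    trace[iter] <- fb$loglik
    done <- iter >= n_iter || (tol > 0 && fb$loglik - prev < tol)
    prev <- fb$loglik
    if (done) break
    if (model$free_mixing) {
      w <- fb$entry_sum + fb$start_gamma_sum
      mixing <- w / sum(w)
    }
    if (want_rates) {
      A <- rowsum(t(fb$survive_w[, informative, drop = FALSE]), dgrp)
      B <- rowsum(t(fb$term_w[, informative, drop = FALSE]), dgrp)
      du <- as.numeric(rownames(A))
      rates <- mstep_rates(model, rates, A, B, du)
      surv <- exp(-outer(rates, d))
      surv[, inp$chrom_start] <- 1
    }
  }
  # final posteriors consistent with the returned parameters
  fb <- fb_hmm(inp$emis, surv, mixing, inp$chrom_start, TRUE, FALSE)
  n_obs <- if (is.null(genoprobs)) sum(!is.na(codes)) else length(codes)
  p <- n_free_parameters(model)
  list(mixing = mixing, rates = rates, loglik = fb$loglik,
       trace = trace, n_iter = iter, n_obs = n_obs,
       bic = -2 * fb$loglik + p * log(n_obs),
       fractions = rowMeans(fb$gamma))
}

# Expected complete-data log-likelihood in the rate of class k:
#   sum_d [ A(d, k) * (-R d) + B(d, k) * log(1 - exp(-R d)) ]
# A = expected survivals, B = expected terminations, aggregated by unique
# inter-marker distance d.  Maximized by stats::optimize on the bounds.
mstep_rates <- function(model, rates, A, B, du) {
  obj <- function(R, a, b)
    sum(-R * du * a + ifelse(b > 0, b * log(-expm1(-R * du)), 0))
  lo <- model$rate_bounds[1]; hi <- model$rate_bounds[2]
  # the optimizer's finite tolerance may propose a point fractionally
  # worse than the current rate; keep the old rate in that case so the
  # EM objective never decreases
  pick <- function(r_new, r_old, a, b) {
    r_new <- min(max(r_new, lo), hi)
    if (obj(r_new, a, b) >= obj(r_old, a, b)) r_new else r_old
  }
  if (model$shared_rate) {
    a <- rowSums(A); b <- rowSums(B)
    r <- stats::optimize(obj, c(lo, hi), a = a, b = b,
                         maximum = TRUE, tol = 1e-4)$maximum
    rates[] <- pick(r, rates[1], a, b)
  } else {
    for (k in which(model$free_rates)) {
      r <- stats::optimize(obj, c(lo, hi), a = A[, k], b = B[, k],
                           maximum = TRUE, tol = 1e-4)$maximum
      rates[k] <- pick(r, rates[k], A[, k], B[, k])
    }
  }
  rates
}

geno_fingerprint <- function(geno, ids) {
  codes <- geno$codes[match(ids, geno$ids), , drop = FALSE]
  c(n = length(codes), na = sum(is.na(codes)),
    s = sum(codes, na.rm = TRUE),
    s2 = sum(as.numeric(codes)^2, na.rm = TRUE))
}

#' @exportS3Method base::print
print.hbd_fit <- function(x, ...) {
  fg <- vapply(x$fits, function(f) sum(f$fractions[-x$model$nonhbd]), 0)
  cat(sprintf(
    "%s model fitted to %d individual(s); mean F_G = %.4f (range %.4f-%.4f)\n",
    x$model$kind, length(x$fits), mean(fg), min(fg), max(fg)))
  invisible(x)
}

#' @export
summary.hbd_fit <- function(object, ...) {
  fr <- t(vapply(object$fits, `[[`, numeric(object$model$K), "fractions"))
  out <- list(
    kind = object$model$kind,
    rates = t(vapply(object$fits, `[[`, numeric(object$model$K), "rates")),
    fractions = fr,
    table = data.frame(
      id = object$ids,
      F_G = rowSums(fr[, -object$model$nonhbd, drop = FALSE]),
      logLik = vapply(object$fits, `[[`, 0, "loglik"),
      BIC = vapply(object$fits, `[[`, 0, "bic"),
      n_iter = vapply(object$fits, `[[`, 0L, "n_iter"),
      row.names = NULL))
  class(out) <- "summary.hbd_fit"
  out
}

#' @exportS3Method base::print
print.summary.hbd_fit <- function(x, ...) {
  cat(sprintf("%s model, %d individuals\n", x$kind, nrow(x$table)))
  print(x$table, row.names = FALSE, digits = 5)
  invisible(x)
}

#' @export
coef.hbd_fit <- function(object, what = c("mixing", "rates"), ...) {
  what <- match.arg(what)
  t(vapply(object$fits, `[[`, numeric(object$model$K), what))
}

#' @export
logLik.hbd_fit <- function(object, ...) {
  ll <- sum(vapply(object$fits, `[[`, 0, "loglik"))
  structure(ll, df = n_free_parameters(object$model) * length(object$fits),
            nobs = sum(vapply(object$fits, `[[`, 0, "n_obs")),
            class = "logLik")
}

#' Quantities derived from a fitted HBD model
#'
#' @param object An [hbd_fit()].
#' @param type `"fractions"`: genome-wide probability per class (markers
#'   averaged, unweighted);
#'   `"inbreeding"`: the inbreeding coefficient F_G-T, i.e. the summed
#'   fractions of HBD classes with rate `R_k <= T` (default `T` includes
#'   all HBD classes, giving total F_G);
#'   `"posterior"`: per-marker posterior class probabilities (a list by
#'   individual);
#'   `"segments"`: HBD segments from the Viterbi path, all individuals
#'   bound into one `data.frame`.
#' @param T Rate threshold defining the base population for
#'   `type = "inbreeding"`.
#' @param ids Individuals (default: all fitted).
#' @param ... Unused.
#' @return See `type`.
#' @export
predict.hbd_fit <- function(object, type = c("fractions", "inbreeding",
                                             "posterior", "segments"),
                            T = NULL, ids = object$ids, ...) {
  type <- match.arg(type)
  if (type == "fractions")
    return(t(vapply(object$fits[ids], `[[`,
                    numeric(object$model$K), "fractions")))
  if (type == "inbreeding") {
    fr <- predict(object, "fractions", ids = ids)
    return(vapply(ids, function(id)
      f_g_threshold(fr[id, ], per_individual_model(object, id), T), 0))
  }
  if (type == "posterior") {
    out <- lapply(ids, function(id)
      forward_backward(per_individual_model(object, id), object$geno,
                       object$map, object$freqs, id = id)$posteriors)
    names(out) <- ids
    return(out)
  }
  segs <- lapply(ids, function(id) {
    m <- per_individual_model(object, id)
    s <- decode_segments(viterbi(m, object$geno, object$map, object$freqs,
                                 id = id), object$map, m)
    if (nrow(s)) cbind(id = id, s, stringsAsFactors = FALSE) else NULL
  })
  do.call(rbind, segs)
}

per_individual_model <- function(fit, id) {
  m <- fit$model
  m$mixing <- fit$fits[[id]]$mixing
  m$rates <- fit$fits[[id]]$rates
  m
}

#' @exportS3Method graphics::plot
plot.hbd_fit <- function(x, type = c("fractions", "curve"), ...) {
  type <- match.arg(type)
  fr <- predict(x, "fractions")
  hbd <- seq_len(x$model$K - 1L)
  if (type == "fractions") {
    graphics::boxplot(fr[, hbd, drop = FALSE] * 100,
                      names = signif(x$model$rates[hbd], 3),
                      xlab = "HBD class rate R_k",
                      ylab = "% of genome in class", ...)
  } else {
    Ts <- sort(unique(x$model$rates[hbd]))
    fgt <- sapply(Ts, function(T)
      predict(x, "inbreeding", T = T))
    graphics::matplot(Ts, t(rbind(fgt)), type = "b", log = "x", pch = 1,
                      xlab = "threshold T (R_k <= T)",
                      ylab = "F_G-T", ...)
  }
  invisible(x)
}

#' Simulate mosaic genotypes from a model
#'
#' Draws `nsim` individuals whose genomes are tiled by the model's renewal
#' process and emits genotypes under the given allele frequencies (see
#' [simulate_mosaic()]).
#'
#' @param object An [hbd_model()] used as the generative truth.
#' @param nsim Number of individuals.
#' @param seed Integer seed.
#' @param map A [marker_map()].
#' @param freqs Allele-A frequencies.
#' @param ... Unused.
#' @return A list with `geno` ([geno_data()]) and `truth` (see
#'   [simulate_mosaic()]).
#' @export
simulate.hbd_model <- function(object, nsim = 1, seed = NULL,
                               map, freqs, ...) {
  simulate_mosaic(object, map, freqs, n_individuals = nsim, seed = seed)
}

#' Select the best model per individual by BIC
#'
#' `BIC = -2 logLik + p log(n_obs)` with `p` the number of free parameters
#' (free rates plus `K - 1` free mixing proportions) and `n_obs` the
#' individual's non-missing marker count.  The smallest BIC wins; ties go
#' to the model with fewer parameters.
#'
#' @param fits A list of [hbd_fit()] objects fitted to the same data.
#' @return A list with `best` (index into `fits` per individual), `bic`
#'   (individuals x models matrix) and `tally` (how often each model won).
#' @export
bic_select <- function(fits) {
  stopifnot(length(fits) >= 2L)
  fp <- lapply(fits, `[[`, "fingerprint")
  if (!all(vapply(fp, identical, TRUE, fp[[1L]])))
    stop("candidate models were not fitted on identical data")
  ids <- fits[[1L]]$ids
  bic <- vapply(fits, function(f)
    vapply(f$fits[ids], `[[`, 0, "bic"), numeric(length(ids)))
  bic <- matrix(bic, nrow = length(ids),
                dimnames = list(ids, NULL))
  p <- vapply(fits, function(f) n_free_parameters(f$model), 0L)
  best <- apply(bic, 1L, function(b) {
    cand <- which(b == min(b))
    cand[which.min(p[cand])]
  })
  list(best = best, bic = bic,
       tally = tabulate(best, nbins = length(fits)))
}

# F_G-T: summed genome fractions of HBD classes with rate <= T
f_g_threshold <- function(fractions, model, T = NULL) {
  hbd <- seq_len(model$K - 1L)
  if (is.null(T)) T <- max(model$rates[hbd])
  if (T <= 0) stop("'T' must be positive")
  sum(fractions[hbd][model$rates[hbd] <= T])
}
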