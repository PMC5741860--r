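#' Multiple HBD-class mixture hidden Markov models
#'
#' Construct the parameterization of the mosaic model: a genome is a
#' succession of segments, each belonging to one of `K` classes (`K - 1`
#' homozygous-by-descent classes plus one non-HBD class).  Segment lengths
#' in Morgans are exponential with class-specific rate `R_k`; new segments
#' pick their class with probability equal to the class mixing proportion
#' `m_k`.  The rate is approximately twice the number of generations to the
#' common ancestor, so small rates describe recent, long HBD segments and
#' large rates ancient, short ones.
#'
#' Three parameterizations are supported:
#' * `"1R"`: one HBD and one non-HBD class sharing a single free rate;
#'   mixing free.
#' * `"KR"`: `K` classes, each with its own free rate; mixing free.
#' * `"MixKR"`: fixed dyadic rates `2^1, ..., 2^(K-1)` for the HBD classes,
#'   with the non-HBD class sharing the largest HBD rate (default `K = 14`:
#'   HBD rates `2, 4, ..., 8192`, non-HBD rate `8192`); only the mixing
#'   proportions are free.
#'
#' The last class (index `K`) is always the non-HBD class.
#'
#' @param kind One of `"1R"`, `"KR"`, `"MixKR"`.
#' @param K Total number of classes (HBD classes plus one non-HBD class).
#'   Ignored for `"1R"` (always 2).  For `"MixKR"` the default is 14.
#' @param epsilon Probability of observing a heterozygous genotype inside
#'   an HBD segment (genotyping-error term), in `[0, 1)`.
#' @param rates Optional explicit rate vector (length `K`), overriding the
#'   defaults; required for `"MixKR"` with `K > 14`.
#' @param mixing Optional initial mixing proportions (length `K`, summing
#'   to 1).  Defaults to uniform.
#' @param rate_bounds Lower/upper bounds enforced on free rates during
#'   fitting.
#' @return An object of class `"hbd_model"`: a list with elements `kind`,
#'   `K`, `rates`, `mixing`, `epsilon`, `free_rates` (logical per class),
#'   `shared_rate` (TRUE for 1R), `free_mixing`, `rate_bounds` and
#'   `nonhbd` (index of the non-HBD class, always `K`).
#' @examples
#' hbd_model("MixKR")            # the 13 HBD-class model
#' hbd_model("1R", epsilon = 0.002)
#' hbd_model("KR", K = 3)
#' @export
hbd_model <- function(kind = c("MixKR", "KR", "1R"), K = NULL,
                      epsilon = 0.002, rates = NULL, mixing = NULL,
                      rate_bounds = c(1, 8192)) {
  kind <- match.arg(kind)
  if (!is.numeric(epsilon) || length(epsilon) != 1L ||
      epsilon < 0 || epsilon >= 1)
    stop("'epsilon' must be a single value in [0, 1)")
  if (kind == "1R") {
    if (!is.null(K) && K != 2L) stop("the 1R model always has K = 2")
    K <- 2L
  } else if (is.null(K)) {
    K <- if (kind == "MixKR") 14L else stop("'K' required for a KR model")
  }
  K <- as.integer(K)
  if (K < 2L) stop("at least one HBD and one non-HBD class are required")

  if (is.null(rates)) {
    rates <- switch(kind,
      "1R" = rep(exp(mean(log(rate_bounds))), 2L),
      "KR" = rep(exp(mean(log(rate_bounds))), K),
      "MixKR" = {
        if (K > 14L)
          stop("the default dyadic grid covers K <= 14; ",
               "supply 'rates' explicitly for larger K")
        c(2^seq_len(K - 1L), 2^(K - 1L))
      })
  } else {
    if (length(rates) != K) stop("'rates' must have length K")
    if (any(rates <= 0)) stop("rates must be positive")
  }
  if (is.null(mixing)) mixing <- rep(1 / K, K)
  if (length(mixing) != K || any(mixing < 0) ||
      abs(sum(mixing) - 1) > 1e-8)
    stop("'mixing' must be length K, non-negative and sum to 1")

  free_rates <- switch(kind,
    "1R" = rep(TRUE, 2L),
    "KR" = rep(TRUE, K),
    "MixKR" = rep(FALSE, K))

  structure(list(kind = kind, K = K, rates = as.numeric(rates),
                 mixing = as.numeric(mixing), epsilon = epsilon,
                 free_rates = free_rates,
                 shared_rate = identical(kind, "1R"),
                 free_mixing = TRUE,
                 rate_bounds = as.numeric(rate_bounds),
                 nonhbd = K),
            class = "hbd_model")
}

#' @exportS3Method base::print
print.hbd_model <- function(x, ...) {
  cat(sprintf("%s model: %d HBD class%s + 1 non-HBD class, epsilon = %g\n",
              x$kind, x$K - 1L, if (x$K > 2L) "es" else "", x$epsilon))
  tab <- data.frame(class = seq_len(x$K),
                    type = c(rep("HBD", x$K - 1L), "non-HBD"),
                    rate = signif(x$rates, 5),
                    mixing = signif(x$mixing, 4),
                    free_rate = x$free_rates)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Number of free parameters of a model
#'
#' Free rates (one for a 1R model, which shares its rate between both
#' classes) plus `K - 1` free mixing proportions.  Used as the BIC penalty.
#'
#' @param model An [hbd_model()].
#' @return Integer parameter count.
#' @export
n_free_parameters <- function(model) {
  p_rates <- if (model$shared_rate) 1L else sum(model$free_rates)
  p_mix <- if (model$free_mixing) model$K - 1L else 0L
  p_rates + p_mix
}

#' Emission probabilities of the HBD model
#'
#' Inside an HBD segment a marker is homozygous for allele A with
#' probability `f_A (1 - epsilon)`, homozygous for the alternative allele
#' with probability `(1 - f_A)(1 - epsilon)`, and heterozygous with
#' probability `epsilon` (the genotyping-error term).  In a non-HBD
#' segment genotypes follow Hardy-Weinberg proportions.  Missing genotypes
#' emit probability 1 in every state; genotype probability triples
#' (e.g. from sequencing likelihoods) are integrated over:
#' `P(obs | state) = sum_g P(g | state) P(g | data)`.
#'
#' @param state `"HBD"` or `"nonHBD"`.
#' @param genotype Either an integer code in `{0, 1, 2}` (copies of allele
#'   A; `NA` = missing) or a numeric triple of genotype probabilities
#'   `(hom-A, het, hom-B)`.
#' @param f_A Frequency of allele A.
#' @param epsilon Heterozygote-in-HBD error probability.
#' @return A single emission probability.
#' @examples
#' emission_probability("HBD", 2, f_A = 0.3, epsilon = 0.01)    # 0.297
#' emission_probability("nonHBD", 1, f_A = 0.5, epsilon = 0.01) # 0.5
#' @export
emission_probability <- function(state = c("HBD", "nonHBD"), genotype,
                                 f_A, epsilon = 0.002) {
  state <- match.arg(state)
  stopifnot(f_A >= 0, f_A <= 1, epsilon >= 0, epsilon < 1)
  # P(g | state) for g = (hom-A, het, hom-B)
  pg <- if (state == "HBD")
    c(f_A * (1 - epsilon), epsilon, (1 - f_A) * (1 - epsilon))
  else
    c(f_A^2, 2 * f_A * (1 - f_A), (1 - f_A)^2)
  if (length(genotype) == 3L) return(sum(pg * genotype))
  if (is.na(genotype)) return(1)
  switch(as.character(genotype),
         "2" = pg[1], "1" = pg[2], "0" = pg[3],
         stop("genotype code must be 0, 1, 2, NA or a probability triple"))
}

# Emission matrix (markers x K) for one individual.  codes: integer vector
# (copies of allele A, NA missing); genoprobs: optional markers x 3 matrix
# (hom-A, het, hom-B) taking precedence over codes where complete.
emission_matrix <- function(model, codes, freqs, genoprobs = NULL) {
  K <- model$K
  eps <- model$epsilon
  n <- length(freqs)
  # P(g | class) per marker: HBD classes share emissions; non-HBD differs
  hbd <- cbind(freqs * (1 - eps), eps, (1 - freqs) * (1 - eps))
  nhb <- cbind(freqs^2, 2 * freqs * (1 - freqs), (1 - freqs)^2)
  if (!is.null(genoprobs)) {
    stopifnot(nrow(genoprobs) == n, ncol(genoprobs) == 3L)
    e_hbd <- rowSums(hbd * genoprobs)
    e_nhb <- rowSums(nhb * genoprobs)
  } else {
    stopifnot(length(codes) == n)
    idx <- 3L - codes  # code 2 -> col 1 (hom-A), 1 -> 2, 0 -> 3
    e_hbd <- hbd[cbind(seq_len(n), idx)]
    e_nhb <- nhb[cbind(seq_len(n), idx)]
    e_hbd[is.na(codes)] <- 1
    e_nhb[is.na(codes)] <- 1
  }
  emis <- matrix(e_hbd, nrow = n, ncol = K)
  emis[, K] <- e_nhb
  emis
}

#' Transition matrix over a genetic distance
#'
#' Over an inter-marker distance `d` Morgans the current class-`k` segment
#' survives with probability `exp(-R_k d)`; if it terminates, the next
#' segment's class is drawn from the mixing proportions (self re-entry
#' allowed):
#' `a(k, l) = exp(-R_k d) [k = l] + (1 - exp(-R_k d)) m_l`.
#'
#' @param model An [hbd_model()].
#' @param d Genetic distance in Morgans (`>= 0`).
#' @return A `K x K` row-stochastic matrix.
#' @examples
#' m <- hbd_model("1R")
#' m$rates <- c(2, 2); m$mixing <- c(0.5, 0.5)
#' transition_matrix(m, 0.5)
#' @export
transition_matrix <- function(model, d) {
  if (!is.numeric(d) || length(d) != 1L || d < 0)
    stop("'d' must be a single non-negative distance in Morgans")
  s <- exp(-model$rates * d)
  diag(s, model$K) + (1 - s) %o% model$mixing
}
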