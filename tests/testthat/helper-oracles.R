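# Independent oracles used across test files.  These deliberately avoid
# the package's own recursions: the HMM oracle enumerates every state
# sequence, the pedigree oracle counts inbreeding paths.

# Exhaustive HMM decoding for tiny instances: emis is N x K, trans_list a
# list of K x K matrices (trans_list[[t]] bridges markers t-1 and t).
enumerate_hmm <- function(emis, trans_list, init) {
  N <- nrow(emis); K <- ncol(emis)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), N)))
  pr <- apply(paths, 1L, function(s) {
    p <- init[s[1L]] * emis[1L, s[1L]]
    if (N > 1L)
      for (t in 2:N) p <- p * trans_list[[t]][s[t - 1L], s[t]] * emis[t, s[t]]
    p
  })
  post <- matrix(0, N, K)
  for (t in seq_len(N))
    for (k in seq_len(K)) post[t, k] <- sum(pr[paths[, t] == k])
  list(posteriors = post / sum(pr), loglik = log(sum(pr)),
       viterbi = paths[which.max(pr), ])
}

# Random small HMM instance on one chromosome, returning everything both
# the package and the oracle need.
random_hmm_instance <- function(K = sample(2:3, 1L), N = sample(2:8, 1L),
                                with_missing = TRUE) {
  model <- hbd_model("KR", K = K, epsilon = stats::runif(1, 0.001, 0.05))
  model$rates <- sort(stats::runif(K, 1, 200))
  m <- stats::runif(K) + 0.05
  model$mixing <- m / sum(m)
  map <- marker_map(chrom = rep("1", N),
                    bp = cumsum(sample(1e4:1e6, N, replace = TRUE)),
                    morgans = cumsum(stats::runif(N, 0.001, 0.05)))
  freqs <- stats::runif(N, 0.05, 0.95)
  pool <- if (with_missing) c(0L, 1L, 2L, NA) else c(0L, 1L, 2L)
  codes <- sample(pool, N, replace = TRUE)
  if (all(is.na(codes))) codes[1L] <- 1L
  emis <- sapply(seq_len(K), function(k) sapply(seq_len(N), function(t)
    emission_probability(if (k < K) "HBD" else "nonHBD", codes[t],
                         freqs[t], model$epsilon)))
  emis <- matrix(emis, nrow = N)
  d <- c(0, diff(map$morgans))
  trans_list <- c(list(NULL),
                  lapply(seq_len(N)[-1L],
                         function(t) transition_matrix(model, d[t])))
  list(model = model, map = map, freqs = freqs, codes = codes,
       emis = emis, trans_list = trans_list)
}

# Wright's path-counting inbreeding coefficient (memoized recursion on
# ancestors' own F).  Exact for any small pedigree.
path_counting_f <- function(pedigree) {
  ped <- as.data.frame(pedigree, stringsAsFactors = FALSE)
  for (col in c("id", "sire", "dam")) {
    ped[[col]] <- as.character(ped[[col]])
    ped[[col]][ped[[col]] %in% c("0", "", "NA")] <- NA
  }
  parents <- function(x) {
    r <- ped[ped$id == x, ]
    c(r$sire, r$dam)[!is.na(c(r$sire, r$dam))]
  }
  # all ancestor paths starting at x (each a vector of ids, x first)
  paths_up <- function(x) {
    out <- list(x)
    for (p in parents(x))
      out <- c(out, lapply(paths_up(p), function(pp) c(x, pp)))
    out
  }
  memo <- new.env()
  f_of <- function(x) {
    if (!is.null(memo[[x]])) return(memo[[x]])
    r <- ped[ped$id == x, ]
    val <- if (is.na(r$sire) || is.na(r$dam)) 0 else
      kinship_paths(r$sire, r$dam)
    memo[[x]] <- val
    val
  }
  kinship_paths <- function(s, d) {
    total <- 0
    for (p1 in paths_up(s)) for (p2 in paths_up(d)) {
      a <- p1[length(p1)]
      if (a != p2[length(p2)]) next
      # the common ancestor must be the only shared individual
      if (length(intersect(p1[-length(p1)], p2[-length(p2)]))) next
      n1 <- length(p1) - 1L; n2 <- length(p2) - 1L
      total <- total + 0.5^(n1 + n2 + 1) * (1 + f_of(a))
    }
    total
  }
  out <- vapply(ped$id, f_of, 0)
  names(out) <- ped$id
  out
}

# Small even map plus uniform frequencies, shared by several files.
toy_panel <- function(n_chrom = 2, len = 1, spacing = 0.01, seed = 1,
                      maf_floor = 0.05) {
  map <- simulate_map(n_chrom, len, spacing)
  freqs <- simulate_frequencies(nrow(map), 1, 1, maf_floor = maf_floor,
                                seed = seed)
  list(map = map, freqs = freqs)
}
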