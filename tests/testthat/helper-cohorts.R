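# Simulated study cohorts shared by the heavier decoding tests.  Built
# lazily and cached for the session: both the single-class recovery cohort
# and the two-age-class cohort are used by several test blocks.

.cohort_cache <- new.env(parent = emptyenv())

cohort_cached <- function(name, builder) {
  if (is.null(.cohort_cache[[name]])) .cohort_cache[[name]] <- builder()
  .cohort_cache[[name]]
}

# 20 individuals x 10 Morgans at HD-like density; one HBD class with
# rate 20 and stationary HBD fraction 0.25 (shared-rate truth), eps 0.002.
recovery_cohort <- function() {
  cohort_cached("recovery", function() {
    truth <- hbd_model("1R", epsilon = 0.002)
    truth$rates <- c(20, 20)
    truth$mixing <- c(0.25, 0.75)
    map <- simulate_map(10, 1, panel_spacing("HD"))
    freqs <- simulate_frequencies(nrow(map), 1, 1, maf_floor = 0.01,
                                  seed = 1201)
    sim <- simulate_mosaic(truth, map, freqs, 20, seed = 1202)
    list(truth = truth, map = map, freqs = freqs, sim = sim)
  })
}

# 20 individuals x 10 Morgans at HD-like density; two HBD classes with
# rates 10 (recent) and 1000 (ancient), non-HBD sharing rate 1000, mixing
# chosen for stationary fractions (0.10, 0.15, 0.75).
two_class_cohort <- function() {
  cohort_cached("two_class", function() {
    truth <- hbd_model("KR", K = 3, epsilon = 0.002)
    truth$rates <- c(10, 1000, 1000)
    p <- c(0.10, 0.15, 0.75)
    m <- p * truth$rates
    truth$mixing <- m / sum(m)
    map <- simulate_map(10, 1, panel_spacing("HD"))
    freqs <- simulate_frequencies(nrow(map), 1, 1, maf_floor = 0.01,
                                  seed = 1301)
    sim <- simulate_mosaic(truth, map, freqs, 20, seed = 1302)
    list(truth = truth, map = map, freqs = freqs, sim = sim)
  })
}

cohort_fit <- function(name, builder) cohort_cached(name, builder)
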