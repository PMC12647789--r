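# shared fixtures and oracles, built in code at test time

TRUTH <- neuron_params(100, 0.5, -4, 150)

# central finite-difference oracle for the first derivative
fd_slope <- function(params, x) {
  h <- 1e-6 * pmax(1, abs(x))
  (predict(params, x + h) - predict(params, x - h)) / (2 * h)
}

# random canonical parameter sets on scales spanning the fixture regimes
random_canonical <- function(n, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    neuron_params(A = runif(1, 0.1, 300), c = runif(1, 0.05, 3),
                  b = runif(1, -15, 2), B = runif(1, -20, 300)))
}

# raw (possibly non-canonical) parameter sets with sign(A) == sign(c)
random_raw <- function(n, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    s <- sample(c(-1, 1), 1)
    neuron_params(A = s * runif(1, 0.1, 300), c = s * runif(1, 0.05, 3),
                  b = runif(1, -10, 10), B = runif(1, -20, 300))
  })
}

tiny_csv <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}

# a small, fast ensemble reused across io/plot tests (computed once)
.cache <- new.env(parent = emptyenv())

small_ensemble <- function() {
  if (is.null(.cache$small_ens)) {
    d <- simulate_nr(sim_design(TRUTH, n_levels = 6L, replicates = 2L,
                                noise = 0.05, seed = 11))
    pool <- augment(d, augment_config(replicates = 5L, seed = 12))
    .cache$small_ens <- list(
      data = d, pool = pool,
      ens = nr_bootstrap(pool, d, train_config(restarts = 3L),
                         boot_config(n_iterations = 20L, seed = 13)))
  }
  .cache$small_ens
}

# the coverage experiment of the bootstrap protocol: 50 seeded worlds
# (8 levels x 3 replicates, 5% proportional noise), full default
# pipeline; cached so the acceptance and synthetic-data suites share one
# computation
coverage_experiment <- function() {
  if (is.null(.cache$coverage)) {
    hits <- t(vapply(1:50, function(s) {
      d <- simulate_nr(sim_design(TRUTH, seed = 1000 + s))
      pool <- augment(d, augment_config(seed = 2000 + s))
      ens <- nr_bootstrap(pool, d, train_config(),
                          boot_config(seed = 3000 + s))
      sm <- summary(ens)
      in_ci <- function(q, value) {
        row <- sm[sm$quantity == q, ]
        row$lower <= value && value <= row$upper
      }
      c(A = in_ci("A", TRUTH$A), B = in_ci("B", TRUTH$B))
    }, logical(2)))
    .cache$coverage <- hits
  }
  .cache$coverage
}
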