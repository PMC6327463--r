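# Independent oracles kept deliberately naive.

# exact binomial quantities by brute-force enumeration of all 2^n weighted
# agree/disagree sequences (n <= 12 or so)
enum_binomial <- function(k, n, p, mode) {
  if (n == 0) return(1)
  outcomes <- as.matrix(expand.grid(rep(list(0:1), n)))
  succ <- rowSums(outcomes)
  prob <- p^succ * (1 - p)^(n - succ)
  switch(mode,
         all_success = sum(prob[succ == n]),
         point_mass = sum(prob[succ == k]),
         upper_tail = sum(prob[succ >= k]))
}

# dense N x N update: raw_j = sum_i W[i,j] x_i, then activation and clamps
dense_step_oracle <- function(state, map, protocol) {
  n <- n_nodes(map)
  W <- matrix(0, n, n)
  e <- map$edges
  W[cbind(e$from, e$to)] <- e$weight
  raw <- vapply(seq_len(n), function(j) sum(W[, j] * state), numeric(1))
  new <- stats::setNames(raw / (1 + abs(raw)), map$labels)
  new[protocol$locked_on] <- 1
  new[protocol$locked_off] <- -1
  new
}

# scalar brute-force iteration of x <- f(drive + w * x)
scalar_fixed_point_oracle <- function(w, drive, x0, iterations) {
  x <- x0
  for (i in seq_len(iterations)) {
    raw <- drive + w * x
    x <- raw / (1 + abs(raw))
  }
  x
}

# random test map with assorted shapes; deterministic per seed
random_test_map <- function(seed, n = NULL) {
  set.seed(seed)
  if (is.null(n)) n <- sample(1:30, 1)
  generate_random_map(
    n_nodes = n,
    mean_degree = min(n, stats::runif(1, 0.5, 5)),
    positive_fraction = stats::runif(1),
    indeterminate_fraction = sample(c(0, 0.2), 1),
    weight_range = sort(stats::runif(2, 0.05, 1)),
    seed = seed + 1000L
  )
}
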