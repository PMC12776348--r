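# shared fixtures and independent oracles; fixtures are generated in code,
# never stored

random_theta <- function(n, seed, sd = 0.5) {
  set.seed(seed)
  matrix(stats::rnorm((n + 1L) * n, sd = sd), n + 1L, n)
}

random_model <- function(n, seed, sd = 0.5, kind = "observation_aware") {
  mhn_model(random_theta(n, seed, sd), kind = kind)
}

# independent full-state-space oracle: rates computed directly from the
# parameter matrix, absorption probabilities from a dense base::solve of
# (diag(R) - transitions) q = e_0 -- a generic solver, not the engine's
# triangular substitution
dense_oracle <- function(model) {
  th <- model$log_theta
  n <- model$n
  ns <- 2^n
  # row s of `states` is the genotype with bit pattern s-1 (bit j-1 <-> event j)
  states <- matrix(0L, ns, n)
  for (s in seq_len(ns))
    states[s, ] <- as.integer(bitwAnd(s - 1L, 2^(seq_len(n) - 1L)) > 0)
  lam <- function(y, i) exp(th[i, i] + sum(th[i, setdiff(which(y == 1L), i)]))
  om <- function(y) if (model$kind == "classic") 1 else
    exp(sum(th[n + 1L, which(y == 1L)]))
  A <- matrix(0, ns, ns)
  omv <- numeric(ns)
  for (s in seq_len(ns)) {
    y <- states[s, ]
    omv[s] <- om(y)
    inact <- which(y == 0L)
    A[s, s] <- omv[s] + sum(vapply(inact, function(i) lam(y, i), 0))
    for (i in inact) {
      tgt <- s + 2^(i - 1L)
      A[tgt, s] <- A[tgt, s] - lam(y, i)
    }
  }
  q <- solve(A, c(1, rep(0, ns - 1L)))
  omv * q
}

# all permutations of a vector
perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  do.call(c, lapply(seq_along(v), function(i)
    lapply(perms(v[-i]), function(p) c(v[i], p))))
}

# brute-force most likely ordering: enumerate all k! orderings, pick the
# maximum probability, ties to the lexicographically smallest ordering
brute_best_order <- function(model, genotype) {
  act <- which(genotype == 1L)
  if (length(act) == 0L)
    return(list(indices = integer(0),
                probability = order_probability(model, integer(0))))
  os <- perms(act) # generated in lexicographic order by construction
  ps <- vapply(os, function(o) order_probability(model, o), 0)
  best <- which.max(ps) # first max = lexicographically smallest
  list(indices = os[[best]], probability = ps[best])
}

# central finite differences of the dataset log-likelihood
fd_gradient <- function(model, data, h = 1e-5) {
  th <- model$log_theta
  n <- model$n
  fd <- matrix(0, n + 1L, n)
  rows <- if (model$kind == "classic") seq_len(n) else seq_len(n + 1L)
  for (a in rows) for (b in seq_len(n)) {
    tp <- th; tp[a, b] <- tp[a, b] + h
    tm <- th; tm[a, b] <- tm[a, b] - h
    fd[a, b] <- (log_likelihood(mhn_model(tp, model$events, model$kind), data) -
                 log_likelihood(mhn_model(tm, model$events, model$kind), data)) /
      (2 * h)
  }
  fd
}

# genotype with bit pattern `code` (bit j-1 <-> event j)
genotype_from_code <- function(code, n) {
  as.integer(bitwAnd(code, 2^(seq_len(n) - 1L)) > 0)
}

# planted sparse ground-truth model for recovery experiments: 5 events,
# moderate base rates, three interactions of unit log-strength and one
# observation effect
planted_model <- function() {
  th <- matrix(0, 6, 5)
  diag(th[1:5, ]) <- c(-1, -1.5, -1, -0.5, -1.5)
  th[2, 1] <- 1    # event 1 promotes event 2
  th[3, 2] <- -1   # event 2 suppresses event 3
  th[1, 4] <- 1    # event 4 promotes event 1
  th[6, 5] <- 1    # event 5 raises the observation rate
  mhn_model(th, events = paste0("E", 1:5))
}
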