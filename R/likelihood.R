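# State-space-restricted likelihood engine.
#
# Irreversibility makes the generator of the chain triangular once states
# are ordered by their integer bit encoding (acquiring an event strictly
# increases the code), so marginal genotype probabilities and their adjoint
# sensitivities are obtained by exact forward / back substitution in
# O(k 2^k) per sample -- no iterative solver, no truncation.  For a sample
# with k active events the computation is confined to the 2^k sub-lattice
# of genotypes below the observation; exit rates on that sub-lattice still
# sum the rates of ALL n events (events outside the active set can fire and
# leave the sub-lattice, and their rates must appear in the diagonal).

.engine_state <- new.env(parent = emptyenv())
.engine_state$states_visited <- 0

# instrumentation used to assert the 2^k cost-scaling contract
lattice_counter <- function(reset = FALSE) {
  v <- .engine_state$states_visited
  if (reset) .engine_state$states_visited <- 0
  v
}

# Precompute, for every state y of the sub-lattice below `g`:
# the full-length genotype (G), all n event rates (Lam), the observation
# rate (omega) and the total exit rate (R).  States are indexed 1..2^k with
# bit b of (index-1) mapped to the b-th active event in `S`.
restricted_lattice <- function(model, g) {
  th <- model$log_theta
  n <- model$n
  S <- which(g == 1L)
  k <- length(S)
  ns <- bitwShiftL(1L, k)
  mask <- bitwShiftL(1L, seq_len(k) - 1L)
  G <- matrix(0, ns, n)
  if (k > 0L) {
    codes <- 0:(ns - 1L)
    for (b in seq_len(k))
      G[, S[b]] <- as.numeric(bitwAnd(codes, mask[b]) != 0L)
  }
  off <- th[seq_len(n), , drop = FALSE]
  d <- diag(off)
  if (n > 1L) diag(off) <- 0 else off[1L, 1L] <- 0
  Lam <- exp(G %*% t(off) + matrix(d, ns, n, byrow = TRUE))
  omega <- if (model$kind == "classic") rep(1, ns)
           else exp(as.vector(G %*% th[n + 1L, ]))
  R <- omega + rowSums(Lam * (1 - G))
  list(S = S, k = k, ns = ns, mask = mask, G = G,
       Lam = Lam, omega = omega, R = R)
}

# forward substitution: q[1] = 1/R(0), q[y] = sum_i lam_i(y-e_i) q[y-e_i] / R(y)
lattice_forward <- function(lat) {
  q <- numeric(lat$ns)
  q[1L] <- 1 / lat$R[1L]
  if (lat$k > 0L) {
    for (s in 2:lat$ns) {
      code <- s - 1L
      b <- which(bitwAnd(code, lat$mask) != 0L)
      prev <- s - lat$mask[b]
      q[s] <- sum(lat$Lam[cbind(prev, lat$S[b])] * q[prev]) / lat$R[s]
    }
  }
  q
}

# adjoint back substitution for the transposed system, unit mass (times
# omega(x)) at the conditioning state
lattice_adjoint <- function(lat) {
  r <- numeric(lat$ns)
  r[lat$ns] <- lat$omega[lat$ns] / lat$R[lat$ns]
  if (lat$k > 0L) {
    for (s in (lat$ns - 1L):1L) {
      code <- s - 1L
      b <- which(bitwAnd(code, lat$mask) == 0L)
      nxt <- s + lat$mask[b]
      r[s] <- sum(lat$Lam[cbind(s, lat$S[b])] * r[nxt]) / lat$R[s]
    }
  }
  r
}

#' Exact marginal distribution over all genotypes
#'
#' Solves the full-lattice flow recurrence
#' \eqn{q(0) = 1/R(0)}, \eqn{q(y) = \sum_{i: y_i=1} \lambda_i(y - e_i)
#' q(y - e_i) / R(y)} by forward substitution and returns
#' \eqn{p(x) = \omega(x) q(x)} for every genotype \eqn{x}, the probability
#' that a tumor is observed with exactly genotype \eqn{x}.  The vector sums
#' to 1: observation is certain since \eqn{\omega > 0} everywhere.
#'
#' Intended as the exhaustive reference for moderate \code{n}; per-sample
#' likelihoods use the restricted computation in [genotype_probability()].
#'
#' @param model an \code{"mhn"} model with \code{n <= 20}.
#' @return numeric vector of length \eqn{2^n}; element \eqn{c + 1}
#'   corresponds to the genotype with bit pattern \eqn{c}
#'   (bit \eqn{j - 1} set iff event \eqn{j} present), named by the
#'   genotype bit strings.
#' @export
marginal_distribution <- function(model) {
  stopifnot(inherits(model, "mhn"))
  if (model$n > 20L)
    stop("full marginal distribution is limited to n <= 20 events")
  lat <- restricted_lattice(model, rep(1L, model$n))
  p <- lat$omega * lattice_forward(lat)
  names(p) <- apply(lat$G, 1L, paste, collapse = "")
  p
}

#' Exact probability of observing one genotype
#'
#' Runs the same flow recurrence as [marginal_distribution()] but confined
#' to the \eqn{2^k} sub-lattice of states below the observed genotype
#' (\eqn{k} = number of active events).  This restriction is exact, not an
#' approximation: no probability mass destined for \eqn{x} ever leaves the
#' sub-lattice, and the rates of events outside the active set enter
#' through the exit rates.
#'
#' @param model an \code{"mhn"} model.
#' @param genotype binary vector with at most 32 active events.
#' @return the probability, a scalar in (0, 1).
#' @export
genotype_probability <- function(model, genotype) {
  g <- as_genotype(genotype, model)
  lat <- restricted_lattice(model, g)
  .engine_state$states_visited <- .engine_state$states_visited + lat$ns
  q <- lattice_forward(lat)
  p <- lat$omega[lat$ns] * q[lat$ns]
  if (p < 1e-300)
    stop("genotype probability underflowed below 1e-300; ",
         "the parameter matrix is too extreme for linear-space computation")
  p
}

#' Log-likelihood of a cross-sectional dataset
#'
#' Sum over samples of the log marginal probability of the observed
#' genotype.  Identical genotypes are aggregated by count before
#' computation (same value, one restricted solve per unique genotype), and
#' the summation order is fixed (sorted by genotype bit string) so the
#' value is invariant to the row order of the dataset.
#'
#' @inheritParams mhn_initial
#' @param model an \code{"mhn"} model.
#' @return the log-likelihood, a finite negative number.
#' @export
log_likelihood <- function(model, data) {
  stopifnot(inherits(model, "mhn"))
  data <- validate_dataset(data, events = model$events)
  if (nrow(data) == 0L)
    stop("empty dataset")
  agg <- aggregate_dataset(data)
  ll <- 0
  for (u in seq_along(agg$counts))
    ll <- ll + agg$counts[u] *
      log(genotype_probability(model, agg$genotypes[u, ]))
  ll
}

# per-genotype log probability and exact gradient of it w.r.t. every entry
# of log_theta, via one forward and one adjoint solve.  Writing the
# restricted system as A q = e_0 with A = diag(R) - transitions and
# p = omega(x) q_F, the gradient is
#   d log p = [ -r' (dA) q + (d omega(x)) q_F ] / p,   A' r = omega(x) e_F.
sample_logp_grad <- function(model, g) {
  n <- model$n
  lat <- restricted_lattice(model, g)
  q <- lattice_forward(lat)
  r <- lattice_adjoint(lat)
  ns <- lat$ns
  p <- lat$omega[ns] * q[ns]
  if (p < 1e-300)
    stop("genotype probability underflowed below 1e-300")
  aware <- model$kind != "classic"
  gr <- matrix(0, n + 1L, n)
  idx_diag <- cbind(seq_len(n), seq_len(n))
  for (s in seq_len(ns)) {
    gvec <- lat$G[s, ]
    act <- which(gvec == 1)
    # exit-rate (diagonal of A) sensitivities: every inactive event i,
    # including events outside the active set, contributes lambda_i(y)
    # to R(y) through theta_{ii} and theta_{ij} for j present in y
    w <- -r[s] * q[s]
    vi <- w * lat$Lam[s, ] * (1 - gvec)
    gr[idx_diag] <- gr[idx_diag] + vi
    if (length(act))
      gr[seq_len(n), act] <- gr[seq_len(n), act] + vi
    if (aware && length(act))
      gr[n + 1L, act] <- gr[n + 1L, act] + w * lat$omega[s]
    # within-lattice transition sensitivities
    code <- s - 1L
    b <- which(bitwAnd(code, lat$mask) != 0L)
    for (bb in b) {
      i <- lat$S[bb]
      prev <- s - lat$mask[bb]
      u <- r[s] * lat$Lam[prev, i] * q[prev]
      gr[i, i] <- gr[i, i] + u
      actp <- lat$S[bitwAnd(prev - 1L, lat$mask) != 0L]
      if (length(actp))
        gr[i, actp] <- gr[i, actp] + u
    }
  }
  gr <- gr / p
  if (aware) {
    act <- which(g == 1L)
    # absorption factor omega(x) in p = omega(x) q_F
    gr[n + 1L, act] <- gr[n + 1L, act] + 1
  }
  list(logp = log(p), grad = gr)
}

#' Analytic gradient of the dataset log-likelihood
#'
#' Exact gradient of [log_likelihood()] with respect to every entry of the
#' \eqn{(n+1) \times n} log-parameter matrix, computed per unique genotype
#' by one forward substitution and one adjoint back-substitution on the
#' restricted sub-lattice.  For a classic model the observation row of the
#' gradient is identically zero (those parameters are inactive).
#'
#' @inheritParams log_likelihood
#' @return an \eqn{(n+1) \times n} matrix.
#' @export
loglik_gradient <- function(model, data) {
  stopifnot(inherits(model, "mhn"))
  data <- validate_dataset(data, events = model$events)
  if (nrow(data) == 0L)
    stop("empty dataset")
  agg <- aggregate_dataset(data)
  gr <- matrix(0, model$n + 1L, model$n)
  for (u in seq_along(agg$counts))
    gr <- gr + agg$counts[u] *
      sample_logp_grad(model, agg$genotypes[u, ])$grad
  dimnames(gr) <- dimnames(model$log_theta)
  gr
}
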