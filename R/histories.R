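# Most-likely event-order reconstruction.  Cross-sectional data carry no
# time stamps; given a trained model, the chain's path probabilities rank
# the possible chronological orders of a genotype's events.

#' Probability of one complete event ordering
#'
#' For an ordering \eqn{\sigma_1, \ldots, \sigma_m} of distinct events,
#' returns the probability that the chain takes exactly this path from the
#' healthy state and is then observed:
#' \deqn{\prod_{s=1}^{m} \frac{\lambda_{\sigma_s}(x_{s-1})}{R(x_{s-1})}
#'       \cdot \frac{\omega(x_m)}{R(x_m)},}
#' where \eqn{x_{s}} is the genotype after the first \eqn{s} events.
#' Summed over all \eqn{m!} orderings of a genotype's active events this
#' recovers [genotype_probability()] exactly (path decomposition of the
#' marginal).
#'
#' @param model an \code{"mhn"} model.
#' @param ordering event labels or 1-based indices, in chronological
#'   order; may be empty (tumor observed healthy).
#' @return the path probability, in (0, 1].
#' @export
order_probability <- function(model, ordering) {
  stopifnot(inherits(model, "mhn"))
  if (length(ordering) == 0L)
    ordering <- integer(0)
  if (is.character(ordering)) {
    idx <- match(ordering, model$events)
    if (anyNA(idx))
      stop("unknown event label(s): ",
           paste(ordering[is.na(idx)], collapse = ", "))
  } else {
    idx <- as.integer(ordering)
    if (anyNA(idx) || any(idx < 1L) || any(idx > model$n))
      stop("event indices must be in 1..", model$n)
  }
  if (anyDuplicated(idx))
    stop("ordering contains a repeated event")
  x <- integer(model$n)
  p <- 1
  for (i in idx) {
    R <- total_exit_rate(model, x)
    p <- p * event_rate(model, x, i) / R
    x[i] <- 1L
  }
  p * observation_rate(model, x) / total_exit_rate(model, x)
}

#' Most likely chronological order of a genotype's events
#'
#' Maximizes [order_probability()] over all \eqn{k!} orderings of the
#' genotype's \eqn{k} active events by dynamic programming over the
#' \eqn{2^k} subsets: with \eqn{h(F) = 1} for the full set,
#' \eqn{h(S) = \max_{i \notin S} \lambda_i(S)/R(S) \cdot h(S \cup i)} is
#' the best completion probability from \eqn{S}, and the ordering is read
#' off forwards from the healthy state (ties broken towards the smallest
#' event index at the earliest differing step, so reconstructions are
#' reproducible).  Since the marginal \eqn{p(x)} is a constant per
#' genotype, the same ordering maximizes the conditional probability given
#' the observed genotype.
#'
#' @param model an \code{"mhn"} model.
#' @param genotype binary vector with at most 25 active events.
#' @return an object of class \code{"mhn_order"}: list with
#'   \code{ordering} (event labels), \code{indices} and
#'   \code{probability} (joint path-and-observation probability).
#' @export
most_likely_order <- function(model, genotype) {
  g <- as_genotype(genotype, model)
  k <- sum(g)
  if (k > 25L)
    stop("order reconstruction is limited to 25 active events ",
         "(dynamic program over 2^k subsets)")
  lat <- restricted_lattice(model, g)
  ns <- lat$ns
  h <- numeric(ns)
  h[ns] <- 1
  if (k > 0L) {
    for (s in (ns - 1L):1L) {
      b <- which(bitwAnd(s - 1L, lat$mask) == 0L)
      h[s] <- max(lat$Lam[cbind(s, lat$S[b])] / lat$R[s] * h[s + lat$mask[b]])
    }
  }
  ord <- integer(0)
  s <- 1L
  while (s < ns) {
    b <- which(bitwAnd(s - 1L, lat$mask) == 0L)
    vals <- lat$Lam[cbind(s, lat$S[b])] / lat$R[s] * h[s + lat$mask[b]]
    j <- b[which.max(vals)]
    ord <- c(ord, lat$S[j])
    s <- s + lat$mask[j]
  }
  structure(list(ordering = model$events[ord],
                 indices = ord,
                 probability = h[1L] * lat$omega[ns] / lat$R[ns]),
            class = "mhn_order")
}

#' @export
print.mhn_order <- function(x, ...) {
  cat(sprintf("most likely order: %s (probability %.4g)\n",
              if (length(x$ordering)) paste(x$ordering, collapse = " -> ")
              else "<healthy>",
              x$probability))
  invisible(x)
}

#' Reconstruct event orders for every sample of a cohort
#'
#' Applies [most_likely_order()] to each sample's genotype (computed once
#' per unique genotype) and returns a per-sample table.
#'
#' @inheritParams log_likelihood
#' @return data frame with columns \code{sample_id}, \code{ordering}
#'   (labels joined by \code{" > "}, empty string for the healthy
#'   genotype) and \code{probability}, one row per input row in input
#'   order.
#' @export
reconstruct_orders <- function(model, data) {
  data <- validate_dataset(data, events = model$events)
  key <- apply(data, 1L, paste, collapse = "")
  uk <- unique(key)
  recs <- lapply(uk, function(k) {
    most_likely_order(model, as.integer(strsplit(k, "")[[1L]]))
  })
  names(recs) <- uk
  ids <- rownames(data)
  if (is.null(ids))
    ids <- paste0("S", seq_len(nrow(data)))
  data.frame(
    sample_id = ids,
    ordering = vapply(key, function(k)
      paste(recs[[k]]$ordering, collapse = " > "), character(1L)),
    probability = vapply(key, function(k)
      recs[[k]]$probability, numeric(1L)),
    row.names = NULL,
    stringsAsFactors = FALSE)
}
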