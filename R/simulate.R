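# Gillespie sampling of tumor histories.  Besides generating artificial
# cohorts from a trained model, this is the package's synthetic-fixture
# generator: the empirical genotype distribution it produces and the
# analytic distribution from the likelihood engine are independent
# derivations of the same law.

#' Sample one tumor history
#'
#' Simulates the competing-exponentials walk of the progression process:
#' starting from the healthy state, at genotype \eqn{x} a waiting time
#' \eqn{Exp(R(x))} is drawn and the next event is the observation with
#' probability \eqn{\omega(x)/R(x)}, otherwise inactive event \eqn{i} with
#' probability \eqn{\lambda_i(x)/R(x)}.  Events accumulate irreversibly
#' until the observation fires, which happens with probability 1.  The
#' categorical choice uses a single uniform draw against cumulative rate
#' fractions in event-index order with the observation last, so histories
#' are bit-reproducible given a seed.
#'
#' @param model an \code{"mhn"} model.
#' @param seed optional integer seed; when given, the global RNG state is
#'   restored afterwards.
#' @return an object of class \code{"mhn_history"}: list with
#'   \code{steps} (data frame of event labels and strictly increasing
#'   occurrence times, in model time units), \code{observation_time} and
#'   \code{genotype} (final binary vector).
#' @export
sample_history <- function(model, seed = NULL) {
  stopifnot(inherits(model, "mhn"))
  if (!is.null(seed))
    return(with_seed(seed, sample_history(model)))
  n <- model$n
  x <- integer(n)
  t <- 0
  labs <- character(0)
  times <- numeric(0)
  repeat {
    inact <- which(x == 0L)
    lam <- inactive_event_rates(model, x)
    om <- observation_rate(model, x)
    R <- om + sum(lam)
    t <- t + stats::rexp(1L, rate = R)
    u <- stats::runif(1L)
    cum <- cumsum(c(lam, om)) / R
    pick <- which(u <= cum)[1L]
    if (is.na(pick)) pick <- length(cum)
    if (pick > length(lam))
      break
    x[inact[pick]] <- 1L
    labs <- c(labs, model$events[inact[pick]])
    times <- c(times, t)
  }
  structure(list(steps = data.frame(event = labs, time = times,
                                    stringsAsFactors = FALSE),
                 observation_time = t,
                 genotype = stats::setNames(x, model$events)),
            class = "mhn_history")
}

#' @export
print.mhn_history <- function(x, ...) {
  if (nrow(x$steps) == 0L) {
    cat("tumor history: no progression events")
  } else {
    cat("tumor history:",
        paste(sprintf("%s@%.3f", x$steps$event, x$steps$time),
              collapse = " -> "))
  }
  cat(sprintf(", observed at %.3f\n", x$observation_time))
  invisible(x)
}

# per-draw substream: dataset seed + draw index, so any subset of draws is
# reproducible independent of the total number requested
substream_seed <- function(seed, d) {
  as.integer((as.numeric(seed) + d) %% 2147483647)
}

#' Sample an artificial cross-sectional cohort
#'
#' Draws \code{n_samples} independent tumor histories from the model and
#' returns their genotypes at observation as a binary sample-by-event
#' matrix, the same format the training functions accept.  Each draw uses
#' its own RNG substream derived from \code{seed} plus the draw index, so
#' the first \eqn{m} samples of a size-\eqn{N} cohort equal a size-\eqn{m}
#' cohort with the same seed.
#'
#' @inheritParams sample_history
#' @param n_samples number of tumors to draw.
#' @param seed integer seed.
#' @param keep_histories also return the full time-stamped histories.
#' @return the genotype matrix (row names \code{S1..SN}); if
#'   \code{keep_histories} is \code{TRUE}, a list with elements
#'   \code{data} and \code{histories}.
#' @export
sample_mhn <- function(model, n_samples, seed, keep_histories = FALSE) {
  stopifnot(inherits(model, "mhn"))
  n_samples <- as.integer(n_samples)
  if (is.na(n_samples) || n_samples < 1L)
    stop("`n_samples` must be a positive integer")
  X <- matrix(0L, n_samples, model$n,
              dimnames = list(paste0("S", seq_len(n_samples)), model$events))
  histories <- if (keep_histories) vector("list", n_samples)
  for (d in seq_len(n_samples)) {
    h <- sample_history(model, seed = substream_seed(seed, d))
    X[d, ] <- h$genotype
    if (keep_histories)
      histories[[d]] <- h
  }
  if (keep_histories)
    list(data = X, histories = histories)
  else
    X
}

#' Write sampled histories to JSON
#'
#' One record per sample: \code{\{"id", "events": [\{"label", "time"\}],
#' "observed_at"\}}, collected in a JSON array.
#'
#' @param histories list of \code{"mhn_history"} objects.
#' @param path output path.
#' @param ids optional sample ids (default \code{S1..SN}).
#' @return \code{path}, invisibly.
#' @export
write_histories <- function(histories, path, ids = NULL) {
  if (is.null(ids))
    ids <- paste0("S", seq_along(histories))
  recs <- lapply(seq_along(histories), function(d) {
    h <- histories[[d]]
    list(id = ids[d],
         events = lapply(seq_len(nrow(h$steps)), function(s)
           list(label = h$steps$event[s], time = h$steps$time[s])),
         observed_at = h$observation_time)
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}
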