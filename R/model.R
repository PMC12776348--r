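#' Construct a mutual hazard network model
#'
#' A mutual hazard network (MHN) describes the irreversible accumulation of
#' \code{n} binary progression events in a tumor as a continuous-time Markov
#' chain on the \eqn{2^n} genotypes, terminated by a competing observation
#' event whose rate depends on the current genotype.  The model is fully
#' parameterized by an \eqn{(n+1) \times n} matrix on natural-log scale:
#' diagonal entries of the first \eqn{n} rows are log base rates, entry
#' \eqn{(i, j)} with \eqn{i \neq j} is the log multiplier that an already
#' present event \eqn{j} applies to the rate of event \eqn{i}, and the last
#' row holds the log multipliers the events apply to the observation rate.
#' The observation event's own base rate is fixed to 1 (log 0): the process
#' is only identified up to a global time scale, so this rate is not a free
#' parameter.
#'
#' @param log_theta numeric \eqn{(n+1) \times n} matrix of log-scale
#'   parameters; an \eqn{n \times n} matrix is accepted and padded with a
#'   zero observation row.  All entries must be finite.
#' @param events character vector of \code{n} unique, non-empty event
#'   labels; defaults to the column names of \code{log_theta} or
#'   \code{E1..En}.
#' @param kind \code{"observation_aware"} for the full model with a
#'   genotype-dependent observation rate, or \code{"classic"} for the
#'   earlier model variant with a constant observation rate (the last row
#'   is then forced to zero and ignored by all rate computations).
#'
#' @return An object of class \code{"mhn"}: a list with elements
#'   \code{log_theta}, \code{events}, \code{kind} and \code{n}.
#' @seealso [event_rate()], [marginal_distribution()], [fit_mhn()],
#'   [sample_mhn()], [most_likely_order()]
#' @export
#' @examples
#' th <- matrix(0, 3, 2)
#' th[1, 1] <- log(2)     # base rate of event 1 is 2
#' th[2, 1] <- log(3)     # event 1 triples the rate of event 2
#' m <- mhn_model(th, events = c("TP53", "KRAS"))
#' event_rate(m, c(1, 0), 2)  # 3 * exp(0) = 3
mhn_model <- function(log_theta, events = NULL,
                      kind = c("observation_aware", "classic")) {
  kind <- match.arg(kind)
  if (!is.matrix(log_theta) || !is.numeric(log_theta))
    stop("`log_theta` must be a numeric matrix")
  n <- ncol(log_theta)
  if (n < 1L)
    stop("the model needs at least one event")
  if (nrow(log_theta) == n)
    log_theta <- rbind(log_theta, 0)
  if (nrow(log_theta) != n + 1L)
    stop("`log_theta` must be (n+1) x n (or n x n) for n = ", n, " events")
  if (!all(is.finite(log_theta)))
    stop("all entries of `log_theta` must be finite")
  if (is.null(events))
    events <- colnames(log_theta)
  if (is.null(events))
    events <- paste0("E", seq_len(n))
  events <- as.character(events)
  if (length(events) != n)
    stop("`events` must have length ", n)
  if (anyDuplicated(events) || !all(nzchar(events)))
    stop("event labels must be unique and non-empty")
  if (kind == "classic")
    log_theta[n + 1L, ] <- 0
  dimnames(log_theta) <- list(c(events, "observation"), events)
  structure(list(log_theta = log_theta, events = events,
                 kind = kind, n = n),
            class = "mhn")
}

#' @export
print.mhn <- function(x, ...) {
  cat(sprintf("Mutual hazard network (%s), %d events: %s\n",
              x$kind, x$n, paste(x$events, collapse = ", ")))
  cat("log-parameter matrix (rows: affected event / observation; columns: influencing event):\n")
  print(round(x$log_theta, 3))
  invisible(x)
}

# coerce and validate a genotype vector against a model
as_genotype <- function(x, model) {
  if (is.list(x)) x <- unlist(x)
  x <- as.integer(x)
  if (length(x) != model$n)
    stop("genotype length ", length(x), " does not match the model's ",
         model$n, " events")
  if (anyNA(x) || !all(x %in% c(0L, 1L)))
    stop("genotype entries must be 0 or 1")
  if (sum(x) > 32L)
    stop("genotypes with more than 32 active events are not supported")
  x
}

#' Elementary rates of the progression process
#'
#' \code{event_rate} returns the transition rate of progression event
#' \code{i} out of genotype \code{x}:
#' \eqn{\lambda_i(x) = \exp(\theta_{ii} + \sum_{j \ne i, x_j = 1} \theta_{ij})}.
#' \code{observation_rate} returns the rate of the terminal observation
#' event, \eqn{\omega(x) = \exp(\sum_{j: x_j = 1} \theta_{obs,j})} for an
#' observation-aware model and constant 1 for a classic model.
#' \code{total_exit_rate} returns
#' \eqn{R(x) = \omega(x) + \sum_{i: x_i = 0} \lambda_i(x)}, the total rate
#' of leaving genotype \code{x}.
#'
#' @param model an \code{"mhn"} model.
#' @param genotype binary vector of length \code{n}.
#' @param i event index (1-based) or event label.
#' @return a positive scalar rate.
#' @export
event_rate <- function(model, genotype, i) {
  g <- as_genotype(genotype, model)
  if (is.character(i)) {
    lab <- i
    i <- match(i, model$events)
    if (is.na(i)) stop("unknown event label: ", lab)
  }
  i <- as.integer(i)
  if (length(i) != 1L || is.na(i) || i < 1L || i > model$n)
    stop("event index out of range 1..", model$n)
  th <- model$log_theta
  act <- which(g == 1L)
  act <- act[act != i]
  exp(th[i, i] + sum(th[i, act]))
}

#' @rdname event_rate
#' @export
observation_rate <- function(model, genotype) {
  g <- as_genotype(genotype, model)
  if (model$kind == "classic")
    return(1)
  exp(sum(model$log_theta[model$n + 1L, g == 1L]))
}

#' @rdname event_rate
#' @export
total_exit_rate <- function(model, genotype) {
  g <- as_genotype(genotype, model)
  observation_rate(model, g) + sum(inactive_event_rates(model, g))
}

# rates of all currently inactive events, named vector indexed by event
inactive_event_rates <- function(model, g) {
  th <- model$log_theta
  inact <- which(g == 0L)
  if (!length(inact)) return(numeric(0))
  act <- which(g == 1L)
  v <- th[cbind(inact, inact)]
  if (length(act))
    v <- v + rowSums(th[inact, act, drop = FALSE])
  stats::setNames(exp(v), model$events[inact])
}

#' Independence initialization for training
#'
#' Builds the standard optimizer starting point: diagonal entries set to the
#' logit of each event's marginal frequency (the exact maximum-likelihood
#' base rate of a classic single-event model), all interactions and
#' observation effects zero.  Frequencies are clipped to
#' \eqn{[1/(2N), 1 - 1/(2N)]} so the logit stays finite for events that are
#' absent from (or present in) every sample.
#'
#' @param data binary sample-by-event matrix (see [read_dataset()]).
#' @inheritParams mhn_model
#' @return an \code{"mhn"} model.
#' @export
mhn_initial <- function(data, kind = c("observation_aware", "classic")) {
  kind <- match.arg(kind)
  data <- validate_dataset(data)
  N <- nrow(data)
  if (N == 0L)
    stop("cannot initialize from an empty dataset")
  n <- ncol(data)
  f <- colMeans(data)
  f <- pmin(pmax(f, 1 / (2 * N)), 1 - 1 / (2 * N))
  th <- matrix(0, n + 1L, n)
  th[cbind(seq_len(n), seq_len(n))] <- log(f / (1 - f))
  mhn_model(th, events = colnames(data), kind = kind)
}

#' Read and write mutual hazard network models as JSON
#'
#' Models are serialized as a human-diffable JSON object with fields
#' \code{version}, \code{kind}, \code{events} and \code{log_theta} (the
#' \eqn{(n+1) \times n} matrix as a row-major nested array, written at full
#' precision so a write/read round trip reproduces the parameters exactly).
#'
#' @param model an \code{"mhn"} model.
#' @param path file path of the model JSON.
#' @return \code{read_mhn} returns an \code{"mhn"} model;
#'   \code{write_mhn} returns \code{path} invisibly.
#' @export
write_mhn <- function(model, path) {
  stopifnot(inherits(model, "mhn"))
  obj <- list(version = "1.0",
              kind = model$kind,
              events = model$events,
              log_theta = unname(model$log_theta))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_mhn
#' @export
read_mhn <- function(path) {
  if (!file.exists(path))
    stop("model file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("kind", "events", "log_theta"))
    if (is.null(obj[[f]]))
      stop("model file ", path, " lacks required field '", f, "'")
  th <- obj$log_theta
  if (!is.matrix(th))
    th <- do.call(rbind, obj$log_theta)
  mhn_model(th, events = obj$events, kind = obj$kind)
}
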