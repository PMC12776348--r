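#' Specify a regularization penalty
#'
#' Penalties act on the interaction entries of the parameter matrix: all
#' off-diagonal entries of the first \eqn{n} rows and (by default) the
#' observation-effect row.  Diagonal entries -- the log base rates that set
#' the time scale of the process -- are never penalized.
#'
#' \describe{
#'   \item{\code{l1}}{sparsity-inducing absolute-value penalty, smoothed
#'     for differentiability: \eqn{\sum \sqrt{\theta^2 + \epsilon^2} -
#'     \epsilon} per penalized entry.  Drives weak interactions to
#'     (numerical) zero, leaving an interpretable sparse network.}
#'   \item{\code{l2}}{\eqn{\sum \theta^2}; shrinks all interactions towards
#'     zero without sparsity, appropriate when many small effects are
#'     expected.}
#'   \item{\code{symmetric}}{pairwise group penalty
#'     \eqn{\sum_{i<j} \sqrt{\theta_{ij}^2 + \theta_{ji}^2 + \epsilon^2} -
#'     \epsilon} plus the smoothed absolute value on the observation row;
#'     the two directions of an event-pair interaction are coupled so they
#'     vanish or survive together unless the data clearly favours an
#'     asymmetric effect.}
#'   \item{\code{custom}}{a user hook \code{function(log_theta)} returning
#'     \code{list(value = <scalar>, gradient = <(n+1) x n matrix>)}.}
#' }
#'
#' @param kind one of \code{"l1"}, \code{"l2"}, \code{"symmetric"},
#'   \code{"custom"}.
#' @param strength non-negative penalty strength multiplying the penalty in
#'   the training objective.
#' @param smoothing positive smoothing constant \eqn{\epsilon} of the
#'   smoothed absolute value (default \code{1e-4}).
#' @param hook the custom penalty function; required iff
#'   \code{kind = "custom"}.
#' @param penalize_observation should the observation-effect row be
#'   penalized (default \code{TRUE})?  Ignored by \code{custom} hooks.
#' @return an object of class \code{"mhn_penalty_spec"}.
#' @export
penalty_spec <- function(kind = c("l1", "l2", "symmetric", "custom"),
                         strength = 0.01, smoothing = 1e-4, hook = NULL,
                         penalize_observation = TRUE) {
  kind <- match.arg(kind)
  if (!is.numeric(strength) || length(strength) != 1L || strength < 0)
    stop("`strength` must be a single non-negative number")
  if (!is.numeric(smoothing) || length(smoothing) != 1L || smoothing <= 0)
    stop("`smoothing` must be a single positive number")
  if (kind == "custom" && !is.function(hook))
    stop("a custom penalty requires a `hook` function")
  if (kind != "custom" && !is.null(hook))
    stop("`hook` is only allowed with kind = 'custom'")
  structure(list(kind = kind, strength = strength, smoothing = smoothing,
                 hook = hook, penalize_observation = penalize_observation),
            class = "mhn_penalty_spec")
}

# smoothed |x|: sqrt(x^2 + eps^2) - eps, and its derivative
smooth_abs <- function(x, eps) sqrt(x^2 + eps^2) - eps
smooth_abs_grad <- function(x, eps) x / sqrt(x^2 + eps^2)

#' Penalty value and gradient
#'
#' Evaluates the penalty of a [penalty_spec()] (without the strength
#' factor) at the model's parameter matrix, together with its exact
#' gradient with respect to every matrix entry.
#'
#' @param model an \code{"mhn"} model (or a bare \eqn{(n+1) \times n}
#'   matrix).
#' @param spec an \code{"mhn_penalty_spec"}.
#' @return \code{list(value = <scalar>, gradient = <(n+1) x n matrix>)}.
#' @export
mhn_penalty <- function(model, spec) {
  th <- if (inherits(model, "mhn")) model$log_theta else model
  stopifnot(is.matrix(th), nrow(th) == ncol(th) + 1L)
  n <- ncol(th)
  eps <- spec$smoothing
  if (spec$kind == "custom") {
    res <- spec$hook(th)
    if (!is.list(res) || !is.numeric(res$value) || length(res$value) != 1L ||
        !is.matrix(res$gradient) || !all(dim(res$gradient) == dim(th)))
      stop("custom penalty hook must return list(value = scalar, ",
           "gradient = ", n + 1L, " x ", n, " matrix)")
    return(list(value = res$value, gradient = unname(res$gradient)))
  }
  mask <- matrix(TRUE, n + 1L, n)
  mask[cbind(seq_len(n), seq_len(n))] <- FALSE
  if (!spec$penalize_observation)
    mask[n + 1L, ] <- FALSE
  gr <- matrix(0, n + 1L, n)
  if (spec$kind == "l2") {
    val <- sum(th[mask]^2)
    gr[mask] <- 2 * th[mask]
  } else if (spec$kind == "l1") {
    val <- sum(smooth_abs(th[mask], eps))
    gr[mask] <- smooth_abs_grad(th[mask], eps)
  } else { # symmetric
    val <- 0
    if (n > 1L) {
      for (i in seq_len(n - 1L)) {
        for (j in (i + 1L):n) {
          s <- sqrt(th[i, j]^2 + th[j, i]^2 + eps^2)
          val <- val + s - eps
          gr[i, j] <- th[i, j] / s
          gr[j, i] <- th[j, i] / s
        }
      }
    }
    if (spec$penalize_observation) {
      val <- val + sum(smooth_abs(th[n + 1L, ], eps))
      gr[n + 1L, ] <- smooth_abs_grad(th[n + 1L, ], eps)
    }
  }
  list(value = val, gradient = gr)
}
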