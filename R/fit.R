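#' Fit a mutual hazard network by penalized maximum likelihood
#'
#' Maximizes the per-sample log-likelihood minus a penalty,
#' \deqn{\frac{1}{N} \sum_d \log p_\theta(x_d) \; - \;
#'       \mathrm{strength} \cdot \mathrm{penalty}(\theta),}
#' with L-BFGS-B and the exact analytic gradient, starting from the
#' independence initialization [mhn_initial()].  The objective is scaled
#' per sample so penalty strengths are comparable across dataset sizes.
#' Given the same data, penalty and options the fit is deterministic.
#'
#' \code{kind = "classic"} reproduces the earlier model variant without an
#' explicit observation event (only the \eqn{n \times n} progression block
#' is optimized).  \code{freeze_observation = TRUE} keeps an
#' observation-aware model's observation row fixed at zero, which yields
#' the same dynamics as a classic fit.
#'
#' @inheritParams mhn_initial
#' @param penalty an [penalty_spec()]; default smoothed-l1 with strength
#'   0.01.
#' @param kind model variant to train.
#' @param max_iter maximum number of L-BFGS-B iterations (default 500).
#' @param tol projected-gradient-norm convergence tolerance (default
#'   \code{1e-6}).
#' @param init optional \code{"mhn"} model used as the starting point.
#' @param freeze_observation keep the observation row at zero during an
#'   observation-aware fit.
#' @return an object of class \code{"mhn_fit"}: list with elements
#'   \code{model}, \code{value} (final objective), \code{logLik},
#'   \code{objective_trace} (objective at each evaluation, line-search
#'   probes included), \code{converged} and \code{settings}.
#' @export
#' @examples
#' m0 <- mhn_model(matrix(c(0, 1, 0, 0, 0, 0), 3, 2), events = c("A", "B"))
#' d <- sample_mhn(m0, 300, seed = 7)
#' fit <- fit_mhn(d, penalty_spec("l1", 0.01))
#' round(exp(fit$model$log_theta), 2)
fit_mhn <- function(data, penalty = penalty_spec("l1", 0.01),
                    kind = c("observation_aware", "classic"),
                    max_iter = 500L, tol = 1e-6, init = NULL,
                    freeze_observation = FALSE) {
  kind <- match.arg(kind)
  stopifnot(inherits(penalty, "mhn_penalty_spec"))
  data <- validate_dataset(data)
  N <- nrow(data)
  if (N == 0L)
    stop("empty dataset")
  n <- ncol(data)
  events <- colnames(data)
  agg <- aggregate_dataset(data)
  if (is.null(init))
    init <- mhn_initial(data, kind = kind)
  stopifnot(inherits(init, "mhn"), init$n == n)
  # classic / frozen fits optimize only the n x n progression block
  n_free_rows <- if (kind == "classic" || freeze_observation) n else n + 1L
  free <- matrix(FALSE, n + 1L, n)
  free[seq_len(n_free_rows), ] <- TRUE

  build_model <- function(par) {
    th <- matrix(0, n + 1L, n)
    th[free] <- par
    mhn_model(th, events = events, kind = kind)
  }
  cache <- new.env(parent = emptyenv())
  evaluate <- function(par) {
    if (!identical(par, cache$par)) {
      model <- build_model(par)
      ll <- 0
      gr <- matrix(0, n + 1L, n)
      for (u in seq_along(agg$counts)) {
        sg <- sample_logp_grad(model, agg$genotypes[u, ])
        ll <- ll + agg$counts[u] * sg$logp
        gr <- gr + agg$counts[u] * sg$grad
      }
      pen <- mhn_penalty(model$log_theta, penalty)
      cache$par <- par
      cache$obj <- ll / N - penalty$strength * pen$value
      gfull <- gr / N - penalty$strength * pen$gradient
      cache$gvec <- gfull[free]
      if (!is.finite(cache$obj))
        stop("non-finite objective during optimization (objective = ",
             cache$obj, ", max |theta| = ", max(abs(par)), ")")
    }
    invisible(NULL)
  }
  trace_env <- new.env(parent = emptyenv())
  trace_env$trace <- numeric(0)
  fn <- function(par) {
    evaluate(par)
    trace_env$trace <- c(trace_env$trace, cache$obj)
    -cache$obj
  }
  gr_fun <- function(par) {
    evaluate(par)
    -cache$gvec
  }
  par0 <- init$log_theta[free]
  opt <- stats::optim(par0, fn, gr_fun, method = "L-BFGS-B",
                      control = list(maxit = as.integer(max_iter),
                                     pgtol = tol))
  model <- build_model(opt$par)
  structure(list(model = model,
                 value = -opt$value,
                 logLik = log_likelihood(model, data),
                 objective_trace = trace_env$trace,
                 converged = opt$convergence == 0L,
                 settings = list(penalty = penalty, kind = kind,
                                 max_iter = max_iter, tol = tol,
                                 freeze_observation = freeze_observation,
                                 n_samples = N)),
            class = "mhn_fit")
}

#' @export
print.mhn_fit <- function(x, ...) {
  cat(sprintf(
    "MHN fit (%s, %s penalty, strength %g): objective %.6f, logLik %.4f, %s\n",
    x$settings$kind, x$settings$penalty$kind, x$settings$penalty$strength,
    x$value, x$logLik,
    if (x$converged) "converged" else "iteration limit reached"))
  invisible(x)
}

#' Cross-validated penalty-strength selection
#'
#' Splits the samples into \code{folds} folds by a seeded random
#' permutation followed by contiguous blocks, fits the model on all but one
#' fold for every strength on the grid, and scores each strength by the
#' mean per-sample log-likelihood on the held-out folds.  The strength with
#' the best mean score is selected (exact ties go to the smaller strength)
#' and the model is refit on the full dataset at that strength.
#'
#' @inheritParams fit_mhn
#' @param grid vector of candidate penalty strengths (default 9 log-spaced
#'   values from \code{1e-4} to \code{1}).
#' @param folds number of folds (default 5, minimum 2).
#' @param seed integer seed for the fold assignment; the global RNG state
#'   is restored afterwards.
#' @param penalty_kind penalty family to tune (\code{"l1"}, \code{"l2"} or
#'   \code{"symmetric"}).
#' @param smoothing,penalize_observation passed to [penalty_spec()].
#' @return an object of class \code{"mhn_cv"}: list with \code{grid},
#'   \code{fold_scores} (strengths x folds matrix), \code{mean_scores},
#'   \code{selected_strength} and \code{final_fit}.
#' @export
cv_mhn <- function(data, grid = 10^seq(-4, 0, length.out = 9), folds = 5L,
                   seed = 1L, penalty_kind = c("l1", "l2", "symmetric"),
                   kind = c("observation_aware", "classic"),
                   smoothing = 1e-4, penalize_observation = TRUE,
                   max_iter = 500L, tol = 1e-6) {
  penalty_kind <- match.arg(penalty_kind)
  kind <- match.arg(kind)
  data <- validate_dataset(data)
  N <- nrow(data)
  if (length(grid) < 1L)
    stop("the strength grid must be non-empty")
  folds <- as.integer(folds)
  if (folds < 2L)
    stop("cross-validation needs at least 2 folds")
  if (N < folds)
    stop("more folds (", folds, ") than samples (", N,
         "): some fold would be empty")
  perm <- with_seed(seed, sample.int(N))
  bounds <- floor(seq(0, N, length.out = folds + 1L))
  fold_id <- integer(N)
  for (f in seq_len(folds))
    fold_id[perm[(bounds[f] + 1L):bounds[f + 1L]]] <- f
  fold_scores <- matrix(NA_real_, length(grid), folds,
                        dimnames = list(signif(grid, 6), NULL))
  for (gi in seq_along(grid)) {
    spec <- penalty_spec(penalty_kind, strength = grid[gi],
                         smoothing = smoothing,
                         penalize_observation = penalize_observation)
    for (f in seq_len(folds)) {
      train <- data[fold_id != f, , drop = FALSE]
      held <- data[fold_id == f, , drop = FALSE]
      fit <- fit_mhn(train, penalty = spec, kind = kind,
                     max_iter = max_iter, tol = tol)
      fold_scores[gi, f] <- log_likelihood(fit$model, held) / nrow(held)
    }
  }
  mean_scores <- rowMeans(fold_scores)
  cand <- which(mean_scores == max(mean_scores))
  best <- cand[which.min(grid[cand])]
  final_spec <- penalty_spec(penalty_kind, strength = grid[best],
                             smoothing = smoothing,
                             penalize_observation = penalize_observation)
  final_fit <- fit_mhn(data, penalty = final_spec, kind = kind,
                       max_iter = max_iter, tol = tol)
  structure(list(grid = grid, fold_scores = fold_scores,
                 mean_scores = mean_scores,
                 selected_strength = grid[best],
                 final_fit = final_fit,
                 seed = seed, folds = folds),
            class = "mhn_cv")
}

#' @export
print.mhn_cv <- function(x, ...) {
  cat(sprintf("MHN cross-validation over %d strengths, %d folds\n",
              length(x$grid), x$folds))
  tab <- data.frame(strength = x$grid, mean_score = x$mean_scores)
  print(tab, row.names = FALSE)
  cat(sprintf("selected strength: %g\n", x$selected_strength))
  invisible(x)
}

# evaluate expr with a fixed seed, restoring the caller-visible RNG state
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed)
      assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
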