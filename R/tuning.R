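#' Bayesian hyperparameter search (GP surrogate + expected improvement)
#'
#' Maximises `objective` over a box of numeric hyperparameters. With
#' `method = "gp"`, a Gaussian-process regression (RBF kernel on inputs
#' rescaled to the unit cube, small nugget) is fitted to the evaluations so
#' far and the next point maximises expected improvement over a seeded
#' random candidate pool; `method = "random"` is pure random search.
#'
#' @param space Named list of length-2 numeric bounds, e.g.
#'   `list(C = c(1e-4, 100))`. Optional attribute-free log scaling is the
#'   caller's responsibility (pass log-bounds and exponentiate in the
#'   objective).
#' @param objective Function taking a named list of parameter values and
#'   returning a scalar to maximise.
#' @param n_iter Total number of objective evaluations (default 100).
#' @param method `"gp"` or `"random"`.
#' @param seed RNG seed.
#' @param n_initial Random initial design size before the GP takes over.
#' @return List with `best_config` (named list), `best_value`, and `trace`
#'   (tibble of all evaluations in order).
#' @export
tune_hyperparameters <- function(space, objective, n_iter = 100,
                                 method = c("gp", "random"), seed = 1,
                                 n_initial = 10) {
  method <- match.arg(method)
  if (length(space) == 0) abort("empty search space")
  lo <- vapply(space, `[[`, 0, 1)
  hi <- vapply(space, `[[`, 0, 2)
  if (any(!is.finite(lo)) || any(!is.finite(hi)) || any(hi <= lo)) {
    abort("invalid space bounds: need finite lower < upper")
  }
  p <- length(space)
  nms <- names(space)
  as_config <- function(u) {
    stats::setNames(as.list(lo + u * (hi - lo)), nms)
  }
  with_seed(seed, {
    n0 <- min(n_initial, n_iter)
    u_mat <- matrix(runif(n0 * p), ncol = p)
    vals <- apply(u_mat, 1, function(u) objective(as_config(u)))
    while (nrow(u_mat) < n_iter) {
      if (method == "random") {
        u_next <- runif(p)
      } else {
        gp <- gp_fit(u_mat, vals)
        cand <- matrix(runif(500 * p), ncol = p)
        pred <- gp_predict(gp, cand)
        ei <- expected_improvement(pred$mean, pred$sd, max(vals))
        u_next <- cand[which.max(ei), ]
      }
      u_mat <- rbind(u_mat, u_next)
      vals <- c(vals, objective(as_config(u_next)))
    }
    best <- which.max(vals)
    trace <- tibble::as_tibble(as.data.frame(
      sweep(sweep(u_mat, 2, hi - lo, "*"), 2, lo, "+")
    ))
    names(trace) <- nms
    trace$value <- vals
    list(
      best_config = as_config(u_mat[best, ]),
      best_value = vals[best],
      trace = trace
    )
  })
}

# RBF-kernel GP regression on the unit cube; fixed length-scale and nugget
# chosen for low-dimensional hyperparameter surfaces.
gp_fit <- function(x, y, lengthscale = 0.3, nugget = 1e-6) {
  mu <- mean(y)
  s <- stats::sd(y)
  if (s == 0) s <- 1
  yc <- (y - mu) / s
  k <- rbf_kernel(x, x, lengthscale)
  diag(k) <- diag(k) + nugget
  l <- chol(k)
  alpha <- backsolve(l, forwardsolve(t(l), yc))
  list(x = x, l = l, alpha = alpha, mu = mu, s = s,
       lengthscale = lengthscale)
}

gp_predict <- function(gp, xnew) {
  ks <- rbf_kernel(xnew, gp$x, gp$lengthscale)
  mean_c <- as.numeric(ks %*% gp$alpha)
  v <- forwardsolve(t(gp$l), t(ks))
  var_c <- pmax(1 - colSums(v^2), 1e-12)
  list(mean = gp$mu + gp$s * mean_c, sd = gp$s * sqrt(var_c))
}

rbf_kernel <- function(a, b, lengthscale) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  exp(-pmax(d2, 0) / (2 * lengthscale^2))
}

expected_improvement <- function(mean, sd, best) {
  z <- (mean - best) / sd
  (mean - best) * pnorm(z) + sd * stats::dnorm(z)
}
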