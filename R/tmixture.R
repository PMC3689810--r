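#' Location-scale Student's-t density
#'
#' @param x Numeric vector.
#' @param mu Location.
#' @param sigma Scale (> 0).
#' @param nu Degrees of freedom (> 0).
#' @param log Return log density?
#' @return Density values.
#' @export
dt_ls <- function(x, mu, sigma, nu, log = FALSE) {
  z <- (x - mu) / sigma
  out <- dt(z, df = nu, log = TRUE) - base::log(sigma)
  if (log) out else exp(out)
}

.mix_loglik <- function(x, par) {
  la <- base::log(par$w[1]) + dt_ls(x, par$mu[1], par$sigma[1], par$nu[1], log = TRUE)
  lx <- base::log(par$w[2]) + dt_ls(x, par$mu[2], par$sigma[2], par$nu[2], log = TRUE)
  m <- pmax(la, lx)
  sum(m + base::log(exp(la - m) + exp(lx - m)))
}

#' Fit a two-component Student's-t mixture by maximum likelihood
#'
#' Models corrected-difference scores as a mixture of an autosomal component
#' (centred at a negative value near `-pi`) and an X-linked component
#' (centred near zero), each a location-scale Student's t.  Fitting uses EM
#' with the scale-mixture representation of the t distribution: the E step
#' computes component responsibilities and the latent precision weights
#' `u = (nu + 1) / (nu + z^2)`; the M step updates weights, locations and
#' scales in closed form, then (unless `nu` is fixed) maximizes the observed
#' log-likelihood over each component's degrees of freedom numerically
#' (an ECME step, so the log-likelihood is non-decreasing at every
#' iteration).  Several restarts are run from jittered initial values and
#' the best log-likelihood is kept; components are relabelled so that the
#' first (autosomal) component has the smaller mean.
#'
#' Initialization follows the scientific expectation: the X component starts
#' at zero (brother-male differences on the X match population diversity),
#' the autosomal component at the median of the negative half of the data,
#' with MAD-based scales and an autosomal weight of 0.85.
#'
#' @param x Numeric vector of corrected differences (at least 20 finite
#'   values).
#' @param nu Fix the degrees of freedom at this value (both components)
#'   instead of estimating them; `NULL` (default) estimates per component.
#' @param n_restarts Number of jittered restarts beyond the deterministic
#'   start.
#' @param max_iter,tol EM stopping rule: stop when the log-likelihood
#'   improves by less than `tol` for three consecutive iterations, or at
#'   `max_iter`.
#' @param weight_floor Minimum mixing weight; a fitted weight at or below
#'   the floor flags a degenerate (effectively single-component) fit.
#' @param seed Seed for the restart jitter.
#' @return A `t_mixture_fit` object with elements `w`, `mu`, `sigma`, `nu`
#'   (each length 2, component order autosome then X), `loglik`, `trace`,
#'   `converged`, `degenerate`, `n`, `iterations`.
#' @export
fit_t_mixture <- function(x, nu = NULL, n_restarts = 5, max_iter = 500,
                          tol = 1e-8, weight_floor = 1e-3, seed = 1L) {
  x <- x[is.finite(x)]
  if (length(x) < 20) stop_input("at least 20 finite values are required")
  if (diff(range(x)) == 0) stop_input("degenerate data: all values are equal")

  neg <- x[x < 0]
  s0 <- max(mad(x) / 2, diff(range(x)) / 100, .Machine$double.eps)
  base_init <- list(
    w = c(0.85, 0.15),
    mu = c(if (length(neg) > 1) median(neg) else min(x), 0),
    sigma = c(s0, s0),
    nu = c(nu %||% 5, nu %||% 5)
  )
  inits <- list(base_init)
  local_seed(derive_seed(seed, 40L), {
    for (r in seq_len(n_restarts)) {
      jit <- base_init
      jit$mu <- base_init$mu + runif(2, -1, 1) * s0 * 2
      jit$sigma <- base_init$sigma * exp(runif(2, -0.7, 0.7))
      jit$w <- pmin(pmax(base_init$w + runif(2, -0.2, 0.2), 0.05), 0.95)
      jit$w <- jit$w / sum(jit$w)
      inits[[r + 1L]] <- jit
    }
  })

  fits <- purrr::map(inits, function(init) {
    .em_t_mixture(x, init, nu_fixed = nu, max_iter = max_iter, tol = tol)
  })
  best <- fits[[which.max(vapply(fits, function(f) f$loglik, 0))]]

  # label identifiability: component 1 (autosomal) has the smaller mean
  if (best$mu[1] > best$mu[2]) {
    ord <- c(2L, 1L)
    best$w <- best$w[ord]; best$mu <- best$mu[ord]
    best$sigma <- best$sigma[ord]; best$nu <- best$nu[ord]
  }
  best$degenerate <- any(best$w <= weight_floor)
  if (best$degenerate) {
    warn("mixture fit is degenerate: a component's weight collapsed to the floor")
  }
  if (!best$converged) {
    warn("EM did not converge within `max_iter` iterations; returning the flagged fit")
  }
  best$n <- length(x)
  structure(best, class = "t_mixture_fit")
}

.em_t_mixture <- function(x, par, nu_fixed, max_iter, tol) {
  n <- length(x)
  ll_old <- .mix_loglik(x, par)
  trace <- ll_old
  stable <- 0L
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    # E step: responsibilities (log space) and precision weights
    l1 <- base::log(par$w[1]) + dt_ls(x, par$mu[1], par$sigma[1], par$nu[1], log = TRUE)
    l2 <- base::log(par$w[2]) + dt_ls(x, par$mu[2], par$sigma[2], par$nu[2], log = TRUE)
    m <- pmax(l1, l2)
    den <- m + base::log(exp(l1 - m) + exp(l2 - m))
    r1 <- exp(l1 - den)
    r2 <- 1 - r1
    z1 <- ((x - par$mu[1]) / par$sigma[1])^2
    z2 <- ((x - par$mu[2]) / par$sigma[2])^2
    u1 <- (par$nu[1] + 1) / (par$nu[1] + z1)
    u2 <- (par$nu[2] + 1) / (par$nu[2] + z2)
    # M step: weights, locations, scales
    par$w <- pmax(c(sum(r1), sum(r2)) / n, 1e-12)
    par$w <- par$w / sum(par$w)
    par$mu[1] <- sum(r1 * u1 * x) / sum(r1 * u1)
    par$mu[2] <- sum(r2 * u2 * x) / sum(r2 * u2)
    par$sigma[1] <- sqrt(max(sum(r1 * u1 * (x - par$mu[1])^2) / sum(r1),
                             .Machine$double.xmin))
    par$sigma[2] <- sqrt(max(sum(r2 * u2 * (x - par$mu[2])^2) / sum(r2),
                             .Machine$double.xmin))
    # ECME step: maximize the observed log-likelihood over each nu
    if (is.null(nu_fixed)) {
      for (j in 1:2) {
        obj <- function(lnu) {
          p <- par; p$nu[j] <- exp(lnu)
          .mix_loglik(x, p)
        }
        opt <- optimize(obj, interval = base::log(c(0.5, 200)), maximum = TRUE)
        if (opt$objective > .mix_loglik(x, par)) par$nu[j] <- exp(opt$maximum)
      }
    }
    ll <- .mix_loglik(x, par)
    trace <- c(trace, ll)
    stable <- if (ll - ll_old < tol) stable + 1L else 0L
    ll_old <- ll
    if (stable >= 3L) break
  }
  list(w = par$w, mu = par$mu, sigma = par$sigma, nu = par$nu,
       loglik = ll_old, trace = trace, iterations = iter,
       converged = stable >= 3L)
}

#' @export
print.t_mixture_fit <- function(x, ...) {
  cat("<t_mixture_fit> two-component location-scale Student's t\n")
  cat(sprintf("  autosomal: w = %.3f, mu = %.3g, sigma = %.3g, nu = %.3g\n",
              x$w[1], x$mu[1], x$sigma[1], x$nu[1]))
  cat(sprintf("  X-linked:  w = %.3f, mu = %.3g, sigma = %.3g, nu = %.3g\n",
              x$w[2], x$mu[2], x$sigma[2], x$nu[2]))
  cat(sprintf("  logLik = %.4f after %d iterations (%s%s)\n", x$loglik,
              x$iterations, if (x$converged) "converged" else "NOT converged",
              if (isTRUE(x$degenerate)) ", degenerate" else ""))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a t-mixture fit
#'
#' @param x A `t_mixture_fit`.
#' @param ... Unused.
#' @return Tibble with one row per component.
#' @export
tidy.t_mixture_fit <- function(x, ...) {
  tibble(component = c("autosome", "X"), weight = x$w, mu = x$mu,
         sigma = x$sigma, nu = x$nu)
}

#' One-row summary of a t-mixture fit
#'
#' @param x A `t_mixture_fit`.
#' @param ... Unused.
#' @return One-row tibble.
#' @export
glance.t_mixture_fit <- function(x, ...) {
  tibble(logLik = x$loglik, n = x$n, iterations = x$iterations,
         converged = x$converged, degenerate = isTRUE(x$degenerate))
}

#' Posterior probability that a corrected difference is X-linked
#'
#' `p_x = w_X t_X(cd) / (w_A t_A(cd) + w_X t_X(cd))`, evaluated in log
#' space so extreme scores cannot underflow.
#'
#' @param cd Numeric vector of corrected differences.
#' @param fit A [fit_t_mixture()] result.
#' @return Probabilities in `[0, 1]`.
#' @export
x_probability <- function(cd, fit) {
  la <- base::log(fit$w[1]) + dt_ls(cd, fit$mu[1], fit$sigma[1], fit$nu[1], log = TRUE)
  lx <- base::log(fit$w[2]) + dt_ls(cd, fit$mu[2], fit$sigma[2], fit$nu[2], log = TRUE)
  1 / (1 + exp(la - lx))
}
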