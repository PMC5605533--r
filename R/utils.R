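# Internal helpers shared across modules.

# Evaluate expr with a temporarily seeded RNG, restoring the caller's RNG
# state afterwards so generators never perturb the global random stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

stopifnot_uniform_grid <- function(x, what = "grid", rel_tol = 1e-8) {
  if (length(x) < 3L) stop(what, " must have at least 3 points", call. = FALSE)
  d <- diff(x)
  if (any(d <= 0)) stop(what, " must be strictly increasing", call. = FALSE)
  if ((max(d) - min(d)) > rel_tol * mean(d)) {
    stop(what, " must be uniform (equally spaced)", call. = FALSE)
  }
  invisible(mean(d))
}

stopifnot_fraction <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop("'", name, "' must lie in [0, 1]", call. = FALSE)
  }
  invisible(x)
}

stopifnot_positive <- function(x, name, strict = TRUE) {
  bad <- if (strict) any(!is.finite(x) | x <= 0) else any(!is.finite(x) | x < 0)
  if (bad) {
    stop("'", name, "' must be ", if (strict) "> 0" else ">= 0", call. = FALSE)
  }
  invisible(x)
}

# Normalised line shapes (unit area in E).
lorentzian_area1 <- function(e, hwhm) {
  (hwhm / pi) / (e^2 + hwhm^2)
}

gaussian_area1 <- function(e, fwhm) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  stats::dnorm(e, mean = 0, sd = sigma)
}

# Weighted-least-squares wrapper around minpack.lm::nls.lm (Levenberg-
# Marquardt with box bounds) returning estimates, standard errors, covariance
# and convergence status without throwing on non-convergence. Standard errors
# follow the usual nonlinear-regression convention of scaling (J'J)^-1 by the
# reduced chi-square.
wls_fit <- function(fn, start, lower, upper, y, sigma, ...) {
  resid_fn <- function(p) (y - fn(p, ...)) / sigma
  res <- tryCatch(
    minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                       fn = resid_fn,
                       control = minpack.lm::nls.lm.control(
                         maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
    error = function(e) e
  )
  k <- length(start)
  n <- length(y)
  fail <- function(msg) {
    list(converged = FALSE, message = msg,
         estimate = start, se = stats::setNames(rep(NA_real_, k), names(start)),
         vcov = matrix(NA_real_, k, k), rss = NA_real_, n = n)
  }
  if (inherits(res, "error")) return(fail(conditionMessage(res)))
  if (!res$info %in% 1:4) return(fail(res$message))
  est <- stats::setNames(res$par, names(start))
  rss <- res$deviance
  s2 <- if (n > k) rss / (n - k) else NA_real_
  vc <- tryCatch(solve(res$hessian) * s2, error = function(e) {
    matrix(NA_real_, k, k)
  })
  se <- stats::setNames(sqrt(pmax(diag(vc), 0)), names(start))
  list(converged = TRUE, message = res$message, estimate = est, se = se,
       vcov = vc, rss = rss, n = n, fit = res)
}

# Small-sample corrected Akaike information criterion from a weighted RSS
# (Gaussian errors with known weights).
aicc_from_rss <- function(rss, n, k) {
  aic <- n * log(rss / n) + 2 * k
  if (n - k - 1 > 0) aic + 2 * k * (k + 1) / (n - k - 1) else Inf
}
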