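#' Parametric distribution specification for a model input
#'
#' Health-economic models conventionally summarise an uncertain input by a
#' deterministic (base-case) value and a low/high parametric range, together
#' with a distribution family used in probabilistic sensitivity analysis:
#' gamma for costs, beta for utilities, normal for stage fractions, and
#' `"fixed"` for inputs held at their base-case value.
#'
#' The low/high range is interpreted as a central 95% interval, so the
#' standard error is `(high - low) / 3.92`. Families are fitted by the method
#' of moments from `(deterministic, se)`.
#'
#' @param family One of `"normal"`, `"gamma"`, `"beta"`, `"fixed"`.
#' @param deterministic Base-case value (also the fitted mean).
#' @param low,high Low/high parametric bounds; ignored for `"fixed"`.
#' @return A `dist_spec` object (a named list).
#' @examples
#' dist_spec("gamma", 13390, 6337, 20443)
#' dist_spec("fixed", 1.13)
#' @export
dist_spec <- function(family = c("normal", "gamma", "beta", "fixed"),
                      deterministic, low = deterministic, high = deterministic) {
  family <- match.arg(family)
  spec <- structure(
    list(family = family, deterministic = deterministic, low = low, high = high),
    class = "dist_spec"
  )
  validate_dist_spec(spec)
  spec
}

validate_dist_spec <- function(spec, name = "parameter") {
  with(spec, {
    if (!is.finite(deterministic)) {
      abort(sprintf("%s: deterministic value must be finite", name))
    }
    if (family != "fixed") {
      if (!(low <= deterministic && deterministic <= high)) {
        abort(sprintf("%s: requires low <= deterministic <= high (got %g, %g, %g)",
                      name, low, deterministic, high))
      }
    }
    if (family == "gamma" && deterministic <= 0) {
      abort(sprintf("%s: gamma requires deterministic > 0", name))
    }
    if (family == "beta" && (deterministic < 0 || deterministic > 1)) {
      abort(sprintf("%s: beta requires deterministic in [0, 1]", name))
    }
  })
  invisible(spec)
}

#' @export
print.dist_spec <- function(x, ...) {
  cat(sprintf("<dist_spec> %s(%g) [%g, %g]\n", x$family, x$deterministic,
              x$low, x$high))
  invisible(x)
}

is_dist_spec <- function(x) inherits(x, "dist_spec")

#' Fit a sampling recipe to a distribution specification
#'
#' Converts the `(deterministic, low, high)` summary into the internal
#' parameters of the named family, treating `(low, high)` as a 95% interval
#' (`se = (high - low) / 3.92`) and matching moments:
#' gamma `shape = (mean/se)^2`, `scale = mean/shape`; beta
#' `alpha + beta = mean(1 - mean)/se^2 - 1`; normal `(mean, se)`.
#'
#' A beta specification with a deterministic value of exactly 0 or 1 is
#' degenerate (the moment system has no solution there) and is fitted as a
#' point mass, matching the convention of carrying no disutility for
#' false-positive findings in the base case. Infeasible beta moments strictly
#' inside (0, 1) are an error.
#'
#' @param spec A [dist_spec()].
#' @param name Parameter name used in error messages.
#' @return A `dist_fit` object with elements `family` and `par`.
#' @examples
#' fit_distribution(dist_spec("gamma", 13390, 6337, 20443))
#' @export
fit_distribution <- function(spec, name = "parameter") {
  validate_dist_spec(spec, name)
  m <- spec$deterministic
  se <- (spec$high - spec$low) / 3.92
  fit <- switch(spec$family,
    fixed = list(value = m),
    normal = list(mean = m, sd = se),
    gamma = {
      if (se == 0) list(value = m)
      else {
        shape <- (m / se)^2
        list(shape = shape, scale = m / shape)
      }
    },
    beta = {
      if (se == 0 || m == 0 || m == 1) {
        # degenerate at the boundary: point mass
        list(value = m)
      } else {
        ab <- m * (1 - m) / se^2 - 1
        alpha <- m * ab
        beta <- (1 - m) * ab
        if (alpha <= 0 || beta <= 0) {
          abort(sprintf(
            "%s: infeasible beta moments (mean %g, se %g imply alpha %g, beta %g)",
            name, m, se, alpha, beta))
        }
        list(alpha = alpha, beta = beta)
      }
    }
  )
  structure(list(family = spec$family, par = fit, deterministic = m),
            class = "dist_fit")
}

#' Draw samples from a fitted distribution
#'
#' @param fit A `dist_fit` from [fit_distribution()].
#' @param n Number of draws.
#' @return Numeric vector of length `n`, within the family's support.
#' @export
draw_dist <- function(fit, n) {
  stopifnot(inherits(fit, "dist_fit"))
  p <- fit$par
  if (!is.null(p$value)) return(rep(p$value, n))
  switch(fit$family,
    normal = rnorm(n, p$mean, p$sd),
    gamma = rgamma(n, shape = p$shape, scale = p$scale),
    beta = rbeta(n, p$alpha, p$beta)
  )
}

#' @export
print.dist_fit <- function(x, ...) {
  cat(sprintf("<dist_fit> %s: %s\n", x$family,
              paste(names(x$par), signif(unlist(x$par), 6),
                    sep = "=", collapse = ", ")))
  invisible(x)
}
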