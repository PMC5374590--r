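#' Beta-uniform mixture density for p-values
#'
#' Density of the two-component beta-uniform mixture (BUM) model of a p-value
#' distribution: nulls are Uniform(0, 1), signals are Beta(a, 1) with
#' 0 < a < 1, mixed with weight `lambda` on the uniform component:
#' \deqn{f(x \mid a, \lambda) = \lambda + (1 - \lambda)\, a\, x^{a-1}.}
#'
#' @param x Numeric vector of p-values, each in (0, 1].
#' @param a Beta shape parameter in (0, 1).
#' @param lambda Mixture weight of the uniform (null) component, in (0, 1).
#' @return Numeric vector of densities (all > 0).
#' @examples
#' bum_pdf(0.25, a = 0.5, lambda = 0.5)  # 1.0
#' bum_pdf(1, a = 0.3, lambda = 0.6)     # lambda + (1 - lambda) * a
#' @export
bum_pdf <- function(x, a, lambda) {
  if (inherits(a, "bum_fit")) {
    lambda <- a$lambda
    a <- a$a
  }
  check_unit_open(a, "a")
  check_unit_open(lambda, "lambda")
  if (any(!is.finite(x)) || any(x <= 0) || any(x > 1)) {
    abort("`x` must contain p-values in (0, 1].")
  }
  lambda + (1 - lambda) * a * x^(a - 1)
}

#' Fit the beta-uniform mixture to a set of p-values
#'
#' Maximum-likelihood fit of the BUM model over the open unit square
#' (a, lambda) in (0, 1)^2. Optimisation is bounded quasi-Newton (L-BFGS-B on
#' the box \[1e-6, 1 - 1e-6\]^2) restarted from the five best points of a
#' coarse grid; the restart with the highest log-likelihood wins. The fit is
#' deterministic for a given input.
#'
#' p-values of exactly zero are clamped to `p_min` before fitting, because the
#' Beta(a, 1) density diverges at zero; p = 1 is retained.
#'
#' @param data A data frame with a `pvalue` column (a `gene_id` column, if
#'   present, is carried along), or a bare numeric vector of p-values.
#' @param p_min Positive clamp applied to zero p-values (default `1e-300`).
#' @return An object of class `bum_fit`: a list with elements `a`, `lambda`,
#'   `log_likelihood`, `n`, and `pvalues` (the clamped vector used for the
#'   fit). Supports [tidy()], [glance()] and [autoplot()].
#' @seealso [bum_tau()], [scoring_scheme()], [bum_pi_hat()]
#' @examples
#' set.seed(1)
#' p <- c(runif(300), rbum(100, a = 0.2, lambda = 0))
#' fit <- fit_bum(p)
#' glance(fit)
#' @export
fit_bum <- function(data, p_min = 1e-300) {
  x <- extract_pvalues(data)
  if (length(x) < 10) {
    abort("At least 10 p-values are required to fit the mixture.")
  }
  x <- clamp_pvalues(x, p_min)
  if (length(unique(x)) == 1L) {
    warn("All p-values are identical; the mixture fit is degenerate.")
  }
  lx <- log(x)
  n <- length(x)

  nll <- function(par) {
    d <- par[2] + (1 - par[2]) * par[1] * exp((par[1] - 1) * lx)
    -sum(log(d))
  }

  # coarse grid, then bounded quasi-Newton from the 5 best grid points
  grid <- expand.grid(a = seq(0.1, 0.9, by = 0.2), lambda = seq(0.1, 0.9, by = 0.2))
  grid_val <- apply(grid, 1L, nll)
  starts <- grid[order(grid_val)[seq_len(5L)], , drop = FALSE]

  eps <- 1e-6
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    opt <- tryCatch(
      optim(as.numeric(starts[i, ]), nll,
        method = "L-BFGS-B",
        lower = c(eps, eps), upper = c(1 - eps, 1 - eps),
        control = list(factr = 1e7, maxit = 500L)
      ),
      error = function(e) NULL
    )
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) abort("BUM maximum-likelihood optimisation failed.")

  structure(
    list(
      a = best$par[1],
      lambda = best$par[2],
      log_likelihood = -best$value,
      n = n,
      pvalues = x
    ),
    class = "bum_fit"
  )
}

#' @export
print.bum_fit <- function(x, ...) {
  cat("Beta-uniform mixture fit (", x$n, " p-values)\n", sep = "")
  cat(sprintf("  a       = %.4g\n", x$a))
  cat(sprintf("  lambda  = %.4g\n", x$lambda))
  cat(sprintf("  pi-hat  = %.4g\n", bum_pi_hat(x)))
  cat(sprintf("  log-lik = %.4f\n", x$log_likelihood))
  invisible(x)
}

#' Upper bound on the null proportion of a BUM fit
#'
#' Returns \eqn{\hat\pi = \lambda + (1 - \lambda) a}, the maximum proportion
#' of the p-values that could arise from the null hypothesis (the BUM density
#' evaluated at x = 1, its minimum).
#'
#' @param fit A `bum_fit`, or a numeric `a` (then supply `lambda`).
#' @param lambda Mixture weight, only when `fit` is a bare numeric `a`.
#' @return A single number in (0, 1).
#' @export
bum_pi_hat <- function(fit, lambda = NULL) {
  if (inherits(fit, "bum_fit")) {
    a <- fit$a
    lambda <- fit$lambda
  } else {
    a <- fit
  }
  lambda + (1 - lambda) * a
}

#' FDR-controlling significance threshold tau
#'
#' The p-value threshold at which the estimated upper bound of the false
#' discovery rate equals `alpha`:
#' \deqn{\tau = \left(\frac{\hat\pi - \alpha\lambda}{\alpha(1-\lambda)}\right)^{1/(a-1)}}
#' with \eqn{\hat\pi = \lambda + (1-\lambda)a}. Node scores are zero at tau
#' and positive below it.
#'
#' When the base of the power is below 1 (very permissive `alpha`), the formula
#' yields tau > 1; the value is clipped to 1 with a warning, so that every
#' p-value scores positively.
#'
#' @param fit A `bum_fit`, or a numeric `a` (then supply `lambda`).
#' @param alpha Target FDR level in (0, 1).
#' @param lambda Mixture weight, only when `fit` is a bare numeric `a`.
#' @return A single number in (0, 1].
#' @examples
#' bum_tau(0.113, alpha = 1e-4, lambda = 9.07e-2)  # ~1.76e-4
#' @export
bum_tau <- function(fit, alpha, lambda = NULL) {
  if (inherits(fit, "bum_fit")) {
    a <- fit$a
    lambda <- fit$lambda
  } else {
    a <- fit
  }
  check_unit_open(alpha, "alpha")
  pi_hat <- lambda + (1 - lambda) * a
  if (alpha * lambda >= pi_hat) {
    abort(sprintf(
      "Invalid FDR level: alpha * lambda (%.3g) must be < pi-hat (%.3g).",
      alpha * lambda, pi_hat
    ))
  }
  base <- (pi_hat - alpha * lambda) / (alpha * (1 - lambda))
  tau <- base^(1 / (a - 1))
  if (tau > 1) {
    warn(sprintf(
      "alpha = %.3g exceeds the estimated null proportion; tau clipped to 1 (all p-values significant).",
      alpha
    ))
    tau <- 1
  }
  tau
}

#' Build an FDR-calibrated scoring scheme from a BUM fit
#'
#' Packages the fitted shape `a`, the threshold `tau` at the requested FDR
#' level, `pi_hat` and `alpha` into a scheme usable by [node_score()] and
#' [score_nodes()].
#'
#' @param fit A `bum_fit`.
#' @param alpha Target FDR level in (0, 1).
#' @return An object of class `scoring_scheme` with fields `a`, `tau`,
#'   `alpha`, `pi_hat`.
#' @export
scoring_scheme <- function(fit, alpha) {
  stopifnot(inherits(fit, "bum_fit"))
  structure(
    list(
      a = fit$a,
      tau = bum_tau(fit, alpha),
      alpha = alpha,
      pi_hat = bum_pi_hat(fit)
    ),
    class = "scoring_scheme"
  )
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat(sprintf(
    "FDR scoring scheme: a = %.4g, tau = %.4g (alpha = %.3g, pi-hat = %.4g)\n",
    x$a, x$tau, x$alpha, x$pi_hat
  ))
  invisible(x)
}

#' Additive FDR node score for a p-value
#'
#' The log-ratio of the signal density at `x` to the signal density at the
#' threshold `tau` (natural log):
#' \deqn{S^{FDR}(x) = (a - 1)(\log x - \log \tau),}
#' positive exactly when x < tau, zero at x = tau, strictly decreasing in x.
#'
#' @param x Numeric vector of p-values in (0, 1].
#' @param scheme A `scoring_scheme`, or a numeric `a` (then supply `tau`).
#' @param tau Threshold, only when `scheme` is a bare numeric `a`.
#' @return Numeric vector of scores.
#' @export
node_score <- function(x, scheme, tau = NULL) {
  if (inherits(scheme, "scoring_scheme")) {
    a <- scheme$a
    tau <- scheme$tau
  } else {
    a <- scheme
  }
  if (any(!is.finite(x)) || any(x <= 0) || any(x > 1)) {
    abort("`x` must contain p-values in (0, 1].")
  }
  (a - 1) * (log(x) - log(tau))
}

#' Score a table of gene-level p-values
#'
#' @param data Data frame with `gene_id` and `pvalue` columns.
#' @param scheme A `scoring_scheme` (see [scoring_scheme()]).
#' @param p_min Positive clamp applied to zero p-values before scoring.
#' @return The input as a tibble with an added `score` column.
#' @export
score_nodes <- function(data, scheme, p_min = 1e-300) {
  data <- as_tibble(data)
  if (!all(c("gene_id", "pvalue") %in% names(data))) {
    abort("`data` must have `gene_id` and `pvalue` columns.")
  }
  dplyr::mutate(data, score = node_score(clamp_pvalues(.data$pvalue, p_min), scheme))
}

#' Sample from the beta-uniform mixture
#'
#' Beta(a, 1) variates are drawn by the inverse transform `u^(1/a)`, so the
#' same uniform stream reproduces the same sample in any language.
#'
#' @param n Number of draws.
#' @param a Beta shape in (0, 1).
#' @param lambda Mixture weight of the uniform component in \[0, 1\].
#' @return Numeric vector of p-values in (0, 1).
#' @export
rbum <- function(n, a, lambda) {
  u <- runif(n)
  is_null <- runif(n) < lambda
  ifelse(is_null, u, u^(1 / a))
}

#' @rdname fit_bum
#' @param x A `bum_fit` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.bum_fit <- function(x, ...) {
  tibble(
    term = c("a", "lambda"),
    estimate = c(x$a, x$lambda)
  )
}

#' @rdname fit_bum
#' @exportS3Method generics::glance
glance.bum_fit <- function(x, ...) {
  tibble(
    a = x$a,
    lambda = x$lambda,
    pi_hat = bum_pi_hat(x),
    log_likelihood = x$log_likelihood,
    n = x$n
  )
}

# ---- internal helpers --------------------------------------------------------

extract_pvalues <- function(data) {
  if (is.data.frame(data)) {
    if (!"pvalue" %in% names(data)) abort("`data` must have a `pvalue` column.")
    x <- data$pvalue
  } else {
    x <- as.numeric(data)
  }
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    abort("p-values must lie in [0, 1] (zeros are clamped before fitting).")
  }
  x
}

clamp_pvalues <- function(x, p_min = 1e-300) {
  pmax(x, p_min)
}

check_unit_open <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0 || x >= 1) {
    abort(sprintf("`%s` must be a single number in (0, 1).", name))
  }
  invisible(x)
}
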