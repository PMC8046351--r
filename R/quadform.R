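#' Tail probability of a positive mixture of 1-df chi-squares
#'
#' Computes `P(sum_k lambda_k * chisq_1 > q)`, the null survival function of
#' a variance-component score statistic. The primary route is numerical
#' inversion of the characteristic function (Imhof-type quadrature, the same
#' integral evaluated by Davies' exact method). When the inversion integral
#' cannot resolve a deep tail (p below ~1e-8) the Kuonen saddlepoint
#' approximation is used; if that fails, the Liu et al. moment-matching
#' approximation. The method actually used is recorded in the `"method"`
#' attribute of the result (`"imhof"`, `"saddlepoint"` or `"liu"`).
#'
#' @param q Observed statistic, a single non-negative number.
#' @param lambdas Numeric vector of non-negative mixture weights
#'   (eigenvalues of the null variance form). Values below
#'   `trunc_tol * max(lambdas)` are dropped.
#' @param trunc_tol Relative eigenvalue truncation threshold.
#' @return A p-value in `(0, 1]` with attribute `"method"`.
#' @examples
#' pvalue_mixture_chisq(3.841, 1)        # ~0.05, 1-df chi-square
#' pvalue_mixture_chisq(5.991, c(1, 1))  # ~0.05, 2-df chi-square
#' @export
pvalue_mixture_chisq <- function(q, lambdas, trunc_tol = 1e-8) {
  if (length(q) != 1L || !is.finite(q) || q < 0)
    stop("'q' must be a single non-negative finite number")
  lambdas <- as.numeric(lambdas)
  if (q == 0) {
    p <- 1
    attr(p, "method") <- "exact"
    return(p)
  }
  if (length(lambdas) == 0L || any(!is.finite(lambdas)) || any(lambdas < 0))
    stop("'lambdas' must be a non-empty vector of non-negative finite values")
  lambdas <- lambdas[lambdas > trunc_tol * max(lambdas)]
  if (length(lambdas) == 0L)
    stop("all mixture weights are zero")

  # exact routes where the inversion integral converges slowest
  if (max(lambdas) / min(lambdas) - 1 < 1e-12) {
    p <- stats::pchisq(q / mean(lambdas), df = length(lambdas),
                       lower.tail = FALSE)
    p <- min(max(p, 1e-300), 1)
    attr(p, "method") <- "exact"
    return(p)
  }
  if (length(lambdas) == 2L) {
    p <- .qf_two_lambda(q, max(lambdas), min(lambdas))
    if (!is.na(p) && p > 1e-12) {
      p <- min(p, 1)
      attr(p, "method") <- "exact"
      return(p)
    }
  }

  ans <- .qf_imhof(q, lambdas)
  p <- ans$p
  method <- "imhof"
  # Quadrature resolves the integral to absolute accuracy ~abs.error; deep
  # tails (or a failed integration) are better served by the saddlepoint.
  if (is.na(p) || p <= max(1e-8, 10 * ans$abs.error) || p > 1) {
    p_sp <- .qf_saddlepoint(q, lambdas)
    if (is.na(p_sp)) {
      p <- .qf_liu(q, lambdas)
      method <- "liu"
    } else {
      p <- p_sp
      method <- "saddlepoint"
    }
  }
  p <- min(max(p, 1e-300), 1)
  attr(p, "method") <- method
  p
}

# --- signed mixtures -------------------------------------------------------
# Tail probability P(sum_i a_i chisq_1 > q) for SIGNED weights a, given as
# unique values `lam` with multiplicities `mult`. Used by the exact
# finite-sample gaussian test, whose null is a signed mixture. Imhof's
# inversion integral is valid for signed weights; the saddlepoint serves the
# deep tails; a normal moment-matching approximation is the last resort.
.qf_tail_signed <- function(q, lam, mult) {
  keep <- lam != 0 & mult > 0
  lam <- lam[keep]; mult <- mult[keep]
  if (length(lam) == 0L) return(if (q <= 0) 1 else 0)
  integrand <- function(u) {
    th <- 0.5 * colSums(mult * atan(outer(lam, u))) - 0.5 * q * u
    lr <- 0.25 * colSums(mult * log1p(outer(lam^2, u^2)))
    out <- sin(th) / u * exp(-lr)
    out[u == 0] <- 0.5 * (sum(mult * lam) - q)
    out
  }
  res <- tryCatch(
    stats::integrate(integrand, 0, Inf, subdivisions = 10000L,
                     rel.tol = 1e-10, abs.tol = 1e-13,
                     stop.on.error = FALSE),
    error = function(e) NULL)
  p <- if (!is.null(res) && is.finite(res$value)) 0.5 + res$value / pi
       else NA_real_
  if (is.na(p) || p <= max(1e-8, if (!is.null(res)) 10 * res$abs.error else 0) ||
      p >= 1 - 1e-8) {
    p_sp <- .qf_saddlepoint_signed(q, lam, mult)
    if (!is.na(p_sp)) p <- p_sp
    else {
      mu <- sum(mult * lam); v <- 2 * sum(mult * lam^2)
      p <- stats::pnorm(q, mean = mu, sd = sqrt(v), lower.tail = FALSE)
    }
  }
  min(max(p, 1e-300), 1)
}

.qf_saddlepoint_signed <- function(q, lam, mult) {
  mu <- sum(mult * lam)
  if (abs(q - mu) < 1e-12 * max(abs(lam))) return(0.5)
  K  <- function(z) -0.5 * sum(mult * log1p(-2 * z * lam))
  Kp <- function(z) sum(mult * lam / (1 - 2 * z * lam))
  Kpp <- function(z) 2 * sum(mult * lam^2 / (1 - 2 * z * lam)^2)
  pos <- lam[lam > 0]; neg <- lam[lam < 0]
  upper <- if (length(pos)) 1 / (2 * max(pos)) * (1 - 1e-10) else 1e3
  lower <- if (length(neg)) 1 / (2 * min(neg)) * (1 - 1e-10) else -1e3
  root <- tryCatch(
    stats::uniroot(function(z) Kp(z) - q, lower = lower, upper = upper,
                   tol = .Machine$double.eps^0.75),
    error = function(e) NULL)
  if (is.null(root)) return(NA_real_)
  zh <- root$root
  w <- sign(zh) * sqrt(max(2 * (zh * q - K(zh)), 0))
  v <- zh * sqrt(Kpp(zh))
  if (!is.finite(w) || !is.finite(v) || abs(w) < 1e-8) return(NA_real_)
  stats::pnorm(w + log(v / w) / w, lower.tail = FALSE)
}

# Exact finite-sample tail of the gaussian ratio statistic t = Q / sigma2_hat.
# With r = (I-H) eps, Q = sigma2 * sum_k lam0_k z_k^2 over the d kernel
# eigendirections and sigma2_hat = sigma2/N * sum_{j=1}^N u_j^2 over the
# N = n - q residual dimensions (the z are the first d of the u), so
#   P(t > t_obs) = P( sum_k (lam0_k - t_obs/N) z_k^2
#                     - (t_obs/N) * chisq_{N-d} > 0 ),
# a signed mixture independent of sigma2. Reduces to the plug-in mixture as
# N -> infinity.
.qf_tail_ratio_exact <- function(t_obs, lam0, N) {
  d <- length(lam0)
  if (d == 0L) return(1)
  if (t_obs <= 0) return(1)
  c0 <- t_obs / N
  lam <- c(lam0 - c0, -c0)
  mult <- c(rep(1, d), N - d)
  .qf_tail_signed(0, lam, mult)
}

# critical value on the t = Q/sigma2_hat scale for the exact gaussian null
.qf_ratio_crit <- function(alpha, lam0, N) {
  f <- function(t) .qf_tail_ratio_exact(t, lam0, N) - alpha
  guess <- tryCatch(mixture_chisq_quantile(alpha, lam0),
                    error = function(e) sum(lam0) * 2)
  lo <- guess / 8; hi <- guess * 8
  while (f(hi) > 0) hi <- hi * 2
  while (f(lo) < 0) lo <- lo / 2
  stats::uniroot(f, lower = lo, upper = hi, tol = 1e-9 * guess)$root
}

# two-component tail by conditioning on the first chi-square:
# P(l1 X + l2 Y > q) = P(X > q/l1) + E_X[ P(Y > (q - l1 X)/l2) ; X < q/l1 ]
.qf_two_lambda <- function(q, l1, l2) {
  res <- tryCatch(
    stats::integrate(function(x)
      stats::dchisq(x, 1) *
        stats::pchisq((q - l1 * x) / l2, 1, lower.tail = FALSE),
      lower = 0, upper = q / l1, rel.tol = 1e-12, subdivisions = 5000L,
      stop.on.error = FALSE),
    error = function(e) NULL)
  if (is.null(res) || !is.finite(res$value)) return(NA_real_)
  res$value + stats::pchisq(q / l1, 1, lower.tail = FALSE)
}

# Imhof (1961) inversion integral:
#   P(Q > q) = 1/2 + (1/pi) * int_0^Inf sin(theta(u)) / (u * rho(u)) du
# theta(u) = (1/2) sum atan(lambda_k u) - q u / 2
# rho(u)   = prod (1 + lambda_k^2 u^2)^(1/4)
.qf_imhof <- function(q, lambdas) {
  integrand <- function(u) {
    theta <- 0.5 * colSums(atan(outer(lambdas, u))) - 0.5 * q * u
    # log-scale magnitude to avoid overflow of the product for many lambdas
    lrho <- 0.25 * colSums(log1p(outer(lambdas^2, u^2)))
    out <- sin(theta) / u * exp(-lrho)
    out[u == 0] <- 0.5 * (sum(lambdas) - q)  # limit as u -> 0
    out
  }
  res <- tryCatch(
    stats::integrate(integrand, lower = 0, upper = Inf,
                     subdivisions = 10000L, rel.tol = 1e-10,
                     abs.tol = 1e-13, stop.on.error = FALSE),
    error = function(e) NULL)
  if (is.null(res) || !is.finite(res$value))
    return(list(p = NA_real_, abs.error = Inf))
  list(p = 0.5 + res$value / pi, abs.error = res$abs.error)
}

# Kuonen (1999) saddlepoint approximation to the survival function.
.qf_saddlepoint <- function(q, lambdas) {
  mu <- sum(lambdas)
  if (abs(q - mu) < 1e-10 * mu) return(0.5)
  K  <- function(z) -0.5 * sum(log1p(-2 * z * lambdas))
  Kp <- function(z) sum(lambdas / (1 - 2 * z * lambdas))
  Kpp <- function(z) 2 * sum(lambdas^2 / (1 - 2 * z * lambdas)^2)
  upper <- 1 / (2 * max(lambdas))
  lower <- if (q > mu) 0 else -1e3 / mu
  # K'(z) is increasing; solve K'(z) = q
  root <- tryCatch(
    stats::uniroot(function(z) Kp(z) - q,
                   lower = lower, upper = upper * (1 - 1e-12),
                   tol = .Machine$double.eps^0.75, extendInt = "no"),
    error = function(e) NULL)
  if (is.null(root)) return(NA_real_)
  zh <- root$root
  w <- sign(zh) * sqrt(max(2 * (zh * q - K(zh)), 0))
  v <- zh * sqrt(Kpp(zh))
  if (!is.finite(w) || !is.finite(v) || abs(w) < 1e-10) return(NA_real_)
  stats::pnorm(w + log(v / w) / w, lower.tail = FALSE)
}

# Liu, Tang & Zhang (2009) four-moment chi-square approximation.
.qf_liu <- function(q, lambdas) {
  c1 <- sum(lambdas); c2 <- sum(lambdas^2)
  c3 <- sum(lambdas^3); c4 <- sum(lambdas^4)
  s1 <- c3 / c2^1.5; s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    delta <- s1 * a^3 - a^2
    l <- a^2 - 2 * delta
  } else {
    a <- 1 / s1; delta <- 0; l <- c2^3 / c3^2
  }
  tstar <- (q - c1) / sqrt(2 * c2)
  qnew <- tstar * sqrt(2 * (l + 2 * delta)) + l + delta
  stats::pchisq(qnew, df = l, ncp = delta, lower.tail = FALSE)
}

#' Upper quantile of a positive mixture of 1-df chi-squares
#'
#' Solves `P(sum_k lambda_k chisq_1 > q) = alpha` for `q`. Used by the
#' simulation harness to turn a per-replicate p-value threshold into a single
#' critical value for the score statistic, so that eigen-decompositions and
#' tail integrations are done once per gene rather than once per replicate.
#'
#' @param alpha Upper-tail probability in (0, 1).
#' @param lambdas Non-negative mixture weights.
#' @return The critical value `q_alpha`.
#' @export
mixture_chisq_quantile <- function(alpha, lambdas) {
  if (length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("'alpha' must be a single value in (0, 1)")
  lambdas <- lambdas[lambdas > 0]
  if (length(lambdas) == 0L) stop("'lambdas' must contain positive values")
  # bracket from the scaled chi-square matching the first two moments
  mu <- sum(lambdas); v <- 2 * sum(lambdas^2)
  guess <- mu + sqrt(v) * stats::qnorm(1 - alpha)
  lo <- max(guess / 4, 1e-12); hi <- max(4 * guess, mu * 2)
  f <- function(x) as.numeric(pvalue_mixture_chisq(x, lambdas)) - alpha
  while (f(hi) > 0) hi <- hi * 2
  while (f(lo) < 0) lo <- lo / 2
  stats::uniroot(f, lower = lo, upper = hi, tol = 1e-10 * max(1, guess))$root
}
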