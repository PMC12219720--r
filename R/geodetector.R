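# Geodetector: factor detection (q-statistic) and interaction detection.

#' Discretise a continuous driver into strata
#'
#' @param x numeric vector (NA preserved).
#' @param k number of strata (>= 2).
#' @param method "jenks" (default, natural breaks), "quantile"
#'   (equal-count by rank), or "equal" (equal-interval).
#' @return integer stratum labels 1..k.
#' @export
discretize <- function(x, k = 5L, method = c("jenks", "quantile", "equal")) {
  method <- match.arg(method)
  if (k < 2L) stop("k must be >= 2")
  ok <- !is.na(x)
  if (length(unique(x[ok])) < k)
    stop("not enough distinct values for ", k, " strata")
  out <- rep(NA_integer_, length(x))
  if (method == "jenks") {
    out[ok] <- classify(x[ok], jenks_breaks(x[ok], k))
  } else if (method == "quantile") {
    r <- rank(x[ok], ties.method = "first")
    out[ok] <- as.integer(ceiling(r * k / sum(ok)))
  } else {
    rng <- range(x[ok])
    br <- seq(rng[1L], rng[2L], length.out = k + 1L)[-c(1L, k + 1L)]
    out[ok] <- findInterval(x[ok], br, left.open = TRUE) + 1L
  }
  out
}

#' Geodetector q-statistic (factor detector)
#'
#' `q = 1 - sum_h N_h sigma_h^2 / (N sigma^2)` with population variances: the
#' fraction of the variance of y explained by the stratification. The
#' p-value follows the noncentral-F transformation
#' `F = ((N - L) / (L - 1)) * q / (1 - q)` with noncentrality
#' `lambda = (sum_h ybar_h^2 - (sum_h sqrt(N_h) ybar_h)^2 / N) / sigma^2`.
#' A seeded permutation test is available as a fallback.
#'
#' @param y numeric response per unit.
#' @param strata stratum labels (any type; NA pairs dropped).
#' @param permutations if > 0, add a permutation p-value.
#' @param seed permutation seed.
#' @return a `q_result`: list (q, L, N, p, strata_table, p_perm).
#' @export
factor_q <- function(y, strata, permutations = 0L, seed = 1L) {
  keep <- !is.na(y) & !is.na(strata)
  y <- y[keep]; strata <- strata[keep]
  N <- length(y)
  if (N < 2L) stop("need at least 2 observations")
  tot <- N * pop_var(y)
  if (tot == 0) stop("zero total variance: q undefined")
  f <- factor(strata)
  L <- nlevels(f)
  Nh <- as.vector(table(f))
  means <- as.vector(tapply(y, f, mean))
  ssw <- sum(as.vector(tapply(y, f, function(v) sum((v - mean(v))^2))))
  q <- 1 - ssw / tot
  sigma2 <- tot / N
  p <- NA_real_
  if (L > 1L && N > L) {
    Fv <- ((N - L) / (L - 1)) * q / (1 - q)
    lambda <- (sum(means^2) - (sum(sqrt(Nh) * means))^2 / N) / sigma2
    # pnbeta warns about precision for large noncentrality; the p is then
    # numerically 0 anyway
    p <- suppressWarnings(
      stats::pf(Fv, L - 1, N - L, ncp = max(0, lambda), lower.tail = FALSE))
    if (!is.finite(p)) p <- 0
  }
  p_perm <- NA_real_
  if (permutations > 0L) {
    qs <- with_seed(seed, vapply(seq_len(permutations), function(i) {
      fp <- f[sample.int(N)]
      1 - sum(as.vector(tapply(y, fp, function(v) sum((v - mean(v))^2)))) / tot
    }, 0))
    p_perm <- (sum(qs >= q) + 1) / (permutations + 1)
  }
  structure(list(q = q, L = L, N = N, p = p,
                 strata_table = data.frame(stratum = levels(f), N_h = Nh,
                                           mean = means),
                 p_perm = p_perm),
            class = "q_result")
}

#' @export
print.q_result <- function(x, ...) {
  cat(sprintf("Geodetector q = %.4f (L = %d strata, N = %d, p = %.3g)\n",
              x$q, x$L, x$N, x$p))
  invisible(x)
}

#' Interaction q: q on the overlay of two stratifications
#'
#' Strata of the pairwise cross-product; empty overlay cells drop out
#' naturally.
#'
#' @param y numeric response.
#' @param strata1,strata2 stratum labels.
#' @return a `q_result` for the overlay.
#' @export
interaction_q <- function(y, strata1, strata2) {
  factor_q(y, interaction(factor(strata1), factor(strata2), drop = TRUE))
}

INTERACTION_TYPES <- c("nonlinear enhancement", "dual-factor enhancement",
                       "single-factor nonlinear attenuation",
                       "nonlinear attenuation", "independence")

#' Classify a factor interaction
#'
#' Ordered rule chain (mutually exclusive and exhaustive for any q triple):
#' independence if `|q12 - (q1 + q2)| <= tol`; nonlinear enhancement if
#' `q12 > q1 + q2`; dual-factor enhancement if `q12 > max(q1, q2) + tol`;
#' nonlinear attenuation if `q12 < min(q1, q2) - tol`; otherwise
#' single-factor nonlinear attenuation. Boundary ties thus resolve toward the
#' weaker claim.
#'
#' @param q1,q2,q12 q-statistics in `[0, 1]`.
#' @param tol equality tolerance on the q scale (default 1e-6).
#' @return one of the five interaction type strings.
#' @export
classify_interaction <- function(q1, q2, q12, tol = 1e-6) {
  qs <- c(q1, q2, q12)
  if (any(qs < -tol | qs > 1 + tol)) stop("q values must lie in [0, 1]")
  if (abs(q12 - (q1 + q2)) <= tol) return("independence")
  if (q12 > q1 + q2) return("nonlinear enhancement")
  if (q12 > max(q1, q2) + tol) return("dual-factor enhancement")
  if (q12 < min(q1, q2) - tol) return("nonlinear attenuation")
  "single-factor nonlinear attenuation"
}

#' Significance stars for q p-values
#' @param p numeric p-values.
#' @return "***" p < 0.01, "**" p < 0.05, "*" p < 0.1, "" otherwise.
#' @export
q_stars <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.01, "***", ifelse(p < 0.05, "**",
                                        ifelse(p < 0.1, "*", ""))))
}
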