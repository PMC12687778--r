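# Kendall rank correlation (tau-b, tie-corrected) with a two-sided
# significance under the exchangeability null: exact permutation enumeration
# for n <= 9, normal approximation with tie correction otherwise.

.kendall_cache <- new.env(parent = emptyenv())

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  for (pos in seq_len(n)) {
    block <- (pos - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[block, pos] <- n
    out[block, -pos] <- sub
  }
  out
}

# n! x npairs matrix of linear indices into an n x n matrix, one column per
# unordered pair (i < j), row per permutation; cached per n
perm_pair_index <- function(n) {
  key <- paste0("n", n)
  cached <- .kendall_cache[[key]]
  if (!is.null(cached)) return(cached)
  P <- all_permutations(n)
  pairs <- utils::combn(n, 2L)
  L <- matrix(0L, nrow(P), ncol(pairs))
  for (q in seq_len(ncol(pairs))) {
    i <- pairs[1, q]
    j <- pairs[2, q]
    L[, q] <- (P[, j] - 1L) * n + P[, i]
  }
  res <- list(L = L, pairs = pairs)
  .kendall_cache[[key]] <- res
  res
}

# tie aggregates used by the tau-b denominator and the variance of S
tie_stats <- function(x) {
  t <- as.numeric(table(x))
  t <- t[t > 1]
  list(n1 = sum(t * (t - 1)) / 2,
       T1 = sum(t * (t - 1)),
       T2 = sum(t * (t - 1) * (t - 2)),
       T3 = sum(t * (t - 1) * (2 * t + 5)))
}

kendall_var_s <- function(n, tx, ty) {
  v0 <- n * (n - 1) * (2 * n + 5)
  v <- (v0 - tx$T3 - ty$T3) / 18
  if (n > 2) {
    v <- v + tx$T2 * ty$T2 / (9 * n * (n - 1) * (n - 2))
  }
  v + tx$T1 * ty$T1 / (2 * n * (n - 1))
}

#' Kendall rank correlation with exchangeability significance
#'
#' Computes the tie-corrected tau-b statistic. The two-sided p-value is the
#' exact permutation probability of an equal-or-larger |S| (concordant minus
#' discordant pair count) for n <= 9, and a tie-corrected normal
#' approximation for larger n. Constant inputs have no defined rank
#' correlation and are flagged via `constant = TRUE` so callers can exclude
#' them.
#'
#' @param x,y equal-length numeric vectors (n >= 3, finite).
#' @return A list with `tau`, `p_value`, `S` (the concordant-discordant
#'   count), `n` and `constant`.
#' @export
#' @examples
#' kendall_tau(1:4, 1:4)$tau         # 1
#' kendall_tau(1:3, 3:1)$tau         # -1
#' kendall_tau(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))$tau  # 0.6
kendall_tau <- function(x, y) {
  n <- length(x)
  if (length(y) != n) {
    stop_salnet("x and y must have equal length", class = "salnet_value_error")
  }
  if (n < 3L) {
    stop_salnet("need at least 3 observations", class = "salnet_value_error")
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop_salnet("inputs must be finite", class = "salnet_value_error")
  }
  sx <- sign(outer(x, x, `-`))
  sy <- sign(outer(y, y, `-`))
  up <- upper.tri(sx)
  S <- sum(sx[up] * sy[up])
  tx <- tie_stats(x)
  ty <- tie_stats(y)
  n0 <- n * (n - 1) / 2
  den <- sqrt((n0 - tx$n1) * (n0 - ty$n1))
  if (den == 0) {
    return(list(tau = NA_real_, p_value = NA_real_, S = S, n = n,
                constant = TRUE))
  }
  tau <- S / den
  if (n <= 9L) {
    pp <- perm_pair_index(n)
    sx_vec <- sx[t(pp$pairs)]
    # S under every permutation of y against fixed x
    Sp <- as.vector(matrix(sy[pp$L], nrow(pp$L)) %*% sx_vec)
    p <- mean(abs(Sp) >= abs(S) - 1e-9)
  } else {
    v <- kendall_var_s(n, tx, ty)
    z <- S / sqrt(v)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(tau = tau, p_value = min(p, 1), S = S, n = n, constant = FALSE)
}

# Fast tau-b + normal-approximation p for every column pair of a matrix.
# The concordance counts for all pairs are a single cross-product of the
# vectorised per-column sign matrices.
kendall_tau_matrix <- function(X) {
  n <- nrow(X)
  R <- ncol(X)
  M <- matrix(0, n * n, R)
  for (r in seq_len(R)) {
    M[, r] <- as.vector(sign(outer(X[, r], X[, r], `-`)))
  }
  S <- crossprod(M) / 2
  ties <- lapply(seq_len(R), function(r) tie_stats(X[, r]))
  n0 <- n * (n - 1) / 2
  n1 <- vapply(ties, `[[`, numeric(1), "n1")
  den <- sqrt(outer(n0 - n1, n0 - n1))
  tau <- S / den
  tau[den == 0] <- NA_real_
  T1 <- vapply(ties, `[[`, numeric(1), "T1")
  T2 <- vapply(ties, `[[`, numeric(1), "T2")
  T3 <- vapply(ties, `[[`, numeric(1), "T3")
  v0 <- n * (n - 1) * (2 * n + 5)
  V <- (v0 - outer(T3, T3, `+`)) / 18 +
    outer(T2, T2) / (9 * n * (n - 1) * (n - 2)) +
    outer(T1, T1) / (2 * n * (n - 1))
  Z <- S / sqrt(V)
  P <- 2 * stats::pnorm(-abs(Z))
  P[den == 0] <- NA_real_
  list(tau = tau, p = P)
}
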