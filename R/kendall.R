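# Kendall rank correlation with tie correction (tau-b).
#
# The engine reports a two-sided p-value from full enumeration of all n!
# pairings for small n (default n <= 8), where the normal approximation is
# poor, and from the tie-adjusted normal approximation otherwise. Under
# permutation the tau-b denominator is fixed by the tie patterns of x and y
# separately, so the enumeration can rank the concordance numerator S alone.

# cache of permutation matrices, keyed by n
.perm_cache <- new.env(parent = emptyenv())

perm_matrix <- function(n) {
  key <- as.character(n)
  if (!is.null(.perm_cache[[key]])) return(.perm_cache[[key]])
  pm <- if (n == 1L) {
    matrix(1L, 1L, 1L)
  } else {
    sub <- perm_matrix(n - 1L)
    do.call(rbind, lapply(seq_len(n), function(k) {
      rest <- sub
      rest[rest >= k] <- rest[rest >= k] + 1L
      cbind(k, rest, deparse.level = 0)
    }))
  }
  .perm_cache[[key]] <- pm
  pm
}

# concordance numerator S = sum_{i<j} sign(x_j - x_i) sign(y_j - y_i);
# summed over all ordered pairs (diagonal contributes 0) and halved,
# in row blocks so memory stays modest for large n
kendall_numerator <- function(x, y, chunk = 512L) {
  n <- length(x)
  s <- 0
  i <- 1L
  while (i <= n) {
    j <- min(i + chunk - 1L, n)
    s <- s + sum(sign(outer(x[i:j], x, "-")) * sign(outer(y[i:j], y, "-")))
    i <- j + 1L
  }
  s / 2
}

tie_sizes <- function(v) {
  t <- as.numeric(table(v))
  t[t > 1]
}

#' Kendall's tau-b with tie correction
#'
#' Rank correlation from concordant/discordant pair counts, with the tau-b
#' tie correction in the denominator. Two-sided p-values come from full
#' enumeration of all pairings when `n <= exact_limit` (exact also under
#' ties) and from the tie-adjusted normal approximation otherwise.
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`.
#' @param stratum Free-text label carried into the result (e.g.
#'   `"UTR, ECER>=10"`).
#' @param exact_limit Largest n for which the exact permutation p-value is
#'   enumerated (default 8; `8! = 40320` pairings).
#' @return One-row tibble: `tau`, `p_value`, `n`, `stratum`, `method`.
#' @export
kendall_tau_b <- function(x, y, stratum = NA_character_, exact_limit = 8L) {
  if (length(x) != length(y)) {
    validation_error("x and y must have equal length")
  }
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3) {
    insufficient_data_error("kendall_tau_b needs at least 3 complete pairs")
  }
  tx <- tie_sizes(x)
  ty <- tie_sizes(y)
  n0 <- n * (n - 1) / 2
  den_x <- n0 - sum(tx * (tx - 1) / 2)
  den_y <- n0 - sum(ty * (ty - 1) / 2)
  if (den_x == 0 || den_y == 0) {
    undefined_result_error("tau undefined: x or y is constant")
  }
  s <- kendall_numerator(x, y)
  tau <- s / sqrt(den_x * den_y)

  if (n <= exact_limit) {
    p <- kendall_exact_p(x, y, s)
    method <- "exact permutation"
  } else {
    p <- kendall_normal_p(s, n, tx, ty)
    method <- "normal approximation"
  }
  tibble::tibble(tau = tau, p_value = p, n = n, stratum = stratum,
                 method = method)
}

# exact two-sided p: fraction of the n! pairings whose |S| >= |S_obs|
kendall_exact_p <- function(x, y, s_obs) {
  n <- length(x)
  pm <- perm_matrix(n)
  pr <- which(upper.tri(diag(n)), arr.ind = TRUE)
  sx <- sign(x[pr[, 2]] - x[pr[, 1]])
  s_perm <- numeric(nrow(pm))
  for (k in seq_len(nrow(pr))) {
    if (sx[k] == 0) next
    s_perm <- s_perm + sx[k] * sign(y[pm[, pr[k, 2]]] - y[pm[, pr[k, 1]]])
  }
  mean(abs(s_perm) >= abs(s_obs) - 1e-9)
}

# tie-adjusted normal approximation for the distribution of S
kendall_normal_p <- function(s, n, tx, ty) {
  v0 <- n * (n - 1) * (2 * n + 5)
  vt <- sum(tx * (tx - 1) * (2 * tx + 5))
  vu <- sum(ty * (ty - 1) * (2 * ty + 5))
  v1 <- sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
  v2 <- sum(tx * (tx - 1) * (tx - 2)) * sum(ty * (ty - 1) * (ty - 2)) /
    (9 * n * (n - 1) * (n - 2))
  var_s <- (v0 - vt - vu) / 18 + v1 + v2
  if (var_s <= 0) {
    undefined_result_error("degenerate variance in normal approximation")
  }
  z <- s / sqrt(var_s)
  min(1, 2 * stats::pnorm(-abs(z)))
}
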