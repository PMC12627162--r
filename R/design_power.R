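#' Power of a one-sample / paired t-test
#'
#' Exact noncentral-t power: `P(T' > t_crit)` where `T'` has `n - 1` degrees
#' of freedom and noncentrality `d * sqrt(n)`, and `t_crit` is the
#' `1 - alpha` Student quantile (one-sided) or `1 - alpha/2` (two-sided).
#'
#' @param d Cohen's d effect size.
#' @param n Number of paired observations.
#' @param alpha Significance level.
#' @param tails `"one"` or `"two"`.
#' @return Power in `[0, 1]`.
#' @examples
#' power_paired_t(0.4, 60)   # ~0.92
#' power_paired_t(0.4, 40)   # ~0.80
#' @export
power_paired_t <- function(d, n, alpha = 0.05, tails = c("one", "two")) {
  tails <- match.arg(tails)
  if (n < 2) stop("n must be at least 2", call. = FALSE)
  stopifnot(alpha > 0, alpha <= 0.5)
  df <- n - 1
  ncp <- d * sqrt(n)
  if (tails == "one") {
    stats::pt(stats::qt(1 - alpha, df), df, ncp, lower.tail = FALSE)
  } else {
    q <- stats::qt(1 - alpha / 2, df)
    stats::pt(q, df, ncp, lower.tail = FALSE) + stats::pt(-q, df, ncp)
  }
}

#' Smallest n achieving a target power
#'
#' Inverse of [power_paired_t()] by integer search.
#'
#' @inheritParams power_paired_t
#' @param target_power Desired power in `(0, 1)`.
#' @param n_max Search ceiling.
#' @return Minimal integer `n` with power at or above `target_power`.
#' @export
required_n <- function(d, target_power, alpha = 0.05, tails = c("one", "two"),
                       n_max = 1e5) {
  tails <- match.arg(tails)
  if (d == 0) stop("effect size 0: target power unreachable", call. = FALSE)
  stopifnot(target_power > 0, target_power < 1)
  lo <- 2L; hi <- 2L
  while (power_paired_t(d, hi, alpha, tails) < target_power) {
    lo <- hi
    hi <- hi * 2L
    if (hi > n_max) stop("required n exceeds n_max", call. = FALSE)
  }
  while (lo < hi) {          # first n in (lo, hi] meeting the target
    mid <- (lo + hi) %/% 2L
    if (power_paired_t(d, mid, alpha, tails) >= target_power) hi <- mid
    else lo <- mid + 1L
  }
  hi
}

# P(no rejection at any look) for a common nominal level, by recursive
# numerical integration over the Markov chain of standardised group-
# sequential statistics Z_k (correlation sqrt(t_i/t_j)).
.gs_accept_prob <- function(nominal, info, sided, n_grid = 512) {
  K <- length(info)
  zc <- if (sided == "two") stats::qnorm(1 - nominal / 2)
        else stats::qnorm(1 - nominal)
  lower <- if (sided == "two") -zc else -8.5
  g <- seq(lower, zc, length.out = n_grid)
  h <- g[2] - g[1]
  w <- rep(h, n_grid); w[c(1, n_grid)] <- h / 2   # trapezoid weights
  f <- stats::dnorm(g)                            # density of Z_1 on region
  if (K == 1) return(sum(f * w))
  for (k in 2:K) {
    dt <- info[k] - info[k - 1]
    sk <- sqrt(info[k]); sk1 <- sqrt(info[k - 1]); sd_inc <- sqrt(dt)
    # transition density: Z_k = (sqrt(t_{k-1}) Z_{k-1} + sqrt(dt) N) / sqrt(t_k)
    trans <- outer(g, g, function(znew, zold)
      stats::dnorm((znew * sk - zold * sk1) / sd_inc) * sk / sd_inc)
    f <- as.vector(trans %*% (f * w))
  }
  sum(f * w)
}

#' Common nominal level for a K-look group-sequential design
#'
#' Solves for the constant per-look significance level (Pocock-type
#' boundary) such that the overall probability of rejecting at any look
#' under the null equals `overall_alpha`, accounting for the correlation
#' `sqrt(t_i / t_j)` between interim test statistics, by recursive normal
#' integration. The classical two-look, two-sided 5% value is 0.0294.
#'
#' @param K Number of looks.
#' @param overall_alpha Overall type-I error to maintain.
#' @param sided `"two"` or `"one"`.
#' @param info_fractions Increasing information fractions ending at 1;
#'   default equally spaced.
#' @param tol Root-finding tolerance on the overall alpha.
#' @return The common nominal per-look level.
#' @export
sequential_nominal_alpha <- function(K, overall_alpha = 0.05,
                                     sided = c("two", "one"),
                                     info_fractions = NULL, tol = 1e-6) {
  sided <- match.arg(sided)
  stopifnot(K >= 1, overall_alpha > 0, overall_alpha < 1)
  if (K == 1) return(overall_alpha)
  if (is.null(info_fractions)) info_fractions <- seq_len(K) / K
  if (length(info_fractions) != K || is.unsorted(info_fractions, strictly = TRUE) ||
      abs(info_fractions[K] - 1) > 1e-12)
    stop("info_fractions must be strictly increasing and end at 1", call. = FALSE)
  obj <- function(nominal)
    (1 - .gs_accept_prob(nominal, info_fractions, sided)) - overall_alpha
  lo <- overall_alpha / (2 * K); hi <- overall_alpha
  flo <- obj(lo); fhi <- obj(hi)
  if (flo > 0 || fhi < 0)
    stop(sprintf("bracketing failed: f(%g)=%g, f(%g)=%g", lo, flo, hi, fhi),
         call. = FALSE)
  stats::uniroot(obj, c(lo, hi), tol = tol)$root
}

#' Audit a balanced shuffle randomisation
#'
#' Group counts, maximal imbalance over even-sized prefixes, and a pass flag
#' for the balanced-shuffle contract: within each block of `block` (default
#' 40) consecutive assignments the groups must be exactly balanced.
#'
#' @param assignments Character vector of `"left"`/`"right"`.
#' @param block Balancing block size.
#' @return List `counts, max_prefix_imbalance, block_balanced, pass`.
#' @export
audit_randomization <- function(assignments, block = 40) {
  if (!all(assignments %in% c("left", "right")))
    stop("unknown group labels", call. = FALSE)
  n <- length(assignments)
  s <- cumsum(ifelse(assignments == "left", 1L, -1L))
  even <- seq(2, n, by = 2)
  max_imb <- if (length(even)) max(abs(s[even])) else 0L
  blocks <- split(assignments, ceiling(seq_len(n) / block))
  full <- vapply(blocks, length, integer(1)) == block
  block_ok <- all(vapply(blocks[full], function(b)
    sum(b == "left") == block / 2, logical(1)))
  counts <- c(left = sum(assignments == "left"),
              right = sum(assignments == "right"))
  final_imb <- abs(diff(counts))
  list(counts = counts, max_prefix_imbalance = max_imb,
       block_balanced = block_ok,
       pass = block_ok && final_imb <= n %% 2)
}
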