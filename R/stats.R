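# Rank-statistics kernel. Everything here is implemented from first
# principles so that each routine can be verified against independent
# oracles (full enumeration, brute-force pair counting, reference
# implementations) in the test suite.

#' Mann-Whitney U test
#'
#' Two-sample rank test with mid-ranks for ties. The U statistic counts
#' pairs won by group `a`: U = #\{a > b\} + 0.5 #\{a = b\}. When both
#' groups have at most `exact_threshold` observations the two-sided
#' p-value is exact, computed by full enumeration of all
#' choose(n_a + n_b, n_a) group assignments of the pooled values
#' (conditional on ties); otherwise a normal approximation with
#' tie-corrected variance and continuity correction is used. The
#' two-sided p is min(1, 2 * one-sided).
#'
#' @param a,b Numeric vectors of scores (each non-empty, finite).
#' @param exact_threshold Largest per-group size for which the exact
#'   enumeration is used (default 8).
#' @return An object of class `immunosig_mwu`: a list with elements
#'   `u_statistic`, `p_two_sided`, `n_a`, `n_b`, `method`. `tidy()`
#'   renders it as a one-row tibble.
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))  # U = 0, exact p = 1/3
#' @export
mann_whitney_u <- function(a, b, exact_threshold = 8) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) == 0 || length(b) == 0) {
    rlang::abort("both groups must be non-empty")
  }
  if (!all(is.finite(a)) || !all(is.finite(b))) {
    rlang::abort("scores must be finite")
  }
  n_a <- length(a)
  n_b <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)  # mid-ranks
  u <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  if (max(n_a, n_b) <= exact_threshold) {
    p <- mwu_exact_p(r, n_a, u)
    method <- "exact"
  } else {
    p <- mwu_normal_p(pooled, r, n_a, n_b, u)
    method <- "normal_approx"
  }
  structure(
    list(
      u_statistic = u, p_two_sided = p,
      n_a = n_a, n_b = n_b, method = method
    ),
    class = "immunosig_mwu"
  )
}

# Exact two-sided p by enumerating every assignment of n_a of the pooled
# mid-ranks to group a. Conditional on the observed ties.
mwu_exact_p <- function(r, n_a, u_obs) {
  n <- length(r)
  offset <- n_a * (n_a + 1) / 2
  combos <- utils::combn(n, n_a)
  u_all <- colSums(matrix(r[combos], nrow = n_a)) - offset
  eps <- 1e-9
  p_le <- mean(u_all <= u_obs + eps)
  p_ge <- mean(u_all >= u_obs - eps)
  min(1, 2 * min(p_le, p_ge))
}

mwu_normal_p <- function(pooled, r, n_a, n_b, u) {
  n <- n_a + n_b
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  v <- n_a * n_b / 12 * ((n + 1) - tie_term)
  if (v <= 0) return(1)
  mu <- n_a * n_b / 2
  diff <- u - mu
  # continuity correction shrinks |diff| by 0.5 toward the mean
  z <- (abs(diff) - 0.5) / sqrt(v)
  z <- max(z, 0)
  min(1, 2 * stats::pnorm(-z))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment: with p-values sorted ascending, q_(i) =
#' min_\{j >= i\} p_(j) * m / j, capped at 1, returned in the original
#' order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values, same length and order as `p`.
#' @examples
#' bh_adjust(c(0.01, 0.04))  # 0.02 0.04
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) {
    rlang::abort("p-values must lie in [0, 1]")
  }
  m <- length(p)
  ord <- order(p)
  scaled <- p[ord] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(scaled)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

#' Area under the ROC curve from two score samples
#'
#' Rank-based AUROC: the probability that a random positive scores above
#' a random negative, with ties counted half. Computed from the
#' mid-rank sum, so it equals U / (n_pos * n_neg) of
#' [mann_whitney_u()] exactly.
#'
#' @param pos,neg Numeric score vectors for the positive (e.g. responder)
#'   and negative class.
#' @return A number in \[0, 1\].
#' @examples
#' auroc(c(3, 5), c(1, 4))  # 0.75
#' @export
auroc <- function(pos, neg) {
  if (length(pos) == 0 || length(neg) == 0) {
    rlang::abort("both groups must be non-empty")
  }
  n_pos <- length(pos)
  n_neg <- length(neg)
  r <- rank(c(pos, neg))
  u <- sum(r[seq_len(n_pos)]) - n_pos * (n_pos + 1) / 2
  u / (n_pos * n_neg)
}

#' Kaplan-Meier product-limit estimator
#'
#' S(t) = prod over event times t_i <= t of (1 - d_i / n_i), with d_i
#' events and n_i at risk at t_i. Subjects censored at an event time are
#' counted at risk for that time (they leave the risk set just after).
#'
#' @param times Non-negative follow-up times (months).
#' @param events Event indicators, 1 = death observed, 0 = censored.
#' @return An object of class `immunosig_km` whose `curve` element is a
#'   tibble with columns `time`, `n_risk`, `n_event`, `n_censor`,
#'   `survival` (one row per distinct observed time). `tidy()` returns
#'   the curve; `autoplot()` draws the step function.
#' @examples
#' km_fit(c(1, 2, 3), c(1, 1, 1))  # S = 2/3, 1/3, 0
#' @export
km_fit <- function(times, events) {
  times <- as.numeric(times)
  if (length(times) != length(events)) {
    rlang::abort("times and events must have the same length")
  }
  if (length(times) == 0) rlang::abort("empty survival data")
  if (any(!is.finite(times)) || any(times < 0)) {
    rlang::abort("times must be finite and non-negative")
  }
  if (!all(events %in% c(0, 1))) {
    rlang::abort("events must be 0 (censored) or 1 (event)")
  }
  events <- as.integer(events)
  tt <- sort(unique(times))
  n_risk <- vapply(tt, function(t) sum(times >= t), numeric(1))
  n_event <- vapply(tt, function(t) sum(times == t & events == 1), numeric(1))
  n_censor <- vapply(tt, function(t) sum(times == t & events == 0), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  structure(
    list(
      curve = tibble::tibble(
        time = tt, n_risk = n_risk, n_event = n_event,
        n_censor = n_censor, survival = surv
      ),
      n = length(times), n_events = sum(events)
    ),
    class = "immunosig_km"
  )
}

#' Median survival time from a fitted curve
#'
#' First observed time at which the survival estimate drops to 0.5 or
#' below; `NA` if the curve never reaches 0.5.
#'
#' @param fit An `immunosig_km` object.
#' @return A single time, or `NA_real_`.
#' @export
km_median <- function(fit) {
  stopifnot(inherits(fit, "immunosig_km"))
  hit <- fit$curve$time[fit$curve$survival <= 0.5]
  if (length(hit) == 0) NA_real_ else hit[1]
}

#' Two-group log-rank test
#'
#' At each distinct pooled event time the observed events in group A are
#' compared with their hypergeometric expectation given the margins;
#' chi2 = (sum O - sum E)^2 / sum V on 1 degree of freedom. The p-value
#' uses the closed form erfc(sqrt(chi2 / 2)). A degenerate comparison
#' with zero total variance returns chi2 = 0, p = 1.
#'
#' @param times_a,events_a,times_b,events_b Follow-up times and event
#'   indicators for the two groups.
#' @return An object of class `immunosig_logrank`: a list with
#'   `chi2`, `p`, `observed`, `expected` (group A), `n_a`, `n_b`.
#' @examples
#' logrank_test(c(1, 2), c(1, 1), c(3, 4), c(1, 1))
#' @export
logrank_test <- function(times_a, events_a, times_b, events_b) {
  fa <- km_fit(times_a, events_a)  # validates inputs
  fb <- km_fit(times_b, events_b)
  times <- c(times_a, times_b)
  events <- as.integer(c(events_a, events_b))
  grp_a <- c(rep(TRUE, length(times_a)), rep(FALSE, length(times_b)))
  ev_times <- sort(unique(times[events == 1]))
  o <- e <- v <- 0
  for (t in ev_times) {
    at_risk <- times >= t
    n <- sum(at_risk)
    n_a <- sum(at_risk & grp_a)
    d <- sum(times == t & events == 1)
    d_a <- sum(times == t & events == 1 & grp_a)
    o <- o + d_a
    e <- e + d * n_a / n
    if (n > 1) {
      v <- v + d * (n_a / n) * (1 - n_a / n) * (n - d) / (n - 1)
    }
  }
  if (v <= 0) {
    chi2 <- 0
    p <- 1
  } else {
    chi2 <- (o - e)^2 / v
    p <- chisq1_p(chi2)
  }
  structure(
    list(
      chi2 = chi2, p = p, observed = o, expected = e,
      n_a = length(times_a), n_b = length(times_b)
    ),
    class = "immunosig_logrank"
  )
}

# Upper tail of chi-square with 1 df via the closed form
# erfc(sqrt(x/2)) = 2 * Phi(-sqrt(x)).
chisq1_p <- function(x) {
  2 * stats::pnorm(-sqrt(x))
}

#' Split scores at a quantile into high/low strata
#'
#' Labels a score `"high"` when it exceeds the cutpoint (the median by
#' default) and `"low"` otherwise; scores exactly equal to the cutpoint
#' go to `"low"`.
#'
#' @param scores Numeric vector, length >= 2.
#' @param prob Quantile for the cutpoint, in (0, 1); 0.5 = median split.
#' @return Character vector of `"high"` / `"low"` labels.
#' @examples
#' median_split(c(1, 2, 3, 4))  # low low high high
#' @export
median_split <- function(scores, prob = 0.5) {
  if (length(scores) < 2) {
    rlang::abort("need at least 2 scores to split")
  }
  if (prob <= 0 || prob >= 1) {
    rlang::abort("prob must lie strictly between 0 and 1")
  }
  cut <- stats::quantile(scores, probs = prob, names = FALSE, type = 7)
  ifelse(scores > cut, "high", "low")
}
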