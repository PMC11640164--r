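# Independent brute-force oracles used to verify the rank-statistics
# kernel. These deliberately avoid the implementation's code paths:
# U by a double loop over pairs, exact p by enumerating group
# assignments with per-assignment double-loop U, BH by the literal
# step-up double loop.

oracle_u <- function(a, b) {
  u <- 0
  for (x in a) {
    for (y in b) {
      u <- u + (x > y) + 0.5 * (x == y)
    }
  }
  u
}

oracle_exact_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  n_a <- length(a)
  u_obs <- oracle_u(a, b)
  combos <- utils::combn(n, n_a, simplify = FALSE)
  u_all <- vapply(combos, function(idx) {
    oracle_u(pooled[idx], pooled[-idx])
  }, numeric(1))
  eps <- 1e-9
  min(1, 2 * min(mean(u_all <= u_obs + eps), mean(u_all >= u_obs - eps)))
}

oracle_auroc <- function(pos, neg) {
  oracle_u(pos, neg) / (length(pos) * length(neg))
}

oracle_bh <- function(p) {
  m <- length(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    # q_i = min over all j with p_j >= p_i of p_j * m / rank(p_j)
    candidates <- vapply(seq_len(m), function(j) {
      if (p[j] >= p[i]) {
        rank_j <- sum(p <= p[j])
        p[j] * m / rank_j
      } else {
        Inf
      }
    }, numeric(1))
    q[i] <- min(1, min(candidates))
  }
  q
}

# empirical survival function: fraction of subjects strictly surviving t
oracle_empirical_survival <- function(times, t) {
  mean(times > t)
}

# small deterministic cohort for pipeline tests
tiny_cohort <- function(seed = 11, n = 20, types = c("melanoma", "ovarian"),
                        delta = NULL, beta = 0.5, censor = 0.2,
                        n_background = 20) {
  sig_names <- unique(immunosig::builtin_signatures()$signature)
  npt <- stats::setNames(rep(n, length(types)), types)
  eff <- if (is.null(delta)) {
    tidyr::expand_grid(cancer_type = types, signature = sig_names) |>
      dplyr::mutate(delta = 0)
  } else {
    delta
  }
  immunosig::generate_cohort(immunosig::synthetic_config(
    seed = seed, n_per_type = npt, n_background_genes = n_background,
    effect_matrix = eff, hazard_coefficient = beta, censor_rate = censor
  ))
}

matrix_to_tbl <- function(mat, genes = NULL, samples = NULL) {
  if (is.null(genes)) genes <- sprintf("G%02d", seq_len(nrow(mat)))
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(mat)))
  dimnames(mat) <- list(genes, samples)
  tibble::as_tibble(mat, rownames = "gene_id")
}
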