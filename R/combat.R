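#' Parametric empirical-Bayes batch adjustment
#'
#' Removes additive (location) and multiplicative (scale) batch effects
#' from a log2(TPM+1) expression table, following the parametric
#' empirical-Bayes location/scale model widely used for expression batch
#' correction. No covariates and no reference batch are modeled.
#'
#' The algorithm: (1) per gene, estimate batch means by least squares, the
#' sample-size-weighted grand mean, and the pooled residual variance, and
#' standardize the data; (2) per batch, estimate the location effect
#' (batch mean of standardized data) and scale effect (batch variance);
#' (3) shrink locations toward a normal prior and scales toward an
#' inverse-gamma prior whose hyperparameters are moment-matched across
#' genes, solving the coupled posterior-mean equations by fixed-point
#' iteration; (4) subtract/divide the shrunken effects and restore the
#' grand mean and pooled variance.
#'
#' Genes with zero pooled variance cannot be standardized; they pass
#' through unadjusted and are listed in the `unadjusted_genes` attribute
#' (with a warning). A single batch is a pass-through.
#'
#' @param expr Expression tibble on the log2(TPM+1) scale.
#' @param batch Batch labels: either a data frame with `sample_id` and
#'   `batch` columns (e.g. the cohort annotation) or a character vector
#'   named by sample id. Every expression sample must be covered and every
#'   batch must contain at least 2 samples.
#' @param tol Convergence tolerance of the fixed-point iteration on the
#'   shrunken effects (default 1e-6).
#' @param max_iter Iteration cap (default 500).
#' @return The adjusted expression tibble, same dimensions and order.
#' @examples
#' cohort <- generate_cohort(synthetic_config(
#'   seed = 1, n_per_type = c(melanoma = 10, ovarian = 10)
#' ))
#' adj <- combat_adjust(cohort$expression, cohort$annotation)
#' @export
combat_adjust <- function(expr, batch, tol = 1e-6, max_iter = 500) {
  validate_expression(expr)
  mat <- expr_to_matrix(expr)
  batch <- resolve_batch(batch, colnames(mat))
  batches <- unique(batch)
  if (length(batches) < 2) {
    return(expr)  # nothing to adjust
  }
  n_per_batch <- table(factor(batch, levels = batches))
  if (any(n_per_batch < 2)) {
    small <- names(n_per_batch)[n_per_batch < 2]
    rlang::abort(paste0(
      "every batch needs at least 2 samples; too small: ",
      paste(small, collapse = ", ")
    ))
  }
  n_array <- ncol(mat)
  n_batch <- length(batches)
  batch_idx <- lapply(batches, function(b) which(batch == b))
  n_b <- vapply(batch_idx, length, numeric(1))

  # (1) standardize: batch means, weighted grand mean, pooled variance
  batch_means <- vapply(batch_idx, function(idx) {
    rowMeans(mat[, idx, drop = FALSE])
  }, numeric(nrow(mat)))                     # genes x batches
  grand_mean <- as.vector(batch_means %*% (n_b / n_array))
  fitted <- batch_means[, match(batch, batches), drop = FALSE]
  var_pooled <- rowSums((mat - fitted)^2) / n_array
  zero_var <- var_pooled <= .Machine$double.eps
  if (all(zero_var)) {
    rlang::warn("all genes have zero pooled variance; returning input unchanged")
    return(expr)
  }
  keep <- which(!zero_var)
  s_data <- (mat[keep, , drop = FALSE] - grand_mean[keep]) /
    sqrt(var_pooled[keep])

  # (2) per-batch location/scale estimates on standardized data
  gamma_hat <- vapply(batch_idx, function(idx) {
    rowMeans(s_data[, idx, drop = FALSE])
  }, numeric(length(keep)))                  # genes x batches
  delta_hat <- vapply(batch_idx, function(idx) {
    apply(s_data[, idx, drop = FALSE], 1, stats::var)
  }, numeric(length(keep)))

  # (3) EB shrinkage, moment-matched hyperpriors per batch
  gamma_star <- gamma_hat
  delta_star <- delta_hat
  for (i in seq_len(n_batch)) {
    g_hat <- gamma_hat[, i]
    d_hat <- delta_hat[, i]
    g_bar <- mean(g_hat)
    t2 <- stats::var(g_hat)
    a_prior <- ig_moment_a(d_hat)
    b_prior <- ig_moment_b(d_hat)
    sol <- eb_fixed_point(
      s_data[, batch_idx[[i]], drop = FALSE],
      g_hat, d_hat, g_bar, t2, a_prior, b_prior,
      tol = tol, max_iter = max_iter
    )
    gamma_star[, i] <- sol$gamma
    delta_star[, i] <- sol$delta
  }

  # (4) remove shrunken effects, restore scale and grand mean
  adj <- s_data
  for (i in seq_len(n_batch)) {
    idx <- batch_idx[[i]]
    adj[, idx] <- (adj[, idx, drop = FALSE] - gamma_star[, i]) /
      sqrt(delta_star[, i])
  }
  adj <- adj * sqrt(var_pooled[keep]) + grand_mean[keep]

  out_mat <- mat
  out_mat[keep, ] <- adj
  if (any(zero_var)) {
    rlang::warn(paste0(
      sum(zero_var), " zero-variance gene(s) passed through unadjusted: ",
      paste(utils::head(rownames(mat)[zero_var], 5), collapse = ", "),
      if (sum(zero_var) > 5) ", ..." else ""
    ))
  }
  out <- matrix_to_expr(out_mat,
                        scale_tag = attr(expr, "scale_tag", exact = TRUE))
  attr(out, "unadjusted_genes") <- rownames(mat)[zero_var]
  out
}

# inverse-gamma hyperparameters matched to the mean/variance of the
# observed per-gene batch variances
ig_moment_a <- function(d_hat) {
  m <- mean(d_hat)
  s2 <- stats::var(d_hat)
  (2 * s2 + m^2) / s2
}

ig_moment_b <- function(d_hat) {
  m <- mean(d_hat)
  s2 <- stats::var(d_hat)
  (m * s2 + m^3) / s2
}

# Coupled posterior means for one batch: location shrinkage weight
# depends on the current scale estimate and vice versa; iterate to a
# fixed point.
eb_fixed_point <- function(x, g_hat, d_hat, g_bar, t2, a_prior, b_prior,
                           tol, max_iter) {
  n <- ncol(x)
  g_old <- g_hat
  d_old <- d_hat
  for (iter in seq_len(max_iter)) {
    g_new <- (t2 * n * g_hat + d_old * g_bar) / (t2 * n + d_old)
    sum2 <- rowSums((x - g_new)^2)
    d_new <- (0.5 * sum2 + b_prior) / (n / 2 + a_prior - 1)
    change <- max(
      abs(g_new - g_old) / (abs(g_old) + 1e-12),
      abs(d_new - d_old) / (abs(d_old) + 1e-12)
    )
    g_old <- g_new
    d_old <- d_new
    if (change < tol) break
  }
  list(gamma = g_old, delta = d_old)
}

resolve_batch <- function(batch, sample_ids) {
  if (is.data.frame(batch)) {
    if (!all(c("sample_id", "batch") %in% names(batch))) {
      rlang::abort("batch data frame needs `sample_id` and `batch` columns")
    }
    vec <- stats::setNames(as.character(batch$batch),
                           as.character(batch$sample_id))
  } else {
    if (is.null(names(batch))) {
      if (length(batch) != length(sample_ids)) {
        rlang::abort("unnamed batch vector must match the sample count")
      }
      vec <- stats::setNames(as.character(batch), sample_ids)
    } else {
      vec <- stats::setNames(as.character(batch), names(batch))
    }
  }
  missing <- setdiff(sample_ids, names(vec))
  if (length(missing) > 0) {
    rlang::abort(paste0(
      "no batch label for sample(s): ",
      paste(utils::head(missing, 5), collapse = ", ")
    ))
  }
  unname(vec[sample_ids])
}
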