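#' Configuration for the synthetic cohort generator
#'
#' Collects every knob of the generator with defaults that emulate the
#' multi-cancer observational cohort the package's analyses are designed
#' for: four cancer types with the published sample sizes (melanoma 232,
#' bladder 349, ovarian 664, pancreatic 647), tumor-type-specific shifts
#' of the signature-member genes with melanoma highest and ovarian lowest,
#' two generic location/scale batches, and survival times whose hazard
#' decreases with the (realized) score of a chosen response signature.
#'
#' @param seed Integer RNG seed; identical configs give byte-identical
#'   cohorts.
#' @param n_per_type Named integer vector, samples per cancer type.
#' @param n_background_genes Number of pure-noise decoy genes appended to
#'   the signature-member genes.
#' @param batch_assignment Named list mapping each cancer type to a named
#'   probability vector over batch labels; default assigns every type
#'   uniformly to batches `b1`/`b2`.
#' @param batch_location Named numeric vector, additive shift per batch
#'   (log2 units).
#' @param batch_scale Named numeric vector, multiplicative noise scale per
#'   batch (> 0).
#' @param effect_matrix Tibble with columns `cancer_type`, `signature`,
#'   `delta`: the mean shift (in units of `gene_noise_sd`) applied,
#'   sign-aware, to that signature's member genes in that cancer type. It
#'   must cover exactly the declared cancer types x signature names.
#'   Default: melanoma 0.8, bladder 0.45, pancreatic 0.3, ovarian -0.3 for
#'   all six built-in signatures.
#' @param gene_noise_sd Per-gene Gaussian noise SD (log2 units).
#' @param baseline_mean Baseline expression (log2 units).
#' @param hazard_baseline Baseline event rate (events/month, > 0).
#' @param hazard_coefficient Coefficient beta in the log hazard
#'   h = hazard_baseline * exp(-beta * score): positive beta makes higher
#'   infiltration scores survive longer.
#' @param censor_rate Probability a sample is independently censored
#'   before its event, in \[0, 1\].
#' @param response_signature Name of the signature whose realized score
#'   drives survival (and hence responder status).
#' @param signatures Signature table used both to lay out member genes and
#'   to compute the score driving survival.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1,
                             n_per_type = c(melanoma = 232, bladder = 349,
                                            ovarian = 664, pancreatic = 647),
                             n_background_genes = 200,
                             batch_assignment = NULL,
                             batch_location = c(b1 = 0, b2 = 0.5),
                             batch_scale = c(b1 = 1, b2 = 1.2),
                             effect_matrix = NULL,
                             gene_noise_sd = 1,
                             baseline_mean = 5,
                             hazard_baseline = 0.02,
                             hazard_coefficient = 0.5,
                             censor_rate = 0.3,
                             response_signature = "trm",
                             signatures = builtin_signatures()) {
  validate_signatures(signatures)
  sig_names <- unique(signatures$signature)
  types <- names(n_per_type)
  if (is.null(types) || any(types == "")) {
    rlang::abort("n_per_type must be a named vector of cancer types")
  }
  if (any(n_per_type < 0)) rlang::abort("sample counts must be >= 0")
  if (sum(n_per_type) == 0) rlang::abort("zero total samples")
  if (is.null(effect_matrix)) {
    default_delta <- c(melanoma = 0.8, bladder = 0.45,
                       pancreatic = 0.3, ovarian = -0.3)
    effect_matrix <- tidyr::expand_grid(
      cancer_type = types, signature = sig_names
    ) |>
      dplyr::mutate(delta = dplyr::coalesce(
        default_delta[.data$cancer_type], 0
      ))
  }
  stopifnot(is.data.frame(effect_matrix),
            all(c("cancer_type", "signature", "delta") %in% names(effect_matrix)))
  unknown_sig <- setdiff(effect_matrix$signature, sig_names)
  if (length(unknown_sig) > 0) {
    rlang::abort(paste0(
      "effect_matrix references unknown signature(s): ",
      paste(unknown_sig, collapse = ", ")
    ))
  }
  unknown_type <- setdiff(effect_matrix$cancer_type, types)
  if (length(unknown_type) > 0) {
    rlang::abort(paste0(
      "effect_matrix references undeclared cancer type(s): ",
      paste(unknown_type, collapse = ", ")
    ))
  }
  full <- tidyr::expand_grid(cancer_type = types, signature = sig_names)
  covered <- dplyr::semi_join(full, effect_matrix,
                              by = c("cancer_type", "signature"))
  if (nrow(covered) != nrow(full) || nrow(effect_matrix) != nrow(full)) {
    rlang::abort(
      "effect_matrix must cover exactly the declared cancer types x signatures"
    )
  }
  if (is.null(batch_assignment)) {
    n_batches <- length(batch_location)
    probs <- stats::setNames(rep(1 / n_batches, n_batches),
                             names(batch_location))
    batch_assignment <- stats::setNames(
      replicate(length(types), probs, simplify = FALSE), types
    )
  }
  if (!setequal(names(batch_assignment), types)) {
    rlang::abort("batch_assignment must cover exactly the declared cancer types")
  }
  batch_labels <- names(batch_location)
  for (ty in types) {
    pr <- batch_assignment[[ty]]
    if (is.null(names(pr)) || !all(names(pr) %in% batch_labels)) {
      rlang::abort("batch_assignment probabilities must be named by batch label")
    }
  }
  if (!setequal(names(batch_scale), batch_labels)) {
    rlang::abort("batch_scale must cover the same batches as batch_location")
  }
  if (any(batch_scale <= 0)) rlang::abort("batch scales must be > 0")
  if (n_background_genes < 0) rlang::abort("n_background_genes must be >= 0")
  if (gene_noise_sd <= 0) rlang::abort("gene_noise_sd must be > 0")
  if (hazard_baseline <= 0) rlang::abort("hazard_baseline must be > 0")
  if (censor_rate < 0 || censor_rate > 1) {
    rlang::abort("censor_rate must lie in [0, 1]")
  }
  if (!response_signature %in% sig_names) {
    rlang::abort(paste0("unknown response signature: ", response_signature))
  }
  structure(
    list(
      seed = as.integer(seed), n_per_type = n_per_type,
      n_background_genes = as.integer(n_background_genes),
      batch_assignment = batch_assignment,
      batch_location = batch_location, batch_scale = batch_scale,
      effect_matrix = effect_matrix, gene_noise_sd = gene_noise_sd,
      baseline_mean = baseline_mean, hazard_baseline = hazard_baseline,
      hazard_coefficient = hazard_coefficient, censor_rate = censor_rate,
      response_signature = response_signature, signatures = signatures
    ),
    class = "synthetic_config"
  )
}

#' Generate a synthetic cohort
#'
#' Draws a genes x samples log2-scale expression table plus a per-sample
#' clinical annotation with the statistical structure the downstream
#' analyses assume. Per gene g and sample s,
#' x = baseline + shift(type(s), g) + location(batch(s)) +
#' scale(batch(s)) * Normal(0, gene_noise_sd), where shift accumulates,
#' over every signature containing g, the signature's configured delta
#' times the marker's sign (so a positive delta always moves the
#' signature *score* up, including for negative markers). Decoy genes
#' carry no structure. Overall-survival months are exponential with rate
#' hazard_baseline * exp(-beta * score) where score is the realized
#' pooled-z score of the configured response signature; a fraction
#' censor_rate of samples is censored at a uniform fraction of their
#' event time.
#'
#' @param config A [synthetic_config()].
#' @return A list with elements `expression` (tibble, `gene_id` + one
#'   column per sample, tagged `log2tpm1`) and `annotation` (tibble with
#'   `sample_id`, `cancer_type`, `batch`, `ici_treated`, `os_months`,
#'   `event`).
#' @examples
#' cohort <- generate_cohort(synthetic_config(
#'   seed = 7, n_per_type = c(melanoma = 10, ovarian = 10),
#'   n_background_genes = 50
#' ))
#' dim(cohort$expression)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  types <- names(config$n_per_type)
  n_total <- sum(config$n_per_type)
  cancer_type <- rep(types, times = config$n_per_type)
  sample_id <- sprintf("S%04d", seq_len(n_total))

  batch <- character(n_total)
  for (ty in types) {
    idx <- which(cancer_type == ty)
    pr <- config$batch_assignment[[ty]]
    batch[idx] <- sample(names(pr), length(idx), replace = TRUE,
                         prob = as.numeric(pr))
  }

  sigs <- config$signatures
  marker_genes <- unique(sigs$gene)
  n_bg <- config$n_background_genes
  bg_genes <- if (n_bg > 0) sprintf("BG%04d", seq_len(n_bg)) else character(0)
  genes <- c(marker_genes, bg_genes)

  # per-gene, per-type shift: sum over signatures containing the gene of
  # sign * delta, in units of gene_noise_sd
  shift <- matrix(0, nrow = length(genes), ncol = length(types),
                  dimnames = list(genes, types))
  eff <- config$effect_matrix
  for (r in seq_len(nrow(eff))) {
    members <- sigs[sigs$signature == eff$signature[r], ]
    shift[members$gene, eff$cancer_type[r]] <-
      shift[members$gene, eff$cancer_type[r]] +
      members$sign * eff$delta[r] * config$gene_noise_sd
  }

  loc <- config$batch_location[batch]
  scl <- config$batch_scale[batch]
  noise <- matrix(stats::rnorm(length(genes) * n_total, sd = config$gene_noise_sd),
                  nrow = length(genes))
  mat <- config$baseline_mean + shift[, cancer_type, drop = FALSE] +
    rep(loc, each = length(genes)) +
    rep(scl, each = length(genes)) * noise
  dimnames(mat) <- list(genes, sample_id)
  expr <- matrix_to_expr(mat, scale_tag = "log2tpm1")

  # survival coupled to the realized response-signature score
  resp_sig <- sigs[sigs$signature == config$response_signature, ]
  score <- score_signature(gene_zscores(expr), resp_sig)$score
  rate <- config$hazard_baseline *
    exp(-config$hazard_coefficient * score)
  event_time <- stats::rexp(n_total, rate = rate)
  censored <- stats::runif(n_total) < config$censor_rate
  os_months <- ifelse(censored, event_time * stats::runif(n_total), event_time)
  event <- as.integer(!censored)

  annotation <- tibble::tibble(
    sample_id = sample_id,
    cancer_type = cancer_type,
    batch = batch,
    ici_treated = TRUE,
    os_months = os_months,
    event = event
  )
  list(expression = expr, annotation = annotation)
}

#' Write a cohort's files to a directory
#'
#' Writes `expression.tsv` (gene_id + sample columns) and
#' `annotation.csv` (sample_id, cancer_type, batch, ici_treated,
#' os_months, event).
#'
#' @param cohort A list as returned by [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_expression(cohort$expression, file.path(dir, "expression.tsv"))
  readr::write_csv(cohort$annotation, file.path(dir, "annotation.csv"),
                   progress = FALSE)
  invisible(dir)
}

#' Read a cohort annotation CSV
#'
#' @param path Path to a CSV with columns `sample_id`, `cancer_type`,
#'   `batch`, `ici_treated`, `os_months`, `event`.
#' @return The annotation tibble.
#' @export
read_annotation <- function(path) {
  out <- readr::read_csv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    cancer_type = readr::col_character(),
    batch = readr::col_character(),
    ici_treated = readr::col_logical(),
    os_months = readr::col_double(),
    event = readr::col_integer()
  ), progress = FALSE)
  if (!all(out$event %in% c(0L, 1L))) {
    rlang::abort("event must be 0 or 1")
  }
  out
}
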