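#' Built-in T-cell gene signatures
#'
#' Returns the six marker panels used throughout the package, one row per
#' marker gene. Each panel describes a T-cell population of the tumor
#' microenvironment; markers carry a sign so that inhibitory markers absent
#' from a phenotype (Tim-3 in early dysfunctional T cells) subtract from the
#' score rather than add to it.
#'
#' The panels are:
#' \describe{
#'   \item{stem_like_til}{Stem-like tumor-infiltrating lymphocytes:
#'     TCF7, IL7R, CXCR5, CD28, CD27 (all positive).}
#'   \item{trm}{Tissue-resident memory T cells: CD69 and ITGAE (CD103).}
#'   \item{apa}{Activated-potentially anti-tumor T cells: PDCD1 (PD-1),
#'     CD27, CD28, TNFRSF9 (CD137), TNFRSF18 (GITR).}
#'   \item{early_dys}{Early dysfunctional T cells: PDCD1, CCR5, TCF7
#'     positive; HAVCR2 (Tim-3) negative.}
#'   \item{late_dys}{Late dysfunctional T cells: PDCD1, CD38, ENTPD1
#'     (CD39), CD101, HAVCR2 (all positive).}
#'   \item{btn3a}{Butyrophilin 3A isoforms: BTN3A1, BTN3A2, BTN3A3.}
#' }
#'
#' @return A tibble with columns `signature`, `gene` (canonical HGNC
#'   symbol) and `sign` (+1 or -1).
#' @examples
#' builtin_signatures()
#' @export
builtin_signatures <- function() {
  tibble::tribble(
    ~signature,      ~gene,      ~sign,
    "stem_like_til", "TCF7",      1,
    "stem_like_til", "IL7R",      1,
    "stem_like_til", "CXCR5",     1,
    "stem_like_til", "CD28",      1,
    "stem_like_til", "CD27",      1,
    "trm",           "CD69",      1,
    "trm",           "ITGAE",     1,
    "apa",           "PDCD1",     1,
    "apa",           "CD27",      1,
    "apa",           "CD28",      1,
    "apa",           "TNFRSF9",   1,
    "apa",           "TNFRSF18",  1,
    "early_dys",     "PDCD1",     1,
    "early_dys",     "CCR5",      1,
    "early_dys",     "TCF7",      1,
    "early_dys",     "HAVCR2",   -1,
    "late_dys",      "PDCD1",     1,
    "late_dys",      "CD38",      1,
    "late_dys",      "ENTPD1",    1,
    "late_dys",      "CD101",     1,
    "late_dys",      "HAVCR2",    1,
    "btn3a",         "BTN3A1",    1,
    "btn3a",         "BTN3A2",    1,
    "btn3a",         "BTN3A3",    1
  )
}

validate_signatures <- function(signatures) {
  stopifnot(is.data.frame(signatures))
  required <- c("signature", "gene", "sign")
  missing <- setdiff(required, names(signatures))
  if (length(missing) > 0) {
    rlang::abort(paste0(
      "signature table is missing column(s): ",
      paste(missing, collapse = ", ")
    ))
  }
  if (nrow(signatures) == 0) {
    rlang::abort("signature table is empty")
  }
  if (!all(signatures$sign %in% c(-1, 1))) {
    rlang::abort("signature signs must be +1 or -1")
  }
  dup <- signatures |>
    dplyr::count(.data$signature, .data$gene) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    rlang::abort(paste0(
      "duplicated marker within a signature: ",
      paste(unique(dup$signature), collapse = ", ")
    ))
  }
  invisible(signatures)
}

#' Per-gene z-scores across a reference population
#'
#' Standardizes every gene of a log2(TPM+1) expression table to zero mean
#' and unit standard deviation over a reference sample set (all samples by
#' default, so that scores from different strata live on one common axis).
#' The standard deviation uses the n-1 denominator. Genes with zero
#' variance over the reference get z = 0 for every sample and are reported
#' in a warning and in the `zero_variance` attribute of the result.
#'
#' @param expr Expression tibble: first column `gene_id`, one numeric
#'   column per sample, values on the log2(TPM+1) scale.
#' @param reference Character vector of sample ids to use as the reference
#'   population, or `NULL` for all samples.
#' @return A tibble of the same shape as `expr` holding z-scores, with a
#'   `zero_variance` attribute listing genes whose reference SD was zero.
#' @examples
#' expr <- tibble::tibble(gene_id = "G1", s1 = 1, s2 = 2, s3 = 3)
#' gene_zscores(expr)
#' @export
gene_zscores <- function(expr, reference = NULL) {
  mat <- expr_to_matrix(expr)
  ref <- if (is.null(reference)) colnames(mat) else as.character(reference)
  missing_ref <- setdiff(ref, colnames(mat))
  if (length(missing_ref) > 0) {
    rlang::abort(paste0(
      "reference samples not in matrix: ",
      paste(utils::head(missing_ref, 5), collapse = ", ")
    ))
  }
  if (length(ref) < 2) {
    rlang::abort("reference population must contain at least 2 samples")
  }
  ref_mat <- mat[, ref, drop = FALSE]
  mu <- rowMeans(ref_mat)
  sd <- apply(ref_mat, 1, stats::sd)
  zero_var <- rownames(mat)[sd == 0]
  sd_safe <- ifelse(sd == 0, 1, sd)
  z <- (mat - mu) / sd_safe
  z[sd == 0, ] <- 0
  if (length(zero_var) > 0) {
    rlang::warn(paste0(
      length(zero_var), " gene(s) with zero variance in the reference ",
      "population set to z = 0: ",
      paste(utils::head(zero_var, 5), collapse = ", "),
      if (length(zero_var) > 5) ", ..." else ""
    ))
  }
  out <- matrix_to_expr(z)
  attr(out, "zero_variance") <- zero_var
  out
}

#' Score one signature on a z-score table
#'
#' The per-sample score is the sign-aware average of the marker z-scores:
#' score_s = (1/k) * sum_i sign_i * z(g_i, s) over the k markers.
#'
#' @param z Z-score tibble as produced by [gene_zscores()].
#' @param signature One-signature subset of a signature table (columns
#'   `gene`, `sign`, optionally `signature`).
#' @param on_missing `"error"` (default) aborts listing markers absent from
#'   `z`; `"drop"` drops them with a warning and averages the rest.
#' @return A tibble with columns `sample_id` and `score`.
#' @examples
#' expr <- tibble::tibble(
#'   gene_id = c("A", "B"),
#'   s1 = c(1, 5), s2 = c(2, 6), s3 = c(3, 7)
#' )
#' z <- gene_zscores(expr)
#' score_signature(z, tibble::tibble(gene = c("A", "B"), sign = c(1, -1)))
#' @export
score_signature <- function(z, signature, on_missing = c("error", "drop")) {
  on_missing <- match.arg(on_missing)
  stopifnot(is.data.frame(signature), all(c("gene", "sign") %in% names(signature)))
  if (nrow(signature) == 0) {
    rlang::abort("empty signature")
  }
  if ("signature" %in% names(signature) &&
      length(unique(signature$signature)) > 1) {
    rlang::abort("score_signature() expects a single signature; use score_signatures()")
  }
  zmat <- expr_to_matrix(z)
  absent <- setdiff(signature$gene, rownames(zmat))
  if (length(absent) > 0) {
    if (on_missing == "error") {
      rlang::abort(paste0(
        "marker gene(s) missing from the matrix: ",
        paste(absent, collapse = ", ")
      ))
    }
    rlang::warn(paste0(
      "dropping ", length(absent), " missing marker(s): ",
      paste(absent, collapse = ", ")
    ))
    signature <- signature[!signature$gene %in% absent, , drop = FALSE]
    if (nrow(signature) == 0) {
      rlang::abort("no signature markers left after dropping missing genes")
    }
  }
  w <- signature$sign
  sub <- zmat[signature$gene, , drop = FALSE]
  scores <- colSums(sub * w) / nrow(signature)
  tibble::tibble(sample_id = colnames(zmat), score = unname(scores))
}

#' Score a set of signatures on an expression matrix
#'
#' Composes [gene_zscores()] and [score_signature()]: genes are
#' standardized over the reference population, then each signature's
#' sign-aware average z-score is computed per sample.
#'
#' @inheritParams gene_zscores
#' @param signatures Signature table (columns `signature`, `gene`, `sign`);
#'   defaults to the six built-in T-cell panels.
#' @inheritParams score_signature
#' @return A long tibble with columns `sample_id`, `signature`, `score`.
#' @examples
#' cohort <- generate_cohort(synthetic_config(
#'   seed = 1, n_per_type = c(melanoma = 5, ovarian = 5)
#' ))
#' score_signatures(cohort$expression)
#' @export
score_signatures <- function(expr, signatures = builtin_signatures(),
                             reference = NULL,
                             on_missing = c("error", "drop")) {
  on_missing <- match.arg(on_missing)
  validate_signatures(signatures)
  z <- gene_zscores(expr, reference = reference)
  signatures |>
    dplyr::group_by(.data$signature) |>
    dplyr::group_modify(function(sig, key) {
      score_signature(z, sig, on_missing = on_missing)
    }) |>
    dplyr::ungroup() |>
    dplyr::select("sample_id", "signature", "score") |>
    dplyr::arrange(match(.data$sample_id, setdiff(names(expr), "gene_id")),
                   match(.data$signature, unique(signatures$signature)))
}

#' Read / write signature tables as YAML
#'
#' The YAML layout is a list of entries with a `name` and a `markers` list
#' of `{gene, sign}` pairs.
#'
#' @param path File path.
#' @return `read_signatures_yaml()` returns a signature tibble;
#'   `write_signatures_yaml()` returns `path` invisibly.
#' @export
read_signatures_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- purrr::map_dfr(raw, function(entry) {
    tibble::tibble(
      signature = entry$name,
      gene = purrr::map_chr(entry$markers, "gene"),
      sign = purrr::map_dbl(entry$markers, "sign")
    )
  })
  validate_signatures(out)
  out
}

#' @rdname read_signatures_yaml
#' @param signatures Signature tibble (columns `signature`, `gene`, `sign`).
#' @export
write_signatures_yaml <- function(signatures, path) {
  validate_signatures(signatures)
  entries <- purrr::map(unique(signatures$signature), function(nm) {
    sig <- signatures[signatures$signature == nm, ]
    list(
      name = nm,
      markers = purrr::map2(sig$gene, sig$sign, function(g, s) {
        list(gene = g, sign = s)
      })
    )
  })
  yaml::write_yaml(entries, path)
  invisible(path)
}
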