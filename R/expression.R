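# Expression tables are tibbles: first column `gene_id` (character,
# unique), one numeric column per sample. A `scale_tag` attribute
# ("tpm" or "log2tpm1") records the scale when known.

expr_to_matrix <- function(expr) {
  stopifnot(is.data.frame(expr))
  if (!"gene_id" %in% names(expr)) {
    rlang::abort("expression table must have a `gene_id` first column")
  }
  sample_cols <- setdiff(names(expr), "gene_id")
  if (length(sample_cols) == 0) {
    rlang::abort("expression table has no sample columns")
  }
  mat <- as.matrix(expr[, sample_cols, drop = FALSE])
  if (!is.numeric(mat)) {
    rlang::abort("expression values must be numeric")
  }
  rownames(mat) <- expr$gene_id
  mat
}

matrix_to_expr <- function(mat, scale_tag = NULL) {
  out <- tibble::as_tibble(mat, rownames = "gene_id")
  if (!is.null(scale_tag)) attr(out, "scale_tag") <- scale_tag
  out
}

validate_expression <- function(expr) {
  mat <- expr_to_matrix(expr)
  if (anyNA(mat) || any(!is.finite(mat))) {
    rlang::abort("expression table contains missing or non-finite values")
  }
  dup_g <- unique(expr$gene_id[duplicated(expr$gene_id)])
  if (length(dup_g) > 0) {
    rlang::abort(paste0(
      "duplicated gene id(s): ", paste(utils::head(dup_g, 5), collapse = ", ")
    ))
  }
  samp <- colnames(mat)
  dup_s <- unique(samp[duplicated(samp)])
  if (length(dup_s) > 0) {
    rlang::abort(paste0(
      "duplicated sample id(s): ", paste(utils::head(dup_s, 5), collapse = ", ")
    ))
  }
  invisible(expr)
}

#' Query or set the expression scale tag
#'
#' @param expr Expression tibble.
#' @return The scale tag (`"tpm"`, `"log2tpm1"`, or `NA` when unknown).
#' @export
expression_scale <- function(expr) {
  tag <- attr(expr, "scale_tag", exact = TRUE)
  if (is.null(tag)) NA_character_ else tag
}

#' Read an expression matrix from TSV
#'
#' The expected layout is a header row of sample ids and a first column of
#' gene ids (any header name is accepted for the first column). Duplicate
#' gene or sample ids, non-numeric cells and missing values are rejected.
#'
#' @param path Path to a tab-separated file.
#' @param scale One of `"tpm"` or `"log2tpm1"`, declaring the scale of the
#'   stored values.
#' @return An expression tibble (column `gene_id` + one column per sample)
#'   with the declared `scale_tag` attribute.
#' @export
read_expression <- function(path, scale = c("log2tpm1", "tpm")) {
  scale <- match.arg(scale)
  header <- names(readr::read_tsv(
    path, n_max = 0, col_types = readr::cols(.default = "c"),
    progress = FALSE, show_col_types = FALSE, name_repair = "minimal"
  ))
  dup_h <- unique(header[duplicated(header)])
  if (length(dup_h) > 0) {
    rlang::abort(paste0(
      "duplicated sample id(s) in header: ", paste(dup_h, collapse = ", ")
    ))
  }
  types <- do.call(readr::cols, c(
    stats::setNames(list(readr::col_character()), header[1]),
    list(.default = readr::col_double())
  ))
  raw <- suppressWarnings(
    readr::read_tsv(path, col_types = types, progress = FALSE)
  )
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    rlang::abort(paste0(
      "non-numeric or malformed cell(s) in ", path, ", e.g. row ",
      probs$row[1], ": expected ", probs$expected[1]
    ))
  }
  names(raw)[1] <- "gene_id"
  validate_expression(raw)
  attr(raw, "scale_tag") <- scale
  raw
}

#' Write an expression matrix to TSV
#'
#' @param expr Expression tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  validate_expression(expr)
  readr::write_tsv(expr, path, progress = FALSE)
  invisible(path)
}

#' log2(TPM + 1) transform
#'
#' Maps every TPM value x to log2(x + 1), the standard variance-stabilizing
#' transform for TPM-normalized bulk RNA-seq. Values must be non-negative;
#' a table already tagged as log-scale is rejected.
#'
#' @param expr Expression tibble on the TPM scale.
#' @return The transformed tibble, tagged `log2tpm1`.
#' @examples
#' expr <- tibble::tibble(gene_id = "G1", s1 = 0, s2 = 1, s3 = 7)
#' log_transform(expr)  # 0, 1, 3
#' @export
log_transform <- function(expr) {
  validate_expression(expr)
  if (identical(expression_scale(expr), "log2tpm1")) {
    rlang::abort("expression is already on the log2(TPM+1) scale")
  }
  mat <- expr_to_matrix(expr)
  if (any(mat < 0)) {
    rlang::abort("TPM values must be non-negative")
  }
  matrix_to_expr(log2(mat + 1), scale_tag = "log2tpm1")
}

#' Invert the log2(TPM + 1) transform
#'
#' @param expr Expression tibble on the log2(TPM+1) scale.
#' @return The TPM-scale tibble (2^x - 1), tagged `tpm`.
#' @export
expression_to_tpm <- function(expr) {
  validate_expression(expr)
  if (identical(expression_scale(expr), "tpm")) {
    rlang::abort("expression is already on the TPM scale")
  }
  mat <- expr_to_matrix(expr)
  matrix_to_expr(2^mat - 1, scale_tag = "tpm")
}

#' Built-in gene alias map
#'
#' Canonicalizes the protein-level marker names of the built-in T-cell
#' panels to HGNC gene symbols: PD-1/PD1 -> PDCD1, Tim-3/TIM-3/TIM3 ->
#' HAVCR2, CD103 -> ITGAE, CD137 -> TNFRSF9, GITR -> TNFRSF18, CD39 ->
#' ENTPD1. Canonical symbols map to themselves.
#'
#' @return A tibble with columns `alias` and `canonical`.
#' @export
builtin_alias_map <- function() {
  pairs <- c(
    "PD-1" = "PDCD1", "PD1" = "PDCD1",
    "Tim-3" = "HAVCR2", "TIM-3" = "HAVCR2", "TIM3" = "HAVCR2",
    "CD103" = "ITGAE",
    "CD137" = "TNFRSF9",
    "GITR" = "TNFRSF18",
    "CD39" = "ENTPD1"
  )
  canon <- unique(unname(pairs))
  tibble::tibble(
    alias = c(names(pairs), canon),
    canonical = c(unname(pairs), canon)
  )
}

validate_alias_map <- function(aliases) {
  stopifnot(is.data.frame(aliases), all(c("alias", "canonical") %in% names(aliases)))
  multi <- aliases |>
    dplyr::distinct(.data$alias, .data$canonical) |>
    dplyr::count(.data$alias) |>
    dplyr::filter(.data$n > 1)
  if (nrow(multi) > 0) {
    rlang::abort(paste0(
      "alias maps to more than one canonical id: ",
      paste(multi$alias, collapse = ", ")
    ))
  }
  canon <- unique(aliases$canonical)
  mapped <- aliases$canonical[match(canon, aliases$alias)]
  bad <- canon[!is.na(mapped) & mapped != canon]
  if (length(bad) > 0) {
    rlang::abort(paste0(
      "canonical id remaps to a different id: ", paste(bad, collapse = ", ")
    ))
  }
  invisible(aliases)
}

#' Standardize gene identifiers with an alias map
#'
#' Replaces every gene id that appears in the alias map by its canonical
#' form; ids not covered by the map pass through verbatim and are recorded
#' in the `unmapped` attribute. Two input rows collapsing onto one
#' canonical id is an error (the input carries the same gene twice under
#' different names).
#'
#' @param expr Expression tibble.
#' @param aliases Alias tibble (columns `alias`, `canonical`); defaults to
#'   the built-in marker alias map.
#' @return The expression tibble with canonical gene ids, `unmapped`
#'   attribute listing ids the map did not cover.
#' @examples
#' expr <- tibble::tibble(gene_id = c("CD103", "CD69"), s1 = c(1, 2), s2 = c(3, 4))
#' standardize_gene_ids(expr)$gene_id  # "ITGAE" "CD69"
#' @export
standardize_gene_ids <- function(expr, aliases = builtin_alias_map()) {
  validate_expression(expr)
  validate_alias_map(aliases)
  idx <- match(expr$gene_id, aliases$alias)
  new_ids <- ifelse(is.na(idx), expr$gene_id, aliases$canonical[idx])
  dup <- unique(new_ids[duplicated(new_ids)])
  if (length(dup) > 0) {
    rlang::abort(paste0(
      "gene rows collapse to the same canonical id after standardization: ",
      paste(dup, collapse = ", ")
    ))
  }
  out <- expr
  out$gene_id <- new_ids
  attr(out, "scale_tag") <- attr(expr, "scale_tag", exact = TRUE)
  attr(out, "unmapped") <- expr$gene_id[is.na(idx)]
  out
}
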