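#' Classify immunotherapy response from overall survival
#'
#' Applies the OS-threshold response rule: among ICI-treated samples,
#' responders are those with `os_months >= cutoff_months`; non-responders
#' died (`event == 1`) before the cutoff. Samples censored before the
#' cutoff carry too little follow-up to be labeled either way and are
#' marked `unevaluable`, as are all non-ICI-treated samples.
#'
#' @param annot Annotation tibble with `sample_id`, `ici_treated`,
#'   `os_months`, `event`.
#' @param cutoff_months Response cutoff in months (default 24).
#' @return `annot` with an added `response` column
#'   (`responder` / `non_responder` / `unevaluable`).
#' @examples
#' annot <- tibble::tibble(
#'   sample_id = c("a", "b", "c"), ici_treated = TRUE,
#'   os_months = c(30, 10, 10), event = c(0L, 1L, 0L)
#' )
#' classify_response(annot)$response
#' @export
classify_response <- function(annot, cutoff_months = 24) {
  if (cutoff_months <= 0) rlang::abort("cutoff_months must be positive")
  stopifnot(all(c("ici_treated", "os_months", "event") %in% names(annot)))
  annot |>
    dplyr::mutate(response = dplyr::case_when(
      !.data$ici_treated ~ "unevaluable",
      .data$os_months >= cutoff_months ~ "responder",
      .data$event == 1 ~ "non_responder",
      TRUE ~ "unevaluable"
    ))
}

#' Cross-cancer differential infiltration analysis
#'
#' Scores every signature on a common (pooled) z-score axis and tests
#' each unordered pair of cancer types per signature with the
#' Mann-Whitney U test, adjusting p-values per signature across its
#' pairwise family with Benjamini-Hochberg. Group medians and IQRs (the
#' boxplot statistics) and the direction of the difference are reported
#' alongside.
#'
#' @param expr Expression tibble on the log2(TPM+1) scale (batch-adjusted
#'   upstream if desired).
#' @param annot Annotation tibble with `sample_id` and `cancer_type`.
#' @param signatures Signature table; defaults to the six built-ins.
#' @param reference Reference population for z-scores (`NULL` = all
#'   samples, the common-axis convention).
#' @param q_threshold FDR threshold for the `significant` flag
#'   (default 0.02).
#' @param display_threshold Raw-p display threshold reported as
#'   `below_display_threshold` (default 0.001).
#' @return A tibble with one row per signature x cancer-type pair:
#'   group sizes, medians, IQRs, `direction` (which type scored higher in
#'   the median), `u_statistic`, `p`, `q`, and the significance flags.
#' @export
run_cross_cancer <- function(expr, annot, signatures = builtin_signatures(),
                             reference = NULL, q_threshold = 0.02,
                             display_threshold = 0.001) {
  scores <- score_signatures(expr, signatures, reference = reference) |>
    dplyr::inner_join(
      dplyr::select(annot, "sample_id", "cancer_type"),
      by = "sample_id"
    )
  types <- sort(unique(scores$cancer_type))
  if (length(types) < 2) {
    rlang::abort("need at least 2 cancer types")
  }
  counts <- scores |>
    dplyr::distinct(.data$sample_id, .data$cancer_type) |>
    dplyr::count(.data$cancer_type)
  if (any(counts$n < 2)) {
    rlang::abort(paste0(
      "cancer type(s) with fewer than 2 samples: ",
      paste(counts$cancer_type[counts$n < 2], collapse = ", ")
    ))
  }
  pairs <- utils::combn(types, 2, simplify = FALSE)
  # one test per signature x unordered type pair
  rows <- purrr::map_dfr(unique(signatures$signature), function(sig) {
    sig_scores <- scores[scores$signature == sig, ]
    purrr::map_dfr(pairs, function(pr) {
      a <- sig_scores$score[sig_scores$cancer_type == pr[1]]
      b <- sig_scores$score[sig_scores$cancer_type == pr[2]]
      test <- mann_whitney_u(a, b)
      tibble::tibble(
        signature = sig, type_a = pr[1], type_b = pr[2],
        n_a = length(a), n_b = length(b),
        median_a = stats::median(a), median_b = stats::median(b),
        iqr_a = stats::IQR(a), iqr_b = stats::IQR(b),
        direction = dplyr::if_else(stats::median(a) >= stats::median(b),
                                   pr[1], pr[2]),
        u_statistic = test$u_statistic, p = test$p_two_sided
      )
    })
  })
  rows |>
    dplyr::group_by(.data$signature) |>
    dplyr::mutate(q = bh_adjust(.data$p)) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      significant = .data$q < q_threshold,
      below_display_threshold = .data$p < display_threshold
    )
}

#' Responder versus non-responder comparison
#'
#' Restricts to ICI-treated samples, labels responders by the OS rule of
#' [classify_response()], and tests each signature's scores between
#' responders and non-responders with the Mann-Whitney U test,
#' Benjamini-Hochberg adjusted across the signature family.
#'
#' @inheritParams run_cross_cancer
#' @param annot Annotation tibble with `sample_id`, `ici_treated`,
#'   `os_months`, `event` (or a precomputed `response` column).
#' @param cutoff_months Response cutoff in months (default 24).
#' @param q_threshold FDR threshold for the `significant` flag
#'   (default 0.02, the FDR-adjusted significance convention).
#' @return A tibble with one row per signature: group sizes, medians,
#'   `u_statistic`, `p`, `q`, `significant`.
#' @export
run_responder_comparison <- function(expr, annot,
                                     signatures = builtin_signatures(),
                                     reference = NULL, cutoff_months = 24,
                                     q_threshold = 0.02) {
  if (!"response" %in% names(annot)) {
    annot <- classify_response(annot, cutoff_months)
  }
  eval_annot <- annot |>
    dplyr::filter(.data$response %in% c("responder", "non_responder"))
  n_resp <- sum(eval_annot$response == "responder")
  n_non <- sum(eval_annot$response == "non_responder")
  if (n_resp < 2 || n_non < 2) {
    rlang::abort(paste0(
      "need at least 2 responders and 2 non-responders (have ",
      n_resp, " / ", n_non, ")"
    ))
  }
  scores <- score_signatures(expr, signatures, reference = reference) |>
    dplyr::inner_join(
      dplyr::select(eval_annot, "sample_id", "response"),
      by = "sample_id"
    )
  rows <- purrr::map_dfr(unique(signatures$signature), function(sig) {
    sig_scores <- scores[scores$signature == sig, ]
    resp <- sig_scores$score[sig_scores$response == "responder"]
    non <- sig_scores$score[sig_scores$response == "non_responder"]
    test <- mann_whitney_u(resp, non)
    tibble::tibble(
      signature = sig,
      n_responder = length(resp), n_non_responder = length(non),
      median_responder = stats::median(resp),
      median_non_responder = stats::median(non),
      u_statistic = test$u_statistic, p = test$p_two_sided
    )
  })
  rows |>
    dplyr::mutate(
      q = bh_adjust(.data$p),
      significant = .data$q < q_threshold
    )
}

#' Median-split survival analysis per signature
#'
#' For each signature, ICI-treated samples are stratified into high and
#' low expression at a score quantile (median by default, ties to low),
#' Kaplan-Meier curves are fitted per stratum, and the strata are
#' compared with the two-group log-rank test.
#'
#' @inheritParams run_responder_comparison
#' @param prob Quantile for the high/low cutpoint (default 0.5).
#' @param alpha Raw-p significance threshold for the flag (default 0.05).
#' @return An object of class `immunosig_survfit` with elements
#'   `summary` (one row per signature: stratum sizes, median OS per
#'   stratum, log-rank `chi2`, `p`, `significant`) and `curves` (the KM
#'   curve rows per signature and stratum). `glance()` returns the
#'   summary, `tidy()` the curves, and `autoplot()` draws faceted KM
#'   plots.
#' @export
run_survival <- function(expr, annot, signatures = builtin_signatures(),
                         reference = NULL, prob = 0.5, alpha = 0.05) {
  stopifnot(all(c("sample_id", "ici_treated", "os_months", "event")
                %in% names(annot)))
  treated <- annot |>
    dplyr::filter(.data$ici_treated, is.finite(.data$os_months))
  if (nrow(treated) < 4) {
    rlang::abort("too few ICI-treated samples for survival analysis")
  }
  scores <- score_signatures(expr, signatures, reference = reference) |>
    dplyr::inner_join(
      dplyr::select(treated, "sample_id", "os_months", "event"),
      by = "sample_id"
    )
  sig_names <- unique(signatures$signature)
  pieces <- purrr::map(sig_names, function(sig) {
    d <- scores[scores$signature == sig, ]
    d$stratum <- median_split(d$score, prob = prob)
    if (!all(c("high", "low") %in% d$stratum)) {
      rlang::abort(paste0("empty stratum for signature ", sig))
    }
    hi <- d[d$stratum == "high", ]
    lo <- d[d$stratum == "low", ]
    lr <- logrank_test(hi$os_months, hi$event, lo$os_months, lo$event)
    km_hi <- km_fit(hi$os_months, hi$event)
    km_lo <- km_fit(lo$os_months, lo$event)
    list(
      summary = tibble::tibble(
        signature = sig, n_high = nrow(hi), n_low = nrow(lo),
        median_os_high = km_median(km_hi), median_os_low = km_median(km_lo),
        chi2 = lr$chi2, p = lr$p, significant = lr$p < alpha
      ),
      curves = dplyr::bind_rows(
        dplyr::mutate(km_hi$curve, signature = sig, stratum = "high"),
        dplyr::mutate(km_lo$curve, signature = sig, stratum = "low")
      )
    )
  })
  structure(
    list(
      summary = purrr::map_dfr(pieces, "summary"),
      curves = purrr::map_dfr(pieces, "curves") |>
        dplyr::select("signature", "stratum", dplyr::everything())
    ),
    class = "immunosig_survfit"
  )
}

#' AUROC validation of response prediction
#'
#' Computes, per signature, the rank AUROC of responder versus
#' non-responder scores (the probability that a random responder scores
#' above a random non-responder). When the annotation carries a `cohort`
#' column with several levels, each cohort is scored and evaluated on its
#' own z-score axis and an unweighted `average` row per signature is
#' appended.
#'
#' @inheritParams run_responder_comparison
#' @return A tibble with columns `signature`, `cohort`, `n_responder`,
#'   `n_non_responder`, `auroc`; per-cohort rows first, then one
#'   `average` row per signature when several cohorts are present.
#' @export
run_auroc_validation <- function(expr, annot,
                                 signatures = builtin_signatures(),
                                 reference = NULL, cutoff_months = 24) {
  has_cohort <- "cohort" %in% names(annot) &&
    length(unique(annot$cohort)) > 1
  if (!"cohort" %in% names(annot)) annot$cohort <- "cohort1"
  if (!"response" %in% names(annot)) {
    annot <- classify_response(annot, cutoff_months)
  }
  cohorts <- unique(annot$cohort)
  per_cohort <- purrr::map_dfr(cohorts, function(co) {
    # z-scores are computed over the whole cohort so single-cohort AUROCs
    # are exactly consistent with the responder comparison's U statistic
    cohort_annot <- annot |> dplyr::filter(.data$cohort == co)
    sub_expr <- expr[, c("gene_id", intersect(names(expr),
                                              cohort_annot$sample_id))]
    eval_annot <- cohort_annot |>
      dplyr::filter(.data$response %in% c("responder", "non_responder"))
    scores <- score_signatures(sub_expr, signatures,
                               reference = reference) |>
      dplyr::inner_join(
        dplyr::select(eval_annot, "sample_id", "response"),
        by = "sample_id"
      )
    purrr::map_dfr(unique(signatures$signature), function(sig) {
      d <- scores[scores$signature == sig, ]
      resp <- d$score[d$response == "responder"]
      non <- d$score[d$response == "non_responder"]
      if (length(resp) == 0 || length(non) == 0) {
        rlang::abort(paste0("empty response group in cohort ", co))
      }
      tibble::tibble(
        signature = sig, cohort = co,
        n_responder = length(resp), n_non_responder = length(non),
        auroc = auroc(resp, non)
      )
    })
  })
  if (!has_cohort) return(per_cohort)
  avg <- per_cohort |>
    dplyr::group_by(.data$signature) |>
    dplyr::summarise(
      cohort = "average",
      n_responder = sum(.data$n_responder),
      n_non_responder = sum(.data$n_non_responder),
      auroc = mean(.data$auroc),
      .groups = "drop"
    )
  dplyr::bind_rows(per_cohort, avg)
}

#' Run the full analysis and write result tables
#'
#' Orchestrates batch adjustment (optional), cross-cancer comparison,
#' responder comparison, median-split survival analysis and AUROC
#' validation, writing `cross_cancer.csv`, `responder.csv`,
#' `survival.csv`, `km_curves.csv`, `auroc.csv` and `run_log.txt` to a
#' directory.
#'
#' @param expr Expression tibble on the log2(TPM+1) scale.
#' @param annot Annotation tibble (see [read_annotation()]).
#' @param out_dir Output directory (created if needed); `NULL` skips
#'   writing.
#' @param signatures Signature table.
#' @param adjust_batches Apply [combat_adjust()] using the annotation's
#'   `batch` column before scoring (default TRUE).
#' @param cutoff_months Response cutoff (default 24).
#' @param prob Survival-split quantile (default 0.5).
#' @param q_threshold FDR significance threshold (default 0.02).
#' @param alpha Raw-p significance threshold (default 0.05).
#' @param display_threshold Cross-cancer display threshold (default 0.001).
#' @return Invisibly, a list with the four result tables
#'   (`cross_cancer`, `responder`, `survival`, `auroc`).
#' @export
run_immunosig <- function(expr, annot, out_dir = NULL,
                          signatures = builtin_signatures(),
                          adjust_batches = TRUE, cutoff_months = 24,
                          prob = 0.5, q_threshold = 0.02, alpha = 0.05,
                          display_threshold = 0.001) {
  warnings_seen <- character(0)
  withCallingHandlers({
    if (adjust_batches) {
      expr <- combat_adjust(expr, annot)
    }
    cross <- run_cross_cancer(expr, annot, signatures,
                              q_threshold = q_threshold,
                              display_threshold = display_threshold)
    resp <- run_responder_comparison(expr, annot, signatures,
                                     cutoff_months = cutoff_months,
                                     q_threshold = q_threshold)
    surv <- run_survival(expr, annot, signatures, prob = prob,
                         alpha = alpha)
    auc <- run_auroc_validation(expr, annot, signatures,
                                cutoff_months = cutoff_months)
  }, warning = function(w) {
    warnings_seen <<- c(warnings_seen, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  results <- list(
    cross_cancer = cross, responder = resp,
    survival = surv, auroc = auc
  )
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    readr::write_csv(cross, file.path(out_dir, "cross_cancer.csv"),
                     progress = FALSE)
    readr::write_csv(resp, file.path(out_dir, "responder.csv"),
                     progress = FALSE)
    readr::write_csv(surv$summary, file.path(out_dir, "survival.csv"),
                     progress = FALSE)
    readr::write_csv(surv$curves, file.path(out_dir, "km_curves.csv"),
                     progress = FALSE)
    readr::write_csv(auc, file.path(out_dir, "auroc.csv"),
                     progress = FALSE)
    log_lines <- c(
      paste0("immunosig ", as.character(utils::packageVersion("immunosig"))),
      paste0("run at: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
      paste0("samples: ", nrow(annot), "; genes: ", nrow(expr)),
      paste0("batch adjustment: ", adjust_batches),
      paste0("response cutoff (months): ", cutoff_months),
      paste0("survival split quantile: ", prob),
      paste0("thresholds: alpha=", alpha, ", q=", q_threshold,
             ", display=", display_threshold),
      if (length(warnings_seen) > 0) {
        c("warnings:", paste0("  - ", warnings_seen))
      } else "warnings: none"
    )
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  }
  invisible(results)
}
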