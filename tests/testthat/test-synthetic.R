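test_that("cohort dimensions follow the configuration", {
  cfg <- synthetic_config(
    seed = 1, n_per_type = c(melanoma = 10, ovarian = 10),
    n_background_genes = 50
  )
  cohort <- generate_cohort(cfg)
  n_markers <- length(unique(builtin_signatures()$gene))
  expect_equal(ncol(cohort$expression), 1 + 20)
  expect_equal(nrow(cohort$expression), 50 + n_markers)
  expect_equal(nrow(cohort$annotation), 20)
  expect_setequal(unique(cohort$annotation$cancer_type),
                  c("melanoma", "ovarian"))
  expect_named(
    cohort$annotation,
    c("sample_id", "cancer_type", "batch", "ici_treated", "os_months", "event")
  )
  expect_true(all(cohort$annotation$os_months >= 0))
  expect_true(all(cohort$annotation$event %in% c(0L, 1L)))
})

test_that("identical configs give byte-identical cohorts", {
  cfg <- synthetic_config(seed = 42, n_per_type = c(melanoma = 8, ovarian = 7),
                          n_background_genes = 10)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$expression, c2$expression)
  expect_identical(c1$annotation, c2$annotation)
  c3 <- generate_cohort(synthetic_config(
    seed = 43, n_per_type = c(melanoma = 8, ovarian = 7),
    n_background_genes = 10
  ))
  expect_false(identical(c1$expression, c3$expression))
})

test_that("config invariants are enforced", {
  expect_error(synthetic_config(n_per_type = c(melanoma = 0, ovarian = 0)),
               "zero total")
  expect_error(synthetic_config(n_per_type = c(10, 10)), "named")
  expect_error(synthetic_config(censor_rate = 1.5), "\\[0, 1\\]")
  expect_error(synthetic_config(batch_scale = c(b1 = 1, b2 = -1)), "> 0")
  expect_error(synthetic_config(hazard_baseline = 0), "> 0")
  expect_error(synthetic_config(response_signature = "nope"), "unknown")
  bad_eff <- tibble::tibble(cancer_type = "melanoma",
                            signature = "not_a_signature", delta = 1)
  expect_error(
    synthetic_config(n_per_type = c(melanoma = 5), effect_matrix = bad_eff),
    "unknown signature"
  )
  partial <- tidyr::expand_grid(
    cancer_type = "melanoma",
    signature = unique(builtin_signatures()$signature)
  ) |> dplyr::mutate(delta = 0)
  expect_error(
    synthetic_config(n_per_type = c(melanoma = 5, ovarian = 5),
                     effect_matrix = partial),
    "cover exactly"
  )
})

test_that("null cohorts give uniform downstream p-values", {
  # all effects zero, beta = 0: Mann-Whitney p for melanoma vs ovarian
  # should be uniform over repeated seeds
  ps <- vapply(1:40, function(s) {
    cohort <- tiny_cohort(seed = s, n = 15, beta = 0, censor = 0)
    scores <- score_signatures(cohort$expression) |>
      dplyr::filter(.data$signature == "trm") |>
      dplyr::inner_join(cohort$annotation, by = "sample_id")
    a <- scores$score[scores$cancer_type == "melanoma"]
    b <- scores$score[scores$cancer_type == "ovarian"]
    mann_whitney_u(a, b)$p_two_sided
  }, numeric(1))
  # U is integer-valued without score ties, so identical p across seeds is
  # expected; the KS tie warning is immaterial here
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("effect shifts move scores monotonically", {
  gaps <- vapply(c(0, 0.5, 1, 2), function(delta) {
    eff <- tidyr::expand_grid(
      cancer_type = c("melanoma", "ovarian"),
      signature = unique(builtin_signatures()$signature)
    ) |>
      dplyr::mutate(delta = dplyr::if_else(
        .data$cancer_type == "melanoma" & .data$signature == "stem_like_til",
        delta, 0
      ))
    gap <- vapply(1:5, function(s) {
      cohort <- tiny_cohort(seed = s, n = 40, delta = eff)
      scores <- score_signatures(cohort$expression) |>
        dplyr::filter(.data$signature == "stem_like_til") |>
        dplyr::inner_join(cohort$annotation, by = "sample_id")
      mean(scores$score[scores$cancer_type == "melanoma"]) -
        mean(scores$score[scores$cancer_type == "ovarian"])
    }, numeric(1))
    mean(gap)
  }, numeric(1))
  expect_true(all(diff(gaps) > 0))
})

test_that("a unit shift yields the closed-form mean-shift AUROC", {
  # melanoma stem-like delta = 1, k = 5 markers: AUROC ~ Phi(sqrt(k)/sqrt(2))
  eff <- tidyr::expand_grid(
    cancer_type = c("melanoma", "other"),
    signature = unique(builtin_signatures()$signature)
  ) |>
    dplyr::mutate(delta = dplyr::if_else(
      .data$cancer_type == "melanoma" & .data$signature == "stem_like_til",
      1, 0
    ))
  cohort <- generate_cohort(synthetic_config(
    seed = 77, n_per_type = c(melanoma = 500, other = 500),
    n_background_genes = 20, effect_matrix = eff
  ))
  scores <- score_signatures(cohort$expression) |>
    dplyr::filter(.data$signature == "stem_like_til") |>
    dplyr::inner_join(cohort$annotation, by = "sample_id")
  emp <- auroc(scores$score[scores$cancer_type == "melanoma"],
               scores$score[scores$cancer_type == "other"])
  k <- 5
  expect_lt(abs(emp - pnorm(sqrt(k) / sqrt(2))), 0.03)
})

test_that("higher response-signature scores survive longer", {
  cohort <- generate_cohort(synthetic_config(
    seed = 19, n_per_type = c(melanoma = 300), n_background_genes = 10,
    hazard_coefficient = 1, censor_rate = 0
  ))
  scores <- score_signatures(cohort$expression) |>
    dplyr::filter(.data$signature == "trm") |>
    dplyr::inner_join(cohort$annotation, by = "sample_id")
  expect_gt(stats::cor(scores$score, scores$os_months, method = "spearman"), 0.2)
})

test_that("cohort files round-trip through the writers", {
  cohort <- tiny_cohort(seed = 3, n = 5, n_background = 5)
  dir <- withr::local_tempdir()
  write_cohort(cohort, dir)
  expr <- read_expression(file.path(dir, "expression.tsv"))
  annot <- read_annotation(file.path(dir, "annotation.csv"))
  expect_equal(expr$gene_id, cohort$expression$gene_id)
  expect_equal(as.matrix(expr[, -1]), as.matrix(cohort$expression[, -1]),
               tolerance = 1e-9)
  expect_equal(as.data.frame(annot), as.data.frame(cohort$annotation),
               tolerance = 1e-9)
})

test_that("TPM export inverts the log scale", {
  cohort <- tiny_cohort(seed = 4, n = 4, n_background = 5)
  tpm <- expression_to_tpm(cohort$expression)
  expect_identical(expression_scale(tpm), "tpm")
  back <- log_transform(tpm)
  expect_equal(as.matrix(back[, -1]), as.matrix(cohort$expression[, -1]),
               tolerance = 1e-9)
})
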