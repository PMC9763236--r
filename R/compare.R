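#' Extract a (gene, gcr) slice for one population
#'
#' @param table A `carrier_table`.
#' @param population Population label.
#' @return Tibble `gene, gcr` sorted by gene symbol.
#' @export
gcr_slice <- function(table, population) {
  rank_genes(table, population) |>
    dplyr::select("gene", "gcr") |>
    dplyr::arrange(.data$gene)
}

#' Align two cohorts' gene carrier rates
#'
#' Pairs gene carrier rates over the intersection of the two gene sets,
#' keeping only genes with a non-zero carrier rate in at least one cohort —
#' genes invisible to both cohorts carry no comparative information and
#' would inflate tied ranks. Pairing order is deterministic (ascending gene
#' symbol).
#'
#' @param a,b Tibbles with columns `gene` and `gcr` (e.g. from
#'   [gcr_slice()]).
#' @return Tibble `gene, gcr_a, gcr_b`.
#' @export
align_cohorts <- function(a, b) {
  assert_cols(a, c("gene", "gcr"), "cohort a")
  assert_cols(b, c("gene", "gcr"), "cohort b")
  paired <- dplyr::inner_join(a[c("gene", "gcr")], b[c("gene", "gcr")],
                              by = "gene", suffix = c("_a", "_b")) |>
    dplyr::filter(.data$gcr_a > 0 | .data$gcr_b > 0) |>
    dplyr::arrange(.data$gene)
  if (nrow(paired) == 0) {
    abort("no genes with a positive carrier rate in either cohort")
  }
  paired
}

#' Correlate two cohorts' gene carrier rates
#'
#' Spearman's rank correlation (average ranks for ties) and Pearson
#' correlation with two-sided p-values. Pearson is computed on the raw
#' carrier rates by default; `pearson_on = "ranks"` computes it on rank
#' indices instead (a sensitivity switch — Spearman already covers rank
#' space). A vector with zero variance leaves the corresponding coefficient
#' undefined (`NA`).
#'
#' @param paired Tibble from [align_cohorts()] (`gene, gcr_a, gcr_b`), with
#'   at least 3 genes.
#' @param cohort_a,cohort_b Labels carried into the result.
#' @param pearson_on `"gcr"` (default) or `"ranks"`.
#' @return A `cr_correlation` object; use `tidy()` for per-method rows or
#'   `glance()` for a one-row summary.
#' @export
correlate <- function(paired, cohort_a = "a", cohort_b = "b",
                      pearson_on = c("gcr", "ranks")) {
  pearson_on <- match.arg(pearson_on)
  assert_cols(paired, c("gcr_a", "gcr_b"), "paired carrier rates")
  n <- nrow(paired)
  if (n < 3) abort("need at least 3 paired genes to correlate")
  x <- paired$gcr_a
  y <- paired$gcr_b
  sp <- safe_cor_test(x, y, method = "spearman")
  if (pearson_on == "ranks") {
    pe <- safe_cor_test(rank(x), rank(y), method = "pearson")
  } else {
    pe <- safe_cor_test(x, y, method = "pearson")
  }
  structure(
    list(cohort_a = cohort_a, cohort_b = cohort_b, n_genes = n,
         spearman_r = sp$estimate, spearman_p = sp$p.value,
         pearson_r = pe$estimate, pearson_p = pe$p.value,
         pearson_on = pearson_on, data = paired),
    class = "cr_correlation")
}

safe_cor_test <- function(x, y, method) {
  if (sd(x) == 0 || sd(y) == 0) {
    return(list(estimate = NA_real_, p.value = NA_real_))
  }
  ct <- suppressWarnings(
    cor.test(x, y, method = method, exact = FALSE,
             alternative = "two.sided"))
  list(estimate = unname(ct$estimate), p.value = ct$p.value)
}

#' @export
print.cr_correlation <- function(x, ...) {
  cat(sprintf(
    "<cr_correlation %s vs %s: n = %d, Spearman R = %.3f (p = %.3g), Pearson R = %.3f (p = %.3g)>\n",
    x$cohort_a, x$cohort_b, x$n_genes, x$spearman_r, x$spearman_p,
    x$pearson_r, x$pearson_p))
  invisible(x)
}

#' @export
tidy.cr_correlation <- function(x, ...) {
  tibble::tibble(
    cohort_a = x$cohort_a, cohort_b = x$cohort_b,
    method = c("spearman", "pearson"),
    estimate = c(x$spearman_r, x$pearson_r),
    p.value = c(x$spearman_p, x$pearson_p),
    n_genes = x$n_genes)
}

#' @export
glance.cr_correlation <- function(x, ...) {
  tibble::tibble(
    cohort_a = x$cohort_a, cohort_b = x$cohort_b, n_genes = x$n_genes,
    spearman_r = x$spearman_r, spearman_p = x$spearman_p,
    pearson_r = x$pearson_r, pearson_p = x$pearson_p)
}

#' All pairwise correlations among cohort slices
#'
#' @param slices Named list of `gene, gcr` tibbles (names label the
#'   cohorts).
#' @param pearson_on Passed to [correlate()].
#' @return Tibble of all ordered pairs (the matrix is symmetric and the
#'   diagonal is the self-correlation, 1): `cohort_a, cohort_b, n_genes,
#'   spearman_r, spearman_p, pearson_r, pearson_p`.
#' @export
correlation_matrix <- function(slices, pearson_on = "gcr") {
  if (length(slices) < 2) abort("need at least two cohort slices")
  if (is.null(names(slices)) || any(names(slices) == "")) {
    names(slices) <- paste0("cohort", seq_along(slices))
  }
  pairs <- tidyr::expand_grid(cohort_a = names(slices),
                              cohort_b = names(slices))
  purrr::pmap_dfr(pairs, \(cohort_a, cohort_b) {
    paired <- align_cohorts(slices[[cohort_a]], slices[[cohort_b]])
    glance(correlate(paired, cohort_a, cohort_b, pearson_on = pearson_on))
  })
}

#' Row-wise Z-scale a correlation matrix for heatmap export
#'
#' Centres and scales each row of the coefficient matrix to mean 0 and SD 1
#' (the convention used to visualise which counterpart each cohort
#' correlates with most, independent of its overall correlation level).
#'
#' @param cor_tbl Output of [correlation_matrix()].
#' @param coefficient `"spearman_r"` (default) or `"pearson_r"`.
#' @return Tibble `cohort_a, cohort_b, z` of row-scaled coefficients.
#' @export
cor_row_zscale <- function(cor_tbl, coefficient = "spearman_r") {
  cor_tbl |>
    dplyr::group_by(.data$cohort_a) |>
    dplyr::mutate(z = as.numeric(scale(.data[[coefficient]]))) |>
    dplyr::ungroup() |>
    dplyr::select("cohort_a", "cohort_b", "z")
}
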