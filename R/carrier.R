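#' Variant carrier rate from allele counts
#'
#' The per-population carrier rate of a variant is the fraction of
#' individuals carrying the allele heterozygously:
#' `VCR = (AC - 2 * Hom) / (0.5 * AN)`, where `AC` is the allele count,
#' `AN` the number of called alleles and `Hom` the number of homozygous
#' individuals (on chromosome X the source's homozygote convention, which
#' includes hemizygous males, is taken as-is). When `AN = 0` the rate is 0.
#'
#' @param ac,an,hom Numeric vectors (recycled) of allele counts, allele
#'   numbers and homozygote counts; `2 * hom > ac` or `ac > an` indicates
#'   corrupt counts and is an error.
#' @return Numeric vector of carrier rates.
#' @examples
#' compute_vcr(10, 1000, 0)   # 0.02
#' compute_vcr(4, 200, 1)     # (4 - 2) / 100 = 0.02
#' @export
compute_vcr <- function(ac, an, hom = 0) {
  n <- max(length(ac), length(an), length(hom))
  ac <- rep_len(ac, n); an <- rep_len(an, n); hom <- rep_len(hom, n)
  if (any(2 * hom > ac)) abort("corrupt counts: 2 * Hom exceeds AC")
  if (any(ac > an)) abort("corrupt counts: AC exceeds AN")
  ifelse(an > 0, (ac - 2 * hom) / (0.5 * an), 0)
}

#' Gene carrier rate from a list of variant carrier rates
#'
#' Probability that an individual carries at least one of the gene's
#' deleterious alleles, assuming independent variants:
#' `GCR = 1 - prod(1 - VCR_i)`. An empty list gives 0.
#'
#' @param vcrs Numeric vector of variant carrier rates.
#' @param clamp Clamp rates into `[0, 1]` before the product (values outside
#'   are pathological; they are flagged with a warning). With
#'   `clamp = FALSE`, out-of-range rates are an error.
#' @return The gene carrier rate.
#' @examples
#' compute_gcr(c(0.5, 0.5))  # 0.75
#' @export
compute_gcr <- function(vcrs, clamp = TRUE) {
  if (length(vcrs) == 0) return(0)
  out_of_range <- vcrs < 0 | vcrs > 1
  if (any(out_of_range)) {
    if (!clamp) abort("variant carrier rate outside [0, 1]")
    warn(sprintf("%d variant carrier rate(s) clamped into [0, 1]",
                 sum(out_of_range)))
    vcrs <- pmin(1, pmax(0, vcrs))
  }
  1 - prod(1 - vcrs)
}

#' Predicted genetic prevalence at the gene level
#'
#' Expected affected-birth frequency under random mating of carriers: both
#' parents carry one of the gene's deleterious alleles and each transmits
#' it, giving the symmetric double sum
#' `pGPg = sum_i sum_k VCR_i * VCR_k / 4 = (sum_i VCR_i)^2 / 4`.
#' An empty list gives 0.
#'
#' @inheritParams compute_gcr
#' @return The predicted genetic prevalence.
#' @examples
#' compute_pgpg(c(0.02, 0.02))  # 0.0004
#' @export
compute_pgpg <- function(vcrs, clamp = TRUE) {
  if (length(vcrs) == 0) return(0)
  out_of_range <- vcrs < 0 | vcrs > 1
  if (any(out_of_range)) {
    if (!clamp) abort("variant carrier rate outside [0, 1]")
    vcrs <- pmin(1, pmax(0, vcrs))
  }
  sum(vcrs)^2 / 4
}

#' Per-gene, per-population carrier table
#'
#' Computes the variant carrier rate of every typed (deleterious) variant in
#' every population, aggregates them into gene carrier rates and predicted
#' genetic prevalence, and ranks genes within each population by descending
#' carrier rate (ties broken by ascending gene symbol). Catalog genes
#' without any typed variant get a carrier rate of 0 and participate in the
#' ranking, so rankings are comparable across cohorts.
#'
#' @param typed A `cr_classification` or a tibble with `chrom, pos, ref,
#'   alt, gene` rows of deleterious variants.
#' @param records Wide callset tibble carrying the `AC_/AN_/Hom_` columns.
#' @param catalog A `gene_catalog` (defines the gene universe).
#' @param populations Populations to compute; default all populations
#'   detected in `records`.
#' @return A `carrier_table`: tibble `gene, population, n_variants, gcr,
#'   pgpg, rank`, with the per-variant detail in attribute `"vcr"`.
#' @export
carrier_table <- function(typed, records, catalog, populations = NULL) {
  if (inherits(typed, "cr_classification")) typed <- typed$typed
  assert_cols(typed, c(.key_cols, "gene"), "typed variants")
  populations <- populations %||% detect_populations(records)
  if (length(populations) == 0) abort("no population count columns found")

  genes <- sort(unique(catalog$symbol))
  typed <- dplyr::filter(typed, .data$gene %in% genes)
  dat <- dplyr::inner_join(
    typed[c(.key_cols, "gene")],
    records[c(.key_cols, count_cols(populations))], by = .key_cols)

  vcr_detail <- purrr::map_dfr(populations, \(pop) {
    tibble::tibble(
      gene = dat$gene, population = pop,
      chrom = dat$chrom, pos = dat$pos, ref = dat$ref, alt = dat$alt,
      AC = dat[[paste0("AC_", pop)]],
      AN = dat[[paste0("AN_", pop)]],
      Hom = dat[[paste0("Hom_", pop)]],
      vcr = compute_vcr(dat[[paste0("AC_", pop)]],
                        dat[[paste0("AN_", pop)]],
                        dat[[paste0("Hom_", pop)]]))
  }) |>
    dplyr::arrange(.data$population, .data$gene, .data$chrom, .data$pos,
                   .data$ref, .data$alt)

  agg <- vcr_detail |>
    dplyr::group_by(.data$gene, .data$population) |>
    dplyr::summarise(n_variants = dplyr::n(),
                     gcr = compute_gcr(.data$vcr),
                     pgpg = compute_pgpg(.data$vcr),
                     .groups = "drop")
  full <- tidyr::expand_grid(gene = genes, population = populations) |>
    dplyr::left_join(agg, by = c("gene", "population")) |>
    dplyr::mutate(n_variants = dplyr::coalesce(.data$n_variants, 0L),
                  gcr = dplyr::coalesce(.data$gcr, 0),
                  pgpg = dplyr::coalesce(.data$pgpg, 0)) |>
    dplyr::group_by(.data$population) |>
    dplyr::arrange(dplyr::desc(.data$gcr), .data$gene,
                   .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$population, .data$rank)
  structure(full, class = c("carrier_table", class(tibble::tibble())),
            vcr = vcr_detail)
}

#' Ranked gene list for one population
#'
#' @param table A `carrier_table`.
#' @param population Population label present in the table.
#' @param top_k Optionally keep only the top `k` genes.
#' @return The population's rows sorted by rank.
#' @export
rank_genes <- function(table, population, top_k = NULL) {
  if (!population %in% table$population) {
    abort(sprintf("unknown population '%s'", population))
  }
  out <- tibble::as_tibble(table) |>
    dplyr::filter(.data$population == !!population) |>
    dplyr::arrange(.data$rank)
  if (!is.null(top_k)) out <- head(out, top_k)
  out
}

#' @export
print.carrier_table <- function(x, ...) {
  cat(sprintf("<carrier_table: %d genes x %d populations>\n",
              dplyr::n_distinct(x$gene), dplyr::n_distinct(x$population)))
  NextMethod()
}

#' @export
tidy.carrier_table <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
glance.carrier_table <- function(x, ...) {
  tibble::tibble(
    n_genes = dplyr::n_distinct(x$gene),
    n_populations = dplyr::n_distinct(x$population),
    n_gene_population_cells = nrow(x),
    n_cells_nonzero = sum(x$gcr > 0),
    max_gcr = max(x$gcr))
}

#' Write carrier-table outputs
#'
#' `write_carrier_table()` writes the long-format gene/population table;
#' `write_vcr_detail()` the per-variant carrier rates behind it;
#' `write_top_genes()` a per-population top-`k` summary.
#'
#' @param table A `carrier_table`.
#' @param path Output TSV path.
#' @param top_k Number of top genes per population (default 10).
#' @return `path`, invisibly.
#' @export
write_carrier_table <- function(table, path) {
  readr::write_tsv(tibble::as_tibble(table), path)
  invisible(path)
}

#' @rdname write_carrier_table
#' @export
write_vcr_detail <- function(table, path) {
  detail <- attr(table, "vcr")
  if (is.null(detail)) abort("carrier table carries no VCR detail")
  readr::write_tsv(detail, path)
  invisible(path)
}

#' @rdname write_carrier_table
#' @export
write_top_genes <- function(table, path, top_k = 10) {
  top <- table |>
    dplyr::group_by(.data$population) |>
    dplyr::slice_min(.data$rank, n = top_k) |>
    dplyr::ungroup()
  readr::write_tsv(top, path)
  invisible(path)
}
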