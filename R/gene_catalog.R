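#' Build the recessive-gene catalog from a genemap2-style table
#'
#' Filters an OMIM genemap2-style gene/phenotype table down to the catalog of
#' autosomal recessive (AR) and X-linked (XL) disease genes. A gene is
#' retained when at least one of its semicolon-separated sub-phenotypes
#' simultaneously
#' (a) carries the phenotype mapping key `"(3)"` (molecular basis known),
#' (b) is annotated `"Autosomal recessive"` or `"X-linked"` — an annotation
#'     that is only `"X-linked dominant"` does not count, and
#' (c) does not begin with `"?"`, `"{"` or `"["` (provisional, susceptibility
#'     or non-disease entries).
#'
#' The three criteria are evaluated per sub-phenotype, so a qualifying
#' sub-phenotype must satisfy all of them at once. Inheritance is labelled by
#' chromosome: genes on chromosome X are `XL`, all others `AR`.
#'
#' @param rows A data frame with (case-insensitively named) columns
#'   `chromosome`, a gene-symbol column (`approved_gene_symbol`,
#'   `gene_symbol` or `symbol`; `gene_symbols` is accepted, using its first
#'   comma-separated token) and `phenotypes`.
#' @param case_sensitive Match the inheritance strings exactly as printed
#'   (default) or case-insensitively.
#' @return A `gene_catalog`: a tibble with one row per retained gene and
#'   columns `symbol`, `chromosome`, `inheritance` (`"AR"`/`"XL"`),
#'   `phenotypes` (list column of the sub-phenotypes that passed, kept for
#'   audit), `n_transcripts` and `coding_length` (filled by
#'   [load_gene_models()]), and `transcripts` (list column of transcript
#'   models).
#' @examples
#' rows <- tibble::tibble(
#'   chromosome = c("chr1", "chrX"),
#'   approved_gene_symbol = c("GENEA", "GENEB"),
#'   phenotypes = c("Disease A, 600000 (3), Autosomal recessive",
#'                  "Disease B, 300000 (3), X-linked recessive")
#' )
#' parse_genemap2(rows)
#' @seealso [read_genemap2()], [load_gene_models()]
#' @export
parse_genemap2 <- function(rows, case_sensitive = TRUE) {
  rows <- tibble::as_tibble(rows)
  names(rows) <- normalize_genemap2_names(names(rows))
  if (nrow(rows) == 0) abort("empty genemap2 input")
  assert_cols(rows, c("chromosome", "phenotypes"), "genemap2 table")
  sym_col <- intersect(c("approved_gene_symbol", "gene_symbol", "symbol",
                         "gene_symbols"),
                       names(rows))[1]
  if (is.na(sym_col)) abort("genemap2 table has no gene-symbol column")

  symbol <- stringr::str_trim(
    stringr::str_split_i(rows[[sym_col]], ",", 1))
  bad <- is.na(rows$phenotypes) | rows$phenotypes == "" |
    is.na(symbol) | symbol == ""
  if (any(bad)) {
    warn(sprintf("skipping %d genemap2 row(s) with missing symbol/phenotypes",
                 sum(bad)))
  }

  kept <- purrr::map(rows$phenotypes,
                     qualifying_subphenotypes,
                     case_sensitive = case_sensitive)
  kept[bad] <- list(character(0))
  retain <- lengths(kept) > 0

  out <- tibble::tibble(
    symbol = symbol[retain],
    chromosome = as.character(rows$chromosome[retain]),
    phenotypes = kept[retain]
  )
  # collapse duplicate symbols (multi-row genes) onto one record
  out <- out |>
    dplyr::group_by(.data$symbol) |>
    dplyr::summarise(
      chromosome = dplyr::first(.data$chromosome),
      phenotypes = list(unique(unlist(.data$phenotypes))),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      inheritance = dplyr::if_else(is_chrx(.data$chromosome), "XL", "AR"),
      n_transcripts = 0L,
      coding_length = NA_integer_,
      transcripts = list(empty_transcripts())
    ) |>
    dplyr::select("symbol", "chromosome", "inheritance", "phenotypes",
                  "n_transcripts", "coding_length", "transcripts") |>
    dplyr::arrange(.data$symbol)
  new_gene_catalog(out)
}

new_gene_catalog <- function(x) {
  structure(x, class = c("gene_catalog", class(tibble::tibble())))
}

empty_transcripts <- function() {
  tibble::tibble(transcript_id = character(), strand = character(),
                 exon_start = list(), exon_end = list(),
                 cds_start = integer(), cds_end = integer(),
                 coding_length = integer())
}

normalize_genemap2_names <- function(nm) {
  nm <- sub("^#\\s*", "", nm)
  gsub("[ .]+", "_", tolower(stringr::str_trim(nm)))
}

# Sub-phenotypes of one Phenotypes cell that pass all three retention rules.
qualifying_subphenotypes <- function(phenotypes, case_sensitive = TRUE) {
  subs <- stringr::str_trim(strsplit(phenotypes, ";", fixed = TRUE)[[1]])
  subs <- subs[subs != ""]
  if (length(subs) == 0) return(character(0))
  fx <- function(pat, x) {
    if (case_sensitive) stringr::str_detect(x, stringr::fixed(pat))
    else stringr::str_detect(x, stringr::fixed(pat, ignore_case = TRUE))
  }
  has_key <- fx("(3)", subs)
  has_ar <- fx("Autosomal recessive", subs)
  has_xl <- fx("X-linked", subs)
  has_xld <- fx("X-linked dominant", subs)
  has_xlr <- fx("X-linked recessive", subs)
  # an X-linked annotation counts unless it is exclusively dominant
  has_mode <- has_ar | has_xlr | (has_xl & !has_xld)
  clean_start <- !stringr::str_detect(subs, "^[?{\\[]")
  subs[has_key & has_mode & clean_start]
}

#' Read a genemap2-style file
#'
#' Reads the tab-separated genemap2 dialect. Comment lines start with `"#"`;
#' if the last comment line before the data looks like the column header
#' (contains both `Chromosome` and `Phenotypes`), it is used as the header,
#' matching the native genemap2.txt layout. Otherwise the first non-comment
#' line is taken as the header.
#'
#' @param path Path to a genemap2-style TSV.
#' @return A tibble of raw rows, suitable for [parse_genemap2()].
#' @export
read_genemap2 <- function(path) {
  lines <- readr::read_lines(path)
  is_comment <- startsWith(lines, "#")
  comments <- lines[is_comment]
  data_lines <- lines[!is_comment & lines != ""]
  header_in_comments <- length(comments) > 0 &&
    grepl("Chromosome", comments[length(comments)]) &&
    grepl("Phenotypes", comments[length(comments)])
  if (header_in_comments) {
    txt <- paste(c(sub("^#\\s*", "", comments[length(comments)]), data_lines),
                 collapse = "\n")
  } else {
    txt <- paste(data_lines, collapse = "\n")
  }
  readr::read_tsv(I(txt), col_types = readr::cols(.default = "c"),
                  progress = FALSE)
}

#' Attach transcript models to a gene catalog
#'
#' Adds genePred-style transcript models to catalog genes. Only protein-coding
#' transcripts (accession starting `"NM_"`) are used; transcripts for genes
#' absent from the catalog are ignored. Exon and CDS coordinates are converted
#' from the genePred 0-based half-open convention to the package-internal
#' 1-based inclusive convention at this boundary. Each transcript's coding
#' length is the number of exonic bases inside the CDS; the gene-level
#' `coding_length` is the longest coding length among its transcripts.
#'
#' @param models A data frame of genePred-style records, e.g. from
#'   [read_genepred()]: columns `name`, `chrom`, `strand`, `tx_start`,
#'   `tx_end`, `cds_start`, `cds_end`, `exon_starts`, `exon_ends`
#'   (comma-separated strings or list columns of integers), `gene`.
#'   Coordinates 0-based half-open.
#' @param catalog A `gene_catalog` from [parse_genemap2()].
#' @return The catalog with `transcripts`, `n_transcripts` and
#'   `coding_length` populated.
#' @export
load_gene_models <- function(models, catalog) {
  stopifnot(inherits(catalog, "gene_catalog"))
  models <- tibble::as_tibble(models)
  assert_cols(models, c("name", "strand", "cds_start", "cds_end",
                        "exon_starts", "exon_ends", "gene"),
              "gene model table")
  models <- dplyr::filter(models, startsWith(.data$name, "NM_"))
  n_unmatched <- sum(!models$gene %in% catalog$symbol)
  models <- dplyr::filter(models, .data$gene %in% catalog$symbol)

  parse_bounds <- function(x) {
    if (is.list(x)) return(purrr::map(x, as.integer))
    purrr::map(strsplit(as.character(x), ",", fixed = TRUE),
               \(v) as.integer(v[v != ""]))
  }
  starts0 <- parse_bounds(models$exon_starts)
  ends0 <- parse_bounds(models$exon_ends)

  tx <- tibble::tibble(
    gene = models$gene,
    transcript_id = models$name,
    strand = models$strand,
    exon_start = purrr::map(starts0, \(s) s + 1L),  # to 1-based inclusive
    exon_end = ends0,
    cds_start = as.integer(models$cds_start) + 1L,
    cds_end = as.integer(models$cds_end)
  )
  tx$coding_length <- purrr::pmap_int(
    tx[c("exon_start", "exon_end", "cds_start", "cds_end")],
    \(exon_start, exon_end, cds_start, cds_end) {
      validate_exons(exon_start, exon_end, cds_start, cds_end)
      sum(pmax(0L, pmin(exon_end, cds_end) - pmax(exon_start, cds_start) + 1L))
    })

  tx_by_gene <- split(
    dplyr::select(tx, -"gene"),
    factor(tx$gene, levels = catalog$symbol))
  catalog$transcripts <- unname(purrr::map(tx_by_gene, tibble::as_tibble))
  catalog$n_transcripts <- purrr::map_int(catalog$transcripts, nrow)
  catalog$coding_length <- purrr::map_int(
    catalog$transcripts,
    \(t) if (nrow(t) == 0) NA_integer_ else max(t$coding_length))
  attr(catalog, "n_unmatched_transcripts") <- n_unmatched
  catalog
}

validate_exons <- function(exon_start, exon_end, cds_start, cds_end) {
  if (length(exon_start) != length(exon_end) || length(exon_start) == 0) {
    abort("transcript with malformed exon bounds")
  }
  if (any(exon_end < exon_start)) abort("exon end precedes exon start")
  if (is.unsorted(exon_start, strictly = TRUE) ||
      any(exon_start[-1] <= exon_end[-length(exon_end)])) {
    abort("exons must be sorted and non-overlapping")
  }
  if (cds_start > cds_end) abort("cds_start must not exceed cds_end")
  if (cds_start < min(exon_start) || cds_end > max(exon_end)) {
    abort("CDS bounds fall outside the exon span")
  }
  invisible(TRUE)
}

#' Read a genePred-style transcript model file
#'
#' Reads the headerless 10+ column genePred TSV dialect (UCSC-style):
#' `name, chrom, strand, txStart, txEnd, cdsStart, cdsEnd, exonCount,
#' exonStarts, exonEnds[, ...,  name2]`. When a 12th (or later `name2`)
#' column is present it is used as the gene symbol.
#'
#' @param path Path to a genePred TSV (no header).
#' @return A tibble with the column names [load_gene_models()] expects.
#' @export
read_genepred <- function(path) {
  raw <- readr::read_tsv(path, col_names = FALSE,
                         col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (ncol(raw) < 10) abort("genePred file must have at least 10 columns")
  out <- tibble::tibble(
    name = raw[[1]], chrom = raw[[2]], strand = raw[[3]],
    tx_start = as.integer(raw[[4]]), tx_end = as.integer(raw[[5]]),
    cds_start = as.integer(raw[[6]]), cds_end = as.integer(raw[[7]]),
    exon_count = as.integer(raw[[8]]),
    exon_starts = raw[[9]], exon_ends = raw[[10]]
  )
  out$gene <- if (ncol(raw) >= 12) raw[[12]] else raw[[1]]
  out
}

#' Write a gene catalog summary TSV
#'
#' @param catalog A `gene_catalog`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_catalog <- function(catalog, path) {
  readr::write_tsv(
    dplyr::select(tibble::as_tibble(catalog), "symbol", "chromosome",
                  "inheritance", "n_transcripts", "coding_length"),
    path)
  invisible(path)
}

#' @export
glance.gene_catalog <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x),
    n_autosomal = sum(x$inheritance == "AR"),
    n_x_linked = sum(x$inheritance == "XL")
  )
}

#' @export
print.gene_catalog <- function(x, ...) {
  cat(sprintf("<gene_catalog: %d genes (%d autosomal recessive, %d X-linked)>\n",
              nrow(x), sum(x$inheritance == "AR"),
              sum(x$inheritance == "XL")))
  NextMethod()
}
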