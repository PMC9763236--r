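#' Reduce per-transcript consequence terms to the most severe
#'
#' When one variant has different consequences on different transcripts, the
#' most severe impact wins. Severity order: the five high-impact
#' loss-of-function terms (`splice_acceptor`, `splice_donor`, `stop_gained`,
#' `frameshift`, `start_lost`, ties broken in that order) above `missense`,
#' above `inframe_indel`, above everything else (which collapses to
#' `other`).
#'
#' @param terms Character vector of consequence terms (annotator ontology;
#'   `inframe_insertion`/`inframe_deletion` collapse onto `inframe_indel`,
#'   low-impact terms onto `other`). Unknown terms are an error.
#' @return The single most severe (collapsed) term.
#' @examples
#' rank_consequence(c("missense", "stop_gained"))  # "stop_gained"
#' @export
rank_consequence <- function(terms) {
  if (length(terms) == 0) abort("no consequence terms supplied")
  mapped <- .cr_term_map[terms]
  if (anyNA(mapped)) {
    abort(paste0("unknown consequence term(s): ",
                 paste(unique(terms[is.na(mapped)]), collapse = ", ")))
  }
  .cr_severity_order[min(match(mapped, .cr_severity_order))]
}

# Per-variant most-severe consequence from a per-transcript table.
summarise_consequences <- function(consequences) {
  assert_cols(consequences, c(.key_cols, "gene", "consequence"),
              "consequence table")
  # fast path: map each term once, then take the per-variant minimum rank
  mapped <- .cr_term_map[consequences$consequence]
  if (anyNA(mapped)) {
    abort(paste0("unknown consequence term(s): ",
                 paste(unique(consequences$consequence[is.na(mapped)]),
                       collapse = ", ")))
  }
  consequences |>
    dplyr::mutate(.rank = match(mapped, .cr_severity_order)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(.key_cols, "gene")))) |>
    dplyr::summarise(most_severe = .cr_severity_order[min(.data$.rank)],
                     .groups = "drop")
}

#' Ensemble tool cutoffs for missense deleteriousness
#'
#' Container for the per-tool score cutoffs used to call a missense variant
#' deleterious. Every tool uses "score at or above cutoff = deleterious"
#' except SIFT, where "at or below" applies. Per-gene cutoffs, when present,
#' are applied only where they are *more* stringent than the global cutoff
#' (higher for `>=`-direction tools, lower for SIFT); the effective cutoff is
#' always the stricter of the two.
#'
#' The shipped global defaults are the mean scores of ClinVar pathogenic
#' missense variants for the seven informative tools: CADD 28.04, DANN 0.99,
#' fathmm_MKL_coding 0.90, phastCons 0.84, Polyphen2 0.90, SIFT 0.04,
#' VEST3 0.78.
#'
#' @param global Named numeric vector of global cutoffs (one per tool).
#' @param per_gene Tibble with columns `gene`, `tool`, `cutoff` of
#'   gene-specific cutoffs, or `NULL`.
#' @param eligible_genes Genes eligible for ensemble-missense calling (genes
#'   with at least one known pathogenic missense variant); defaults to the
#'   genes present in `per_gene`. `NULL` leaves eligibility to be supplied at
#'   classification time.
#' @param mandatory_tools Tools that must always pass (default CADD, DANN,
#'   Polyphen2, SIFT, phastCons).
#' @param min_tools_passing Minimum number of the seven tools that must pass
#'   (default 5).
#' @param require_mandatory If `FALSE`, fall back to the plain
#'   "at least `min_tools_passing` of all tools" rule without a mandatory
#'   subset.
#' @return A `tool_cutoffs` object.
#' @export
tool_cutoffs <- function(global = .cr_default_cutoffs,
                         per_gene = NULL,
                         eligible_genes = NULL,
                         mandatory_tools = .cr_mandatory_tools,
                         min_tools_passing = 5L,
                         require_mandatory = TRUE) {
  stopifnot(all(names(global) %in% .cr_tools))
  if (!is.null(per_gene)) {
    assert_cols(per_gene, c("gene", "tool", "cutoff"), "per-gene cutoffs")
    if (is.null(eligible_genes)) eligible_genes <- unique(per_gene$gene)
  }
  structure(
    list(global = global, per_gene = per_gene,
         eligible_genes = eligible_genes,
         mandatory_tools = mandatory_tools,
         min_tools_passing = as.integer(min_tools_passing),
         require_mandatory = isTRUE(require_mandatory)),
    class = "tool_cutoffs")
}

#' @export
print.tool_cutoffs <- function(x, ...) {
  cat("<tool_cutoffs>\n  global:",
      paste(sprintf("%s=%.3g", names(x$global), x$global), collapse = ", "),
      "\n")
  cat(sprintf("  per-gene entries: %d gene(s); eligible genes: %s\n",
              if (is.null(x$per_gene)) 0L else dplyr::n_distinct(x$per_gene$gene),
              if (is.null(x$eligible_genes)) "unset" else
                length(x$eligible_genes)))
  invisible(x)
}

# stricter-of-two cutoff, honouring tool direction
stricter_cutoff <- function(tool, gene_cutoff, global_cutoff) {
  if (tool %in% .cr_le_tools) pmin(gene_cutoff, global_cutoff)
  else pmax(gene_cutoff, global_cutoff)
}

#' Derive ensemble cutoffs from labelled pathogenic missense scores
#'
#' The global cutoff for each tool is the mean score of labelled pathogenic
#' missense variants (missing scores skipped). A gene-specific cutoff — the
#' mean over that gene's pathogenic missense variants — is recorded for every
#' gene with at least one labelled variant, replaced by the global cutoff
#' wherever it would be *less* stringent, so the effective cutoff never
#' relaxes below the global one. Genes without any labelled pathogenic
#' missense variant get no entry and are ineligible for ensemble-missense
#' classification.
#'
#' @param labeled_scores Tibble with columns `chrom, pos, ref, alt, gene,
#'   significance` plus one column per tool; rows are ClinVar-classified
#'   missense variants.
#' @param classes Significance classes treated as pathogenic for the means
#'   (default `P` and `LP`; set to `"P"` for pathogenic-only).
#' @inheritParams tool_cutoffs
#' @return A `tool_cutoffs` object with per-gene entries.
#' @export
derive_tool_cutoffs <- function(labeled_scores,
                                classes = c("P", "LP"),
                                mandatory_tools = .cr_mandatory_tools,
                                min_tools_passing = 5L,
                                require_mandatory = TRUE) {
  assert_cols(labeled_scores, c("gene", "significance"), "labelled scores")
  tools <- intersect(.cr_tools, names(labeled_scores))
  if (length(tools) == 0) abort("labelled score table has no tool columns")
  path <- dplyr::filter(labeled_scores, .data$significance %in% classes)
  if (nrow(path) == 0) abort("no labelled pathogenic missense variants")

  global <- vapply(tools, \(t) mean(path[[t]], na.rm = TRUE), numeric(1))
  if (anyNA(global)) {
    abort(paste0("no pathogenic scores at all for tool(s): ",
                 paste(tools[is.na(global)], collapse = ", ")))
  }
  per_gene <- path |>
    tidyr::pivot_longer(dplyr::all_of(tools), names_to = "tool",
                        values_to = "score") |>
    dplyr::filter(!is.na(.data$score)) |>
    dplyr::group_by(.data$gene, .data$tool) |>
    dplyr::summarise(cutoff = mean(.data$score), .groups = "drop") |>
    dplyr::rowwise() |>
    dplyr::mutate(cutoff = stricter_cutoff(.data$tool, .data$cutoff,
                                           global[[.data$tool]])) |>
    dplyr::ungroup()
  tool_cutoffs(global = global, per_gene = per_gene,
               eligible_genes = unique(path$gene),
               mandatory_tools = mandatory_tools,
               min_tools_passing = min_tools_passing,
               require_mandatory = require_mandatory)
}

#' Select known pathogenic variants (Type 1)
#'
#' A variant is Type 1 when its ClinVar significance is pathogenic or likely
#' pathogenic, or when its curation is conflicting but carries at least
#' `conflicting_min_pathogenic` pathogenic submissions. Manually curated
#' exclusions are removed. Type 1 variants whose allele frequency reaches
#' `af_review_threshold` in any population are *not* auto-removed; they are
#' returned in the `"review"` attribute so a curator can decide (the
#' exclusion list is the vehicle for that curation).
#'
#' @param records Wide callset tibble (with `AF_` columns).
#' @param clinvar ClinVar-style table: `chrom, pos, ref, alt, significance,
#'   n_pathogenic_entries, variant_class` (significance levels `P, LP, B,
#'   LB, VUS, CONFLICTING, OTHER`).
#' @param manual_exclusions Optional exclusion-key data frame.
#' @param include_lp Count likely-pathogenic as Type 1 (default `TRUE`).
#' @param conflicting_min_pathogenic Minimum pathogenic submissions for a
#'   conflicting variant (default 10).
#' @param af_review_threshold Allele frequency flagging a Type 1 variant for
#'   review (default 0.005).
#' @param gene_map Optional `chrom, pos, ref, alt, gene` table used to label
#'   the gene; if `NULL`, gene is taken from `clinvar` when present.
#' @return Tibble of Type 1 variants (`category = 1L`) with evidence columns.
#' @export
select_type1 <- function(records, clinvar, manual_exclusions = NULL,
                         include_lp = TRUE,
                         conflicting_min_pathogenic = 10L,
                         af_review_threshold = 0.005,
                         gene_map = NULL) {
  assert_cols(clinvar, c(.key_cols, "significance"), "ClinVar table")
  path_classes <- if (include_lp) c("P", "LP") else "P"
  hits <- dplyr::inner_join(records, clinvar, by = .key_cols)
  if (!"n_pathogenic_entries" %in% names(hits)) {
    hits$n_pathogenic_entries <- 0L
  }
  hits <- dplyr::filter(
    hits,
    .data$significance %in% path_classes |
      (.data$significance == "CONFLICTING" &
         .data$n_pathogenic_entries >= conflicting_min_pathogenic))
  hits <- apply_exclusion_list(hits, manual_exclusions)
  if (!"gene" %in% names(hits)) {
    if (!is.null(gene_map)) {
      hits <- dplyr::left_join(hits, gene_map[c(.key_cols, "gene")],
                               by = .key_cols)
    } else {
      hits$gene <- NA_character_
    }
  }
  af_cols <- grep("^AF_", names(hits), value = TRUE)
  max_af <- if (length(af_cols)) {
    do.call(pmax, c(unname(as.list(hits[af_cols])), list(na.rm = TRUE)))
  } else {
    rep(0, nrow(hits))
  }
  out <- hits |>
    dplyr::transmute(
      dplyr::across(dplyr::all_of(c(.key_cols, "gene"))),
      category = 1L,
      significance = .data$significance,
      n_pathogenic_entries = .data$n_pathogenic_entries)
  attr(out, "review") <- out[max_af >= af_review_threshold, , drop = FALSE]
  out
}

#' Prefilter candidates for the predicted-deleterious categories
#'
#' Variants not already known-pathogenic are eligible for the
#' loss-of-function, missense and in-frame INDEL categories only if they are
#' plausibly recessive-deleterious in a healthy cohort: any homozygous call
#' in any population (which on chromosome X includes hemizygous males, per
#' the source convention) removes a variant, as does an allele frequency at
#' or above `af_threshold` in any population whose allele number reaches
#' `min_an` (the floor avoids small-denominator artefacts).
#'
#' @param records Wide callset tibble.
#' @param af_threshold Inclusive allele-frequency bound (default 0.005).
#' @param min_an Minimum AN for a population's AF to count (default 1000).
#' @return The retained rows; removal counts in attribute `"removals"`.
#' @export
candidate_prefilter <- function(records, af_threshold = 0.005,
                                min_an = 1000) {
  pops <- setdiff(detect_populations(records), "ALL")
  if (length(pops) == 0) pops <- detect_populations(records)
  hom_any <- rep(FALSE, nrow(records))
  af_any <- rep(FALSE, nrow(records))
  for (pop in detect_populations(records)) {
    hom_col <- paste0("Hom_", pop)
    if (hom_col %in% names(records)) {
      hom_any <- hom_any | records[[hom_col]] > 0
    }
  }
  for (pop in pops) {
    ac <- records[[paste0("AC_", pop)]]
    an <- records[[paste0("AN_", pop)]]
    af <- ifelse(an > 0, ac / an, 0)
    af_any <- af_any | (an >= min_an & af >= af_threshold)
  }
  out <- records[!hom_any & !af_any, , drop = FALSE]
  attr(out, "removals") <- c(homozygous = sum(hom_any),
                             high_af = sum(!hom_any & af_any))
  out
}

# CDS segments (exon pieces clipped to the CDS) of one transcript,
# ordered 5'->3' along the transcript strand.
cds_segments <- function(exon_start, exon_end, cds_start, cds_end, strand) {
  s <- pmax(exon_start, cds_start)
  e <- pmin(exon_end, cds_end)
  keep <- s <= e
  seg <- tibble::tibble(start = unname(s[keep]), end = unname(e[keep]))
  if (isTRUE(unname(strand) == "-")) seg <- seg[rev(seq_len(nrow(seg))), ]
  seg
}

#' Does a premature stop escape nonsense-mediated decay?
#'
#' Canonical 50-nucleotide rule: a stop-gained variant escapes NMD when its
#' coding position falls in the final exon, or within 50 coding bases
#' (inclusive) upstream of the final exon-exon junction. Transcripts whose
#' CDS spans a single exon always escape. Distances are measured in coding
#' bases along the transcript strand.
#'
#' @param pos 1-based genomic position of the stop-gained variant; must lie
#'   in the transcript's CDS.
#' @param transcript One transcript model row (as stored in a
#'   `gene_catalog`'s `transcripts` list column): fields `strand`,
#'   `exon_start`, `exon_end` (integer vectors, possibly wrapped in lists),
#'   `cds_start`, `cds_end`.
#' @param window Size of the escape window upstream of the final junction,
#'   in coding bases (default 50, inclusive).
#' @return `TRUE` if the variant escapes NMD.
#' @export
nmd_escapes <- function(pos, transcript, window = 50L) {
  tx <- as.list(transcript)
  unwrap <- function(x) unname(if (is.list(x)) x[[1]] else x)
  seg <- cds_segments(unwrap(tx$exon_start), unwrap(tx$exon_end),
                      unwrap(tx$cds_start), unwrap(tx$cds_end),
                      unwrap(tx$strand))
  if (nrow(seg) == 0) abort("transcript has no coding sequence")
  in_seg <- which(pos >= seg$start & pos <= seg$end)
  if (length(in_seg) == 0) abort("variant position outside the CDS")
  if (nrow(seg) == 1) return(TRUE)
  lens <- seg$end - seg$start + 1L
  offset <- if (isTRUE(unwrap(tx$strand) == "-")) {
    seg$end[in_seg] - pos
  } else {
    pos - seg$start[in_seg]
  }
  cds_pos <- sum(lens[seq_len(in_seg - 1)]) + offset + 1L
  junction <- sum(lens) - lens[nrow(seg)]  # coding coord of last junction
  cds_pos >= junction - window
}

# Genomic ranges of one transcript's CDS and of its NMD-escape region
# (final exon plus the window upstream of the last junction), used for
# vectorised escape tests. Equivalent to nmd_escapes() position by position.
transcript_nmd_ranges <- function(transcript, window = 50L) {
  tx <- as.list(transcript)
  unwrap <- function(x) unname(if (is.list(x)) x[[1]] else x)
  strand <- unwrap(tx$strand)
  seg <- cds_segments(unwrap(tx$exon_start), unwrap(tx$exon_end),
                      unwrap(tx$cds_start), unwrap(tx$cds_end), strand)
  if (nrow(seg) == 0) return(NULL)
  lens <- seg$end - seg$start + 1L
  total <- sum(lens)
  lo <- max(1L, total - lens[nrow(seg)] - window)  # first escaping coding pos
  offs <- cumsum(c(0L, lens[-length(lens)]))       # coding offset per segment
  esc_start <- integer(0)
  esc_end <- integer(0)
  for (i in seq_len(nrow(seg))) {
    a <- offs[i] + 1L
    b <- offs[i] + lens[i]
    s <- max(a, lo)
    if (s > b) next
    if (identical(strand, "-")) {
      esc_start <- c(esc_start, seg$end[i] - (b - a))
      esc_end <- c(esc_end, seg$end[i] - (s - a))
    } else {
      esc_start <- c(esc_start, seg$start[i] + (s - a))
      esc_end <- c(esc_end, seg$start[i] + (b - a))
    }
  }
  list(cds_start = seg$start, cds_end = seg$end,
       esc_start = esc_start, esc_end = esc_end)
}

#' Select presumed loss-of-function variants (Type 2)
#'
#' A candidate variant is Type 2 when its most severe consequence is one of
#' the five high-impact terms (stop gained, start lost, frameshift, splice
#' acceptor, splice donor). Stop-gained variants additionally face the NMD
#' test: by default a nonsense variant is excluded only when it escapes NMD
#' on *every* protein-coding transcript that harbours it
#' (`nmd_mode = "all"`); `nmd_mode = "any"` excludes on a single escaping
#' transcript. A stop-gained with no transcript model is retained with a
#' warning (no evidence of escape).
#'
#' @param records Prefiltered wide callset tibble.
#' @param consequences Per-transcript consequence table (`chrom, pos, ref,
#'   alt, gene, consequence`).
#' @param catalog A `gene_catalog` with transcript models loaded.
#' @param nmd_mode `"all"` (default) or `"any"`.
#' @param nmd_window Escape window in coding bases (default 50).
#' @return Tibble of Type 2 variants (`category = 2L`) with NMD evidence.
#' @export
select_type2 <- function(records, consequences, catalog,
                         nmd_mode = c("all", "any"), nmd_window = 50L,
                         .sev = NULL) {
  nmd_mode <- match.arg(nmd_mode)
  sev <- .sev %||% summarise_consequences(consequences)
  cand <- dplyr::inner_join(records[.key_cols], sev, by = .key_cols) |>
    dplyr::filter(.data$most_severe %in% .cr_lof_terms)
  if (nrow(cand) == 0) {
    return(tibble::tibble(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          gene = character(), category = integer(),
                          most_severe = character(), nmd_escape = logical()))
  }
  tx_of <- setNames(catalog$transcripts, catalog$symbol)
  # precompute CDS/escape ranges once per gene carrying a stop-gained
  stop_genes <- unique(cand$gene[cand$most_severe == "stop_gained"])
  ranges_of <- lapply(setNames(stop_genes, stop_genes), \(g) {
    tx <- tx_of[[g]]
    if (is.null(tx) || nrow(tx) == 0) return(list())
    Filter(Negate(is.null), lapply(seq_len(nrow(tx)), \(i) {
      transcript_nmd_ranges(tx[i, ], window = nmd_window)
    }))
  })
  n_no_model <- 0L
  escape <- purrr::pmap_lgl(
    cand[c("pos", "gene", "most_severe")],
    function(pos, gene, most_severe) {
      if (most_severe != "stop_gained") return(FALSE)
      verdicts <- logical(0)
      for (rg in ranges_of[[gene]]) {
        if (any(pos >= rg$cds_start & pos <= rg$cds_end)) {
          verdicts <- c(verdicts,
                        any(pos >= rg$esc_start & pos <= rg$esc_end))
        }
      }
      if (length(verdicts) == 0) {  # no transcript harbours the variant
        n_no_model <<- n_no_model + 1L
        return(FALSE)
      }
      if (nmd_mode == "all") all(verdicts) else any(verdicts)
    })
  if (n_no_model > 0) {
    warn(sprintf(
      "%d stop-gained variant(s) had no covering transcript model; retained",
      n_no_model))
  }
  cand |>
    dplyr::mutate(nmd_escape = escape, category = 2L) |>
    dplyr::filter(!.data$nmd_escape) |>
    dplyr::select(dplyr::all_of(c(.key_cols, "gene")), "category",
                  "most_severe", "nmd_escape")
}

#' Select predicted deleterious missense variants (Type 3)
#'
#' A candidate missense variant is Type 3 when its gene is eligible (has at
#' least one known pathogenic missense variant, hence a per-gene cutoff
#' entry) and its scores meet the effective cutoff in all mandatory tools
#' and in at least `min_tools_passing` of the seven tools overall. Missing
#' scores count as failing. With `require_mandatory = FALSE` in the cutoffs,
#' the plain at-least-k-of-n rule applies instead.
#'
#' @param records Prefiltered wide callset tibble.
#' @param consequences Per-transcript consequence table.
#' @param scores Score table: `chrom, pos, ref, alt` plus one column per
#'   tool.
#' @param cutoffs A `tool_cutoffs` object.
#' @return Tibble of Type 3 variants (`category = 3L`) with the number and
#'   names of tools passed.
#' @export
select_type3 <- function(records, consequences, scores, cutoffs,
                         .sev = NULL) {
  stopifnot(inherits(cutoffs, "tool_cutoffs"))
  sev <- .sev %||% summarise_consequences(consequences)
  cand <- dplyr::inner_join(records[.key_cols], sev, by = .key_cols) |>
    dplyr::filter(.data$most_severe == "missense")
  if (!is.null(cutoffs$eligible_genes)) {
    cand <- dplyr::filter(cand, .data$gene %in% cutoffs$eligible_genes)
  }
  empty <- tibble::tibble(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          gene = character(), category = integer(),
                          n_tools_passed = integer(), tools_passed = list())
  if (nrow(cand) == 0) return(empty)
  tools <- intersect(.cr_tools, names(cutoffs$global))
  cand <- dplyr::left_join(cand, scores[c(.key_cols, intersect(tools, names(scores)))],
                           by = .key_cols)

  score_mat <- matrix(NA_real_, nrow(cand), length(tools),
                      dimnames = list(NULL, tools))
  for (t in intersect(tools, names(cand))) score_mat[, t] <- cand[[t]]

  cut_mat <- matrix(rep(cutoffs$global[tools], each = nrow(cand)),
                    nrow(cand), length(tools), dimnames = list(NULL, tools))
  if (!is.null(cutoffs$per_gene) && nrow(cutoffs$per_gene) > 0) {
    pg <- dplyr::filter(cutoffs$per_gene, .data$tool %in% tools)
    if (nrow(pg) > 0) {
      pg_wide <- tidyr::pivot_wider(pg, names_from = "tool",
                                    values_from = "cutoff")
      ridx <- match(cand$gene, pg_wide$gene)
      for (t in setdiff(names(pg_wide), "gene")) {
        g_cut <- pg_wide[[t]][ridx]
        have <- !is.na(g_cut)
        cut_mat[have, t] <- stricter_cutoff(t, g_cut[have],
                                            cutoffs$global[[t]])
      }
    }
  }
  pass <- matrix(FALSE, nrow(cand), length(tools),
                 dimnames = list(NULL, tools))
  for (t in tools) {
    pass[, t] <- if (t %in% .cr_le_tools) {
      !is.na(score_mat[, t]) & score_mat[, t] <= cut_mat[, t]
    } else {
      !is.na(score_mat[, t]) & score_mat[, t] >= cut_mat[, t]
    }
  }
  n_pass <- rowSums(pass)
  ok <- n_pass >= cutoffs$min_tools_passing
  if (cutoffs$require_mandatory) {
    mand <- intersect(cutoffs$mandatory_tools, tools)
    ok <- ok & rowSums(pass[, mand, drop = FALSE]) == length(mand)
  }
  out <- cand[ok, c(.key_cols, "gene"), drop = FALSE]
  out$category <- 3L
  out$n_tools_passed <- as.integer(n_pass[ok])
  out$tools_passed <- purrr::map(which(ok), \(i) tools[pass[i, ]])
  out
}

#' Select harmful in-frame INDELs (Type 4)
#'
#' A candidate in-frame INDEL is Type 4 when it is evolutionarily conserved
#' (CADD score strictly above 20) and falls in a protein domain that also
#' contains at least one known ClinVar P/LP in-frame INDEL of the same gene.
#' Genes without any known pathogenic in-frame INDEL yield no Type 4
#' variants; variants without a CADD score are excluded.
#'
#' @param records Prefiltered wide callset tibble.
#' @param consequences Per-transcript consequence table.
#' @param scores Score table with a `CADD` column.
#' @param domains Domain interval table: `chrom, start, end, domain_id,
#'   gene`, 1-based inclusive coordinates (see [read_domains()] for BED
#'   input).
#' @param clinvar ClinVar-style table with `variant_class`; rows with
#'   significance P/LP and class `inframe_indel` anchor the domains.
#' @param cadd_min Strict CADD lower bound (default 20).
#' @return Tibble of Type 4 variants (`category = 4L`) with the matched
#'   domain.
#' @export
select_type4 <- function(records, consequences, scores, domains, clinvar,
                         cadd_min = 20, .sev = NULL) {
  assert_cols(domains, c("chrom", "start", "end", "domain_id", "gene"),
              "domain table")
  sev <- .sev %||% summarise_consequences(consequences)
  cand <- dplyr::inner_join(records[.key_cols], sev, by = .key_cols) |>
    dplyr::filter(.data$most_severe == "inframe_indel")
  empty <- tibble::tibble(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          gene = character(), category = integer(),
                          CADD = numeric(), domain_id = character())
  if (nrow(cand) == 0) return(empty)

  # domains anchored by a known pathogenic in-frame INDEL of the same gene
  anchors <- clinvar |>
    dplyr::filter(.data$significance %in% c("P", "LP"),
                  .data$variant_class == "inframe_indel")
  if (nrow(anchors) == 0) return(empty)
  anchored <- dplyr::inner_join(
    domains, anchors[c("chrom", "pos", "ref")],
    by = "chrom", relationship = "many-to-many") |>
    dplyr::filter(.data$pos >= .data$start,
                  .data$pos + nchar(.data$ref) - 1L <= .data$end) |>
    dplyr::distinct(.data$chrom, .data$start, .data$end, .data$domain_id,
                    .data$gene)
  if (nrow(anchored) == 0) return(empty)

  cand <- dplyr::left_join(cand, scores[c(.key_cols, "CADD")],
                           by = .key_cols) |>
    dplyr::filter(!is.na(.data$CADD), .data$CADD > cadd_min)
  if (nrow(cand) == 0) return(empty)
  hits <- dplyr::inner_join(cand, anchored,
                            by = c("chrom", "gene"),
                            relationship = "many-to-many") |>
    dplyr::filter(.data$pos + nchar(.data$ref) - 1L >= .data$start,
                  .data$pos <= .data$end) |>
    dplyr::distinct(dplyr::across(dplyr::all_of(c(.key_cols, "gene"))),
                    .keep_all = TRUE)
  hits |>
    dplyr::transmute(dplyr::across(dplyr::all_of(c(.key_cols, "gene"))),
                     category = 4L, CADD = .data$CADD,
                     domain_id = .data$domain_id)
}

#' Classify all variants into the four deleterious categories
#'
#' Runs the full decision cascade: known pathogenic (Type 1) first; the
#' remainder through the homozygote/allele-frequency prefilter; then
#' presumed loss-of-function (Type 2), predicted deleterious missense
#' (Type 3) and harmful in-frame INDELs (Type 4) by most severe consequence.
#' Each variant lands in at most one category (the consequence classes are
#' mutually exclusive downstream of Type 1).
#'
#' @param records Wide callset tibble (already quality-filtered and merged).
#' @param clinvar ClinVar-style annotation table.
#' @param consequences Per-transcript consequence table.
#' @param scores Tool score table.
#' @param domains Domain interval table (1-based inclusive).
#' @param catalog A `gene_catalog` with transcript models.
#' @param cutoffs A `tool_cutoffs`; when `NULL`, the shipped global defaults
#'   are used and Type 3 gene eligibility is read from `clinvar` (genes with
#'   at least one P/LP missense entry).
#' @param exclusions Optional manual exclusion-key table (applied to Type 1).
#' @param benign_blocks_candidacy Variants curated benign or likely benign
#'   are barred from the predicted categories (default `TRUE`): only
#'   variants of uncertain significance, conflicting curation or absent from
#'   the annotation move forward as Type 2-4 candidates.
#' @inheritParams select_type1
#' @inheritParams candidate_prefilter
#' @inheritParams select_type2
#' @return A `cr_classification` object: list with `typed` (tibble of
#'   `chrom, pos, ref, alt, gene, category` plus evidence columns),
#'   `unclassified` (keys of untyped variants), `counts` (per-category) and
#'   `removals` (prefilter ledger). `tidy()` returns the typed tibble,
#'   `glance()` the count summary.
#' @export
classify_all <- function(records, clinvar, consequences, scores, domains,
                         catalog, cutoffs = NULL, exclusions = NULL,
                         include_lp = TRUE, conflicting_min_pathogenic = 10L,
                         af_threshold = 0.005, min_an = 1000,
                         nmd_mode = "all", benign_blocks_candidacy = TRUE) {
  if (is.null(cutoffs)) {
    eligible <- clinvar |>
      dplyr::filter(.data$significance %in% c("P", "LP"),
                    .data$variant_class == "missense") |>
      dplyr::pull("gene") |>
      unique()
    cutoffs <- tool_cutoffs(eligible_genes = eligible)
  }
  gene_map <- dplyr::distinct(consequences[c(.key_cols, "gene")])
  t1 <- select_type1(records, clinvar, manual_exclusions = exclusions,
                     include_lp = include_lp,
                     conflicting_min_pathogenic = conflicting_min_pathogenic,
                     gene_map = gene_map)
  review <- attr(t1, "review")
  rest <- dplyr::anti_join(records, t1, by = .key_cols)
  if (benign_blocks_candidacy) {
    benign_keys <- dplyr::filter(clinvar,
                                 .data$significance %in% c("B", "LB"))
    rest <- dplyr::anti_join(rest, benign_keys[.key_cols], by = .key_cols)
  }
  cand <- candidate_prefilter(rest, af_threshold = af_threshold,
                              min_an = min_an)
  removals <- attr(cand, "removals")
  sev <- summarise_consequences(consequences)
  t2 <- select_type2(cand, consequences, catalog, nmd_mode = nmd_mode,
                     .sev = sev)
  t3 <- select_type3(cand, consequences, scores, cutoffs, .sev = sev)
  t4 <- select_type4(cand, consequences, scores, domains, clinvar,
                     .sev = sev)
  typed <- dplyr::bind_rows(t1, t2, t3, t4) |>
    dplyr::arrange(.data$chrom, .data$pos, .data$ref, .data$alt)
  unclassified <- dplyr::anti_join(records[.key_cols], typed,
                                   by = .key_cols)
  structure(
    list(typed = typed,
         unclassified = unclassified,
         counts = table(factor(typed$category, levels = 1:4)),
         removals = removals,
         review = review,
         cutoffs = cutoffs),
    class = "cr_classification")
}

#' @export
print.cr_classification <- function(x, ...) {
  cat("<cr_classification>\n")
  cat(sprintf("  Type 1 (known pathogenic):      %d\n", x$counts[["1"]]))
  cat(sprintf("  Type 2 (loss-of-function):      %d\n", x$counts[["2"]]))
  cat(sprintf("  Type 3 (deleterious missense):  %d\n", x$counts[["3"]]))
  cat(sprintf("  Type 4 (harmful in-frame INDEL):%d\n", x$counts[["4"]]))
  cat(sprintf("  unclassified: %d; prefilter removals: %s\n",
              nrow(x$unclassified),
              paste(names(x$removals), x$removals, collapse = ", ")))
  invisible(x)
}

#' Cross-check typed variants against an external classifier
#'
#' Among typed variants present in an external per-variant classification
#' table (e.g. an evolutionary model scoring missense variants as Benign /
#' Uncertain / Pathogenic), reports the fraction falling in each external
#' class, with numerator and denominator.
#'
#' @param typed A `cr_classification` or a typed-variant tibble.
#' @param external Table `chrom, pos, ref, alt, class`.
#' @return Tibble `class, n, n_overlap, fraction, percent`; zero overlap
#'   yields `NA` fractions.
#' @examples
#' typed <- tibble::tibble(chrom = "chr1", pos = 1:4, ref = "A", alt = "T",
#'                         gene = "G", category = 3L)
#' ext <- tibble::tibble(chrom = "chr1", pos = 1:2, ref = "A", alt = "T",
#'                       class = c("Benign", "Pathogenic"))
#' crosscheck_external(typed, ext)
#' @export
crosscheck_external <- function(typed, external) {
  if (inherits(typed, "cr_classification")) typed <- typed$typed
  assert_cols(external, c(.key_cols, "class"), "external classification")
  overlap <- dplyr::inner_join(typed[.key_cols],
                               dplyr::distinct(external), by = .key_cols)
  denom <- nrow(overlap)
  classes <- sort(unique(external$class))
  counts <- vapply(classes, \(cl) sum(overlap$class == cl), integer(1),
                   USE.NAMES = FALSE)
  tibble::tibble(
    class = classes,
    n = counts,
    n_overlap = denom,
    fraction = if (denom > 0) counts / denom else NA_real_,
    percent = if (denom > 0) 100 * counts / denom else NA_real_)
}

#' Class-conditional score summaries per prediction tool
#'
#' Summarises each tool's scores for pathogenic (P/LP) versus benign (B/LB)
#' labelled variants — the statistics behind violin-style tool comparisons:
#' n, mean, SD, median and quartiles per class. Tools with fewer than two
#' values in a class have `sd = NA` and are flagged.
#'
#' @param labeled_scores Tibble with `significance` plus tool columns.
#' @return Long tibble: `tool, label, n, mean, sd, median, q25, q75,
#'   flagged`.
#' @export
evaluate_tool_separation <- function(labeled_scores) {
  tools <- intersect(.cr_tools, names(labeled_scores))
  if (length(tools) == 0) abort("no tool columns found")
  labeled_scores |>
    dplyr::mutate(label = dplyr::case_when(
      .data$significance %in% c("P", "LP") ~ "pathogenic",
      .data$significance %in% c("B", "LB") ~ "benign",
      TRUE ~ NA_character_)) |>
    dplyr::filter(!is.na(.data$label)) |>
    tidyr::pivot_longer(dplyr::all_of(tools), names_to = "tool",
                        values_to = "score") |>
    dplyr::filter(!is.na(.data$score)) |>
    dplyr::group_by(.data$tool, .data$label) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$score),
      sd = if (dplyr::n() >= 2) sd(.data$score) else NA_real_,
      median = median(.data$score),
      q25 = quantile(.data$score, 0.25, names = FALSE),
      q75 = quantile(.data$score, 0.75, names = FALSE),
      .groups = "drop") |>
    dplyr::mutate(flagged = is.na(.data$sd))
}

#' Read a BED-like protein domain table
#'
#' Columns `chrom, start, end, domain_id, gene`, with `start` 0-based
#' half-open (BED convention); converted to 1-based inclusive on read.
#'
#' @param path Path to the TSV (with header).
#' @return Domain tibble in internal coordinates.
#' @export
read_domains <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    chrom = "c", start = "i", end = "i", .default = "c"),
    progress = FALSE)
  assert_cols(df, c("chrom", "start", "end", "domain_id", "gene"),
              "domain table")
  dplyr::mutate(df, start = .data$start + 1L)
}

#' Read a ClinVar-style annotation TSV
#'
#' Columns `chrom, pos, ref, alt, significance, n_pathogenic_entries,
#' variant_class` (and optionally `gene`).
#'
#' @param path Path to the TSV.
#' @return A tibble.
#' @export
read_clinvar_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    chrom = "c", pos = "i", ref = "c", alt = "c",
    n_pathogenic_entries = "i", .default = "c"),
    progress = FALSE)
}

#' Read a dbNSFP-style score TSV
#'
#' Columns `chrom, pos, ref, alt` plus one numeric column per tool; `"."`
#' denotes a missing score.
#'
#' @param path Path to the TSV.
#' @return A tibble with numeric tool columns.
#' @export
read_score_table <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    chrom = "c", pos = "i", ref = "c", alt = "c", .default = "c"),
    na = c("", "NA", "."), progress = FALSE)
  for (t in setdiff(names(df), .key_cols)) df[[t]] <- as.numeric(df[[t]])
  df
}

#' Write typed variants with JSON evidence
#'
#' One row per typed variant: key columns, gene, category and a JSON-encoded
#' `evidence` column holding the category-specific evidence fields.
#'
#' @param typed A `cr_classification` or typed tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_typed_variants <- function(typed, path) {
  if (inherits(typed, "cr_classification")) typed <- typed$typed
  ev_cols <- setdiff(names(typed), c(.key_cols, "gene", "category"))
  evidence <- purrr::map_chr(seq_len(nrow(typed)), \(i) {
    row <- as.list(typed[i, ev_cols])
    row <- purrr::map(row, \(v) if (is.list(v)) v[[1]] else v)
    row <- row[!vapply(row, \(v) length(v) == 0 ||
                         (length(v) == 1 && is.na(v)), logical(1))]
    jsonlite::toJSON(row, auto_unbox = TRUE)
  })
  out <- dplyr::bind_cols(typed[c(.key_cols, "gene", "category")],
                          tibble::tibble(evidence = evidence))
  readr::write_tsv(out, path)
  invisible(path)
}
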