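#' Read a sites-only population callset
#'
#' Reads per-population allele counts from either a sites-only VCF (4.x) or
#' the package TSV dialect, returning one row per alternate allele
#' (multiallelic VCF sites are decomposed). Coordinates are 1-based
#' (VCF convention).
#'
#' For VCF input, per-population counts are pulled from INFO fields named by
#' `info_template` (gnomAD-style `AC_<pop>`, `AN_<pop>`, `nhomalt_<pop>`
#' by default; `<pop>` empty, i.e. `AC`/`AN`/`nhomalt`, for the `ALL`
#' population). For TSV input, columns are `chrom, pos, ref, alt` plus
#' `AC_<pop>, AN_<pop>, Hom_<pop>` triplets, optionally `filter` and
#' `covered_fraction`.
#'
#' `covered_fraction` — the fraction of cohort individuals with a call at the
#' site — is taken from the file when present; otherwise, when
#' `n_individuals` is supplied, it is approximated as
#' `AN_ALL / (2 * n_individuals)` (the approximation is exact on autosomes
#' when every called individual is diploid). With neither available it is set
#' to `NA`.
#'
#' @param path Path to a `.vcf`/`.vcf.gz` or TSV file.
#' @param populations Character vector of population labels to extract
#'   (default the seven gnomAD labels). A missing count field for a requested
#'   population is an error.
#' @param include_all Also carry the cohort-wide `ALL` counts, read from the
#'   source when present, else computed as the sum over `populations`.
#' @param n_individuals Optional cohort size used for the AN-based
#'   `covered_fraction` approximation.
#' @param info_template Named character vector with entries `AC`, `AN`,
#'   `Hom` giving INFO-field name templates; `{pop}` is replaced by the
#'   population label.
#' @return A tibble with columns `chrom, pos, ref, alt, filter,
#'   covered_fraction` and `AC_/AN_/Hom_` columns per population (plus
#'   `ALL` when `include_all`).
#' @export
read_sites_callset <- function(path,
                               populations = .cr_default_populations,
                               include_all = TRUE,
                               n_individuals = NULL,
                               info_template = c(AC = "AC_{pop}",
                                                 AN = "AN_{pop}",
                                                 Hom = "nhomalt_{pop}")) {
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    rec <- read_callset_vcf(path, populations, info_template)
  } else {
    rec <- read_callset_tsv(path, populations)
  }
  finalize_callset(rec, populations, include_all, n_individuals)
}

read_callset_tsv <- function(path, populations) {
  header <- strsplit(readr::read_lines(path, n_max = 1), "\t")[[1]]
  spec <- readr::cols(chrom = "c", pos = "i", ref = "c", alt = "c",
                      .default = "d")
  if ("filter" %in% header) spec$cols$filter <- readr::col_character()
  df <- readr::read_tsv(path, col_types = spec, progress = FALSE)
  assert_cols(df, .key_cols, "callset TSV")
  need <- c(paste0("AC_", populations), paste0("AN_", populations))
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    abort(paste0("callset is missing count column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (any(grepl(",", df$alt, fixed = TRUE))) {
    abort("TSV callsets must be biallelic (one alt allele per row)")
  }
  if (!"filter" %in% names(df)) df$filter <- "PASS"
  df$filter <- as.character(df$filter)
  df
}

read_callset_vcf <- function(path, populations, info_template) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  alt_list <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
  n_alt <- lengths(alt_list)
  idx <- rep(seq_len(nrow(fix)), n_alt)        # source row of each record
  alt_i <- sequence(n_alt)                      # which alt within the site

  field_name <- function(tmpl, pop) {
    if (pop == "ALL") sub("[_]?\\{pop\\}", "", tmpl)
    else sub("\\{pop\\}", pop, tmpl, fixed = FALSE)
  }
  grab <- function(tmpl, pop, per_alt) {
    el <- field_name(tmpl, pop)
    raw <- vcfR::extract.info(vcf, element = el)
    if (all(is.na(raw))) return(NULL)
    if (per_alt) {
      vals <- strsplit(raw, ",", fixed = TRUE)
      out <- suppressWarnings(as.numeric(
        purrr::map2_chr(vals[idx], alt_i, \(v, i) {
          if (i <= length(v)) v[i] else NA_character_
        })))
    } else {
      out <- suppressWarnings(as.numeric(raw))[idx]
    }
    out
  }

  rec <- tibble::tibble(
    chrom = fix[idx, "CHROM"],
    pos = as.integer(fix[idx, "POS"]),
    ref = fix[idx, "REF"],
    alt = purrr::map2_chr(alt_list[idx], alt_i, \(v, i) v[i]),
    filter = fix[idx, "FILTER"]
  )
  for (pop in c(populations, "ALL")) {
    ac <- grab(info_template[["AC"]], pop, per_alt = TRUE)
    an <- grab(info_template[["AN"]], pop, per_alt = FALSE)
    hom <- grab(info_template[["Hom"]], pop, per_alt = TRUE)
    if (pop != "ALL" && (is.null(ac) || is.null(an))) {
      abort(sprintf("population '%s': INFO field '%s' or '%s' not found",
                    pop, field_name(info_template[["AC"]], pop),
                    field_name(info_template[["AN"]], pop)))
    }
    if (is.null(ac)) next
    rec[[paste0("AC_", pop)]] <- ac
    rec[[paste0("AN_", pop)]] <- an
    if (!is.null(hom)) rec[[paste0("Hom_", pop)]] <- hom
  }
  rec
}

finalize_callset <- function(rec, populations, include_all, n_individuals) {
  all_pops <- populations
  if (include_all) {
    if (!"AC_ALL" %in% names(rec)) {
      rec$AC_ALL <- rowSums(as.matrix(rec[paste0("AC_", populations)]),
                            na.rm = TRUE)
      rec$AN_ALL <- rowSums(as.matrix(rec[paste0("AN_", populations)]),
                            na.rm = TRUE)
      homs <- intersect(paste0("Hom_", populations), names(rec))
      rec$Hom_ALL <- if (length(homs)) {
        rowSums(as.matrix(rec[homs]), na.rm = TRUE)
      } else {
        0
      }
    }
    all_pops <- c(populations, "ALL")
  }
  missing_hom <- setdiff(paste0("Hom_", all_pops), names(rec))
  if (length(missing_hom) > 0) {
    warn(paste0("homozygote counts absent for: ",
                paste(sub("^Hom_", "", missing_hom), collapse = ", "),
                "; treating as 0"))
    for (h in missing_hom) rec[[h]] <- 0
  }
  for (col in count_cols(all_pops)) {
    rec[[col]][is.na(rec[[col]])] <- 0
  }
  if (!"covered_fraction" %in% names(rec)) {
    rec$covered_fraction <- if (!is.null(n_individuals)) {
      pmin(1, rec$AN_ALL / (2 * n_individuals))
    } else {
      NA_real_
    }
  }
  rec <- dplyr::relocate(rec, "chrom", "pos", "ref", "alt", "filter",
                         "covered_fraction")
  validate_callset(rec)
  add_allele_frequencies(rec)
}

#' Validate callset count invariants
#'
#' Checks `AC <= AN` and `2 * Hom <= AC` for every population column pair and
#' errors naming the first offending variant.
#'
#' @param records A wide callset tibble.
#' @return `records`, invisibly.
#' @export
validate_callset <- function(records) {
  for (pop in detect_populations(records)) {
    ac <- records[[paste0("AC_", pop)]]
    an <- records[[paste0("AN_", pop)]]
    hom_col <- paste0("Hom_", pop)
    hom <- if (hom_col %in% names(records)) records[[hom_col]] else 0
    bad <- which(ac > an | 2 * hom > ac)
    if (length(bad) > 0) {
      i <- bad[1]
      abort(sprintf(
        "corrupt counts for %s in %s (AC=%g, AN=%g, Hom=%g)",
        variant_key(records$chrom[i], records$pos[i],
                    records$ref[i], records$alt[i]),
        pop, ac[i], an[i], if (length(hom) > 1) hom[i] else hom))
    }
  }
  invisible(records)
}

#' Recompute per-population allele frequencies
#'
#' Adds/overwrites `AF_<pop> = AC_<pop> / AN_<pop>` (0 where `AN` is 0).
#'
#' @param records A wide callset tibble.
#' @return The tibble with refreshed `AF_` columns.
#' @export
add_allele_frequencies <- function(records) {
  for (pop in detect_populations(records)) {
    ac <- records[[paste0("AC_", pop)]]
    an <- records[[paste0("AN_", pop)]]
    records[[paste0("AF_", pop)]] <- ifelse(an > 0, ac / an, 0)
  }
  records
}

#' Retain high-quality variants
#'
#' Keeps variants that are flagged `PASS` and covered in more than
#' `min_covered_fraction` of cohort individuals (strict inequality). Removal
#' counts per reason are attached as the `"removals"` attribute.
#'
#' @param records A wide callset tibble with `filter` and `covered_fraction`.
#' @param min_covered_fraction Strict lower bound on coverage (default 0.5).
#' @return The retained rows.
#' @export
filter_high_quality <- function(records, min_covered_fraction = 0.5) {
  pass <- records$filter == "PASS"
  covered <- !is.na(records$covered_fraction) &
    records$covered_fraction > min_covered_fraction
  out <- records[pass & covered, , drop = FALSE]
  attr(out, "removals") <- c(non_pass = sum(!pass),
                             low_coverage = sum(pass & !covered))
  out
}

#' Merge two callsets (e.g. exome + genome)
#'
#' Sums `AC`, `AN` and `Hom` per variant and population across two callsets
#' and recomputes allele frequencies from the merged counts. A variant
#' present in only one callset passes through unchanged. Both callsets must
#' use the same population labels and genome build; the same `chrom:pos`
#' carrying different `ref` alleles is an error. The merged record is `PASS`
#' only if every contributing record is, and keeps the larger
#' `covered_fraction`.
#'
#' @param a,b Wide callset tibbles.
#' @return The merged callset.
#' @export
merge_callsets <- function(a, b) {
  pops <- detect_populations(a)
  if (!setequal(pops, detect_populations(b))) {
    abort("callsets use different population label sets")
  }
  ref_conflict <- dplyr::inner_join(
    dplyr::distinct(a[c("chrom", "pos", "ref")]),
    dplyr::distinct(b[c("chrom", "pos", "ref")]),
    by = c("chrom", "pos"), relationship = "many-to-many") |>
    dplyr::filter(.data$ref.x != .data$ref.y)
  if (nrow(ref_conflict) > 0) {
    abort(sprintf("conflicting ref alleles at %s:%d (%s vs %s)",
                  ref_conflict$chrom[1], ref_conflict$pos[1],
                  ref_conflict$ref.x[1], ref_conflict$ref.y[1]))
  }
  cols <- count_cols(pops)
  keep <- c(.key_cols, "filter", "covered_fraction", cols)
  merged <- dplyr::bind_rows(a[intersect(keep, names(a))],
                             b[intersect(keep, names(b))]) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(.key_cols))) |>
    dplyr::summarise(
      filter = if (all(.data$filter == "PASS")) "PASS" else {
        paste(unique(.data$filter[.data$filter != "PASS"]), collapse = ";")
      },
      covered_fraction = max(.data$covered_fraction),
      dplyr::across(dplyr::all_of(cols), sum),
      .groups = "drop"
    )
  validate_callset(merged)
  add_allele_frequencies(merged)
}

#' Remove variants on an exclusion list
#'
#' Drops exact `chrom, pos, ref, alt` matches. Exclusion keys never observed
#' in the callset are reported with an informational message.
#'
#' @param records A wide callset tibble.
#' @param excluded A data frame with columns `chrom, pos, ref, alt` (a
#'   `reason` column, if present, is ignored for matching).
#' @return The retained rows; the number removed is attached as attribute
#'   `"n_excluded"`.
#' @export
apply_exclusion_list <- function(records, excluded) {
  if (is.null(excluded) || nrow(excluded) == 0) {
    attr(records, "n_excluded") <- 0L
    return(records)
  }
  assert_cols(excluded, .key_cols, "exclusion list")
  excluded <- dplyr::mutate(tibble::as_tibble(excluded),
                            pos = as.integer(.data$pos))
  out <- dplyr::anti_join(records, excluded, by = .key_cols)
  n_removed <- nrow(records) - nrow(out)
  unseen <- nrow(dplyr::anti_join(excluded, records, by = .key_cols))
  if (unseen > 0) {
    inform(sprintf("%d exclusion key(s) not observed in the callset", unseen))
  }
  attr(out, "n_excluded") <- n_removed
  out
}

#' Read a variant exclusion list TSV
#'
#' Columns `chrom, pos, ref, alt` and optionally `reason`.
#'
#' @param path Path to the TSV.
#' @return A tibble of exclusion keys.
#' @export
read_exclusion_list <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    chrom = "c", pos = "i", ref = "c", alt = "c", .default = "c"),
    progress = FALSE)
}

#' Write a callset in the package TSV dialect
#'
#' @param records A wide callset tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_callset_tsv <- function(records, path) {
  readr::write_tsv(records, path)
  invisible(path)
}
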