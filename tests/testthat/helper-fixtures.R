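# Fixture builders: toy gene models and randomized classification fixtures.

toy_spec <- function(gene, chrom, strand, exons, cds,
                     transcript_id = paste0("NM_", gene)) {
  list(gene = gene, chrom = chrom, strand = strand,
       exons = tibble::tibble(start = exons[, 1], end = exons[, 2]),
       cds = cds, transcript_id = transcript_id)
}

# Six genes with varied exon counts, strands and transcript multiplicity.
fixture_gene_specs <- function() {
  list(
    G1 = list(toy_spec("G1", "chr1", "+", cbind(1000, 4000),
                       c(1100, 3700))),
    G2 = list(toy_spec("G2", "chr2", "+",
                       cbind(c(1000, 3000), c(2000, 4200)),
                       c(1500, 3800))),
    G3 = list(toy_spec("G3", "chr3", "-",
                       cbind(c(1000, 3000, 5000), c(1900, 3800, 5900)),
                       c(1200, 5500))),
    G4 = list(toy_spec("G4", "chr4", "+",
                       cbind(c(1000, 2000, 3000, 4000),
                             c(1500, 2500, 3500, 4500)),
                       c(1100, 4400))),
    G5 = list(
      toy_spec("G5", "chr5", "+",
               cbind(c(1000, 2600, 4200), c(1800, 3400, 5000)),
               c(1200, 4800), transcript_id = "NM_G5a"),
      toy_spec("G5", "chr5", "+",
               cbind(c(1000, 4200), c(1800, 5000)),
               c(1200, 4800), transcript_id = "NM_G5b")),
    G6 = list(toy_spec("G6", "chr6", "-",
                       cbind(c(1000, 3000), c(2200, 4000)),
                       c(1300, 3900)))
  )
}

# genePred-style table (0-based half-open) for a list of specs
specs_to_genepred <- function(specs) {
  flat <- unlist(specs, recursive = FALSE)
  tibble::tibble(
    name = vapply(flat, `[[`, "", "transcript_id"),
    chrom = vapply(flat, `[[`, "", "chrom"),
    strand = vapply(flat, `[[`, "", "strand"),
    tx_start = vapply(flat, \(s) as.integer(min(s$exons$start) - 1L), 1L),
    tx_end = vapply(flat, \(s) as.integer(max(s$exons$end)), 1L),
    cds_start = vapply(flat, \(s) as.integer(s$cds[1] - 1L), 1L),
    cds_end = vapply(flat, \(s) as.integer(s$cds[2]), 1L),
    exon_count = vapply(flat, \(s) as.integer(nrow(s$exons)), 1L),
    exon_starts = vapply(flat, \(s) paste(s$exons$start - 1L,
                                          collapse = ","), ""),
    exon_ends = vapply(flat, \(s) paste(s$exons$end, collapse = ","), ""),
    gene = vapply(flat, `[[`, "", "gene")
  )
}

specs_to_catalog <- function(specs) {
  flat <- unlist(specs, recursive = FALSE)
  genes <- unique(tibble::tibble(
    chromosome = vapply(flat, `[[`, "", "chrom"),
    approved_gene_symbol = vapply(flat, `[[`, "", "gene")))
  genes$phenotypes <- paste0(genes$approved_gene_symbol,
                             " deficiency, 600000 (3), Autosomal recessive")
  load_gene_models(specs_to_genepred(specs), parse_genemap2(genes))
}

# one transcript model row (catalog representation) from a spec
spec_to_tx_row <- function(spec) {
  tibble::tibble(
    transcript_id = spec$transcript_id, strand = spec$strand,
    exon_start = list(as.integer(spec$exons$start)),
    exon_end = list(as.integer(spec$exons$end)),
    cds_start = as.integer(spec$cds[1]), cds_end = as.integer(spec$cds[2]),
    coding_length = sum(pmax(
      0L, pmin(spec$exons$end, spec$cds[2]) -
        pmax(spec$exons$start, spec$cds[1]) + 1L)))
}

fixture_domains <- function() {
  tibble::tibble(
    chrom = c("chr1", "chr1", "chr2", "chr3", "chr4"),
    start = c(1500L, 2800L, 3100L, 3000L, 2000L),
    end = c(2500L, 3200L, 3600L, 3800L, 2500L),
    domain_id = c("D1a", "D1b", "D2", "D3", "D4"),
    gene = c("G1", "G1", "G2", "G3", "G4"))
}

# knowledge-base ClinVar rows that are not cohort variants: pathogenic
# missense anchors (gene eligibility) for G1/G3/G5 and pathogenic in-frame
# INDEL anchors inside domains D1a, D2 and D4
fixture_clinvar_anchors <- function() {
  tibble::tibble(
    chrom = c("chr1", "chr3", "chr5", "chr1", "chr2", "chr4"),
    pos = c(1105L, 1205L, 1205L, 1600L, 3150L, 2100L),
    ref = c("A", "A", "A", "GTCA", "GTCA", "GTCA"),
    alt = c("G", "G", "G", "G", "G", "G"),
    gene = c("G1", "G3", "G5", "G1", "G2", "G4"),
    significance = "P",
    n_pathogenic_entries = 3L,
    variant_class = c("missense", "missense", "missense",
                      "inframe_indel", "inframe_indel", "inframe_indel"))
}

# Randomized classification fixture: cohort records plus all annotation
# tables, including NMD-window boundary stops (48-52 coding bases upstream
# of the final junction), allele-frequency and CADD threshold boundaries,
# and exact-cutoff tool scores.
make_random_fixture <- function(seed, n = 250, derived_cutoffs = FALSE) {
  withr::with_seed(seed, {
    specs <- fixture_gene_specs()
    catalog <- specs_to_catalog(specs)
    domains <- fixture_domains()
    anchors <- fixture_clinvar_anchors()
    gene_names <- names(specs)
    anchor_keys <- paste(anchors$chrom, anchors$pos)

    cons_terms <- c("missense", "stop_gained", "frameshift",
                    "splice_acceptor", "splice_donor", "start_lost",
                    "inframe_indel", "synonymous", "intronic")
    cons_prob <- c(0.35, 0.13, 0.08, 0.04, 0.04, 0.04, 0.15, 0.10, 0.07)

    rows <- list()
    for (g in gene_names) {
      sp <- specs[[g]][[1]]
      cp <- sort(unique(unlist(
        lapply(specs[[g]], oracle_coding_positions))))
      n_g <- rpois(1, n / length(gene_names)) + 1L
      pos <- sample(cp, min(n_g, length(cp)))
      cons <- sample(cons_terms, length(pos), TRUE, cons_prob)
      rows[[g]] <- tibble::tibble(chrom = sp$chrom, pos = pos, gene = g,
                                  consequence = cons)
    }
    # NMD boundary stops on the multi-exon genes, 48-52 coding bases
    # upstream of the final junction (computed per transcript-order index)
    for (g in c("G2", "G3", "G4")) {
      sp <- specs[[g]][[1]]
      cp <- oracle_coding_positions(sp)
      j <- length(cp) - oracle_last_segment_len(sp)
      bpos <- cp[j - (48:52)]
      rows[[paste0(g, "_nmd")]] <- tibble::tibble(
        chrom = sp$chrom, pos = bpos, gene = g,
        consequence = "stop_gained")
      # and a couple inside the final exon / window
      rows[[paste0(g, "_nmd2")]] <- tibble::tibble(
        chrom = sp$chrom, pos = cp[c(j + 5L, length(cp) - 3L)], gene = g,
        consequence = "stop_gained")
    }
    # intronic stop-gained calls with no covering transcript
    rows$orphan <- tibble::tibble(
      chrom = "chr2", pos = c(2500L, 2600L), gene = "G2",
      consequence = "stop_gained")

    v <- dplyr::bind_rows(rows) |>
      dplyr::distinct(.data$chrom, .data$pos, .keep_all = TRUE) |>
      dplyr::filter(!paste(.data$chrom, .data$pos) %in% anchor_keys)
    nv <- nrow(v)
    v$ref <- ifelse(v$consequence == "inframe_indel", "ATCG",
                    ifelse(v$consequence == "frameshift", "AT", "A"))
    v$alt <- ifelse(v$consequence %in% c("inframe_indel", "frameshift"),
                    "A", "C")
    v$alt[v$ref == "A" & v$alt == "A"] <- "T"

    # counts for two populations with boundary-heavy AF draws
    records <- v[c("chrom", "pos", "ref", "alt")]
    records$filter <- "PASS"
    records$covered_fraction <- 1
    for (p in c("EAS", "NFE")) {
      an <- sample(c(40L, 500L, 999L, 1000L, 2000L, 20000L), nv, TRUE)
      regime <- sample(c("rare", "boundary", "common"), nv, TRUE,
                       prob = c(0.6, 0.25, 0.15))
      ac <- integer(nv)
      ac[regime == "rare"] <- sample(0:5, sum(regime == "rare"), TRUE)
      ac[regime == "boundary"] <- round(0.005 * an[regime == "boundary"]) +
        sample(-1:1, sum(regime == "boundary"), TRUE)
      ac[regime == "common"] <- ceiling(
        runif(sum(regime == "common"), 0.006, 0.05) *
          an[regime == "common"])
      ac <- pmin(pmax(ac, 0L), an)
      hom <- ifelse(runif(nv) < 0.06 & ac >= 2, 1L, 0L)
      records[[paste0("AC_", p)]] <- ac
      records[[paste0("AN_", p)]] <- an
      records[[paste0("Hom_", p)]] <- hom
    }

    # ClinVar labels for ~55% of variants
    in_cv <- runif(nv) < 0.55
    sig <- sample(c("P", "LP", "B", "LB", "VUS", "CONFLICTING", "OTHER"),
                  nv, TRUE, prob = c(.08, .05, .10, .08, .35, .20, .14))
    vclass <- dplyr::case_match(
      v$consequence,
      "missense" ~ "missense", "stop_gained" ~ "nonsense",
      "frameshift" ~ "frameshift",
      c("splice_acceptor", "splice_donor") ~ "splice",
      "inframe_indel" ~ "inframe_indel", .default = "other")
    clinvar <- dplyr::bind_rows(
      anchors,
      tibble::tibble(chrom = v$chrom[in_cv], pos = v$pos[in_cv],
                     ref = v$ref[in_cv], alt = v$alt[in_cv],
                     gene = v$gene[in_cv], significance = sig[in_cv],
                     n_pathogenic_entries = sample(0:14, sum(in_cv), TRUE),
                     variant_class = vclass[in_cv]))

    # scores near (and sometimes exactly at) the cutoffs
    defaults <- c(CADD = 28.04, DANN = 0.99, fathmm_MKL_coding = 0.90,
                  phastCons = 0.84, Polyphen2 = 0.90, SIFT = 0.04,
                  VEST3 = 0.78)
    scores <- v[c("chrom", "pos", "ref", "alt")]
    for (t in names(defaults)) {
      spread <- switch(t, CADD = 6, SIFT = 0.05, 0.12)
      val <- defaults[[t]] + rnorm(nv, 0, spread)
      exact <- runif(nv) < 0.15
      val[exact] <- defaults[[t]]
      if (t == "CADD") {
        val <- pmin(pmax(val, 0), 60)
        at20 <- runif(nv) < 0.08
        val[at20] <- 20
      } else {
        val <- pmin(pmax(val, 0), 1)
      }
      val[runif(nv) < 0.1] <- NA_real_
      scores[[t]] <- val
    }

    consequences <- v[c("chrom", "pos", "ref", "alt", "gene", "consequence")]

    cutoffs <- NULL
    if (derived_cutoffs) {
      lab_genes <- sample(gene_names, 4)
      lab <- purrr::map_dfr(lab_genes, \(g) {
        sp <- specs[[g]][[1]]
        k <- sample(3:8, 1)
        out <- tibble::tibble(
          chrom = sp$chrom, pos = 90000L + seq_len(k), ref = "A", alt = "G",
          gene = g, significance = sample(c("P", "LP"), k, TRUE))
        for (t in names(defaults)) {
          spread <- switch(t, CADD = 4, SIFT = 0.03, 0.08)
          out[[t]] <- pmax(0, defaults[[t]] + rnorm(k, 0, spread))
        }
        out
      })
      cutoffs <- derive_tool_cutoffs(lab)
    }

    exclusions <- NULL
    if (runif(1) < 0.4 && nv >= 2) {
      pick <- sample(nv, 2)
      exclusions <- v[pick, c("chrom", "pos", "ref", "alt")]
    }

    list(records = records, clinvar = clinvar, consequences = consequences,
         scores = scores, domains = domains, catalog = catalog,
         specs = specs, cutoffs = cutoffs, exclusions = exclusions)
  })
}

# run classify_all and the brute-force oracle on a fixture; both as
# key|gene|category strings for set comparison
fixture_compare_sets <- function(fx) {
  cls <- suppressMessages(suppressWarnings(classify_all(
    fx$records, fx$clinvar, fx$consequences, fx$scores, fx$domains,
    fx$catalog, cutoffs = fx$cutoffs, exclusions = fx$exclusions)))
  got <- with(cls$typed, paste(chrom, pos, ref, alt, category, sep = "|"))
  ora <- oracle_classify(fx$records, fx$clinvar, fx$consequences, fx$scores,
                         fx$domains, fx$specs, cutoffs = fx$cutoffs,
                         exclusions = fx$exclusions)
  want <- if (nrow(ora) == 0) character(0) else {
    paste(gsub("\\|", "|", ora$key), ora$category, sep = "|")
  }
  list(got = sort(got), want = sort(want), cls = cls)
}
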