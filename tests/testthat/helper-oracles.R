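# Independent oracles, deliberately implemented by different routes than the
# package code they check.

# Union probability via inclusion-exclusion, computed from elementary
# symmetric polynomials (iterative convolution): P(union) = sum_k (-1)^(k+1) e_k.
oracle_union_esp <- function(v) {
  e <- 1
  for (x in v) e <- c(e, 0) + c(0, x * e)
  k <- seq_along(v)
  sum((-1)^(k + 1) * e[k + 1])
}

# Union probability by explicit subset enumeration (n <= 15).
oracle_union_subsets <- function(v) {
  n <- length(v)
  stopifnot(n <= 15)
  total <- 0
  for (mask in seq_len(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    total <- total + (-1)^(length(idx) + 1) * prod(v[idx])
  }
  total
}

# Genetic prevalence by explicit double-sum enumeration.
oracle_pgpg_doublesum <- function(v) {
  total <- 0
  for (i in seq_along(v)) {
    for (k in seq_along(v)) {
      total <- total + v[i] * v[k]
    }
  }
  total / 4
}

# --- transcript / NMD oracle ------------------------------------------------

# Genomic positions of the coding sequence in transcript (5'->3') order,
# built base by base from a gene spec (1-based inclusive exons).
oracle_coding_positions <- function(spec) {
  pos <- integer(0)
  for (i in seq_len(nrow(spec$exons))) {
    s <- max(spec$exons$start[i], spec$cds[1])
    e <- min(spec$exons$end[i], spec$cds[2])
    if (s <= e) pos <- c(pos, s:e)
  }
  if (spec$strand == "-") pos <- rev(pos)
  pos
}

# length of the final coding exon segment, in transcript order
oracle_last_segment_len <- function(spec) {
  lens <- integer(0)
  for (i in seq_len(nrow(spec$exons))) {
    s <- max(spec$exons$start[i], spec$cds[1])
    e <- min(spec$exons$end[i], spec$cds[2])
    if (s <= e) lens <- c(lens, e - s + 1L)
  }
  if (spec$strand == "-") lens <- rev(lens)
  lens[length(lens)]
}

# NMD escape by position lookup in the enumerated coding sequence.
oracle_nmd <- function(pos, spec, window = 50L) {
  cp <- oracle_coding_positions(spec)
  i <- match(pos, cp)
  if (is.na(i)) stop("position not in CDS")
  l_last <- oracle_last_segment_len(spec)
  i >= (length(cp) - l_last - window)
}

# --- brute-force classification oracle --------------------------------------

# Per-variant re-derivation of the four-category decision cascade with plain
# loops and if/else, independent of the package's join/vector implementation.
oracle_classify <- function(records, clinvar, consequences, scores, domains,
                            gene_specs, cutoffs = NULL, exclusions = NULL,
                            af_threshold = 0.005, min_an = 1000,
                            conflicting_min = 10) {
  keyify <- function(d) paste(d$chrom, d$pos, d$ref, d$alt, sep = "|")
  cv_key <- keyify(clinvar)
  sc_key <- keyify(scores)
  cons_key <- keyify(consequences)
  excl_key <- if (is.null(exclusions)) character(0) else keyify(exclusions)

  sev_rank <- c(splice_acceptor = 1, splice_donor = 2, stop_gained = 3,
                frameshift = 4, start_lost = 5, missense = 6,
                inframe_insertion = 7, inframe_deletion = 7,
                inframe_indel = 7,
                synonymous = 99, intronic = 99, other = 99)
  tools <- c("CADD", "DANN", "fathmm_MKL_coding", "phastCons",
             "Polyphen2", "SIFT", "VEST3")
  global <- if (is.null(cutoffs)) {
    c(CADD = 28.04, DANN = 0.99, fathmm_MKL_coding = 0.90,
      phastCons = 0.84, Polyphen2 = 0.90, SIFT = 0.04, VEST3 = 0.78)
  } else {
    cutoffs$global
  }
  eligible <- if (!is.null(cutoffs) && !is.null(cutoffs$eligible_genes)) {
    cutoffs$eligible_genes
  } else {
    unique(clinvar$gene[clinvar$significance %in% c("P", "LP") &
                          clinvar$variant_class == "missense"])
  }
  pops <- sub("^AC_", "", grep("^AC_", names(records), value = TRUE))
  af_pops <- setdiff(pops, "ALL")
  if (length(af_pops) == 0) af_pops <- pops

  # anchored domains: gene domains containing a known pathogenic
  # in-frame INDEL (whole indel interval inside the domain)
  anchors <- clinvar[clinvar$significance %in% c("P", "LP") &
                       clinvar$variant_class == "inframe_indel", ,
                     drop = FALSE]
  domain_anchored <- logical(nrow(domains))
  for (d in seq_len(nrow(domains))) {
    for (a in seq_len(nrow(anchors))) {
      if (anchors$chrom[a] == domains$chrom[d] &&
          anchors$pos[a] >= domains$start[d] &&
          anchors$pos[a] + nchar(anchors$ref[a]) - 1 <= domains$end[d]) {
        domain_anchored[d] <- TRUE
        break
      }
    }
  }

  out <- list()
  for (r in seq_len(nrow(records))) {
    key <- paste(records$chrom[r], records$pos[r], records$ref[r],
                 records$alt[r], sep = "|")
    cv <- which(cv_key == key)
    sig <- if (length(cv) > 0) clinvar$significance[cv[1]] else "ABSENT"
    npe <- if (length(cv) > 0) clinvar$n_pathogenic_entries[cv[1]] else 0

    ci <- which(cons_key == key)
    gene <- if (length(ci) > 0) consequences$gene[ci[1]] else NA_character_

    # Type 1
    if ((sig %in% c("P", "LP") ||
         (sig == "CONFLICTING" && npe >= conflicting_min)) &&
        !(key %in% excl_key)) {
      out[[length(out) + 1]] <- list(key = key, gene = gene, category = 1L)
      next
    }
    if (sig %in% c("B", "LB")) next

    # prefilter
    removed <- FALSE
    for (p in pops) {
      hom <- records[[paste0("Hom_", p)]][r]
      if (!is.null(hom) && !is.na(hom) && hom > 0) removed <- TRUE
    }
    if (!removed) {
      for (p in af_pops) {
        ac <- records[[paste0("AC_", p)]][r]
        an <- records[[paste0("AN_", p)]][r]
        if (an >= min_an && an > 0 && ac / an >= af_threshold) removed <- TRUE
      }
    }
    if (removed) next
    if (length(ci) == 0) next

    terms <- consequences$consequence[ci]
    best <- terms[which.min(sev_rank[terms])]
    brank <- sev_rank[best]

    if (brank <= 5) {
      # loss of function; nonsense faces the NMD test
      if (best == "stop_gained") {
        specs <- gene_specs[[gene]]
        verdicts <- logical(0)
        for (sp in specs) {
          cp <- oracle_coding_positions(sp)
          if (records$pos[r] %in% cp) {
            verdicts <- c(verdicts, oracle_nmd(records$pos[r], sp))
          }
        }
        if (length(verdicts) > 0 && all(verdicts)) next  # escapes on all
      }
      out[[length(out) + 1]] <- list(key = key, gene = gene, category = 2L)
      next
    }
    if (best == "missense") {
      if (!gene %in% eligible) next
      si <- which(sc_key == key)
      n_pass <- 0
      mand_ok <- TRUE
      for (t in tools) {
        cut <- global[[t]]
        if (!is.null(cutoffs) && !is.null(cutoffs$per_gene)) {
          pg <- cutoffs$per_gene
          hit <- which(pg$gene == gene & pg$tool == t)
          if (length(hit) > 0) {
            g_cut <- pg$cutoff[hit[1]]
            cut <- if (t == "SIFT") min(g_cut, cut) else max(g_cut, cut)
          }
        }
        val <- if (length(si) > 0 && t %in% names(scores)) {
          scores[[t]][si[1]]
        } else {
          NA_real_
        }
        ok <- !is.na(val) && if (t == "SIFT") val <= cut else val >= cut
        if (ok) n_pass <- n_pass + 1
        if (!ok && t %in% c("CADD", "DANN", "Polyphen2", "SIFT",
                            "phastCons")) {
          mand_ok <- FALSE
        }
      }
      if (n_pass >= 5 && mand_ok) {
        out[[length(out) + 1]] <- list(key = key, gene = gene, category = 3L)
      }
      next
    }
    if (brank == 7) {
      si <- which(sc_key == key)
      cadd <- if (length(si) > 0) scores$CADD[si[1]] else NA_real_
      if (is.na(cadd) || cadd <= 20) next
      v_start <- records$pos[r]
      v_end <- records$pos[r] + nchar(records$ref[r]) - 1
      hit <- FALSE
      for (d in seq_len(nrow(domains))) {
        if (domain_anchored[d] && domains$gene[d] == gene &&
            domains$chrom[d] == records$chrom[r] &&
            v_end >= domains$start[d] && v_start <= domains$end[d]) {
          hit <- TRUE
          break
        }
      }
      if (hit) {
        out[[length(out) + 1]] <- list(key = key, gene = gene, category = 4L)
      }
      next
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(key = character(), gene = character(),
                          category = integer()))
  }
  dplyr::bind_rows(lapply(out, tibble::as_tibble))
}
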