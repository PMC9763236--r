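#' Configuration for a synthetic cohort
#'
#' Describes the study conditions a simulated cohort emulates: a catalog of
#' recessive genes with one transcript model each, per-gene variants with
#' known true category, per-population allele frequencies, and the
#' annotation tables (ClinVar-style labels, tool scores, consequences,
#' protein domains) the classification pipeline consumes.
#'
#' Deleterious allele frequencies are drawn log-uniformly on
#' `q_deleterious`, kept well below the 0.005 allele-frequency filter so the
#' filter does not silently erase truth; benign/uncertain variants draw from
#' the wider `q_benign`, deliberately crossing the filter threshold so the
#' prefilter is exercised. Genotypes of truly deleterious variants are
#' sampled conditional on zero homozygotes — the healthy cohorts the method
#' targets exclude individuals affected by severe recessive disease, so
#' carriers are the only genotype observed; benign variants are sampled
#' under full Hardy-Weinberg, homozygotes included.
#'
#' @param n_genes Number of catalog genes (default 200).
#' @param populations Named integer vector: diploid sample size per
#'   population (default the seven standard labels at 10,000 each).
#' @param variants_per_gene Mean of the Poisson number of cohort variants
#'   per gene (default 8).
#' @param class_mixture Named proportions over
#'   `type1, type2, type3, type4, benign, vus` (default
#'   .15/.15/.15/.05/.35/.15).
#' @param q_deleterious Range of true allele frequencies for deleterious
#'   variants (log-uniform; default `c(1e-5, 5e-4)`).
#' @param q_benign Range for benign/uncertain variants (default
#'   `c(1e-5, 0.05)`).
#' @param pop_sigma Log-normal SD of the per-population frequency
#'   multiplier, creating population differentiation (default 0.5).
#' @param type3_eligible_fraction Fraction of genes given a known pathogenic
#'   missense anchor, making them eligible for ensemble-missense calling
#'   (default 0.9).
#' @param type4_anchored_fraction Fraction of genes whose protein domain
#'   holds a known pathogenic in-frame INDEL anchor (default 0.8).
#' @param x_fraction Fraction of genes placed on chromosome X (default
#'   0.064, the share of X-linked genes among known recessive genes);
#'   X genes are simulated with the same autosomal machinery.
#' @param borderline If `TRUE`, tool scores are drawn overlapping the
#'   cutoffs instead of strictly beyond them (stress mode; classification
#'   recovery is then only guaranteed for non-borderline draws).
#' @param seed Integer seed making the whole cohort deterministic.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 200,
                       populations = setNames(rep(10000L, 7),
                                              .cr_default_populations),
                       variants_per_gene = 8,
                       class_mixture = c(type1 = 0.15, type2 = 0.15,
                                         type3 = 0.15, type4 = 0.05,
                                         benign = 0.35, vus = 0.15),
                       q_deleterious = c(1e-5, 5e-4),
                       q_benign = c(1e-5, 0.05),
                       pop_sigma = 0.5,
                       type3_eligible_fraction = 0.9,
                       type4_anchored_fraction = 0.8,
                       x_fraction = 0.064,
                       borderline = FALSE,
                       seed = 1L) {
  stopifnot(n_genes >= 1, all(populations > 0),
            abs(sum(class_mixture) - 1) < 1e-8,
            all(names(class_mixture) %in%
                  c("type1", "type2", "type3", "type4", "benign", "vus")))
  if (class_mixture[["type4"]] > 0 && type4_anchored_fraction <= 0) {
    abort("type4 variants requested but no gene has an anchored domain")
  }
  structure(
    list(n_genes = as.integer(n_genes), populations = populations,
         variants_per_gene = variants_per_gene,
         class_mixture = class_mixture,
         q_deleterious = q_deleterious, q_benign = q_benign,
         pop_sigma = pop_sigma,
         type3_eligible_fraction = type3_eligible_fraction,
         type4_anchored_fraction = type4_anchored_fraction,
         x_fraction = x_fraction, borderline = borderline,
         seed = as.integer(seed)),
    class = "sim_config")
}

# Fixed gene architecture: three exons, CDS spanning all three.
# All coordinates are offsets from the gene's base position (1-based).
.sim_layout <- list(
  exon_start = c(1L, 3001L, 6001L),
  exon_end = c(1000L, 4000L, 7000L),
  cds_start = 101L,
  cds_end = 6900L,
  domain_start = 3001L,   # domain == exon 2
  domain_end = 4000L,
  anchor_missense = 151L,
  anchor_indel = 3101L
)

# Exonic coding offsets (relative to base) under the fixed layout: coding
# exon lengths 900/1000/900, so L = 2800 and the final exon-exon junction
# sits at coding position 1900 in transcript orientation.
sim_coding_offsets <- function() {
  c(101:1000, 3001:4000, 6001:6900)
}

# Offsets of stop positions that do or do not escape NMD (50-base inclusive
# window upstream of the final junction, plus the whole final exon), per
# strand.
sim_stop_regions <- function(strand) {
  if (strand == "+") {
    # coding position 1850 maps to offset 3950
    list(nonescape = c(101:1000, 3001:3949),
         escape = c(3950:4000, 6001:6900))
  } else {
    # transcript runs right to left: coding position 1850 maps to offset 3051
    list(nonescape = c(3052:4000, 6001:6900),
         escape = c(101:1000, 3001:3051))
  }
}

#' Simulate the ground truth of a synthetic cohort
#'
#' Builds the gene catalog (with genemap2-style and genePred-style source
#' tables), the variant set with true categories and per-population allele
#' frequencies, and every annotation table the pipeline consumes. Stop-gained
#' variants are placed to exercise both NMD branches (truly deleterious
#' stops upstream of the escape window; decoy stops inside it); decoy
#' missense variants with deleterious-looking scores are planted in
#' ineligible genes, decoy in-frame INDELs outside anchored domains or below
#' the conservation cutoff, and common or homozygote-carrying variants
#' exercise the prefilter.
#'
#' @param config A [sim_config()].
#' @return A `cr_truth` object: list with `config`, `catalog`, `genemap2`,
#'   `gene_models`, `variants` (with `true_category`, `class` and `q_<pop>`
#'   columns), `clinvar`, `consequences`, `scores`, `domains` and
#'   `gene_truth` (per gene and population: `true_gcr`, `se_gcr`,
#'   `n_deleterious`).
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, simulate_truth_impl(config))
}

simulate_truth_impl <- function(config) {
  n_genes <- config$n_genes
  pops <- names(config$populations)
  ly <- .sim_layout

  n_x <- round(n_genes * config$x_fraction)
  genes <- tibble::tibble(
    gene = sprintf("GENE%04d", seq_len(n_genes)),
    chrom = c(paste0("chr", (seq_len(n_genes - n_x) - 1) %% 22 + 1),
              rep("chrX", n_x)),
    strand = ifelse(seq_len(n_genes) %% 2 == 1, "+", "-"),
    base = 1000000L + (seq_len(n_genes) - 1L) * 50000L,
    type3_eligible = runif(n_genes) < config$type3_eligible_fraction,
    type4_anchored = runif(n_genes) < config$type4_anchored_fraction
  )

  genemap2 <- tibble::tibble(
    chromosome = genes$chrom,
    approved_gene_symbol = genes$gene,
    phenotypes = paste0(
      genes$gene, "-related disorder, 600000 (3), ",
      ifelse(genes$chrom == "chrX", "X-linked recessive",
             "Autosomal recessive"))
  )
  gene_models <- tibble::tibble(
    name = paste0("NM_", sprintf("%06d", seq_len(n_genes))),
    chrom = genes$chrom, strand = genes$strand,
    tx_start = genes$base - 1L + ly$exon_start[1] - 1L,
    tx_end = genes$base - 1L + ly$exon_end[3],
    cds_start = genes$base - 1L + ly$cds_start - 1L,   # 0-based half-open
    cds_end = genes$base - 1L + ly$cds_end,
    exon_count = 3L,
    exon_starts = purrr::map_chr(genes$base, \(b) paste(
      b - 1L + ly$exon_start - 1L, collapse = ",")),
    exon_ends = purrr::map_chr(genes$base, \(b) paste(
      b - 1L + ly$exon_end, collapse = ",")),
    gene = genes$gene
  )
  catalog <- load_gene_models(gene_models, parse_genemap2(genemap2))

  domains <- tibble::tibble(
    chrom = genes$chrom,
    start = genes$base - 1L + ly$domain_start,
    end = genes$base - 1L + ly$domain_end,
    domain_id = paste0("PF_", genes$gene),
    gene = genes$gene
  )

  variants <- sim_variants(genes, config)
  anchors <- sim_anchors(genes, ly)
  clinvar <- dplyr::bind_rows(
    anchors$clinvar,
    dplyr::filter(variants, .data$significance != "ABSENT") |>
      dplyr::select("chrom", "pos", "ref", "alt", "gene", "significance",
                    "n_pathogenic_entries", "variant_class"))
  scores <- dplyr::bind_rows(
    anchors$scores,
    variants[c(.key_cols, .cr_tools)])
  consequences <- variants |>
    dplyr::transmute(dplyr::across(dplyr::all_of(.key_cols)),
                     gene = .data$gene,
                     transcript_id = paste0(
                       "NM_", sprintf("%06d", match(.data$gene, genes$gene))),
                     consequence = .data$consequence)

  gene_truth <- compute_gene_truth(variants, genes$gene, config$populations)
  structure(
    list(config = config, catalog = catalog, genemap2 = genemap2,
         gene_models = gene_models,
         variants = variants, clinvar = clinvar, scores = scores,
         consequences = consequences, domains = domains,
         gene_truth = gene_truth),
    class = "cr_truth")
}

# Anchor ClinVar entries: one pathogenic missense per eligible gene (its
# tool scores equal the global cutoffs, so the derived per-gene cutoff
# coincides with the global one) and one pathogenic in-frame INDEL inside
# the domain of each anchored gene. Anchors live in the knowledge base only,
# not in the cohort callset.
sim_anchors <- function(genes, ly) {
  mis <- genes[genes$type3_eligible, ]
  ind <- genes[genes$type4_anchored, ]
  clinvar <- dplyr::bind_rows(
    tibble::tibble(
      chrom = mis$chrom, pos = mis$base - 1L + ly$anchor_missense,
      ref = "G", alt = "C", gene = mis$gene, significance = "P",
      n_pathogenic_entries = 3L, variant_class = "missense"),
    tibble::tibble(
      chrom = ind$chrom, pos = ind$base - 1L + ly$anchor_indel,
      ref = "GACT", alt = "G", gene = ind$gene, significance = "P",
      n_pathogenic_entries = 2L, variant_class = "inframe_indel"))
  scores <- tibble::tibble(
    chrom = mis$chrom, pos = mis$base - 1L + ly$anchor_missense,
    ref = "G", alt = "C")
  for (t in .cr_tools) scores[[t]] <- .cr_default_cutoffs[[t]]
  list(clinvar = clinvar, scores = scores)
}

sim_variants <- function(genes, config) {
  n_v <- rpois(nrow(genes), config$variants_per_gene)
  pools <- list("+" = sim_position_pools("+"), "-" = sim_position_pools("-"))
  idx <- which(n_v > 0)
  per_gene <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    per_gene[[k]] <- sim_gene_variants(genes[i, ], n_v[i], config,
                                       pools[[genes$strand[i]]])
  }
  variants <- dplyr::bind_rows(per_gene)
  variants <- sim_clinvar_labels(variants)
  variants <- sim_scores_for(variants, config$borderline)
  sim_frequencies(variants, config)
}

# offset pools (exonic coding positions relative to the gene base) per region
sim_position_pools <- function(strand) {
  ly <- .sim_layout
  stops <- sim_stop_regions(strand)
  coding <- sim_coding_offsets()
  anchors <- c(ly$anchor_missense, ly$anchor_indel)
  list(
    coding = setdiff(coding, anchors),
    nonescape_stop = setdiff(stops$nonescape, anchors),
    escape_stop = setdiff(stops$escape, anchors),
    domain = setdiff(seq(ly$domain_start + 10L, ly$domain_end - 10L, by = 5L),
                     anchors),
    outside_domain = seq(ly$cds_start, 990L, by = 5L),
    anywhere = setdiff(coding[seq(1, length(coding), by = 3L)], anchors)
  )
}

# one gene's cohort variants: positions, alleles, classes, evidence
sim_gene_variants <- function(g, n, config, pool) {
  ly <- .sim_layout
  cls <- sample(names(config$class_mixture), n, replace = TRUE,
                prob = config$class_mixture)
  # genes without a pathogenic-missense anchor cannot yield ensemble
  # missense calls; planted deleterious-looking missense there is a decoy
  cls[cls == "type3" & !g$type3_eligible] <- "missense_decoy"
  cls[cls == "type4" & !g$type4_anchored] <- "inframe_decoy"
  # refine benign draws into concrete decoy mechanisms
  benign_kinds <- c("synonymous", "missense_benign", "stop_escape",
                    "inframe_outside", "inframe_lowcadd", "common_missense",
                    "conflicting_low")
  is_b <- cls == "benign"
  cls[is_b] <- sample(benign_kinds, sum(is_b), replace = TRUE,
                      prob = c(0.3, 0.25, 0.12, 0.08, 0.08, 0.12, 0.05))

  region_of <- c(
    type1 = "coding", type2 = "type2_special", type3 = "coding",
    type4 = "domain", vus = "coding",
    missense_decoy = "coding", inframe_decoy = "outside_domain",
    synonymous = "anywhere", missense_benign = "coding",
    stop_escape = "escape_stop", inframe_outside = "outside_domain",
    inframe_lowcadd = "domain", common_missense = "coding",
    conflicting_low = "coding")

  # consequence assignment; type2 splits over the five LoF terms
  lof_draw <- sample(c("stop_gained", "frameshift", "splice_acceptor",
                       "splice_donor", "start_lost"),
                     n, replace = TRUE,
                     prob = c(0.4, 0.3, 0.1, 0.1, 0.1))
  # known-pathogenic variants are missense only in ensemble-eligible genes;
  # elsewhere they are nonsense, so a gene's eligibility (driven by known
  # pathogenic missense entries) matches the configured flag
  cons_map <- c(
    type1 = if (g$type3_eligible) "missense" else "stop_gained",
    type2 = "dummy", type3 = "missense", vus = "missense",
    missense_decoy = "missense", missense_benign = "missense",
    common_missense = "missense", conflicting_low = "missense",
    type4 = "inframe_indel", inframe_decoy = "inframe_indel",
    inframe_outside = "inframe_indel", inframe_lowcadd = "inframe_indel",
    stop_escape = "stop_gained", synonymous = "synonymous")
  consequence <- unname(cons_map[cls])
  consequence[cls == "type2"] <- lof_draw[cls == "type2"]

  region <- region_of[cls]
  region[cls == "type2"] <- ifelse(
    consequence[cls == "type2"] == "stop_gained", "nonescape_stop", "coding")

  # draw distinct offsets per variant, respecting each variant's region
  used <- integer(0)
  offset <- integer(n)
  for (i in seq_len(n)) {
    avail <- setdiff(pool[[region[i]]], used)
    if (length(avail) == 0) avail <- setdiff(pool$anywhere, used)
    offset[i] <- if (length(avail) == 1) avail else sample(avail, 1)
    used <- c(used, offset[i])
  }

  is_indel <- consequence == "inframe_indel"
  is_fs <- consequence == "frameshift"
  ref <- ifelse(is_indel, "TGCA", ifelse(is_fs, "TG", "A"))
  alt <- ifelse(is_indel | is_fs, "T", "G")

  cat_map <- c(type1 = 1L, type2 = 2L, type3 = 3L, type4 = 4L)
  tibble::tibble(
    chrom = g$chrom, pos = g$base - 1L + offset, ref = ref, alt = alt,
    gene = g$gene, class = cls, consequence = consequence,
    true_category = unname(cat_map[cls]))
}

sim_clinvar_labels <- function(v) {
  n <- nrow(v)
  sig <- rep("ABSENT", n)
  npe <- rep(0L, n)
  t1 <- which(v$class == "type1")
  t1_kind <- sample(c("P", "LP", "CONFLICTING"), length(t1), replace = TRUE,
                    prob = c(0.6, 0.3, 0.1))
  sig[t1] <- t1_kind
  npe[t1] <- ifelse(t1_kind == "CONFLICTING", 10L + rpois(length(t1), 5),
                    1L + rpois(length(t1), 3))
  low <- which(v$class == "conflicting_low")
  sig[low] <- "CONFLICTING"
  npe[low] <- sample(0:9, length(low), replace = TRUE)
  mb <- which(v$class == "missense_benign")
  sig[mb] <- sample(c("B", "LB", "ABSENT"), length(mb), replace = TRUE)
  vus <- which(v$class %in% c("vus"))
  sig[vus] <- "VUS"
  t3 <- which(v$class == "type3")
  sig[t3] <- sample(c("VUS", "ABSENT"), length(t3), replace = TRUE,
                    prob = c(0.3, 0.7))
  v$significance <- sig
  v$n_pathogenic_entries <- npe
  v$variant_class <- dplyr::case_match(
    v$consequence,
    "missense" ~ "missense", "stop_gained" ~ "nonsense",
    "frameshift" ~ "frameshift",
    c("splice_acceptor", "splice_donor") ~ "splice",
    "inframe_indel" ~ "inframe_indel", .default = "other")
  v
}

# class-conditional tool scores; strictly beyond / inside the cutoffs unless
# borderline mode is on
sim_scores_for <- function(v, borderline) {
  n <- nrow(v)
  for (t in .cr_tools) v[[t]] <- NA_real_
  path_like <- v$class %in% c("type1", "type3", "missense_decoy",
                              "common_missense")
  benign_like <- v$consequence == "missense" & !path_like
  for (t in setdiff(.cr_tools, "CADD")) {
    cut <- .cr_default_cutoffs[[t]]
    if (t == "SIFT") {
      p_draw <- cut * runif(n, 0, 0.75)
      b_draw <- cut + (1 - cut) * runif(n, 0.1, 1)
    } else {
      p_draw <- cut + (1 - cut) * runif(n, 0.1, 1)
      b_draw <- cut * runif(n, 0, 0.9)
    }
    if (borderline) {
      p_draw <- pmin(1, pmax(0, rnorm(n, cut, 0.05)))
      b_draw <- pmin(1, pmax(0, rnorm(n, cut - 0.1, 0.05)))
    }
    v[[t]][path_like] <- p_draw[path_like]
    v[[t]][benign_like] <- b_draw[benign_like]
  }
  cadd_cut <- .cr_default_cutoffs[["CADD"]]
  v$CADD[path_like] <- cadd_cut + runif(n, 0.5, 10)[path_like]
  v$CADD[benign_like] <- runif(n, 0, cadd_cut - 2)[benign_like]
  # VEST3 occasionally missing: a non-mandatory tool failing as "missing"
  drop <- runif(n) < 0.1
  v$VEST3[drop] <- NA_real_
  # in-frame INDELs carry only CADD
  indel <- v$consequence == "inframe_indel"
  v$CADD[indel & v$class %in% c("type4", "inframe_decoy",
                                "inframe_outside")] <-
    21 + runif(n, 0.5, 15)[indel & v$class %in% c("type4", "inframe_decoy",
                                                  "inframe_outside")]
  v$CADD[indel & v$class == "inframe_lowcadd"] <- runif(n, 1, 19.5)[
    indel & v$class == "inframe_lowcadd"]
  v
}

# true per-population allele frequencies
sim_frequencies <- function(variants, config) {
  n <- nrow(variants)
  deleterious <- !is.na(variants$true_category)
  base_q <- numeric(n)
  base_q[deleterious] <- rloguniform(sum(deleterious),
                                     config$q_deleterious[1],
                                     config$q_deleterious[2])
  base_q[!deleterious] <- rloguniform(sum(!deleterious),
                                      config$q_benign[1],
                                      config$q_benign[2])
  common <- variants$class == "common_missense"
  base_q[common] <- runif(sum(common), 0.006, 0.04)
  for (pop in names(config$populations)) {
    mult <- exp(rnorm(n, 0, config$pop_sigma))
    cap <- ifelse(deleterious, config$q_deleterious[2], 0.5)
    variants[[paste0("q_", pop)]] <- pmin(base_q * mult, cap)
    # common decoys must stay above the frequency filter in at least the
    # population where they were planted; keep their floor above it
    variants[[paste0("q_", pop)]][common] <-
      pmax(variants[[paste0("q_", pop)]][common], 0.006)
  }
  variants
}

compute_gene_truth <- function(variants, gene_levels, populations) {
  purrr::map_dfr(names(populations), \(pop) {
    q <- variants[[paste0("q_", pop)]]
    p_carrier <- 2 * q * (1 - q)
    n_dip <- populations[[pop]]
    variants |>
      dplyr::mutate(p_carrier = p_carrier) |>
      dplyr::filter(!is.na(.data$true_category)) |>
      dplyr::group_by(.data$gene) |>
      dplyr::summarise(
        n_deleterious = dplyr::n(),
        true_gcr = 1 - prod(1 - .data$p_carrier),
        se_gcr = sqrt(sum(.data$p_carrier * (1 - .data$p_carrier) / n_dip)),
        .groups = "drop") |>
      tidyr::complete(gene = gene_levels,
                      fill = list(n_deleterious = 0L, true_gcr = 0,
                                  se_gcr = 0)) |>
      dplyr::mutate(population = pop, .after = "gene")
  })
}

#' True gene carrier frequency from a truth table
#'
#' `1 - prod(1 - 2 q_i (1 - q_i))` over the gene's truly deleterious
#' variants in the given population.
#'
#' @param truth A `cr_truth` or `cr_cohort` object.
#' @param gene Gene symbol (must exist in the truth).
#' @param population Population label.
#' @return The true carrier frequency.
#' @export
truth_gcr <- function(truth, gene, population) {
  stopifnot(inherits(truth, c("cr_truth", "cr_cohort")))
  if (!gene %in% truth$gene_truth$gene) {
    abort(sprintf("unknown gene '%s'", gene))
  }
  qcol <- paste0("q_", population)
  if (!qcol %in% names(truth$variants)) {
    abort(sprintf("unknown population '%s'", population))
  }
  v <- truth$variants
  q <- v[[qcol]][v$gene == gene & !is.na(v$true_category)]
  if (length(q) == 0) return(0)
  1 - prod(1 - 2 * q * (1 - q))
}

#' Sample a callset realisation from a simulated truth
#'
#' Draws genotype counts for every variant and population. Deleterious
#' variants are drawn conditional on no homozygotes (healthy-cohort
#' ascertainment): carriers `~ Binomial(n, 2q(1-q))`, so the variant carrier
#' rate estimator is exactly binomial around the true carrier rate. Benign
#' variants follow full Hardy-Weinberg sampling (`hom ~ Binomial(n, q^2)`,
#' then heterozygotes among the remainder), so homozygous calls occur.
#' All individuals are called at every site (`AN = 2n`,
#' `covered_fraction = 1`, filter `PASS`).
#'
#' @param truth A `cr_truth` or `cr_cohort` object.
#' @param seed Integer seed for this realisation (defaults to the config
#'   seed plus one, so the cohort differs from `truth`'s own draws).
#' @return A wide callset tibble in the [read_sites_callset()] layout.
#' @export
sample_callset <- function(truth, seed = NULL) {
  stopifnot(inherits(truth, c("cr_truth", "cr_cohort")))
  seed <- seed %||% (truth$config$seed + 1L)
  withr::with_seed(seed, {
    v <- truth$variants
    n_var <- nrow(v)
    deleterious <- !is.na(v$true_category)
    out <- v[.key_cols]
    out$filter <- "PASS"
    out$covered_fraction <- 1
    for (pop in names(truth$config$populations)) {
      n_dip <- truth$config$populations[[pop]]
      q <- v[[paste0("q_", pop)]]
      hom <- integer(n_var)
      het <- integer(n_var)
      # benign variants: sequential multinomial decomposition of HW genotypes
      hw <- which(!deleterious)
      hom[hw] <- rbinom(length(hw), n_dip, q[hw]^2)
      het[hw] <- rbinom(length(hw), n_dip - hom[hw],
                        2 * q[hw] * (1 - q[hw]) / (1 - q[hw]^2))
      # deleterious variants: healthy-cohort carriers only
      del <- which(deleterious)
      het[del] <- rbinom(length(del), n_dip, 2 * q[del] * (1 - q[del]))
      out[[paste0("AC_", pop)]] <- het + 2L * hom
      out[[paste0("AN_", pop)]] <- 2L * n_dip
      out[[paste0("Hom_", pop)]] <- hom
    }
    finalize_callset(out, names(truth$config$populations),
                     include_all = TRUE, n_individuals = NULL)
  })
}

#' Simulate a complete synthetic cohort
#'
#' [simulate_truth()] followed by one [sample_callset()] realisation, fully
#' deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A `cr_cohort` list: all `cr_truth` components plus `callset`.
#' @export
simulate_cohort <- function(config) {
  truth <- simulate_truth(config)
  callset <- sample_callset(truth, seed = config$seed + 1L)
  structure(c(truth, list(callset = callset)), class = "cr_cohort")
}

#' @export
print.cr_cohort <- function(x, ...) {
  cat(sprintf(
    "<cr_cohort: %d genes, %d variants, %d populations (seed %d)>\n",
    nrow(x$catalog), nrow(x$variants), length(x$config$populations),
    x$config$seed))
  invisible(x)
}

#' Run the classification and carrier pipeline on a simulated cohort
#'
#' Convenience wrapper: classifies the cohort's callset with the shipped
#' global cutoffs (gene eligibility from the simulated ClinVar table) and
#' aggregates carrier rates over the simulated catalog.
#'
#' @param cohort A `cr_cohort`.
#' @param populations Populations to aggregate (default: all simulated).
#' @return List with `classification` (a `cr_classification`) and `carrier`
#'   (a `carrier_table`).
#' @export
run_pipeline <- function(cohort, populations = NULL) {
  stopifnot(inherits(cohort, "cr_cohort"))
  cls <- classify_all(cohort$callset, cohort$clinvar, cohort$consequences,
                      cohort$scores, cohort$domains, cohort$catalog)
  ct <- carrier_table(cls, cohort$callset, cohort$catalog,
                      populations = populations %||%
                        names(cohort$config$populations))
  list(classification = cls, carrier = ct)
}

#' Write all cohort tables in their consumed file dialects
#'
#' Emits the callset TSV, ClinVar-style TSV, score TSV, per-transcript
#' consequence TSV, BED-like domain table (0-based starts), genePred
#' transcript models (headerless), the genemap2-style catalog source and the
#' two truth tables into `dir`.
#'
#' @param cohort A `cr_cohort`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  readr::write_tsv(cohort$callset, p("callset.tsv"))
  readr::write_tsv(cohort$clinvar, p("clinvar.tsv"))
  readr::write_tsv(cohort$scores, p("scores.tsv"))
  readr::write_tsv(cohort$consequences, p("consequences.tsv"))
  bed <- dplyr::mutate(cohort$domains, start = .data$start - 1L)
  readr::write_tsv(bed, p("domains.bed.tsv"))
  gp <- dplyr::mutate(cohort$gene_models, score = 0L, .before = "gene")
  readr::write_tsv(gp, p("gene_models.genepred.tsv"), col_names = FALSE)
  readr::write_tsv(cohort$genemap2, p("genemap2.tsv"))
  readr::write_tsv(cohort$variants, p("truth_variants.tsv"))
  readr::write_tsv(cohort$gene_truth, p("truth_genes.tsv"))
  invisible(dir)
}
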