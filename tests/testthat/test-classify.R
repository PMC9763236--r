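base_records <- function(n, pos = seq_len(n), chrom = "chr1",
                         ac = 1, an = 10000, hom = 0) {
  tibble::tibble(chrom = chrom, pos = as.integer(pos), ref = "A", alt = "G",
                 filter = "PASS", covered_fraction = 1,
                 AC_EAS = ac, AN_EAS = an, Hom_EAS = hom)
}

test_that("the most severe consequence wins, with the stated ordering", {
  expect_equal(rank_consequence(c("missense", "stop_gained")), "stop_gained")
  expect_equal(rank_consequence("missense"), "missense")
  expect_equal(rank_consequence(c("synonymous", "intronic")), "other")
  expect_equal(rank_consequence(c("inframe_insertion", "missense")),
               "missense")
  expect_equal(rank_consequence(c("frameshift", "splice_acceptor")),
               "splice_acceptor")
  expect_error(rank_consequence("exotic_term"), "unknown consequence")
})

test_that("known pathogenic selection covers P/LP and high-evidence conflicts", {
  rec <- base_records(4)
  clinvar <- tibble::tibble(
    chrom = "chr1", pos = 1:4, ref = "A", alt = "G", gene = "G",
    significance = c("P", "CONFLICTING", "CONFLICTING", "VUS"),
    n_pathogenic_entries = c(1L, 26L, 9L, 0L),
    variant_class = "missense")
  t1 <- select_type1(rec, clinvar)
  expect_equal(sort(t1$pos), c(1L, 2L))  # 26 pathogenic entries qualify, 9 do not
  # likely pathogenic included by default, excluded in pathogenic-only mode
  clinvar$significance[4] <- "LP"
  expect_equal(nrow(select_type1(rec, clinvar)), 3L)
  expect_equal(nrow(select_type1(rec, clinvar, include_lp = FALSE)), 2L)
})

test_that("common known pathogenic variants are flagged for review, not dropped", {
  rec <- base_records(2, ac = c(5, 200), an = 20000)  # AF 0.00025 and 0.01
  rec <- add_allele_frequencies(rec)
  clinvar <- tibble::tibble(
    chrom = "chr1", pos = 1:2, ref = "A", alt = "G", gene = "G",
    significance = "P", n_pathogenic_entries = 1L,
    variant_class = "missense")
  t1 <- select_type1(rec, clinvar)
  expect_equal(nrow(t1), 2L)                  # both kept
  expect_equal(attr(t1, "review")$pos, 2L)    # the common one is reported
  # the exclusion list carries the curation
  t1b <- select_type1(rec, clinvar, manual_exclusions = attr(t1, "review"))
  expect_equal(t1b$pos, 1L)
})

test_that("the candidate prefilter removes homozygote carriers and common alleles", {
  rec <- tibble::tibble(
    chrom = "chr1", pos = 1:5, ref = "A", alt = "G",
    AC_EAS = c(4, 50, 49, 4, 2),
    AN_EAS = c(10000, 10000, 10000, 40, 10000),
    Hom_EAS = c(1, 0, 0, 0, 0),
    AC_NFE = c(1, 1, 1, 1, 1),
    AN_NFE = c(10000, 10000, 10000, 10000, 10000),
    Hom_NFE = 0)
  rec$AC_EAS[4] <- 4  # AF 0.1 but AN below the floor
  kept <- candidate_prefilter(rec)
  # 1: homozygote; 2: AF exactly 0.005 (inclusive) removed;
  # 3: AF 0.0049 kept; 4: small-AN population ignored; 5: rare kept
  expect_equal(kept$pos, c(3L, 4L, 5L))
  expect_equal(attr(kept, "removals"), c(homozygous = 1L, high_af = 1L))
})

test_that("cutoff derivation takes pathogenic means and keeps the stricter cutoff", {
  lab <- tibble::tibble(
    chrom = "chr9", pos = 1:6, ref = "A", alt = "G",
    gene = c("GA", "GA", "GA", "GB", "GB", "GC"),
    significance = c("P", "LP", "P", "P", "P", "B"),
    CADD = c(30, 32, 34, 25, 27, 10),
    DANN = c(0.99, 0.995, 0.985, 0.97, 0.99, 0.5),
    fathmm_MKL_coding = 0.95, phastCons = 0.9, Polyphen2 = 0.95,
    SIFT = c(0.02, 0.02, 0.02, 0.06, 0.06, 0.5), VEST3 = 0.8)
  cut <- derive_tool_cutoffs(lab)
  # global mean over the five P/LP rows
  expect_equal(cut$global[["CADD"]], mean(c(30, 32, 34, 25, 27)))
  expect_equal(cut$global[["SIFT"]], mean(c(0.02, 0.02, 0.02, 0.06, 0.06)))
  expect_setequal(cut$eligible_genes, c("GA", "GB"))
  pg <- cut$per_gene
  # GA mean CADD 32 is stricter than the global 29.6 -> kept
  expect_equal(pg$cutoff[pg$gene == "GA" & pg$tool == "CADD"], 32)
  # GB mean CADD 26 is laxer -> replaced by the global cutoff
  expect_equal(pg$cutoff[pg$gene == "GB" & pg$tool == "CADD"],
               mean(c(30, 32, 34, 25, 27)))
  # SIFT direction: lower is stricter; GA 0.02 kept, GB 0.06 -> global 0.036
  expect_equal(pg$cutoff[pg$gene == "GA" & pg$tool == "SIFT"], 0.02)
  expect_equal(pg$cutoff[pg$gene == "GB" & pg$tool == "SIFT"],
               cut$global[["SIFT"]])
})

test_that("per-gene cutoffs reproduce brute-force pass/fail on a score grid", {
  lab <- tibble::tibble(
    chrom = "chr9", pos = 1:4, ref = "A", alt = "G",
    gene = c("GA", "GA", "GB", "GB"), significance = "P",
    CADD = c(30, 34, 20, 22), DANN = 0.99, fathmm_MKL_coding = 0.9,
    phastCons = 0.85, Polyphen2 = 0.92,
    SIFT = c(0.02, 0.04, 0.05, 0.07), VEST3 = 0.8)
  cut <- derive_tool_cutoffs(lab)
  grid <- expand.grid(gene = c("GA", "GB"), CADD = c(21, 28, 31, 33),
                      SIFT = c(0.01, 0.03, 0.05, 0.08),
                      stringsAsFactors = FALSE)
  n <- nrow(grid)
  rec <- base_records(n, chrom = "chr9", pos = 100 + seq_len(n))
  cons <- tibble::tibble(chrom = "chr9", pos = rec$pos, ref = "A", alt = "G",
                         gene = grid$gene, consequence = "missense")
  sco <- tibble::tibble(chrom = "chr9", pos = rec$pos, ref = "A", alt = "G",
                        CADD = grid$CADD, DANN = 0.995,
                        fathmm_MKL_coding = 0.95, phastCons = 0.9,
                        Polyphen2 = 0.95, SIFT = grid$SIFT, VEST3 = 0.85)
  t3 <- select_type3(rec, cons, sco, cut)
  # brute force: all five mandatory tools at the stricter-of-two cutoff
  eff <- function(g, tool, glob) {
    pg <- cut$per_gene
    v <- pg$cutoff[pg$gene == g & pg$tool == tool]
    if (length(v) == 0) glob else v
  }
  want <- vapply(seq_len(n), \(i) {
    g <- grid$gene[i]
    grid$CADD[i] >= eff(g, "CADD", cut$global[["CADD"]]) &&
      grid$SIFT[i] <= eff(g, "SIFT", cut$global[["SIFT"]]) &&
      0.995 >= eff(g, "DANN", cut$global[["DANN"]]) &&
      0.9 >= eff(g, "phastCons", cut$global[["phastCons"]]) &&
      0.95 >= eff(g, "Polyphen2", cut$global[["Polyphen2"]])
  }, TRUE)
  expect_setequal(t3$pos, rec$pos[want])
})

test_that("a failing mandatory tool vetoes an otherwise five-of-seven pass", {
  rec <- base_records(1, pos = 50L)
  cons <- tibble::tibble(chrom = "chr1", pos = 50L, ref = "A", alt = "G",
                         gene = "G", consequence = "missense")
  # passes CADD, DANN, fathmm_MKL, phastCons, VEST3 (5 of 7) but fails
  # SIFT and Polyphen2 - and SIFT/Polyphen2 are mandatory
  sco <- tibble::tibble(chrom = "chr1", pos = 50L, ref = "A", alt = "G",
                        CADD = 35, DANN = 1, fathmm_MKL_coding = 0.99,
                        phastCons = 0.99, Polyphen2 = 0.2, SIFT = 0.5,
                        VEST3 = 0.95)
  strict <- tool_cutoffs(eligible_genes = "G")
  expect_equal(nrow(select_type3(rec, cons, sco, strict)), 0L)
  plain <- tool_cutoffs(eligible_genes = "G", require_mandatory = FALSE)
  expect_equal(nrow(select_type3(rec, cons, sco, plain)), 1L)
})

test_that("missense in genes without known pathogenic missense is never called", {
  rec <- base_records(1, pos = 60L)
  cons <- tibble::tibble(chrom = "chr1", pos = 60L, ref = "A", alt = "G",
                         gene = "NOPE", consequence = "missense")
  sco <- tibble::tibble(chrom = "chr1", pos = 60L, ref = "A", alt = "G",
                        CADD = 40, DANN = 1, fathmm_MKL_coding = 1,
                        phastCons = 1, Polyphen2 = 1, SIFT = 0, VEST3 = 1)
  cut <- tool_cutoffs(eligible_genes = "OTHER")
  expect_equal(nrow(select_type3(rec, cons, sco, cut)), 0L)
  # and a missing mandatory score counts as failing
  cut2 <- tool_cutoffs(eligible_genes = "NOPE")
  sco$SIFT <- NA_real_
  expect_equal(nrow(select_type3(rec, cons, sco, cut2)), 0L)
})

test_that("harmful in-frame INDELs need conservation and an anchored domain", {
  rec <- tibble::tibble(chrom = "chr1", pos = c(100L, 110L, 300L, 120L),
                        ref = "ATCG", alt = "A", filter = "PASS",
                        covered_fraction = 1,
                        AC_EAS = 1, AN_EAS = 10000, Hom_EAS = 0)
  cons <- tibble::tibble(chrom = "chr1", pos = rec$pos, ref = "ATCG",
                         alt = "A", gene = "G",
                         consequence = "inframe_indel")
  sco <- tibble::tibble(chrom = "chr1", pos = rec$pos, ref = "ATCG",
                        alt = "A",
                        CADD = c(25, 20, 30, NA))
  domains <- tibble::tibble(chrom = "chr1", start = c(90L, 280L),
                            end = c(200L, 400L),
                            domain_id = c("DA", "DB"), gene = "G")
  clinvar <- tibble::tibble(chrom = "chr1", pos = 150L, ref = "GGGT",
                            alt = "G", gene = "G", significance = "P",
                            n_pathogenic_entries = 1L,
                            variant_class = "inframe_indel")
  t4 <- select_type4(rec, cons, sco, domains, clinvar)
  # 100: CADD 25 in the anchored domain -> kept
  # 110: CADD exactly 20 -> excluded (strict bound)
  # 300: CADD 30 but domain DB has no pathogenic INDEL -> excluded
  # 120: missing CADD -> excluded
  expect_equal(t4$pos, 100L)
  expect_equal(t4$domain_id, "DA")
})

test_that("the full cascade assigns each variant to exactly one category", {
  fx <- make_random_fixture(101, n = 400)
  cls <- suppressWarnings(classify_all(
    fx$records, fx$clinvar, fx$consequences, fx$scores, fx$domains,
    fx$catalog, exclusions = fx$exclusions))
  keys <- with(cls$typed, paste(chrom, pos, ref, alt))
  expect_equal(anyDuplicated(keys), 0L)
  expect_true(all(cls$typed$category %in% 1:4))
  expect_lte(nrow(cls$typed) + nrow(cls$unclassified), nrow(fx$records))
  expect_equal(sum(cls$counts), nrow(cls$typed))
  # empty input gives an empty partition
  empty <- classify_all(fx$records[0, ], fx$clinvar, fx$consequences,
                        fx$scores, fx$domains, fx$catalog)
  expect_equal(nrow(empty$typed), 0L)
})

test_that("a known pathogenic variant that is also loss-of-function is Type 1 only", {
  rec <- base_records(1, pos = 70L)
  clinvar <- tibble::tibble(chrom = "chr1", pos = 70L, ref = "A", alt = "G",
                            gene = "G1", significance = "P",
                            n_pathogenic_entries = 2L,
                            variant_class = "nonsense")
  cons <- tibble::tibble(chrom = "chr1", pos = 70L, ref = "A", alt = "G",
                         gene = "G1", consequence = "stop_gained")
  fx_cat <- specs_to_catalog(fixture_gene_specs())
  cls <- classify_all(rec, clinvar, cons, fx_cat$transcripts[[1]][0, ],
                      fixture_domains(), fx_cat)
  expect_equal(cls$typed$category, 1L)
})

test_that("classification matches the brute-force evaluator exactly", {
  for (s in c(3, 14, 159)) {
    fx <- make_random_fixture(s, n = 300, derived_cutoffs = s %% 2 == 1)
    cmp <- fixture_compare_sets(fx)
    expect_identical(cmp$got, cmp$want, label = paste("fixture seed", s))
  }
})

test_that("tightening cutoffs never adds ensemble-missense calls", {
  withr::with_seed(77, {
    for (rep in 1:10) {
      n <- 100
      rec <- base_records(n, pos = 1000 + seq_len(n))
      cons <- tibble::tibble(chrom = "chr1", pos = rec$pos, ref = "A",
                             alt = "G", gene = "G",
                             consequence = "missense")
      sco <- tibble::tibble(chrom = "chr1", pos = rec$pos, ref = "A",
                            alt = "G",
                            CADD = runif(n, 20, 40),
                            DANN = runif(n, 0.9, 1),
                            fathmm_MKL_coding = runif(n, 0.7, 1),
                            phastCons = runif(n, 0.6, 1),
                            Polyphen2 = runif(n, 0.7, 1),
                            SIFT = runif(n, 0, 0.1),
                            VEST3 = runif(n, 0.5, 1))
      base <- tool_cutoffs(eligible_genes = "G")
      loose <- select_type3(rec, cons, sco, base)
      tightened <- base$global
      tool <- sample(names(tightened), 1)
      delta <- runif(1, 0.001, 0.05)
      tightened[tool] <- tightened[tool] +
        if (tool == "SIFT") -delta else if (tool == "CADD") delta * 100 else delta
      tight <- tool_cutoffs(global = tightened, eligible_genes = "G")
      strict <- select_type3(rec, cons, sco, tight)
      expect_true(all(strict$pos %in% loose$pos))
    }
  })
})

test_that("the allele-frequency threshold is monotone in both directions", {
  withr::with_seed(88, {
    an <- 10000
    rec <- tibble::tibble(
      chrom = "chr1", pos = 1:500, ref = "A", alt = "G",
      AC_EAS = sample(0:80, 500, TRUE), AN_EAS = an, Hom_EAS = 0)
    thresholds <- c(0.001, 0.003, 0.005, 0.008)
    kept <- lapply(thresholds, \(th) candidate_prefilter(rec, th)$pos)
    for (i in seq_len(length(thresholds) - 1)) {
      expect_true(all(kept[[i]] %in% kept[[i + 1]]))  # raising never removes
    }
  })
})

test_that("external cross-checks report per-class fractions of the overlap", {
  typed <- tibble::tibble(chrom = "chr1", pos = 1:20, ref = "A", alt = "G",
                          gene = "G", category = 3L)
  ext <- tibble::tibble(chrom = "chr1", pos = 1:10, ref = "A", alt = "G",
                        class = c("Benign", rep("Pathogenic", 9)))
  out <- crosscheck_external(typed, ext)
  expect_equal(out$n_overlap, c(10L, 10L))
  expect_equal(out$percent[out$class == "Benign"], 10)
  # no overlap -> undefined fractions
  ext2 <- dplyr::mutate(ext, chrom = "chr9")
  out2 <- crosscheck_external(typed, ext2)
  expect_true(all(is.na(out2$fraction)))
  # 0 of N in a class -> 0.00
  ext3 <- dplyr::mutate(ext, class = "Pathogenic")
  out3 <- crosscheck_external(typed, ext3)
  expect_equal(out3$percent, 100)
})

test_that("tool separation summaries are class-conditional and flag tiny classes", {
  lab <- tibble::tibble(
    significance = c(rep("P", 4), rep("B", 4)),
    CADD = c(26, 28, 30, 28.16, 10, 12, 8, 11),
    SIFT = c(0.01, 0.02, 0.03, 0.02, 0.4, 0.5, 0.6, 0.5))
  out <- evaluate_tool_separation(lab)
  expect_equal(out$mean[out$tool == "CADD" & out$label == "pathogenic"],
               mean(c(26, 28, 30, 28.16)))
  # identical distributions give identical summaries
  lab2 <- tibble::tibble(significance = c("P", "P", "B", "B"),
                         CADD = c(20, 30, 20, 30))
  out2 <- evaluate_tool_separation(lab2)
  expect_equal(out2$mean[1], out2$mean[2])
  expect_equal(out2$sd[1], out2$sd[2])
  # a single labelled value leaves the spread undefined and flagged
  lab3 <- tibble::tibble(significance = c("P", "B", "B"),
                         CADD = c(30, 10, 12))
  out3 <- evaluate_tool_separation(lab3)
  expect_true(out3$flagged[out3$label == "pathogenic"])
})

test_that("shifted score distributions separate the classes in simulation", {
  withr::with_seed(99, {
    hits <- 0
    for (rep in 1:20) {
      lab <- tibble::tibble(
        significance = rep(c("P", "B"), each = 500),
        CADD = c(rnorm(500, 28, 6), rnorm(500, 16, 6)))
      out <- evaluate_tool_separation(lab)
      hits <- hits + (out$mean[out$label == "pathogenic"] >
                        out$mean[out$label == "benign"])
    }
    expect_gte(hits, 20 * 0.99)
  })
})
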