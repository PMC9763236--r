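write_test_vcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AC_EAS,Number=A,Type=Integer,Description=\"EAS allele count\">",
    "##INFO=<ID=AN_EAS,Number=1,Type=Integer,Description=\"EAS allele number\">",
    "##INFO=<ID=nhomalt_EAS,Number=A,Type=Integer,Description=\"EAS homozygotes\">",
    "##INFO=<ID=AC_NFE,Number=A,Type=Integer,Description=\"NFE allele count\">",
    "##INFO=<ID=AN_NFE,Number=1,Type=Integer,Description=\"NFE allele number\">",
    "##INFO=<ID=nhomalt_NFE,Number=A,Type=Integer,Description=\"NFE homozygotes\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    paste0("chr1\t100\t.\tA\tG\t.\tPASS\t",
           "AC_EAS=3;AN_EAS=100;nhomalt_EAS=1;AC_NFE=0;AN_NFE=200;nhomalt_NFE=0"),
    paste0("chr1\t200\t.\tA\tC,T\t.\tPASS\t",
           "AC_EAS=2,5;AN_EAS=120;nhomalt_EAS=0,1;AC_NFE=1,1;AN_NFE=80;nhomalt_NFE=0,0"),
    paste0("chr2\t300\t.\tG\tA\t.\tAC0\t",
           "AC_EAS=1;AN_EAS=50;nhomalt_EAS=0;AC_NFE=2;AN_NFE=60;nhomalt_NFE=1")),
    path)
  path
}

test_that("VCF sites are read and multiallelics decomposed per alt allele", {
  path <- write_test_vcf(withr::local_tempfile(fileext = ".vcf"))
  rec <- read_sites_callset(path, populations = c("EAS", "NFE"))
  expect_equal(nrow(rec), 4L)  # 2 biallelic + 1 site split in 2
  one <- dplyr::filter(rec, .data$pos == 100)
  expect_equal(one$AC_EAS, 3)
  expect_equal(one$AN_EAS, 100)
  expect_equal(one$Hom_EAS, 1)
  expect_equal(one$AF_EAS, 0.03)
  multi <- dplyr::filter(rec, .data$pos == 200) |> dplyr::arrange(.data$alt)
  expect_equal(multi$alt, c("C", "T"))
  expect_equal(multi$AC_EAS, c(2, 5))
  expect_equal(multi$Hom_EAS, c(0, 1))
  expect_equal(multi$AN_EAS, c(120, 120))
  expect_equal(rec$filter[rec$pos == 300], "AC0")
  # ALL synthesised as the sum over populations
  expect_equal(one$AC_ALL, 3)
  expect_equal(one$AN_ALL, 300)
})

test_that("per-alt decomposition recomposes to the original AC vector", {
  path <- write_test_vcf(withr::local_tempfile(fileext = ".vcf"))
  rec <- read_sites_callset(path, populations = c("EAS", "NFE"))
  recomposed <- rec |>
    dplyr::group_by(.data$chrom, .data$pos, .data$ref) |>
    dplyr::summarise(ac = sum(.data$AC_EAS), .groups = "drop")
  expect_equal(recomposed$ac[recomposed$pos == 200], 7)  # 2 + 5
})

test_that("a requested population missing from the source is an error", {
  path <- write_test_vcf(withr::local_tempfile(fileext = ".vcf"))
  expect_error(read_sites_callset(path, populations = c("EAS", "SAS")),
               "SAS")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    chrom = "chr1", pos = 1L, ref = "A", alt = "G",
    AC_EAS = 1, AN_EAS = 10, Hom_EAS = 0), tsv)
  expect_error(read_sites_callset(tsv, populations = c("EAS", "NFE")),
               "AC_NFE")
})

test_that("TSV callsets map columns directly and missing Hom warns to zero", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    chrom = "chr1", pos = 5L, ref = "A", alt = "T",
    AC_EAS = 4, AN_EAS = 200), tsv)
  expect_warning(rec <- read_sites_callset(tsv, populations = "EAS"),
                 "homozygote")
  expect_equal(rec$Hom_EAS, 0)
  expect_equal(rec$AF_EAS, 0.02)
})

test_that("coverage is approximated from AN when cohort size is known", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    chrom = "chr1", pos = 5L, ref = "A", alt = "T",
    AC_EAS = 1, AN_EAS = 120, Hom_EAS = 0), tsv)
  rec <- read_sites_callset(tsv, populations = "EAS", n_individuals = 100)
  expect_equal(rec$covered_fraction, 0.6)
})

test_that("quality filter is PASS-only and strictly more than the coverage bound", {
  rec <- tibble::tibble(
    chrom = "chr1", pos = 1:4, ref = "A", alt = "G",
    filter = c("PASS", "PASS", "AC0", "PASS"),
    covered_fraction = c(0.9, 0.5, 1.0, 0.51),
    AC_EAS = 1, AN_EAS = 100, Hom_EAS = 0)
  kept <- filter_high_quality(rec)
  expect_equal(kept$pos, c(1L, 4L))  # 0.5 exactly is removed; non-PASS removed
  expect_equal(attr(kept, "removals"),
               c(non_pass = 1L, low_coverage = 1L))
})

test_that("merging sums counts per population and recomputes frequencies", {
  a <- tibble::tibble(chrom = "chr1", pos = 10L, ref = "A", alt = "G",
                      filter = "PASS", covered_fraction = 0.9,
                      AC_EAS = 2, AN_EAS = 100, Hom_EAS = 1)
  b <- tibble::tibble(chrom = c("chr1", "chr1"), pos = c(10L, 20L),
                      ref = "A", alt = "G", filter = "PASS",
                      covered_fraction = 0.8,
                      AC_EAS = c(1, 3), AN_EAS = c(50, 60),
                      Hom_EAS = c(0, 0))
  m <- merge_callsets(a, b)
  shared <- dplyr::filter(m, .data$pos == 10)
  expect_equal(shared$AC_EAS, 3)
  expect_equal(shared$AN_EAS, 150)
  expect_equal(shared$Hom_EAS, 1)
  expect_equal(shared$AF_EAS, 0.02)
  only_b <- dplyr::filter(m, .data$pos == 20)
  expect_equal(only_b$AC_EAS, 3)   # passes through unchanged
  expect_equal(only_b$AN_EAS, 60)
})

test_that("merging conserves totals and is commutative on random callsets", {
  withr::with_seed(17, {
    make <- function(n) {
      an <- sample(50:500, n, TRUE)
      ac <- vapply(an, \(x) sample(0:min(x, 20), 1), 1L)
      hom <- vapply(ac, \(x) sample(0:(x %/% 2), 1), 1L)
      tibble::tibble(
        chrom = "chr1", pos = sample(1:40, n), ref = "A", alt = "G",
        filter = "PASS", covered_fraction = 1,
        AC_EAS = ac, AN_EAS = an, Hom_EAS = hom)
    }
    for (rep in 1:20) {
      a <- make(sample(5:15, 1))
      b <- make(sample(5:15, 1))
      ab <- merge_callsets(a, b)
      ba <- merge_callsets(b, a)
      expect_equal(sum(ab$AC_EAS), sum(a$AC_EAS) + sum(b$AC_EAS))
      expect_equal(sum(ab$AN_EAS), sum(a$AN_EAS) + sum(b$AN_EAS))
      expect_equal(sum(ab$Hom_EAS), sum(a$Hom_EAS) + sum(b$Hom_EAS))
      expect_true(all(2 * ab$Hom_EAS <= ab$AC_EAS))
      expect_equal(dplyr::arrange(ab, .data$pos), dplyr::arrange(ba, .data$pos))
    }
  })
})

test_that("merging is associative over three callsets", {
  withr::with_seed(23, {
    make <- function() tibble::tibble(
      chrom = "chr1", pos = sample(1:10, 6), ref = "A", alt = "G",
      filter = "PASS", covered_fraction = 1,
      AC_EAS = sample(0:5, 6, TRUE), AN_EAS = sample(100:200, 6, TRUE),
      Hom_EAS = 0)
    a <- make(); b <- make(); c <- make()
    left <- merge_callsets(merge_callsets(a, b), c)
    right <- merge_callsets(a, merge_callsets(b, c))
    expect_equal(dplyr::arrange(left, .data$pos)[c("pos", "AC_EAS", "AN_EAS")],
                 dplyr::arrange(right, .data$pos)[c("pos", "AC_EAS", "AN_EAS")])
  })
})

test_that("conflicting ref alleles at one site abort the merge", {
  a <- tibble::tibble(chrom = "chr1", pos = 10L, ref = "A", alt = "G",
                      filter = "PASS", covered_fraction = 1,
                      AC_EAS = 1, AN_EAS = 10, Hom_EAS = 0)
  b <- dplyr::mutate(a, ref = "C")
  expect_error(merge_callsets(a, b), "conflicting ref")
})

test_that("exclusion lists remove exact key matches only", {
  rec <- tibble::tibble(chrom = "chr1", pos = 1:10, ref = "A", alt = "G",
                        AC_EAS = 1, AN_EAS = 100, Hom_EAS = 0)
  excl <- tibble::tibble(chrom = "chr1", pos = c(2L, 5L, 7L),
                         ref = "A", alt = "G", reason = "curated")
  out <- apply_exclusion_list(rec, excl)
  expect_equal(nrow(out), 7L)
  expect_equal(attr(out, "n_excluded"), 3L)
  expect_false(any(out$pos %in% c(2, 5, 7)))
  # empty list is the identity
  ident <- apply_exclusion_list(rec, NULL)
  expect_equal(nrow(ident), 10L)
  # wrong alt does not match; unseen key only informs
  miss <- dplyr::mutate(excl, alt = "T")
  expect_message(out2 <- apply_exclusion_list(rec, miss), "not observed")
  expect_equal(nrow(out2), 10L)
})

test_that("count invariants are validated on read", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    chrom = "chr1", pos = 5L, ref = "A", alt = "T",
    AC_EAS = 4, AN_EAS = 200, Hom_EAS = 3), tsv)
  expect_error(read_sites_callset(tsv, populations = "EAS"),
               "corrupt counts")
})
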