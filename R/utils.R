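# Internal helpers shared across modules.

# Canonical string key for a variant; used only for set operations where a
# four-column join would be awkward.
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

.key_cols <- c("chrom", "pos", "ref", "alt")

assert_cols <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# Population count columns present in a wide callset, inferred from AC_<pop>.
detect_populations <- function(df) {
  pops <- sub("^AC_", "", grep("^AC_", names(df), value = TRUE))
  pops[paste0("AN_", pops) %in% names(df)]
}

count_cols <- function(populations) {
  c(paste0("AC_", populations), paste0("AN_", populations),
    paste0("Hom_", populations))
}

# log-uniform draw on [lo, hi]
rloguniform <- function(n, lo, hi) {
  exp(runif(n, log(lo), log(hi)))
}

is_chrx <- function(chrom) {
  toupper(sub("^chr", "", chrom)) == "X"
}
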