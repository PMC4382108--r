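#' Configuration for the genotype QC cascade
#'
#' Thresholds for the target-capture SNP filter cascade: per-call depth and
#' allele-balance replacement, per-marker call rate, parental/Mendelian
#' consistency and segregation-distortion testing.
#'
#' @param min_call_depth calls with total read depth below this become
#'   no-calls (default 20).
#' @param binomial_alpha two-sided significance level of the exact binomial
#'   test of 0.5 allele balance applied to heterozygous calls (default 1e-3).
#' @param min_call_rate minimum fraction of called samples (parents plus
#'   offspring) a marker must retain after call replacement (default 0.8).
#' @param seg_p_threshold markers whose segregation chi-square p-value falls
#'   below this are dropped as distorted (default 1e-5).
#' @param min_seg_offspring minimum called offspring required to test
#'   segregation; markers below it are dropped and counted (default 10).
#' @return an object of class `qc_config`.
#' @export
qc_config <- function(min_call_depth = 20, binomial_alpha = 1e-3,
                      min_call_rate = 0.8, seg_p_threshold = 1e-5,
                      min_seg_offspring = 10) {
  check_num(min_call_depth, "min_call_depth", 0, Inf)
  check_num(binomial_alpha, "binomial_alpha", 0, 1)
  check_num(min_call_rate, "min_call_rate", 0, 1)
  check_num(seg_p_threshold, "seg_p_threshold", 0, 1)
  check_num(min_seg_offspring, "min_seg_offspring", 0, Inf)
  structure(list(min_call_depth = min_call_depth,
                 binomial_alpha = binomial_alpha,
                 min_call_rate = min_call_rate,
                 seg_p_threshold = seg_p_threshold,
                 min_seg_offspring = min_seg_offspring),
            class = "qc_config")
}

# two-sided exact binomial p for balance 0.5; identical to
# binom.test(x, n, 0.5)$p.value for all x, n
binom_balance_p <- function(x, n) {
  m <- pmin(x, n - x)
  pmin(1, 2 * stats::pbinom(m, n, 0.5))
}

#' Replace unreliable calls with no-calls
#'
#' Any call with total depth below `min_call_depth` becomes a no-call, as
#' does any heterozygous call whose two allele read depths reject a
#' symmetric-split (p = 0.5) two-sided exact binomial test at
#' `binomial_alpha`. Heterozygous calls lacking allele depths are also
#' replaced and counted. Homozygous calls are filtered by depth alone — the
#' natural 0.5 allele-balance null only exists for heterozygotes.
#'
#' @param vt a [variant_table].
#' @param config a [qc_config()].
#' @return the table with calls replaced; attribute `"replacements"` counts
#'   replacements by reason (`low_depth`, `allele_balance`, `missing_ad`).
#' @export
apply_call_filters <- function(vt, config = qc_config()) {
  am_check(inherits(vt, "variant_table"), "'vt' must be a variant_table")
  gt <- vt$gt
  called <- which(!is.na(gt))
  dp <- vt$dp[called]
  dp[is.na(dp)] <- 0
  low <- dp < config$min_call_depth

  sp <- strsplit(gt[called], "/", fixed = TRUE)
  a1 <- vapply(sp, `[`, character(1), 1L)
  a2 <- vapply(sp, `[`, character(1), 2L)
  het <- a1 != a2

  bal_fail <- logical(length(called))
  no_ad <- logical(length(called))
  hi <- which(het & !low)
  if (length(hi)) {
    ad <- vt$ad[called[hi]]
    no_ad[hi] <- is.na(ad)
    ok <- hi[!is.na(ad)]
    if (length(ok)) {
      adl <- strsplit(vt$ad[called[ok]], ",", fixed = TRUE)
      i1 <- as.integer(a1[ok]) + 1L
      i2 <- as.integer(a2[ok]) + 1L
      d1 <- as.numeric(mapply(`[`, adl, i1))
      d2 <- as.numeric(mapply(`[`, adl, i2))
      p <- binom_balance_p(d1, d1 + d2)
      bal_fail[ok] <- p < config$binomial_alpha
    }
  }
  kill <- low | bal_fail | no_ad
  gt[called[kill]] <- NA_character_
  vt$gt <- gt
  attr(vt, "replacements") <- c(low_depth = sum(low),
                                allele_balance = sum(bal_fail),
                                missing_ad = sum(no_ad))
  vt
}

#' Drop markers with insufficient call rate
#'
#' Retains sites whose called-sample fraction, over all samples (parents and
#' offspring), is at least `min_call_rate`. Applied after call replacement.
#'
#' @param vt a [variant_table].
#' @param min_call_rate minimum called fraction (default 0.8).
#' @return the filtered table, with attribute `"removed"` (count).
#' @export
filter_call_rate <- function(vt, min_call_rate = 0.8) {
  am_check(inherits(vt, "variant_table"), "'vt' must be a variant_table")
  frac <- rowMeans(!is.na(vt$gt))
  out <- subset_sites(vt, frac >= min_call_rate)
  attr(out, "removed") <- sum(frac < min_call_rate)
  out
}

# segregation type from parental allele pairs
seg_type_of <- function(p1, p2) {
  h1 <- p1[1] != p1[2]; h2 <- p2[1] != p2[2]
  if (h1 && !h2) "lm"
  else if (!h1 && h2) "np"
  else if (h1 && h2 && setequal(p1, p2)) "hk"
  else if (h1 && h2) "fi"
  else NA_character_  # neither parent heterozygous: non-segregating
}

# Mendelian genotype space: one allele from each parent
mendel_space <- function(p1, p2) unique(as.vector(outer(p1, p2, geno_str)))

#' Parental and Mendelian-consistency filter
#'
#' Drops markers with a no-call in either parent, markers where neither
#' parent is heterozygous (no segregation information), and markers where any
#' offspring genotype is impossible under Mendelian transmission of one
#' allele from each parent. Surviving markers are typed by their parental
#' configuration (P1-het 1:1, P2-het 1:1, both-het 1:2:1, fully informative
#' 1:1:1:1) and re-expressed as allele-pair genotypes.
#'
#' @param vt a [variant_table].
#' @param parents names of the two parent samples (defaults to the table's).
#' @return a `marker_set`: list with `markers` (data frame: `marker_id`,
#'   `contig_id`, `position`, `p1`, `p2`, `seg_type`), `geno` (character
#'   matrix markers x offspring of `"X/Y"` genotypes) and `offspring` ids.
#'   Attribute `"removed"` counts drops by reason.
#' @export
filter_parental <- function(vt, parents = vt$parents) {
  am_check(inherits(vt, "variant_table"), "'vt' must be a variant_table")
  am_check(length(parents) == 2L && all(parents %in% vt$samples),
           "both parent samples must be present in the VCF",
           class = "anchormap_config_error")
  off <- setdiff(vt$samples, parents)
  pi <- match(parents, vt$samples)
  oi <- match(off, vt$samples)
  M <- nrow(vt$sites)
  keep <- logical(M)
  reason <- character(M)
  type <- character(M)
  p1s <- character(M); p2s <- character(M)
  geno <- matrix(NA_character_, M, length(off),
                 dimnames = list(vt$sites$marker_id, off))
  for (m in seq_len(M)) {
    ref <- vt$sites$ref[m]; alt <- vt$sites$alt[m]
    p1 <- gt_to_alleles(vt$gt[m, pi[1L]], ref, alt)
    p2 <- gt_to_alleles(vt$gt[m, pi[2L]], ref, alt)
    if (anyNA(p1) || anyNA(p2)) { reason[m] <- "parent_nocall"; next }
    st <- seg_type_of(p1, p2)
    if (is.na(st)) { reason[m] <- "non_segregating"; next }
    og <- vt$gt[m, oi]
    al <- c(ref, strsplit(alt, ",", fixed = TRUE)[[1]])
    codes <- outer(seq_along(al), seq_along(al), function(i, j)
      geno_str(al[pmin(i, j)], al[pmax(i, j)]))
    idx <- !is.na(og)
    gsplit <- strsplit(og[idx], "/", fixed = TRUE)
    gi <- vapply(gsplit, function(z) {
      i <- as.integer(z) + 1L
      codes[min(i), max(i)]
    }, character(1))
    space <- mendel_space(p1, p2)
    if (!all(gi %in% space)) { reason[m] <- "mendelian"; next }
    keep[m] <- TRUE
    type[m] <- st
    p1s[m] <- geno_str(p1[1], p1[2]); p2s[m] <- geno_str(p2[1], p2[2])
    geno[m, idx] <- gi
  }
  markers <- data.frame(marker_id = vt$sites$marker_id[keep],
                        contig_id = vt$sites$contig_id[keep],
                        position = vt$sites$position[keep],
                        p1 = p1s[keep], p2 = p2s[keep],
                        seg_type = type[keep], stringsAsFactors = FALSE)
  ms <- structure(list(markers = markers,
                       geno = geno[keep, , drop = FALSE],
                       offspring = off),
                  class = "marker_set")
  attr(ms, "removed") <- c(parent_nocall = sum(reason == "parent_nocall"),
                           non_segregating = sum(reason == "non_segregating"),
                           mendelian = sum(reason == "mendelian"))
  ms
}

#' @export
print.marker_set <- function(x, ...) {
  cat(sprintf("marker_set: %d markers x %d offspring\n",
              nrow(x$markers), length(x$offspring)))
  print(table(x$markers$seg_type))
  invisible(x)
}

#' @export
`[.marker_set` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$markers$marker_id)
  structure(list(markers = x$markers[i, , drop = FALSE],
                 geno = x$geno[i, , drop = FALSE],
                 offspring = x$offspring),
            class = "marker_set")
}

# expected offspring genotype classes and Mendelian proportions per type
seg_classes <- function(p1, p2, type) {
  a1 <- split_geno(p1); a2 <- split_geno(p2)
  if (type %in% c("lm", "np")) {
    cls <- unique(mendel_space(a1, a2))
    list(classes = cls, probs = rep(0.5, 2))
  } else if (type == "hk") {
    al <- sort(unique(a1))
    list(classes = c(geno_str(al[1], al[1]), geno_str(al[1], al[2]),
                     geno_str(al[2], al[2])),
         probs = c(0.25, 0.5, 0.25))
  } else {
    cls <- unique(as.vector(outer(a1, a2, geno_str)))
    list(classes = cls, probs = rep(0.25, 4))
  }
}

#' Chi-square test of Mendelian segregation per marker
#'
#' Observed offspring genotype-class counts are compared with the expected
#' Mendelian ratio for the marker's segregation type — 1:1 (1 df) for
#' single-parent heterozygous markers, 1:2:1 (2 df) for both-het shared-allele
#' markers, 1:1:1:1 (3 df) for fully informative markers — with the ordinary
#' (uncorrected) goodness-of-fit statistic.
#'
#' @param ms a `marker_set` from [filter_parental()].
#' @return data frame with `marker_id`, `n_called`, `chi2`, `df`, `p`.
#' @export
segregation_test <- function(ms) {
  am_check(inherits(ms, "marker_set"), "'ms' must be a marker_set")
  M <- nrow(ms$markers)
  chi2 <- df <- p <- n <- numeric(M)
  for (m in seq_len(M)) {
    sc <- seg_classes(ms$markers$p1[m], ms$markers$p2[m], ms$markers$seg_type[m])
    obs <- table(factor(ms$geno[m, ], levels = sc$classes))
    n[m] <- sum(obs)
    if (n[m] == 0) { chi2[m] <- NA; df[m] <- length(sc$classes) - 1L; p[m] <- NA; next }
    e <- sc$probs * n[m]
    chi2[m] <- sum((as.numeric(obs) - e)^2 / e)
    df[m] <- length(sc$classes) - 1L
    p[m] <- stats::pchisq(chi2[m], df[m], lower.tail = FALSE)
  }
  data.frame(marker_id = ms$markers$marker_id, n_called = n,
             chi2 = chi2, df = df, p = p, stringsAsFactors = FALSE)
}

#' Drop markers with distorted segregation
#'
#' @param ms a `marker_set`.
#' @param config a [qc_config()]; markers with `p < seg_p_threshold`, too few
#'   called offspring, or no called offspring are dropped.
#' @return the filtered `marker_set`; attribute `"removed"` counts by reason.
#' @export
filter_segregation <- function(ms, config = qc_config()) {
  st <- segregation_test(ms)
  too_few <- st$n_called < config$min_seg_offspring
  distorted <- !too_few & !is.na(st$p) & st$p < config$seg_p_threshold
  out <- ms[!(too_few | distorted)]
  attr(out, "removed") <- c(distorted = sum(distorted), too_few = sum(too_few))
  attr(out, "segregation") <- st
  out
}

#' Run the full genotype QC cascade
#'
#' Stages in order: call replacement (depth and allele balance), marker call
#' rate, parental/Mendelian consistency, segregation test. Per-stage marker
#' and call accounting is returned alongside the mapping-ready markers.
#'
#' @param vt a [variant_table] (e.g. from [read_vcf()]).
#' @param parents the two parent sample names.
#' @param config a [qc_config()].
#' @return list of class `qc_result`: `markers` (a `marker_set`) and `report`
#'   (data frame of per-stage input/output marker counts and call
#'   replacements).
#' @export
run_qc_cascade <- function(vt, parents = vt$parents, config = qc_config()) {
  n0 <- nrow(vt$sites)
  vt1 <- apply_call_filters(vt, config)
  rep1 <- attr(vt1, "replacements")
  vt2 <- filter_call_rate(vt1, config$min_call_rate)
  ms <- filter_parental(vt2, parents)
  rem3 <- attr(ms, "removed")
  ms2 <- filter_segregation(ms, config)
  rem4 <- attr(ms2, "removed")
  report <- data.frame(
    stage = c("call_replacement", "call_rate", "parental_mendelian", "segregation"),
    n_in = c(n0, n0, nrow(vt2$sites), nrow(ms$markers)),
    n_out = c(n0, nrow(vt2$sites), nrow(ms$markers), nrow(ms2$markers)),
    calls_replaced = c(sum(rep1), 0L, 0L, 0L),
    detail = c(paste(names(rep1), rep1, sep = "=", collapse = ";"),
               paste0("low_call_rate=", attr(vt2, "removed")),
               paste(names(rem3), rem3, sep = "=", collapse = ";"),
               paste(names(rem4), rem4, sep = "=", collapse = ";")),
    stringsAsFactors = FALSE)
  structure(list(markers = ms2, report = report,
                 segregation = attr(ms2, "segregation"), config = config),
            class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat("Genotype QC cascade\n")
  print(x$report, row.names = FALSE)
  invisible(x)
}
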