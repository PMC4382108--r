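#' Multi-sample variant table
#'
#' The in-memory form of one multi-sample VCF: a per-site data frame plus
#' per-sample genotype (`GT`, allele-index strings such as `"0/1"`, `NA` for
#' no-call), allele-depth (`AD`, comma strings) and depth (`DP`) matrices.
#' Constructed by [read_vcf()] or [sample_observed_calls()].
#'
#' @param sites data frame with columns `contig_id`, `position`, `marker_id`,
#'   `ref`, `alt` (comma-separated), `qual`, `combined_depth`.
#' @param gt,ad character matrices (sites x samples); `dp` numeric matrix.
#' @param samples sample names in VCF column order (parents first by default).
#' @param parents names of the two parent samples.
#' @return an object of class `variant_table`.
#' @keywords internal
variant_table <- function(sites, gt, ad, dp, samples, parents = samples[1:2]) {
  am_check(all(c("contig_id", "position", "marker_id", "ref", "alt",
                 "qual", "combined_depth") %in% names(sites)),
           "sites is missing required columns")
  am_check(all(sites$position >= 1), "positions must be >= 1")
  am_check(nrow(gt) == nrow(sites) && ncol(gt) == length(samples),
           "genotype matrix does not match sites/samples")
  am_check(all(parents %in% samples), "parents must be among the samples")
  structure(list(sites = sites, gt = gt, ad = ad, dp = dp,
                 samples = samples, parents = parents),
            class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("variant_table: %d sites x %d samples (parents: %s)\n",
              nrow(x$sites), length(x$samples), paste(x$parents, collapse = ", ")))
  invisible(x)
}

#' @export
dim.variant_table <- function(x) c(nrow(x$sites), length(x$samples))

# subset sites
subset_sites <- function(vt, keep) {
  vt$sites <- vt$sites[keep, , drop = FALSE]
  rownames(vt$sites) <- NULL
  vt$gt <- vt$gt[keep, , drop = FALSE]
  vt$ad <- vt$ad[keep, , drop = FALSE]
  vt$dp <- vt$dp[keep, , drop = FALSE]
  vt
}

#' Read a multi-sample VCF
#'
#' Parses a VCF 4.x file with per-sample `GT` (and optionally `AD`, `DP`)
#' into a [variant_table]. Sample order is preserved; `"./."` genotypes become
#' `NA`; a missing `AD` field yields an `NA` allele-depth entry, which the
#' depth-based call filters treat as a no-call for heterozygous calls.
#' Malformed headers or records are rejected with an error naming the line.
#'
#' @param path path to an uncompressed VCF file.
#' @param parents character vector of length 2 naming the parent samples;
#'   defaults to the first two sample columns.
#' @return a [variant_table].
#' @export
read_vcf <- function(path, parents = NULL) {
  am_check(file.exists(path), sprintf("file not found: %s", path))
  lines <- readLines(path)
  hdr <- grep("^#CHROM\t", lines)
  if (length(hdr) != 1L)
    am_stop(sprintf("%s: malformed VCF, expected exactly one #CHROM header line", path),
            class = "anchormap_parse_error")
  nfield <- length(strsplit(lines[hdr], "\t", fixed = TRUE)[[1]])
  am_check(nfield >= 10L, "VCF has no sample columns")
  body <- which(!startsWith(lines, "#"))
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  bad <- body[nf != nfield]
  if (length(bad))
    am_stop(sprintf("%s: malformed VCF record at line %d (%d fields, expected %d)",
                    path, bad[1L], nf[which(nf != nfield)[1L]], nfield),
            class = "anchormap_parse_error")

  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  samples <- colnames(v@gt)[-1L]
  gt <- vcfR::extract.gt(v, element = "GT")
  has_ad <- any(grepl("AD", v@gt[, "FORMAT"], fixed = TRUE))
  ad <- if (has_ad) vcfR::extract.gt(v, element = "AD") else
    matrix(NA_character_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  has_dp <- any(grepl("DP", v@gt[, "FORMAT"], fixed = TRUE))
  dp <- if (has_dp) {
    suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  } else {
    # fall back to summed allele depths
    matrix(vapply(strsplit(ad, ",", fixed = TRUE),
                  function(z) sum(suppressWarnings(as.numeric(z))), numeric(1)),
           nrow(gt), ncol(gt), dimnames = dimnames(gt))
  }
  gt[gt %in% c("./.", ".", ".|.")] <- NA_character_
  gt <- gsub("|", "/", gt, fixed = TRUE)

  info_dp <- suppressWarnings(as.numeric(sub(".*DP=([0-9.]+).*", "\\1", fix$INFO)))
  no_dp <- !grepl("DP=", fix$INFO %||% "")
  if (any(no_dp)) info_dp[no_dp] <- rowSums(dp[no_dp, , drop = FALSE], na.rm = TRUE)

  sites <- data.frame(contig_id = fix$CHROM,
                      position = as.integer(fix$POS),
                      marker_id = ifelse(is.na(fix$ID) | fix$ID == ".",
                                         paste(fix$CHROM, fix$POS, sep = "_"), fix$ID),
                      ref = fix$REF,
                      alt = fix$ALT,
                      qual = suppressWarnings(as.numeric(fix$QUAL)),
                      combined_depth = info_dp,
                      stringsAsFactors = FALSE)
  am_check(all(nzchar(sites$alt) & sites$alt != "."),
           "every site must have at least one alt allele")
  rownames(gt) <- rownames(ad) <- rownames(dp) <- sites$marker_id
  variant_table(sites, gt, ad, dp, samples,
                parents = parents %||% samples[1:2])
}

# Write a variant_table as plain-text VCF 4.2 (GT:AD:DP). Used by fixtures;
# the reader/writer pair round-trips exactly.
write_vcf_file <- function(vt, path) {
  n <- nrow(vt$sites)
  fmt <- character(n * length(vt$samples))
  gtv <- ifelse(is.na(vt$gt), "./.", vt$gt)
  adv <- ifelse(is.na(vt$ad), ".", vt$ad)
  dpv <- ifelse(is.na(vt$dp), ".", as.character(vt$dp))
  cells <- matrix(paste(gtv, adv, dpv, sep = ":"), n, length(vt$samples))
  recs <- paste(vt$sites$contig_id, vt$sites$position, vt$sites$marker_id,
                vt$sites$ref, vt$sites$alt,
                ifelse(is.na(vt$sites$qual), ".", as.character(vt$sites$qual)),
                "PASS", paste0("DP=", vt$sites$combined_depth), "GT:AD:DP",
                apply(cells, 1L, paste, collapse = "\t"), sep = "\t")
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele read depths\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Combined depth\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", vt$samples), collapse = "\t"))
  writeLines(c(hdr, recs), path)
  invisible(path)
}

# allele letters of a call: gt index string + site ref/alt -> c("A","G") or NA
gt_to_alleles <- function(gt, ref, alt) {
  alleles <- c(ref, strsplit(alt, ",", fixed = TRUE)[[1]])
  if (is.na(gt)) return(c(NA_character_, NA_character_))
  idx <- as.integer(strsplit(gt, "/", fixed = TRUE)[[1]]) + 1L
  alleles[idx]
}
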