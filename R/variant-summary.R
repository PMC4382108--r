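#' Site-level QC for RNA-seq variant calls
#'
#' Retains sites with call quality at least `min_quality` AND combined-sample
#' read depth at least `min_combined_depth` (a site failing either criterion
#' is excluded — the standard QC intent for joint quality/depth thresholds).
#' Sites missing either quantity are excluded and counted separately.
#'
#' @param sites a [variant_table] or a data frame with columns `qual` and
#'   `combined_depth`.
#' @param min_quality phred-scaled quality threshold (default 40, inclusive).
#' @param min_combined_depth combined read-depth threshold (default 60,
#'   inclusive).
#' @return the filtered object, with an attribute `"removed"` giving counts
#'   of sites removed for low quality, low depth, or missing values.
#' @export
filter_rnaseq_sites <- function(sites, min_quality = 40, min_combined_depth = 60) {
  df <- if (inherits(sites, "variant_table")) sites$sites else sites
  am_check(all(c("qual", "combined_depth") %in% names(df)),
           "sites must carry 'qual' and 'combined_depth'")
  missing <- is.na(df$qual) | is.na(df$combined_depth)
  lowq <- !missing & df$qual < min_quality
  lowd <- !missing & df$combined_depth < min_combined_depth
  keep <- !missing & !lowq & !lowd
  out <- if (inherits(sites, "variant_table")) subset_sites(sites, keep)
         else df[keep, , drop = FALSE]
  attr(out, "removed") <- c(low_quality = sum(lowq), low_depth = sum(lowd),
                            missing = sum(missing))
  out
}

# strip bases shared by ref and all alts from the right, then the left
normalize_alleles <- function(ref, alts) {
  all_al <- c(ref, alts)
  am_check(all(nzchar(all_al)), "empty allele")
  while (all(nchar(all_al) > 1L) &&
         length(unique(substring(all_al, nchar(all_al), nchar(all_al)))) == 1L) {
    all_al <- substring(all_al, 1L, nchar(all_al) - 1L)
  }
  while (all(nchar(all_al) > 1L) &&
         length(unique(substring(all_al, 1L, 1L))) == 1L) {
    all_al <- substring(all_al, 2L)
  }
  list(ref = all_al[1L], alts = all_al[-1L])
}

#' Classify a variant site by its ref and alt alleles
#'
#' After stripping flanking bases shared by all alleles: a site whose alleles
#' are all single bases is a `snp`; all alts shorter than the ref give a
#' `deletion`, all longer an `insertion`; a mixture of forms (or multi-base
#' substitutions) is `complex`. A bi-allelic SNP is labelled a transition when
#' the allele pair is `{A,G}` or `{C,T}` and a transversion otherwise;
#' multi-allelic SNPs get substitution `"none"`, so transitions plus
#' transversions always equal the bi-allelic SNP count.
#'
#' @param ref reference allele (non-empty string).
#' @param alts character vector of alternate alleles (or one comma-separated
#'   string).
#' @return a list with `kind` (`snp`/`deletion`/`insertion`/`complex`),
#'   `allele_count` (number of distinct alt alleles) and `substitution`
#'   (`transition`/`transversion`/`none`).
#' @examples
#' classify_variant("A", "G")          # snp, transition
#' classify_variant("A", c("C", "T"))  # tri-allelic snp, substitution none
#' @export
classify_variant <- function(ref, alts) {
  if (length(alts) == 1L && grepl(",", alts, fixed = TRUE))
    alts <- strsplit(alts, ",", fixed = TRUE)[[1]]
  am_check(length(alts) >= 1L && nzchar(ref) && all(nzchar(alts)),
           "ref and alts must be non-empty")
  am_check(!ref %in% alts && !anyDuplicated(alts),
           "alt alleles must be distinct from ref and from each other")
  nz <- normalize_alleles(ref, alts)
  nr <- nchar(nz$ref); na <- nchar(nz$alts)
  form <- ifelse(nr == 1L & na == 1L, "sub",
          ifelse(na < nr & nr >= 1L & na >= 1L, "del",
          ifelse(na > nr, "ins", "mnp")))
  kind <- if (all(form == "sub")) "snp"
          else if (all(form == "del")) "deletion"
          else if (all(form == "ins")) "insertion"
          else "complex"
  subst <- "none"
  if (kind == "snp" && length(alts) == 1L) {
    pair <- sort(c(nz$ref, nz$alts))
    subst <- if (identical(pair, c("A", "G")) || identical(pair, c("C", "T")))
      "transition" else "transversion"
  }
  list(kind = kind, allele_count = length(alts), substitution = subst)
}

#' Summarize variant classifications over a set of sites
#'
#' Applies [classify_variant()] to every site and tallies counts per kind,
#' multi-allelic SNP counts, and the transition/transversion split (tallied
#' for bi-allelic SNPs only, so `transitions + transversions` equals the
#' bi-allelic SNP count).
#'
#' @param sites a [variant_table] or data frame with `ref` and `alt` columns.
#' @return a list of class `variant_summary` with fields `total_variants`,
#'   `by_kind`, `tri_allelic`, `quad_allelic`, `transitions`, `transversions`.
#' @export
summarize_variants <- function(sites) {
  df <- if (inherits(sites, "variant_table")) sites$sites else sites
  cls <- lapply(seq_len(nrow(df)), function(i) classify_variant(df$ref[i], df$alt[i]))
  kind <- vapply(cls, `[[`, character(1), "kind")
  nalt <- vapply(cls, `[[`, integer(1), "allele_count")
  subst <- vapply(cls, `[[`, character(1), "substitution")
  by_kind <- c(snp = sum(kind == "snp"), deletion = sum(kind == "deletion"),
               insertion = sum(kind == "insertion"), complex = sum(kind == "complex"))
  out <- list(total_variants = nrow(df),
              by_kind = by_kind,
              tri_allelic = sum(kind == "snp" & nalt == 2L),
              quad_allelic = sum(kind == "snp" & nalt == 3L),
              transitions = sum(subst == "transition"),
              transversions = sum(subst == "transversion"))
  stopifnot(sum(by_kind) == out$total_variants,
            out$transitions + out$transversions ==
              sum(kind == "snp" & nalt == 1L))
  class(out) <- "variant_summary"
  out
}

#' @export
print.variant_summary <- function(x, ...) {
  cat(sprintf("%d variants: %d SNPs (%d tri-, %d quad-allelic), %d deletions, %d insertions, %d complex\n",
              x$total_variants, x$by_kind[["snp"]], x$tri_allelic, x$quad_allelic,
              x$by_kind[["deletion"]], x$by_kind[["insertion"]], x$by_kind[["complex"]]))
  bi <- x$transitions + x$transversions
  if (bi > 0)
    cat(sprintf("  transitions %d (%.0f%%), transversions %d (%.0f%%) of %d bi-allelic SNPs\n",
                x$transitions, 100 * x$transitions / bi,
                x$transversions, 100 * x$transversions / bi, bi))
  invisible(x)
}

gene_granges <- function(genes) {
  GenomicRanges::GRanges(genes$contig_id,
                         IRanges::IRanges(genes$start, genes$end),
                         strand = genes$strand)
}

#' Reconcile two gene-annotation sets (intersection and union)
#'
#' Two independent prediction pipelines rarely agree exactly; the intersect
#' set keeps the genes of `set_a` that have a same-location partner in
#' `set_b` (same contig, same strand, any overlap of at least `min_overlap`
#' bp), represented by the `set_a` model. The union set is `set_a` plus the
#' `set_b` genes with no same-location partner in `set_a`.
#'
#' @param set_a,set_b gene model data frames (see [read_gene_models()]);
#'   `set_a` plays the role of the preferred pipeline.
#' @param min_overlap minimum overlap in bp to call two genes the same
#'   location (default 1).
#' @return list with elements `intersect` and `union` (gene model data
#'   frames).
#' @export
merge_gene_sets <- function(set_a, set_b, min_overlap = 1L) {
  am_check(!anyDuplicated(set_a$gene_id), "duplicate gene_ids in set_a")
  am_check(!anyDuplicated(set_b$gene_id), "duplicate gene_ids in set_b")
  ga <- gene_granges(set_a); gb <- gene_granges(set_b)
  # sets predicted on disjoint contig universes legitimately share no
  # sequence levels; that is an empty intersect, not a problem
  hits_a <- suppressWarnings(
    GenomicRanges::countOverlaps(ga, gb, minoverlap = min_overlap,
                                 ignore.strand = FALSE) > 0)
  hits_b <- suppressWarnings(
    GenomicRanges::countOverlaps(gb, ga, minoverlap = min_overlap,
                                 ignore.strand = FALSE) > 0)
  list(intersect = set_a[hits_a, , drop = FALSE],
       union = rbind(set_a, set_b[!hits_b, , drop = FALSE]))
}

#' Count variants inside genes and inside 1 kb-extended genes
#'
#' @param variants a [variant_table] or data frame with `contig_id` and
#'   `position`.
#' @param genes gene model data frame.
#' @param flank_bp extension added to each side of every gene (default 1000);
#'   the extension is clipped at position 1.
#' @return named integer vector `c(inside, inside_extended, outside)`.
#' @export
variants_in_genes <- function(variants, genes, flank_bp = 1000L) {
  df <- if (inherits(variants, "variant_table")) variants$sites else variants
  unknown <- !df$contig_id %in% genes$contig_id
  if (any(unknown))
    warning(sprintf("%d variants on contigs absent from the gene set; counted outside",
                    sum(unknown)))
  vr <- GenomicRanges::GRanges(df$contig_id,
                               IRanges::IRanges(df$position, df$position))
  gg <- gene_granges(genes)
  ext <- GenomicRanges::GRanges(genes$contig_id,
                                IRanges::IRanges(pmax(1L, genes$start - flank_bp),
                                                 genes$end + flank_bp),
                                strand = genes$strand)
  inside <- sum(suppressWarnings(
    GenomicRanges::countOverlaps(vr, gg, ignore.strand = TRUE)) > 0)
  inside_ext <- sum(suppressWarnings(
    GenomicRanges::countOverlaps(vr, ext, ignore.strand = TRUE)) > 0)
  c(inside = inside, inside_extended = inside_ext,
    outside = nrow(df) - inside_ext)
}
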