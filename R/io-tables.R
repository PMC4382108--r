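#' Read a scaffold-membership table
#'
#' Tab-separated, AGP-like: columns `scaffold_id`, `contig_id`, `order_index`,
#' `contig_length_bp`. Each contig must belong to exactly one scaffold and
#' order indices must be contiguous from 1 within each scaffold.
#'
#' @param path path to the TSV file.
#' @return a data frame.
#' @export
read_scaffold_map <- function(path) {
  am_check(file.exists(path), sprintf("file not found: %s", path))
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("scaffold_id", "contig_id", "order_index", "contig_length_bp")
  am_check(all(need %in% names(d)),
           sprintf("scaffold map must have columns %s", paste(need, collapse = ", ")),
           class = "anchormap_parse_error")
  am_check(!anyDuplicated(d$contig_id),
           "each contig must belong to exactly one scaffold",
           class = "anchormap_parse_error")
  ok <- vapply(split(d$order_index, d$scaffold_id),
               function(o) identical(sort(as.integer(o)), seq_along(o)), logical(1))
  am_check(all(ok), "order indices must be contiguous from 1 within each scaffold",
           class = "anchormap_parse_error")
  d[need]
}

#' Read a reference (microsatellite) map table
#'
#' Tab-separated with columns `marker_id`, `contig_id`, `linkage_group`,
#' `position_cm`. Positions must be non-negative and group labels non-empty.
#'
#' @param path path to the TSV file.
#' @return a data frame.
#' @export
read_reference_map <- function(path) {
  am_check(file.exists(path), sprintf("file not found: %s", path))
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("marker_id", "contig_id", "linkage_group", "position_cm")
  am_check(all(need %in% names(d)),
           sprintf("reference map must have columns %s", paste(need, collapse = ", ")),
           class = "anchormap_parse_error")
  am_check(all(is.finite(d$position_cm)) && all(d$position_cm >= 0),
           "reference positions must be non-negative", class = "anchormap_parse_error")
  am_check(all(nzchar(d$linkage_group)), "linkage group labels must be non-empty",
           class = "anchormap_parse_error")
  d[need]
}

#' Read blast tabular (outfmt 6) primer hits
#'
#' Expects the standard 12-column dialect (`qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore`), no header.
#' Strand is inferred from the subject coordinate order: `sstart > send`
#' marks a minus-strand hit.
#'
#' @param path path to the tabular blast output.
#' @param primers optional primer table (columns `primer_id`, `pair_id`,
#'   `role`, `length`); when given, primer length, pair and role are joined
#'   on, and query coverage and 3'-end inclusion are computed.
#' @return a data frame of hits with `strand` and, when lengths are known,
#'   `coverage` (aligned query fraction) and `three_prime_covered`.
#' @export
read_blast_tab <- function(path, primers = NULL) {
  am_check(file.exists(path), sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  nf <- lengths(strsplit(lines, "\t", fixed = TRUE))
  if (any(nf != 12L))
    am_stop(sprintf("%s: line %d has %d columns, expected 12 (blast outfmt 6)",
                    path, which(nf != 12L)[1L], nf[nf != 12L][1L]),
            class = "anchormap_parse_error")
  d <- utils::read.delim(text = lines, header = FALSE, stringsAsFactors = FALSE)
  names(d) <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
                "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  d$strand <- ifelse(d$sstart <= d$send, "+", "-")
  if (!is.null(primers)) {
    i <- match(d$qseqid, primers$primer_id)
    am_check(!anyNA(i), "blast query ids missing from the primer table")
    d$pair_id <- primers$pair_id[i]
    d$role <- primers$role[i]
    d$primer_length <- primers$length[i]
    am_check(all(d$qend <= d$primer_length & d$qstart >= 1),
             "query coordinates exceed primer length")
    d$coverage <- (d$qend - d$qstart + 1) / d$primer_length
    # "one or both of the 3' terminal bases": final or penultimate base aligned
    d$three_prime_covered <- d$qend >= d$primer_length - 1L
  }
  d
}

#' Read gene models from a GFF3 annotation file
#'
#' Imports `gene`-type features via rtracklayer and returns the flat gene
#' model table used by the gene-set reconciliation and variant-overlap
#' operations.
#'
#' @param path path to a GFF3 file.
#' @param source label for the predicting pipeline (e.g. `"A"` or `"B"`).
#' @return data frame with columns `gene_id`, `contig_id`, `start`, `end`,
#'   `strand`, `source`.
#' @export
read_gene_models <- function(path, source = "A") {
  am_check(file.exists(path), sprintf("file not found: %s", path))
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  ids <- gr$ID %||% gr$Name
  if (is.null(ids) || anyNA(ids)) ids <- paste0(source, "_gene_", seq_along(gr))
  data.frame(gene_id = as.character(ids),
             contig_id = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             source = source,
             stringsAsFactors = FALSE)
}

#' Read a per-linkage-group map summary table
#'
#' Tab-separated with columns `linkage_group`, `snps`, `positions`
#' (non-redundant marker positions) and `length_cm`. The package ships the
#' published rubber tree capture-map summary as
#' `system.file("extdata", "rubber_lg_summary.tsv", package = "anchormap")`.
#'
#' @param path path to the TSV file.
#' @return a data frame.
#' @export
read_lg_summary <- function(path) {
  am_check(file.exists(path), sprintf("file not found: %s", path))
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("linkage_group", "snps", "positions", "length_cm")
  am_check(all(need %in% names(d)),
           sprintf("summary must have columns %s", paste(need, collapse = ", ")),
           class = "anchormap_parse_error")
  d[need]
}
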