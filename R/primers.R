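#' Basic per-primer blast hit filter
#'
#' A hit passes when its aligned query interval includes one or both of the
#' primer's two 3'-terminal bases and covers at least `min_coverage` of the
#' primer length. Both rules act on the aligned query span, so gaps in the
#' alignment are not counted as covered primer sequence.
#'
#' @param hits blast hit data frame carrying `qstart`, `qend` and
#'   `primer_length` (see [read_blast_tab()] with a primer table).
#' @param min_coverage minimum aligned fraction of the primer (default 0.8).
#' @param three_prime_window how many terminal bases satisfy the 3' rule
#'   (default 2: the final or penultimate base).
#' @return logical vector, one element per hit.
#' @export
filter_hit_basic <- function(hits, min_coverage = 0.8, three_prime_window = 2L) {
  am_check(all(c("qstart", "qend", "primer_length") %in% names(hits)),
           "hits must carry qstart, qend and primer_length")
  am_check(all(hits$qstart >= 1 & hits$qend <= hits$primer_length),
           "query coordinates exceed primer length")
  covered3 <- hits$qend >= hits$primer_length - (three_prime_window - 1L)
  coverage <- (hits$qend - hits$qstart + 1) >= min_coverage * hits$primer_length
  covered3 & coverage
}

# enumerate convergent products for one pair's basic-passing hits
.pair_products <- function(fh, rh, max_product) {
  prods <- list()
  shared <- intersect(fh$sseqid, rh$sseqid)
  for (cid in shared) {
    f <- fh[fh$sseqid == cid, , drop = FALSE]
    r <- rh[rh$sseqid == cid, , drop = FALSE]
    for (i in seq_len(nrow(f))) for (j in seq_len(nrow(r))) {
      h1 <- f[i, ]; h2 <- r[j, ]
      if (h1$strand == h2$strand) next
      plus <- if (h1$strand == "+") h1 else h2
      minus <- if (h1$strand == "+") h2 else h1
      # 3' ends facing inward: plus-strand 3' end upstream of minus-strand 3' end
      if (plus$send > minus$send) next
      len <- max(minus$sstart, minus$send) - min(plus$sstart, plus$send) + 1
      if (len > 0 && len <= max_product)
        prods[[length(prods) + 1L]] <- data.frame(contig_id = cid,
                                                  product_length = len,
                                                  stringsAsFactors = FALSE)
    }
  }
  if (length(prods)) do.call(rbind, prods) else NULL
}

#' Place a primer pair whose hits share a contig
#'
#' Enumerates convergently oriented hit pairs (primers on opposite strands,
#' 3' ends facing inward) on every shared contig and accepts the pair only
#' when exactly one product of at most `max_product` bp exists genome-wide.
#' Product length runs between the outermost subject coordinates, inclusive
#' (the e-PCR convention).
#'
#' @param pair_hits basic-passing hits of one pair (must carry `role`).
#' @param max_product maximum product size in bp (default 500).
#' @return one-row placement data frame: `pair_id`, `mode`, `contig_id`,
#'   `product_length`, `status` (`placed` or `rejected:<reason>`).
#' @export
place_same_contig <- function(pair_hits, max_product = 500) {
  pid <- pair_hits$pair_id[1L]
  fh <- pair_hits[pair_hits$role == "forward", , drop = FALSE]
  rh <- pair_hits[pair_hits$role == "reverse", , drop = FALSE]
  prods <- .pair_products(fh, rh, max_product)
  if (is.null(prods))
    return(data.frame(pair_id = pid, mode = "same_contig",
                      contig_id = NA_character_, product_length = NA_real_,
                      status = "rejected:no_product", stringsAsFactors = FALSE))
  if (nrow(prods) > 1L)
    return(data.frame(pair_id = pid, mode = "same_contig",
                      contig_id = NA_character_, product_length = NA_real_,
                      status = "rejected:not_unique", stringsAsFactors = FALSE))
  data.frame(pair_id = pid, mode = "same_contig", contig_id = prods$contig_id,
             product_length = prods$product_length, status = "placed",
             stringsAsFactors = FALSE)
}

#' Place a primer pair spanning two contigs
#'
#' For pairs whose forward and reverse primers hit different contigs —
#' candidate evidence that the two contigs are adjacent — a placement
#' requires, for each primer, a perfect-identity (100%) match over at least
#' `min_coverage` of the primer length, lying entirely within `end_window`
#' bp of its contig's start or end, and exactly one such qualifying hit per
#' primer; pairs with multiple qualifying hits are excluded.
#'
#' @param pair_hits all hits of one pair (any identity), with `role`.
#' @param contig_lengths named numeric vector of contig lengths in bp.
#' @param end_window distance window from a contig end in bp (default 300).
#' @param min_coverage minimum perfect-match fraction (default 0.7).
#' @return one-row placement data frame with `contig_id` as
#'   `"<fwd>|<rev>"` when placed.
#' @export
place_cross_contig <- function(pair_hits, contig_lengths, end_window = 300,
                               min_coverage = 0.7) {
  pid <- pair_hits$pair_id[1L]
  reject <- function(reason) data.frame(
    pair_id = pid, mode = "cross_contig", contig_id = NA_character_,
    product_length = NA_real_, status = paste0("rejected:", reason),
    stringsAsFactors = FALSE)
  qual <- function(h) {
    L <- contig_lengths[h$sseqid]
    if (anyNA(L)) return(NULL)
    lo <- pmin(h$sstart, h$send); hi <- pmax(h$sstart, h$send)
    near <- hi <= end_window | lo >= L - end_window + 1
    h[h$pident == 100 & h$length >= min_coverage * h$primer_length & near, ,
      drop = FALSE]
  }
  fh <- pair_hits[pair_hits$role == "forward", , drop = FALSE]
  rh <- pair_hits[pair_hits$role == "reverse", , drop = FALSE]
  if (!all(c(fh$sseqid, rh$sseqid) %in% names(contig_lengths)))
    return(reject("no_length"))
  fq <- qual(fh); rq <- qual(rh)
  if (is.null(fq) || is.null(rq) || nrow(fq) == 0L || nrow(rq) == 0L)
    return(reject("no_qualifying_hit"))
  if (nrow(fq) > 1L || nrow(rq) > 1L) return(reject("multiple_hits"))
  if (fq$sseqid == rq$sseqid) return(reject("same_contig"))
  data.frame(pair_id = pid, mode = "cross_contig",
             contig_id = paste(fq$sseqid, rq$sseqid, sep = "|"),
             product_length = NA_real_, status = "placed",
             stringsAsFactors = FALSE)
}

#' Place all primer pairs
#'
#' Applies the per-primer basic filter, then routes each pair: pairs whose
#' forward and reverse basic-passing hits share a contig go through the
#' same-contig product rules; pairs hitting only different contigs go
#' through the cross-contig end rules.
#'
#' @param hits blast hits joined to the primer table
#'   (see [read_blast_tab()]).
#' @param contig_lengths named numeric vector of contig lengths.
#' @param max_product,end_window,cross_min_coverage,min_coverage,three_prime_window
#'   rule thresholds (see [place_same_contig()], [place_cross_contig()],
#'   [filter_hit_basic()]).
#' @return placement data frame, one row per pair.
#' @export
place_primer_pairs <- function(hits, contig_lengths, max_product = 500,
                               end_window = 300, min_coverage = 0.8,
                               cross_min_coverage = 0.7,
                               three_prime_window = 2L) {
  am_check(all(c("pair_id", "role") %in% names(hits)),
           "hits must be joined to the primer table (pair_id, role)")
  basic <- filter_hit_basic(hits, min_coverage, three_prime_window)
  out <- lapply(split(seq_len(nrow(hits)), hits$pair_id), function(idx) {
    ph <- hits[idx, , drop = FALSE]
    bh <- ph[basic[idx], , drop = FALSE]
    fshared <- intersect(bh$sseqid[bh$role == "forward"],
                         bh$sseqid[bh$role == "reverse"])
    if (length(fshared)) place_same_contig(bh, max_product)
    else place_cross_contig(ph, contig_lengths, end_window, cross_min_coverage)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
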