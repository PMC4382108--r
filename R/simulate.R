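#' Simulate an outbred F1 cross with assembly structure
#'
#' Generates the ground truth for a two-parent cross: marker layout on
#' chromosomes, assignment of markers to contigs and contigs to scaffolds,
#' phased parental genotypes for a mix of pseudo-testcross segregation types,
#' and offspring gametes produced by independent maternal and paternal meioses
#' under a no-interference (Poisson) crossover process, so that the
#' recombinant-gamete probability between loci `d` cM apart is the Haldane
#' value `(1 - exp(-2d/100))/2` and loci on different chromosomes segregate
#' independently.
#'
#' Artifacts are planted and logged in the truth registry: segregation-
#' distorted loci (each heterozygous parent transmits its favoured allele —
#' the lexicographically first of its pair — with probability
#' `distortion_skew` at that locus) and repeat-duplicated
#' contigs (a proper subset of a contig's markers is relocated to a second
#' true map position, half the time on the same chromosome at least 30 cM
#' away, half the time on a different chromosome).
#'
#' @param config a [sim_config()] object.
#' @return an object of class `f1_truth` with components:
#'   \describe{
#'     \item{markers}{data frame of per-marker truth: ids, contig/scaffold,
#'       bp and true chromosome/cM position, segregation type, parental
#'       genotypes and haplotype phases, distortion/relocation flags.}
#'     \item{geno}{character matrix (markers x offspring) of true offspring
#'       genotypes, e.g. `"A/G"`.}
#'     \item{gametes}{list of two integer matrices (`h1`, `h2`) giving the
#'       transmitted haplotype (1 or 2) per marker and meiosis for each parent.}
#'     \item{scaffolds}{scaffold membership table (AGP-like).}
#'     \item{reference_map}{microsatellite-style reference map for a subset of
#'       contigs plus SNP-less reference-anchored scaffolds.}
#'     \item{primers, primer_hits, primer_truth}{synthetic primer pairs, their
#'       blast-style hits against the contigs, and the planted expected
#'       placement for each pair.}
#'     \item{artifacts}{registry of planted artifacts.}
#'     \item{config}{the configuration used.}
#'   }
#' @seealso [sample_observed_calls()], [write_fixture()]
#' @export
simulate_cross <- function(config = sim_config()) {
  am_check(inherits(config, "sim_config"), "'config' must be a sim_config object")
  set.seed(config$seed)
  nchr <- config$n_chromosomes
  noff <- config$n_offspring
  mper <- config$markers_per_chromosome
  cm_per_kb <- 0.002  # ~500 kb per cM, typical of a large plant genome

  ## ---- marker / contig / scaffold layout -------------------------------
  rows <- list()
  contig_no <- 0L
  for (ch in seq_len(nchr)) {
    left <- mper
    while (left > 0L) {
      contig_no <- contig_no + 1L
      k <- min(left, sample(1:5, 1L, prob = c(0.15, 0.25, 0.30, 0.20, 0.10)))
      len_bp <- round(stats::runif(1, 5000, 50000))
      bp <- sort(sample(seq(100L, len_bp - 100L), k))
      start_cm <- stats::runif(1, 0, config$chrom_length)
      rows[[length(rows) + 1L]] <- data.frame(
        contig_id = sprintf("CTG%05d", contig_no),
        contig_len = len_bp,
        pos_bp = bp,
        true_chrom = ch,
        true_cm = pmin(start_cm + (bp - bp[1L]) / 1000 * cm_per_kb,
                       config$chrom_length),
        stringsAsFactors = FALSE)
      left <- left - k
    }
  }
  mk <- do.call(rbind, rows)
  mk$marker_id <- sprintf("SNP%05d", seq_len(nrow(mk)))

  ## contigs -> scaffolds (consecutive contigs on the same chromosome)
  ctg <- unique(mk[, c("contig_id", "contig_len", "true_chrom")])
  scaff_of <- character(nrow(ctg))
  sc_no <- 0L
  i <- 1L
  while (i <= nrow(ctg)) {
    sc_no <- sc_no + 1L
    size <- 1L + stats::rpois(1L, max(config$contigs_per_scaffold - 1, 0))
    j <- i
    while (j <= nrow(ctg) && (j - i + 1L) <= size &&
           ctg$true_chrom[j] == ctg$true_chrom[i]) {
      scaff_of[j] <- sprintf("SCF%04d", sc_no)
      j <- j + 1L
    }
    i <- j
  }
  ctg$scaffold_id <- scaff_of
  mk$scaffold_id <- ctg$scaffold_id[match(mk$contig_id, ctg$contig_id)]

  ## ---- repeat-duplicated contigs ---------------------------------------
  mk$relocated <- FALSE
  eligible <- names(which(table(mk$contig_id) >= 2L))
  ndup <- round(config$repeat_dup_fraction * length(unique(mk$contig_id)))
  dup_contigs <- if (ndup > 0L) sample(eligible, min(ndup, length(eligible))) else character(0)
  artifacts <- list()
  for (cid in dup_contigs) {
    idx <- which(mk$contig_id == cid)
    k <- length(idx)
    nmove <- if (k == 2L) 1L else sample(seq_len(k - 1L), 1L)
    move <- idx[(k - nmove + 1L):k]              # suffix in bp order
    same_chr <- stats::runif(1) < 0.5 && nchr > 1 && config$chrom_length >= 60
    old_chr <- mk$true_chrom[move[1L]]
    old_cm <- mk$true_cm[move[1L]]
    if (same_chr || nchr == 1L) {
      repeat {
        new_cm <- stats::runif(1, 0, config$chrom_length)
        if (abs(new_cm - old_cm) >= min(30, config$chrom_length / 2)) break
      }
      new_chr <- old_chr
    } else {
      new_chr <- sample(setdiff(seq_len(nchr), old_chr), 1L)
      new_cm <- stats::runif(1, 0, config$chrom_length)
    }
    off_bp <- mk$pos_bp[move] - mk$pos_bp[move[1L]]
    mk$true_chrom[move] <- new_chr
    mk$true_cm[move] <- pmin(new_cm + off_bp / 1000 * cm_per_kb, config$chrom_length)
    mk$relocated[move] <- TRUE
    artifacts[[length(artifacts) + 1L]] <- data.frame(
      type = "relocated_marker", id = mk$marker_id[move], sample = NA_character_,
      detail = sprintf("contig %s duplicated: chr%d@%.2f -> chr%d@%.2f",
                       cid, old_chr, old_cm, new_chr, new_cm),
      stringsAsFactors = FALSE)
  }

  ## order markers by true position for the meiosis model
  mk <- mk[order(mk$true_chrom, mk$true_cm, mk$marker_id), ]
  rownames(mk) <- NULL
  M <- nrow(mk)

  ## ---- segregation types and phased parental genotypes -----------------
  bases <- c("A", "C", "G", "T")
  type <- sample(c("lm", "np", "hk", "fi"), M, replace = TRUE,
                 prob = config$cross_type_mix)
  p1h <- matrix(NA_character_, M, 2)   # parent 1 haplotype alleles
  p2h <- matrix(NA_character_, M, 2)
  for (m in seq_len(M)) {
    al <- sample(bases)
    ht <- type[m]
    if (ht == "lm") {                 # ab x aa
      p1 <- al[1:2]; p2 <- c(al[1], al[1])
    } else if (ht == "np") {          # aa x ab
      p1 <- c(al[1], al[1]); p2 <- al[1:2]
    } else if (ht == "hk") {          # ab x ab
      p1 <- al[1:2]; p2 <- al[1:2]
    } else {                          # ab x cd, four distinct alleles
      p1 <- al[1:2]; p2 <- al[3:4]
    }
    # random phase: which allele sits on haplotype 1
    if (stats::runif(1) < 0.5) p1 <- rev(p1)
    if (stats::runif(1) < 0.5) p2 <- rev(p2)
    p1h[m, ] <- p1
    p2h[m, ] <- p2
  }
  mk$seg_type <- type
  mk$p1 <- geno_str(p1h[, 1], p1h[, 2])
  mk$p2 <- geno_str(p2h[, 1], p2h[, 2])
  mk$p1_hap1 <- p1h[, 1]; mk$p1_hap2 <- p1h[, 2]
  mk$p2_hap1 <- p2h[, 1]; mk$p2_hap2 <- p2h[, 2]

  ## ---- distorted loci ---------------------------------------------------
  ndist <- round(config$distorted_fraction * M)
  dist_idx <- if (ndist > 0L) sort(sample(M, ndist)) else integer(0)
  mk$distorted <- seq_len(M) %in% dist_idx
  if (ndist > 0L) {
    artifacts[[length(artifacts) + 1L]] <- data.frame(
      type = "distorted", id = mk$marker_id[dist_idx], sample = NA_character_,
      detail = sprintf("skew %.2f toward haplotype 1", config$distortion_skew),
      stringsAsFactors = FALSE)
  }

  ## ---- meioses ----------------------------------------------------------
  meiosis <- function() {
    h <- matrix(NA_integer_, M, noff)
    for (ch in seq_len(nchr)) {
      idx <- which(mk$true_chrom == ch)
      if (!length(idx)) next
      d <- diff(mk$true_cm[idx])
      r <- haldane_rf(pmax(d, 0))
      h[idx[1L], ] <- sample(1:2, noff, replace = TRUE)
      if (length(idx) > 1L) {
        sw <- matrix(stats::runif((length(idx) - 1L) * noff) <
                       rep(r, noff), length(idx) - 1L, noff)
        for (k in seq_along(idx)[-1L]) {
          h[idx[k], ] <- ifelse(sw[k - 1L, ], 3L - h[idx[k - 1L], ], h[idx[k - 1L], ])
        }
      }
    }
    h
  }
  h1 <- meiosis()
  h2 <- meiosis()

  ## distortion: resample the het parent's transmission at the locus only,
  ## favouring the lexicographically first allele of its pair — so at
  ## shared-allele (ab x ab) loci both parents are skewed toward the same
  ## allele, as locus-level gametic selection would act
  for (m in dist_idx) {
    if (mk$p1_hap1[m] != mk$p1_hap2[m]) {
      fav <- if (mk$p1_hap1[m] < mk$p1_hap2[m]) 1L else 2L
      h1[m, ] <- ifelse(stats::runif(noff) < config$distortion_skew, fav, 3L - fav)
    }
    if (mk$p2_hap1[m] != mk$p2_hap2[m]) {
      fav <- if (mk$p2_hap1[m] < mk$p2_hap2[m]) 1L else 2L
      h2[m, ] <- ifelse(stats::runif(noff) < config$distortion_skew, fav, 3L - fav)
    }
  }

  a1 <- matrix(p1h[cbind(rep(seq_len(M), noff), as.vector(h1))], M, noff)
  a2 <- matrix(p2h[cbind(rep(seq_len(M), noff), as.vector(h2))], M, noff)
  geno <- matrix(geno_str(as.vector(a1), as.vector(a2)), M, noff,
                 dimnames = list(mk$marker_id, sprintf("F1_%03d", seq_len(noff))))

  ## ---- scaffold table (including SNP-less reference scaffolds) ---------
  scaff <- ctg[, c("scaffold_id", "contig_id", "contig_len")]
  names(scaff)[3] <- "contig_length_bp"
  extra <- list()
  if (config$n_snpless_ref_scaffolds > 0L) {
    for (s in seq_len(config$n_snpless_ref_scaffolds)) {
      sc_no <- sc_no + 1L
      nct <- sample(1:3, 1L)
      for (j in seq_len(nct)) {
        contig_no <- contig_no + 1L
        extra[[length(extra) + 1L]] <- data.frame(
          scaffold_id = sprintf("SCF%04d", sc_no),
          contig_id = sprintf("CTG%05d", contig_no),
          contig_length_bp = round(stats::runif(1, 5000, 50000)),
          stringsAsFactors = FALSE)
      }
    }
    scaff <- rbind(scaff, do.call(rbind, extra))
  }
  scaff <- scaff[order(scaff$scaffold_id, scaff$contig_id), ]
  ord <- stats::ave(seq_len(nrow(scaff)), scaff$scaffold_id, FUN = seq_along)
  scaff <- data.frame(scaffold_id = scaff$scaffold_id,
                      contig_id = scaff$contig_id,
                      order_index = as.integer(ord),
                      contig_length_bp = scaff$contig_length_bp,
                      stringsAsFactors = FALSE)
  rownames(scaff) <- NULL

  ## ---- reference (microsatellite-style) map ----------------------------
  ref_rows <- list()
  for (ch in seq_len(nchr)) {
    cand <- unique(mk$contig_id[mk$true_chrom == ch & !mk$relocated])
    pick <- sample(cand, min(3L, length(cand)))
    for (cid in pick) {
      cm <- mk$true_cm[mk$contig_id == cid & mk$true_chrom == ch][1L]
      ref_rows[[length(ref_rows) + 1L]] <- data.frame(
        marker_id = sprintf("SSR_%02d_%s", ch, cid),
        contig_id = cid, linkage_group = sprintf("LG%d", ch),
        position_cm = round(cm, 2), stringsAsFactors = FALSE)
    }
  }
  snpless_scf <- setdiff(unique(scaff$scaffold_id), unique(mk$scaffold_id))
  for (sid in snpless_scf) {
    cid <- scaff$contig_id[scaff$scaffold_id == sid][1L]
    ch <- sample(nchr, 1L)
    ref_rows[[length(ref_rows) + 1L]] <- data.frame(
      marker_id = sprintf("SSR_X_%s", cid),
      contig_id = cid, linkage_group = sprintf("LG%d", ch),
      position_cm = round(stats::runif(1, 0, config$chrom_length), 2),
      stringsAsFactors = FALSE)
  }
  reference_map <- do.call(rbind, ref_rows)

  primers <- simulate_primer_hits(reference_map, scaff)

  truth <- list(markers = mk, geno = geno,
                gametes = list(h1 = h1, h2 = h2),
                scaffolds = scaff, reference_map = reference_map,
                primers = primers$primers, primer_hits = primers$hits,
                primer_truth = primers$truth,
                artifacts = if (length(artifacts)) do.call(rbind, artifacts) else
                  data.frame(type = character(0), id = character(0),
                             sample = character(0), detail = character(0)),
                config = config)
  class(truth) <- "f1_truth"
  truth
}

#' @export
print.f1_truth <- function(x, ...) {
  cat(sprintf("Synthetic F1 cross truth: %d markers on %d chromosomes, %d offspring\n",
              nrow(x$markers), x$config$n_chromosomes, x$config$n_offspring))
  cat(sprintf("  %d contigs in %d scaffolds; %d distorted loci, %d relocated markers\n",
              length(unique(x$markers$contig_id)),
              length(unique(x$scaffolds$scaffold_id)),
              sum(x$markers$distorted), sum(x$markers$relocated)))
  invisible(x)
}

# Synthetic blast hits for the reference-map primer pairs: most pairs get a
# clean same-contig product; every fourth SNP-contig pair is planted as a
# cross-contig case near contig ends; decoy hits violate the coverage or
# 3'-inclusion rules, and a couple of pairs get duplicated products.
simulate_primer_hits <- function(reference_map, scaff) {
  prim <- list(); hits <- list(); tru <- list()
  plen <- 20L
  add_hit <- function(qid, sid, pid, len, mism, qs, qe, ss, se) {
    data.frame(qseqid = qid, sseqid = sid, pident = pid, length = len,
               mismatch = mism, gapopen = 0L, qstart = qs, qend = qe,
               sstart = ss, send = se, evalue = 1e-20, bitscore = 40,
               stringsAsFactors = FALSE)
  }
  clen <- stats::setNames(scaff$contig_length_bp, scaff$contig_id)
  for (i in seq_len(nrow(reference_map))) {
    pair <- reference_map$marker_id[i]
    cid <- reference_map$contig_id[i]
    fwd <- paste0(pair, "_F"); rev <- paste0(pair, "_R")
    prim[[length(prim) + 1L]] <- data.frame(
      primer_id = c(fwd, rev), pair_id = pair, role = c("forward", "reverse"),
      length = plen, stringsAsFactors = FALSE)
    L <- clen[[cid]]
    sc_members <- scaff$contig_id[scaff$scaffold_id ==
                                    scaff$scaffold_id[scaff$contig_id == cid][1L]]
    cross <- (i %% 4L == 0L) && length(sc_members) >= 2L
    if (!cross) {
      s0 <- sample(seq(10L, max(11L, L - 520L)), 1L)
      prod <- sample(120:480, 1L)
      hits[[length(hits) + 1L]] <- add_hit(fwd, cid, 100, plen, 0L, 1L, plen,
                                           s0, s0 + plen - 1L)
      hits[[length(hits) + 1L]] <- add_hit(rev, cid, 100, plen, 0L, 1L, plen,
                                           s0 + prod - 1L, s0 + prod - plen)
      tru[[length(tru) + 1L]] <- data.frame(pair_id = pair, expected = "same_contig",
                                            stringsAsFactors = FALSE)
    } else {
      mate <- setdiff(sc_members, cid)[1L]
      L2 <- clen[[mate]]
      hits[[length(hits) + 1L]] <- add_hit(fwd, cid, 100, plen, 0L, 1L, plen,
                                           L - 250L, L - 250L + plen - 1L)
      hits[[length(hits) + 1L]] <- add_hit(rev, mate, 100, plen, 0L, 1L, plen,
                                           min(220L, L2 - plen), min(220L, L2 - plen) - plen + 1L)
      tru[[length(tru) + 1L]] <- data.frame(pair_id = pair, expected = "cross_contig",
                                            stringsAsFactors = FALSE)
    }
    # decoy: short 5'-anchored partial hit elsewhere (fails 3' rule and coverage)
    if (i %% 3L == 0L) {
      other <- sample(scaff$contig_id, 1L)
      hits[[length(hits) + 1L]] <- add_hit(fwd, other, 95, 13L, 1L, 1L, 13L,
                                           500L, 512L)
    }
  }
  list(primers = do.call(rbind, prim), hits = do.call(rbind, hits),
       truth = do.call(rbind, tru))
}
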