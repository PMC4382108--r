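#' Sample observed genotype calls from a simulated cross
#'
#' Emulates the read-depth regime of targeted capture genotyping: per-call
#' total depth is drawn from an over-dispersed negative-binomial distribution
#' with mean `mean_depth` and size `depth_dispersion`; heterozygous calls get
#' allele depths split binomially with success probability 0.5; genotyping
#' errors (a different genotype from the locus's genotype space) and no-calls
#' are injected at the configured rates and logged in the truth registry.
#' The two parents are genotyped alongside the offspring and are subject to
#' the same depth, error and missingness processes.
#'
#' @param truth an `f1_truth` from [simulate_cross()].
#' @param config the [sim_config()] used to generate `truth` (defaults to the
#'   one stored in `truth`).
#' @return a list of class `f1_sim` with elements `calls` (a [variant_table]
#'   with parents as the first two samples) and `truth` (the input truth with
#'   an updated artifact registry).
#' @export
sample_observed_calls <- function(truth, config = truth$config) {
  am_check(inherits(truth, "f1_truth"), "'truth' must come from simulate_cross()")
  am_check(inherits(config, "sim_config"), "'config' must be a sim_config object")
  set.seed(config$seed + 1L)
  mk <- truth$markers
  M <- nrow(mk)
  noff <- ncol(truth$geno)
  samples <- c("P1", "P2", colnames(truth$geno))
  S <- length(samples)

  true_gt <- cbind(mk$p1, mk$p2, truth$geno)
  colnames(true_gt) <- samples

  ## per-marker allele set and VCF ref/alt coding
  refs <- character(M); alts <- character(M)
  allele_list <- vector("list", M)
  space <- vector("list", M)  # genotype space (strings) per marker
  for (m in seq_len(M)) {
    p1 <- c(mk$p1_hap1[m], mk$p1_hap2[m])
    p2 <- c(mk$p2_hap1[m], mk$p2_hap2[m])
    al <- sort(unique(c(p1, p2)))
    refs[m] <- sample(al, 1L)
    alts[m] <- paste(setdiff(al, refs[m]), collapse = ",")
    allele_list[[m]] <- c(refs[m], setdiff(al, refs[m]))
    gs <- unique(c(as.vector(outer(p1, p2, geno_str)), geno_str(p1[1], p1[2]),
                   geno_str(p2[1], p2[2])))
    space[[m]] <- gs
  }

  ## genotyping errors
  obs <- true_gt
  err <- matrix(stats::runif(M * S) < config$error_rate, M, S)
  art <- list()
  if (any(err)) {
    wh <- which(err, arr.ind = TRUE)
    for (k in seq_len(nrow(wh))) {
      m <- wh[k, 1L]; s <- wh[k, 2L]
      alt_g <- setdiff(space[[m]], obs[m, s])
      if (length(alt_g)) obs[m, s] <- sample(alt_g, 1L)
    }
    art[[length(art) + 1L]] <- data.frame(
      type = "error_call", id = mk$marker_id[wh[, 1L]],
      sample = samples[wh[, 2L]], detail = "genotype replaced",
      stringsAsFactors = FALSE)
  }

  ## missingness
  mis <- matrix(stats::runif(M * S) < config$missing_rate, M, S)
  obs[mis] <- NA_character_
  if (any(mis)) {
    wh <- which(mis, arr.ind = TRUE)
    art[[length(art) + 1L]] <- data.frame(
      type = "missing_call", id = mk$marker_id[wh[, 1L]],
      sample = samples[wh[, 2L]], detail = "no-call",
      stringsAsFactors = FALSE)
  }

  ## depths and allele depths
  dp <- matrix(stats::rnbinom(M * S, size = config$depth_dispersion,
                              mu = config$mean_depth), M, S)
  gt <- matrix(NA_character_, M, S)
  ad <- matrix(NA_character_, M, S)
  for (m in seq_len(M)) {
    al <- allele_list[[m]]
    na <- length(al)
    for (s in seq_len(S)) {
      g <- obs[m, s]
      if (is.na(g)) next
      pair <- split_geno(g)
      i1 <- match(pair[1L], al); i2 <- match(pair[2L], al)
      gt[m, s] <- paste(sort(c(i1, i2)) - 1L, collapse = "/")
      counts <- integer(na)
      d <- dp[m, s]
      if (i1 == i2) {
        counts[i1] <- d
      } else {
        x <- stats::rbinom(1L, d, 0.5)
        counts[i1] <- x; counts[i2] <- d - x
      }
      ad[m, s] <- paste(counts, collapse = ",")
    }
  }
  dimnames(gt) <- dimnames(ad) <- dimnames(dp) <- list(mk$marker_id, samples)

  sites <- data.frame(contig_id = mk$contig_id,
                      position = mk$pos_bp,
                      marker_id = mk$marker_id,
                      ref = refs, alt = alts,
                      qual = round(stats::runif(M, 100, 5000), 1),
                      combined_depth = rowSums(dp),
                      stringsAsFactors = FALSE)

  ## VCF order: by contig then position
  ord <- order(sites$contig_id, sites$position)
  vt <- variant_table(sites[ord, ], gt[ord, , drop = FALSE],
                      ad[ord, , drop = FALSE], dp[ord, , drop = FALSE],
                      samples, parents = c("P1", "P2"))
  rownames(vt$sites) <- NULL

  truth$artifacts <- rbind(truth$artifacts, do.call(rbind, art))
  out <- list(calls = vt, truth = truth)
  class(out) <- "f1_sim"
  out
}

#' @export
print.f1_sim <- function(x, ...) {
  print(x$truth)
  print(x$calls)
  invisible(x)
}

#' Write a simulated cross to disk as analysis-ready fixture files
#'
#' Emits the external files the pipeline consumes: a multi-sample VCF
#' (parents first), the scaffold-membership table, a reference-map table, the
#' synthetic primer-pair table and blast-style primer hits, truth tables and a
#' JSON echo of the configuration. Writing then reading through the package's
#' readers round-trips the genotype matrix exactly.
#'
#' @param sim an `f1_sim` from [sample_observed_calls()] (or an `f1_truth`,
#'   in which case calls are sampled first with the stored config).
#' @param out_dir output directory, created if needed.
#' @return invisibly, a named character vector of the files written.
#' @export
write_fixture <- function(sim, out_dir) {
  if (inherits(sim, "f1_truth")) sim <- sample_observed_calls(sim)
  am_check(inherits(sim, "f1_sim"), "'sim' must come from sample_observed_calls()")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  am_check(dir.exists(out_dir), sprintf("cannot create directory %s", out_dir))
  tr <- sim$truth
  paths <- c(vcf = file.path(out_dir, "genotypes.vcf"),
             scaffolds = file.path(out_dir, "scaffolds.tsv"),
             reference_map = file.path(out_dir, "reference_map.tsv"),
             primers = file.path(out_dir, "primers.tsv"),
             primer_hits = file.path(out_dir, "primer_hits.tsv"),
             truth_markers = file.path(out_dir, "truth_markers.tsv"),
             truth_artifacts = file.path(out_dir, "truth_artifacts.tsv"),
             config = file.path(out_dir, "config.json"))
  write_vcf_file(sim$calls, paths[["vcf"]])
  wt <- function(d, p) utils::write.table(d, p, sep = "\t", quote = FALSE,
                                          row.names = FALSE)
  wt(tr$scaffolds, paths[["scaffolds"]])
  wt(tr$reference_map, paths[["reference_map"]])
  wt(tr$primers, paths[["primers"]])
  utils::write.table(tr$primer_hits, paths[["primer_hits"]], sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  wt(tr$markers, paths[["truth_markers"]])
  wt(tr$artifacts, paths[["truth_artifacts"]])
  cfg <- tr$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, paths[["config"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
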