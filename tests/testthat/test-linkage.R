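test_that("two-point estimates match closed forms on phase-known 1:1 pairs", {
  g <- rbind(c(rep("A/A", 5), rep("A/G", 5)), c(rep("A/A", 5), rep("A/G", 5)))
  ms <- make_marker_set(p1 = c("A/G", "A/G"), p2 = c("A/A", "A/A"), geno = g)
  r <- estimate_two_point(ms[1], ms[2])
  expect_equal(r$rf, 0)
  expect_equal(r$lod, 10 * log10(2), tolerance = 1e-6)   # 3.0103
  expect_equal(r$informative_meioses, 10)
  # 2 recombinants of 10: rf 0.2, lod = 10 log10 2 + 2 log10 .2 + 8 log10 .8
  g2 <- g; g2[2, c(1, 6)] <- c("A/G", "A/A")
  ms2 <- make_marker_set(p1 = c("A/G", "A/G"), p2 = c("A/A", "A/A"), geno = g2)
  r2 <- estimate_two_point(ms2[1], ms2[2])
  expect_equal(r2$rf, 0.2, tolerance = 1e-5)
  expect_equal(r2$lod, 10 * log10(2) + 2 * log10(0.2) + 8 * log10(0.8),
               tolerance = 1e-4)
})

test_that("pairs informative in strictly different single parents are null", {
  g <- rbind(rep(c("A/A", "A/G"), 10), rep(c("A/A", "A/G"), 10))
  ms <- make_marker_set(p1 = c("A/G", "A/A"), p2 = c("A/A", "A/G"), geno = g)
  r <- estimate_two_point(ms[1], ms[2])
  expect_equal(r$rf, 0.5)
  expect_equal(r$lod, 0)
  expect_equal(r$informative_meioses, 0)
})

test_that("mismatched offspring panels are rejected", {
  g <- rbind(rep("A/A", 10))
  a <- make_marker_set("A/G", "A/A", g)
  b <- make_marker_set("A/G", "A/A", g)
  b$offspring <- paste0("x", b$offspring)
  colnames(b$geno) <- b$offspring
  expect_error(estimate_two_point(a, b), class = "anchormap_validation_error")
})

test_that("independent markers have rf near 0.5 and lod near 0", {
  set.seed(51)
  meds <- replicate(30, {
    p <- random_marker_pair(n = 100, r = 0.5,
                            classes = sample(c("lm", "hk", "fi"), 2, replace = TRUE))
    est <- estimate_two_point(p$ms[1], p$ms[2])
    c(est$rf, est$lod)
  })
  expect_gt(median(meds[1, ]), 0.4)
  expect_lt(median(meds[2, ]), 0.3)
})

test_that("EM agrees with the grid-search likelihood oracle on random pairs", {
  set.seed(52)
  for (i in 1:120) {
    p <- random_marker_pair(n = 60)
    est <- estimate_two_point(p$ms[1], p$ms[2])
    orc <- grid_oracle_two_point(p$ms)
    if (est$rf == 0.5 && orc$rf > 0.49) next   # both at the boundary
    expect_lt(abs(est$rf - orc$rf), 1e-3)
    expect_lt(abs(est$lod - orc$lod), 0.01)
  }
})

test_that("batched pairwise estimates equal the single-pair path", {
  set.seed(53)
  sets <- lapply(1:6, function(i) random_marker_pair(n = 50)$ms)
  mk <- do.call(rbind, lapply(sets, `[[`, "markers"))
  mk$marker_id <- sprintf("m%02d", seq_len(nrow(mk)))
  geno <- do.call(rbind, lapply(sets, `[[`, "geno"))
  rownames(geno) <- mk$marker_id
  ms <- structure(list(markers = mk, geno = geno, offspring = sets[[1]]$offspring),
                  class = "marker_set")
  pw <- pairwise_linkage(ms)
  for (i in c(1, 4, 7)) for (j in c(2, 6, 11)) {
    if (i >= j) next
    est <- estimate_two_point(ms[i], ms[j])
    expect_equal(pw$rf[i, j], est$rf, tolerance = 1e-9)
    expect_equal(pw$lod[i, j], est$lod, tolerance = 1e-9)
    expect_equal(pw$n[i, j], est$informative_meioses)
  }
})

test_that("rf estimator is nearly unbiased for linked fully-informative pairs", {
  set.seed(54)
  for (r in c(0.05, 0.1, 0.2, 0.3)) {
    errs <- replicate(40, {
      p <- random_marker_pair(n = 149, r = r, classes = c("fi", "fi"),
                              missing = 0)
      abs(estimate_two_point(p$ms[1], p$ms[2])$rf - r)
    })
    expect_lte(mean(errs), 0.05)
  }
})

test_that("grouping is exact single linkage and input-order invariant", {
  set.seed(55)
  cfg <- sim_config(n_chromosomes = 3, markers_per_chromosome = 15,
                    n_offspring = 80, seed = 330)
  obs <- sample_observed_calls(simulate_cross(cfg), cfg)
  qc <- run_qc_cascade(obs$calls)
  pw <- pairwise_linkage(qc$markers)
  part <- build_groups(pw, 6)
  # oracle: union-find over the explicit edge list
  M <- length(pw$ids)
  edges <- which(pw$lod >= 6 & upper.tri(pw$lod), arr.ind = TRUE)
  uf <- unionfind_components(M, edges)
  expect_equal(length(unique(part)), length(unique(uf)))
  expect_true(all(tapply(uf, part[pw$ids], function(z) length(unique(z))) == 1))
  # threshold above the maximum lod: all singletons
  part_hi <- build_groups(pw, max(pw$lod) + 1)
  expect_equal(length(unique(part_hi)), M)
  # permuting marker order does not change the partition
  perm <- sample(M)
  ms_p <- qc$markers[perm]
  part_p <- build_groups(pairwise_linkage(ms_p), 6)
  for (g in unique(part)) {
    ids <- names(part)[part == g]
    expect_equal(length(unique(part_p[ids])), 1)
  }
})

test_that("threshold selection targets the chromosome number with tie-breaks", {
  mk <- data.frame(marker_id = sprintf("m%d", 1:12),
                   contig_id = sprintf("c%d", 1:12), stringsAsFactors = FALSE)
  p12 <- setNames(rep(1:12, each = 1), mk$marker_id)          # 12 singletons
  p18 <- setNames(rep(1:2, each = 6), mk$marker_id)           # 2 groups
  p3 <- setNames(rep(1:3, each = 4), mk$marker_id)            # 3 groups
  sel <- select_threshold(list(`8` = p18, `9` = p3), mk, target_n = 2,
                          min_group_size = 1)
  expect_equal(sel$threshold, 8)
  # single candidate: that candidate
  sel1 <- select_threshold(list(`10` = p3), mk, target_n = 18, min_group_size = 1)
  expect_equal(sel1$threshold, 10)
  # tie on group count: reference agreement decides
  pA <- setNames(rep(1:2, each = 6), mk$marker_id)
  pB <- setNames(rep(1:2, times = 6), mk$marker_id)
  ref <- data.frame(marker_id = paste0("ssr", 1:12), contig_id = mk$contig_id,
                    linkage_group = rep(c("LG1", "LG2"), each = 6),
                    position_cm = 1:12, stringsAsFactors = FALSE)
  sel2 <- select_threshold(list(`8` = pB, `9` = pA), mk, reference = ref,
                           target_n = 2, min_group_size = 1)
  expect_equal(sel2$threshold, 9)   # pA matches the reference grouping
  # remaining tie goes to the higher threshold
  sel3 <- select_threshold(list(`8` = pA, `9` = pA), mk, target_n = 2,
                           min_group_size = 1)
  expect_equal(sel3$threshold, 9)
  expect_error(select_threshold(list(), mk), class = "anchormap_validation_error")
})

test_that("bin collapsing merges markers identical up to allele relabelling", {
  # identical vectors -> one bin; one offspring different -> two bins
  g <- rbind(c("A/A", "A/G", "A/A", "A/G"),
             c("A/A", "A/G", "A/A", "A/G"),
             c("A/A", "A/G", "A/G", "A/G"),
             c("A/G", "A/A", "A/G", "A/A"))   # row 4 = row 1 relabelled
  ms <- make_marker_set(p1 = rep("A/G", 4), p2 = rep("A/A", 4), geno = g)
  b <- collapse_bins(ms)
  expect_equal(b$bin[1], b$bin[2])
  expect_equal(b$bin[1], b$bin[4])   # allele swap is the same signature
  expect_false(b$bin[1] == b$bin[3])
  expect_equal(length(unique(b$bin)), 2)
  # strict no-call handling: an NA pattern difference keeps bins apart
  g2 <- g[1:2, ]; g2[2, 1] <- NA
  ms2 <- make_marker_set(p1 = rep("A/G", 2), p2 = rep("A/A", 2), geno = g2)
  expect_equal(length(unique(collapse_bins(ms2, strict = TRUE)$bin)), 2)
  expect_equal(length(unique(collapse_bins(ms2, strict = FALSE)$bin)), 1)
})

test_that("a redundant group collapses to the planted number of bins", {
  # 30 SNPs built from 6 distinct segregation signatures
  set.seed(56)
  n <- 40
  sig <- replicate(6, sample(c("A/A", "A/G"), n, replace = TRUE))
  g <- t(sig[, rep(1:6, each = 5)])
  ms <- make_marker_set(p1 = rep("A/G", 30), p2 = rep("A/A", 30), geno = g)
  b <- collapse_bins(ms)
  expect_equal(length(unique(b$bin)), 6)
  expect_equal(nrow(b), 30)
})

test_that("ordering recovers a three-bin chain with Haldane positions", {
  # true order A-B-C with rf(AB) = rf(BC) = 0.1: positions 0 / 11.157 / 22.31
  set.seed(57)
  n <- 2000   # large n so rf estimates are tight
  t1 <- sample(1:2, n, replace = TRUE)
  flip <- function(t, r) ifelse(runif(n) < r, 3 - t, t)
  t2 <- flip(t1, 0.1); t3 <- flip(t2, 0.1)
  enc <- function(t) c("A/A", "A/G")[t]
  ms <- make_marker_set(p1 = rep("A/G", 3), p2 = rep("A/A", 3),
                        geno = rbind(enc(t1), enc(t2), enc(t3)),
                        ids = c("A", "B", "C"))
  pw <- pairwise_linkage(ms)
  bins <- collapse_bins(ms)
  ord <- order_and_position(bins, pw)
  expect_equal(ord$members, c("A", "B", "C"))
  expect_equal(ord$position[1], 0)
  expect_equal(ord$position[2], haldane_cm(0.1), tolerance = 0.12)
  expect_equal(ord$position[3], 2 * haldane_cm(0.1), tolerance = 0.2)
  # single bin: position 0, length 0
  ord1 <- order_and_position(bins[bins$marker_id == "A", , drop = FALSE], pw)
  expect_equal(ord1$position, 0)
})

test_that("ordering is invariant to orientation flips of the input", {
  set.seed(58)
  cfg <- sim_config(n_chromosomes = 1, markers_per_chromosome = 25,
                    n_offspring = 120, seed = 331)
  obs <- sample_observed_calls(simulate_cross(cfg), cfg)
  qc <- run_qc_cascade(obs$calls)
  pw <- pairwise_linkage(qc$markers)
  bins <- collapse_bins(qc$markers, strict = FALSE)
  o1 <- order_and_position(bins, pw)
  o2 <- order_and_position(bins[rev(seq_len(nrow(bins))), ], pw)
  expect_equal(o1$members, o2$members)
  expect_equal(o1$position, o2$position)
})

test_that("map totals are reproducible for a fixed seed", {
  cfg <- sim_config(n_chromosomes = 2, markers_per_chromosome = 15,
                    n_offspring = 50, seed = 332)
  run_once <- function() {
    obs <- sample_observed_calls(simulate_cross(cfg), cfg)
    qc <- run_qc_cascade(obs$calls)
    map <- build_linkage_map(qc$markers, 5:10, target_n = 2)
    sum(map$groups$length_cm)
  }
  expect_identical(run_once(), run_once())
})
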