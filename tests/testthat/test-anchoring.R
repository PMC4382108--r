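# a small hand-built placed-marker table standing in for a linkage_map
placed_df <- function(...) {
  d <- data.frame(..., stringsAsFactors = FALSE)
  names(d) <- c("marker_id", "contig_id", "group", "bin", "position")
  d
}

test_that("contig placement computes spans, majorities and flags", {
  mk <- placed_df(
    marker_id = sprintf("m%d", 1:12),
    contig_id = c(rep("ctgA", 2), rep("ctgB", 7), rep("ctgC", 2), "ctgD"),
    group = c("LG3", "LG3", rep("LG1", 6), "LG2", "LG5", "LG5", "LG4"),
    bin = sprintf("b%d", 1:12),
    position = c(105.83, 255.22, 1:6, 50, 10, 12, 0))
  pl <- assign_contigs(mk, span_threshold = 10)
  a <- pl[pl$contig_id == "ctgA", ]
  expect_equal(a$span, 149.39)                 # the within-contig span rule
  expect_true(a$span_gt_threshold)
  expect_false(a$multi_group)
  b <- pl[pl$contig_id == "ctgB", ]
  expect_equal(b$group, "LG1")                 # 6 vs 1 majority
  expect_true(b$multi_group)
  expect_false(b$span_gt_threshold)
  d <- pl[pl$contig_id == "ctgD", ]
  expect_equal(d$span, 0)                      # single SNP
  expect_false(d$span_gt_threshold)
  # a 1-vs-1 tie is flagged unresolved
  mk2 <- placed_df(marker_id = c("x1", "x2"), contig_id = "ctgT",
                   group = c("LG1", "LG2"), bin = c("b1", "b2"),
                   position = c(0, 5))
  expect_true(assign_contigs(mk2)$unresolved)
})

test_that("scaffold concordance flags gaps and split groups", {
  mk <- placed_df(
    marker_id = sprintf("m%d", 1:6),
    contig_id = c("c1", "c2", "c3", "c4", "c5", "c6"),
    group = c("LG1", "LG1", "LG1", "LG1", "LG2", "LG1"),
    bin = sprintf("b%d", 1:6),
    position = c(10, 35, 12, 12, 40, 12.5))
  scf <- data.frame(scaffold_id = c("s1", "s1", "s2", "s2", "s3", "s3"),
                    contig_id = c("c1", "c2", "c3", "c4", "c5", "c6"),
                    order_index = c(1, 2, 1, 2, 1, 2),
                    contig_length_bp = 1000, stringsAsFactors = FALSE)
  pl <- assign_contigs(mk)
  res <- scaffold_concordance(pl, scf, gap_threshold = 20)
  s1 <- res$scaffolds[res$scaffolds$scaffold_id == "s1", ]
  expect_equal(s1$max_gap, 25)                 # 10 vs 35 cM
  expect_true(s1$gap_ge_threshold)
  expect_false(s1$split_groups)
  s2 <- res$scaffolds[res$scaffolds$scaffold_id == "s2", ]
  expect_equal(s2$max_gap, 0)
  expect_false(s2$gap_ge_threshold)
  s3 <- res$scaffolds[res$scaffolds$scaffold_id == "s3", ]
  expect_true(s3$split_groups)                 # c5 uniquely LG2, c6 uniquely LG1
  expect_equal(res$report$scaffold_gaps$scaffold_id, "s1")
  expect_equal(res$report$scaffold_splits$scaffold_id, "s3")
  # contig missing from the scaffold map: singleton with a warning
  mk_orphan <- placed_df(marker_id = "m9", contig_id = "c9", group = "LG1",
                         bin = "b9", position = 3)
  expect_warning(res2 <- scaffold_concordance(assign_contigs(mk_orphan), scf))
  expect_true(any(grepl("singleton", res2$scaffolds$scaffold_id)))
})

test_that("planted whole-contig relocations are exactly the split scaffolds", {
  set.seed(60)
  cfg <- sim_config(n_chromosomes = 4, markers_per_chromosome = 25,
                    n_offspring = 100, error_rate = 0, missing_rate = 0,
                    distorted_fraction = 0, repeat_dup_fraction = 0, seed = 333)
  tr <- simulate_cross(cfg)
  # relocate all markers of 3 contigs (from multi-contig scaffolds) to other
  # chromosomes: their scaffolds must be flagged split_groups
  scf_sizes <- table(tr$scaffolds$scaffold_id[tr$scaffolds$contig_id %in%
                                                tr$markers$contig_id])
  big <- names(scf_sizes[scf_sizes >= 2])
  planted <- character(0)
  for (sid in big) {
    if (length(planted) >= 3) break
    cands <- intersect(tr$scaffolds$contig_id[tr$scaffolds$scaffold_id == sid],
                       tr$markers$contig_id)
    if (length(cands) < 2) next
    cid <- cands[1]
    idx <- which(tr$markers$contig_id == cid)
    old_chr <- tr$markers$true_chrom[idx[1]]
    new_chr <- setdiff(seq_len(cfg$n_chromosomes), old_chr)[1]
    sw <- which(tr$markers$true_chrom == new_chr)
    # swap genotype rows with markers of the target chromosome region
    take <- sw[seq_along(idx)]
    tr$geno[idx, ] <- tr$geno[take, ]
    cols <- c("seg_type", "p1", "p2", "p1_hap1", "p1_hap2", "p2_hap1", "p2_hap2")
    tr$markers[idx, cols] <- tr$markers[take, cols]
    tr$markers$true_chrom[idx] <- new_chr
    tr$markers$true_cm[idx] <- tr$markers$true_cm[take] + 0.01
    planted <- c(planted, sid)
  }
  expect_length(planted, 3)
  obs <- sample_observed_calls(tr, cfg)
  qc <- run_qc_cascade(obs$calls)
  map <- build_linkage_map(qc$markers, 6:12, target_n = 4)
  anch <- anchor_map(map, tr$scaffolds)
  found <- anch$report$scaffold_splits$scaffold_id
  expect_setequal(intersect(found, big), planted)
})

test_that("group renumbering follows maximum shared-contig matching", {
  mk <- placed_df(
    marker_id = sprintf("m%d", 1:12),
    contig_id = sprintf("c%d", c(1:6, 1, 7:11)),
    group = rep(c("LG1", "LG2"), each = 6),
    bin = sprintf("b%d", 1:12), position = 1:12)
  map <- structure(list(markers = mk,
                        groups = data.frame(group = c("LG1", "LG2"),
                                            n_snps = 6, n_bins = 6,
                                            length_cm = 12,
                                            stringsAsFactors = FALSE)),
                   class = "linkage_map")
  # LG1 shares 5 contigs with reference A, LG2 shares 1 (c1 is multi-group)
  ref <- data.frame(marker_id = sprintf("s%d", 1:6),
                    contig_id = sprintf("c%d", c(2:6, 7)),
                    linkage_group = c(rep("LGA", 5), "LGA"),
                    position_cm = 1:6, stringsAsFactors = FALSE)
  out <- renumber_groups(map, ref)
  ren <- out$renumbering
  expect_equal(ren$new[ren$old == "LG1"], "LGA")   # 5 shared beats 1
  expect_false(ren$new[ren$old == "LG2"] == "LGA") # fresh label
  # identical grouping: identity relabelling
  ref2 <- data.frame(marker_id = sprintf("s%d", 1:10),
                     contig_id = sprintf("c%d", c(2:6, 7:11)),
                     linkage_group = rep(c("LG1", "LG2"), each = 5),
                     position_cm = 1:10, stringsAsFactors = FALSE)
  out2 <- renumber_groups(map, ref2)
  expect_equal(out2$renumbering$new, out2$renumbering$old)
  # no shared contigs: warning, labels kept
  ref3 <- data.frame(marker_id = "s1", contig_id = "cz",
                     linkage_group = "LGZ", position_cm = 1,
                     stringsAsFactors = FALSE)
  expect_warning(out3 <- renumber_groups(map, ref3))
  expect_equal(out3$groups$group, c("LG1", "LG2"))
})

test_that("reference-only scaffolds are interpolated between co-anchored markers", {
  mk <- placed_df(
    marker_id = sprintf("m%d", 1:4),
    contig_id = c("c1", "c2", "c3", "c4"),
    group = "LG1", bin = sprintf("b%d", 1:4),
    position = c(0, 10, 20, 30))
  map <- structure(list(markers = mk,
                        groups = data.frame(group = "LG1", n_snps = 4,
                                            n_bins = 4, length_cm = 30,
                                            stringsAsFactors = FALSE)),
                   class = "linkage_map")
  scf <- data.frame(scaffold_id = c("s1", "s2", "s3", "s4", "s5", "s6"),
                    contig_id = c("c1", "c2", "c3", "c4", "c9", "c10"),
                    order_index = 1, contig_length_bp = 1000,
                    stringsAsFactors = FALSE)
  # reference: c1 at 0, c3 at 40 on its own scale; c9 midway (20) -> snp 10;
  # c10 outside the co-anchored range -> group-only placement
  ref <- data.frame(marker_id = c("r1", "r3", "r9", "r10"),
                    contig_id = c("c1", "c3", "c9", "c10"),
                    linkage_group = "LG1",
                    position_cm = c(0, 40, 20, 95), stringsAsFactors = FALSE)
  anch <- anchor_map(map, scf, ref)
  s5 <- anch$scaffolds[anch$scaffolds$scaffold_id == "s5", ]
  expect_equal(s5$provenance, "microsatellite")
  expect_equal(s5$position, 10)            # linear interpolation 0..40 -> 0..20
  s6 <- anch$scaffolds[anch$scaffolds$scaffold_id == "s6", ]
  expect_equal(s6$provenance, "microsatellite")
  expect_true(is.na(s6$position))          # no flanking co-anchored pair
  expect_equal(s6$group, "LG1")
  # snp-anchored scaffolds that also carry a reference marker are "both"
  s1 <- anch$scaffolds[anch$scaffolds$scaffold_id == "s1", ]
  expect_equal(s1$provenance, "both")
})

test_that("map summaries reconcile per-group rows with totals", {
  per <- data.frame(linkage_group = c("LGa", "LGb", "LGc"),
                    snps = c(10, 20, 5), positions = c(4, 6, 2),
                    length_cm = c(0, 5, 10))
  s <- summarize_map(per)
  expect_equal(s$totals$total_snps, 35)
  expect_equal(s$totals$total_length_cm, 15)
  expect_equal(s$totals$max_snps_group, "LGb")
  expect_equal(s$totals$min_positions_group, "LGc")
  # empty input gives an empty summary
  s0 <- summarize_map(per[0, ])
  expect_equal(s0$totals$n_groups, 0)
  # single group with bins at 0/5/10: length 10, median inter-bin distance 5
  mk <- placed_df(marker_id = c("m1", "m2", "m3"), contig_id = "c1",
                  group = "LG1", bin = c("b1", "b2", "b3"),
                  position = c(0, 5, 10))
  map <- structure(list(markers = mk), class = "linkage_map")
  sm <- summarize_map(map)
  expect_equal(sm$per_group$length_cm, 10)
  expect_equal(sm$per_group$median_interbin_cm, 5)
  expect_equal(sm$per_group$positions, 3)
})
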