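# small hand-built variant table: 2 parents + 4 offspring
toy_vt <- function(gt, ad = NULL, dp = NULL, ref = "A", alt = "G") {
  M <- nrow(gt)
  samples <- c("P1", "P2", paste0("O", seq_len(ncol(gt) - 2L)))
  colnames(gt) <- samples
  rownames(gt) <- sprintf("s%02d", seq_len(M))
  if (is.null(dp)) dp <- matrix(50, M, length(samples), dimnames = dimnames(gt))
  if (is.null(ad)) {
    ad <- ifelse(gt == "0/1", paste(dp %/% 2, dp - dp %/% 2, sep = ","),
                 paste(dp, 0, sep = ","))
    ad[is.na(gt)] <- NA
    dim(ad) <- dim(gt); dimnames(ad) <- dimnames(gt)
  }
  sites <- data.frame(contig_id = "c1", position = seq_len(M) * 10,
                      marker_id = rownames(gt), ref = ref, alt = alt,
                      qual = 1000, combined_depth = rowSums(dp),
                      stringsAsFactors = FALSE)
  anchormap:::variant_table(sites, gt, ad, dp, samples)
}

test_that("call replacement enforces the depth and allele-balance rules", {
  gt <- rbind(c("0/1", "0/0", "0/1", "0/1", "0/1", "0/0"))
  dp <- rbind(c(50, 50, 19, 50, 20, 19))
  ad <- rbind(c("25,25", "50,0", "10,9", "1,19", "10,10", "19,0"))
  dimnames(ad) <- dimnames(dp) <- dimnames(gt)
  vt <- toy_vt(gt, ad = ad, dp = dp)
  out <- apply_call_filters(vt, qc_config(binomial_alpha = 1e-3))
  # depth 19 -> no-call regardless of genotype
  expect_true(is.na(out$gt[1, "O1"]))   # het, depth 19
  expect_true(is.na(out$gt[1, "O4"]))   # hom, depth 19
  # balanced het retained (two-sided p = 1)
  expect_false(is.na(out$gt[1, "O3"]))
  # het 1:19 rejected: exact two-sided p ~ 4.0e-05 < 1e-3
  expect_true(is.na(out$gt[1, "O2"]))
  expect_equal(unname(attr(out, "replacements")["low_depth"]), 2)
  expect_equal(unname(attr(out, "replacements")["allele_balance"]), 1)
  # the exact binomial p agrees with binom.test
  expect_equal(anchormap:::binom_balance_p(1, 20),
               binom.test(1, 20, 0.5)$p.value)
  expect_equal(anchormap:::binom_balance_p(1, 20), 4.00543e-05,
               tolerance = 1e-4)
  expect_equal(anchormap:::binom_balance_p(10, 20), 1)
})

test_that("het calls lacking allele depths become no-calls and are counted", {
  gt <- rbind(c("0/1", "0/0", "0/1", "0/0", "0/0", "0/0"))
  ad <- rbind(c("25,25", "50,0", NA, "50,0", "50,0", "50,0"))
  dimnames(ad) <- dimnames(gt)
  vt <- toy_vt(gt, ad = ad)
  out <- apply_call_filters(vt)
  expect_true(is.na(out$gt[1, "O1"]))
  expect_equal(unname(attr(out, "replacements")["missing_ad"]), 1)
})

test_that("call-rate filter uses the called fraction over all samples", {
  # 151 samples: 121 called (80.1%) retained, 120 called (79.5%) dropped
  n <- 151
  gt <- rbind(c(rep("0/1", 121), rep(NA, n - 121)),
              c(rep("0/1", 120), rep(NA, n - 120)))
  vt <- toy_vt(gt)
  out <- filter_call_rate(vt, 0.8)
  expect_equal(out$sites$marker_id, "s01")
  expect_equal(attr(out, "removed"), 1)
  # threshold 0 is the identity
  out0 <- filter_call_rate(vt, 0)
  expect_equal(nrow(out0$sites), 2)
})

test_that("parental filter drops no-calls, non-segregating and impossible offspring", {
  # rows: parent no-call; AA x AA; A/G x A/A with an impossible G/G offspring;
  # a clean A/G x A/A marker
  gt <- rbind(c(NA, "0/0", "0/1", "0/1", "0/0", "0/1"),
              c("0/0", "0/0", "0/0", "0/0", "0/0", "0/0"),
              c("0/1", "0/0", "1/1", "0/1", "0/0", "0/1"),
              c("0/1", "0/0", "0/1", "0/1", "0/0", "0/0"))
  vt <- toy_vt(gt)
  ms <- filter_parental(vt)
  expect_equal(ms$markers$marker_id, "s04")
  expect_equal(ms$markers$seg_type, "lm")
  rem <- attr(ms, "removed")
  expect_equal(unname(rem["parent_nocall"]), 1)
  expect_equal(unname(rem["non_segregating"]), 1)
  expect_equal(unname(rem["mendelian"]), 1)
  # offspring genotypes re-expressed as allele pairs
  expect_equal(unname(ms$geno["s04", ]), c("A/G", "A/G", "A/A", "A/A"))
  # unknown parent sample is a configuration error
  expect_error(filter_parental(vt, c("P1", "nope")),
               class = "anchormap_config_error")
})

test_that("segregation chi-square matches direct computation for each type", {
  # 1:1 with 100:49 -> chi2 ~ 17.46, p ~ 2.9e-05 (retained at 1e-5)
  n <- 149
  gt <- rbind(c("0/1", "0/0", rep("0/1", 100), rep("0/0", 49)),
              c("0/1", "0/0", rep("0/1", 110), rep("0/0", 39)))
  vt <- toy_vt(gt)
  ms <- filter_parental(vt)
  st <- segregation_test(ms)
  expect_equal(st$chi2[1], 2 * 25.5^2 / 74.5, tolerance = 1e-10)
  expect_equal(st$p[1], 2.9e-5, tolerance = 0.02)
  expect_equal(st$chi2[2], 33.83, tolerance = 1e-2)
  expect_lt(st$p[2], 1e-5)
  keep <- filter_segregation(ms, qc_config(seg_p_threshold = 1e-5))
  expect_equal(keep$markers$marker_id, "s01")
  # 1:2:1 at the exact expectation: chi2 = 0, p = 1
  gt2 <- rbind(c("0/1", "0/1", rep("0/0", 37), rep("0/1", 74), rep("1/1", 37)))
  ms2 <- filter_parental(toy_vt(gt2))
  st2 <- segregation_test(ms2)
  expect_equal(st2$chi2, 0)
  expect_equal(st2$p, 1)
  expect_equal(st2$df, 2)
})

test_that("segregation test matches a multinomial oracle on random vectors", {
  set.seed(77)
  for (i in 1:300) {
    type <- sample(c("lm", "hk", "fi"), 1)
    if (type == "lm") {
      probs <- c(0.5, 0.5)
      k <- rbinom(1, 120, runif(1, 0.2, 0.8))
      counts <- c(k, 120 - k)
      gt <- rbind(c("0/1", "0/0", rep("0/1", counts[1]), rep("0/0", counts[2])))
    } else if (type == "hk") {
      probs <- c(0.25, 0.5, 0.25)
      counts <- as.vector(rmultinom(1, 120, runif(3)))
      gt <- rbind(c("0/1", "0/1", rep("0/0", counts[1]), rep("0/1", counts[2]),
                    rep("1/1", counts[3])))
    } else {
      probs <- rep(0.25, 4)
      counts <- as.vector(rmultinom(1, 120, runif(4)))
      gt <- rbind(c("0/1", "2/3", rep("0/2", counts[1]), rep("0/3", counts[2]),
                    rep("1/2", counts[3]), rep("1/3", counts[4])))
    }
    ref <- "A"; alt <- if (type == "fi") "G,C,T" else "G"
    ms <- filter_parental(toy_vt(gt, ref = ref, alt = alt))
    st <- segregation_test(ms)
    orc <- chisq_oracle(counts[counts >= 0], probs)
    expect_equal(st$chi2, orc$chi2, tolerance = 1e-9)
    expect_equal(st$p, orc$p, tolerance = 1e-9)
  }
})

test_that("cascade stages reconcile and disabling thresholds is the identity", {
  cfg <- sim_config(n_chromosomes = 2, markers_per_chromosome = 20,
                    n_offspring = 60, seed = 320)
  obs <- sample_observed_calls(simulate_cross(cfg), cfg)
  res <- run_qc_cascade(obs$calls)
  rep <- res$report
  expect_true(all(rep$n_out <= rep$n_in))
  expect_equal(rep$n_in[-1], rep$n_out[-4])
  # thresholds disabled: no marker lost except structural (parental) drops
  loose <- qc_config(min_call_depth = 0, binomial_alpha = 0,
                     min_call_rate = 0, seg_p_threshold = 0,
                     min_seg_offspring = 0)
  res0 <- run_qc_cascade(obs$calls, config = loose)
  expect_equal(res0$report$calls_replaced[1], 0)
  expect_equal(res0$report$n_in[2], res0$report$n_out[2])
  expect_equal(res0$report$n_in[4], res0$report$n_out[4])
})
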