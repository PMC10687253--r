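# A reference with easily enumerated contexts: tx1 carries GCT sites, tx2
# carries ACT/CCT sites, so fractions can be planted per context.
ctx_ref <- function() c(tx1 = "AGCTAGCTAGCTAGCTA", tx2 = "AACTACCTAACTACCTA")

ctx_sites <- function(fr_gcu, fr_other, depth = 200L) {
  gcu_pos <- c(2L, 6L, 10L, 14L)[seq_along(fr_gcu)]
  oth_pos <- c(2L, 6L, 10L, 14L)[seq_along(fr_other)]
  rbind(
    data.frame(transcript_id = "tx1", pos = gcu_pos, depth = depth,
               mod_count = as.integer(round(fr_gcu * depth)),
               fraction = as.integer(round(fr_gcu * depth)) / depth),
    data.frame(transcript_id = "tx2", pos = oth_pos, depth = depth,
               mod_count = as.integer(round(fr_other * depth)),
               fraction = as.integer(round(fr_other * depth)) / depth))
}

test_that("fraction histograms use half-open bins with a closed top bin", {
  h <- summarize_density(c(0.0, 0.024, 0.025), bin_width = 0.025)
  expect_identical(h$count[1], 2L)
  expect_identical(h$count[2], 1L)
  expect_identical(nrow(h), 40L)

  expect_identical(sum(summarize_density(numeric(0))$count), 0L)
  h1 <- summarize_density(1.0)
  expect_identical(h1$count[40], 1L)  # 1.0 falls in [0.975, 1.0]

  withr::with_seed(12, {
    for (i in 1:20) {
      x <- runif(sample(1:200, 1))
      bw <- sample(c(0.025, 0.1, 0.3), 1)
      h <- summarize_density(x, bw)
      expect_identical(sum(h$count), length(x))  # n conserved
    }
  })
})

test_that("histogram counts match a loop oracle", {
  withr::with_seed(13, {
    for (i in 1:20) {
      x <- round(runif(50), 3)
      expect_identical(summarize_density(x, 0.025)$count,
                       oracle_histogram(x, 0.025))
    }
  })
})

test_that("stratification groups by central k-mer with strict filters", {
  ref <- c(t1 = "AGCTA", t2 = "TGCTT", t3 = "AACTA")
  sites <- data.frame(transcript_id = c("t1", "t2", "t3"), pos = 2L,
                      depth = 10L, mod_count = c(4L, 6L, 2L),
                      fraction = c(0.4, 0.6, 0.2))
  st <- stratify(sites, ref, min_depth = 0, min_fraction = 0)
  expect_identical(sort(names(st)), c("ACU", "GCU"))
  expect_identical(st$GCU$n, 2L)
  expect_identical(st$GCU$median, 0.5)
  expect_identical(st$ACU$median, 0.2)

  # strict "> 0": a fraction of exactly 0 is excluded
  sites$fraction[3] <- 0; sites$mod_count[3] <- 0L
  st <- stratify(sites, ref, min_depth = 0, min_fraction = 0)
  expect_null(st$ACU)
  expect_identical(sum(strata_table(st)$n), 2L)
})

test_that("GCU comparison computes Welch z, p, Cohen's d and median fold", {
  # planted: GCU {0.1,0.2,0.3}, others {0.2,0.3,0.4} -> d = -1.0 exactly
  sites <- ctx_sites(c(0.1, 0.2, 0.3), c(0.2, 0.3, 0.4), depth = 200L)
  cmp <- compare_gcu(sites, ctx_ref(), min_depth = 0)
  expect_equal(cmp$cohens_d, -1, tolerance = 1e-12)
  expect_equal(cmp$median_fold, 0.2 / 0.3, tolerance = 1e-12)
  expect_equal(cmp$p_two_tailed, 2 * (1 - pnorm(abs(cmp$z))), tolerance = 1e-12)

  # identical groups: z = 0, p = 1, d = 0, fold = 1
  same <- ctx_sites(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3))
  cmp0 <- compare_gcu(same, ctx_ref(), min_depth = 0)
  expect_identical(cmp0$z, 0)
  expect_identical(cmp0$p_two_tailed, 1)
  expect_identical(cmp0$cohens_d, 0)
  expect_identical(cmp0$median_fold, 1)

  # median fold 2.0 for medians 0.4 vs 0.2
  cmp2 <- compare_gcu(ctx_sites(c(0.3, 0.4, 0.5), c(0.1, 0.2, 0.3)),
                      ctx_ref(), min_depth = 0)
  expect_equal(cmp2$median_fold, 2, tolerance = 1e-12)
})

test_that("GCU comparison errors on empty groups and zero variance", {
  only_gcu <- ctx_sites(c(0.1, 0.2), c(0.3))
  only_gcu <- only_gcu[only_gcu$transcript_id == "tx1", ]
  expect_error(compare_gcu(only_gcu, ctx_ref(), min_depth = 0),
               class = "gcuaudit_comparison_error")
  flat <- ctx_sites(c(0.2, 0.2), c(0.2, 0.2))
  expect_error(compare_gcu(flat, ctx_ref(), min_depth = 0),
               class = "gcuaudit_degenerate_variance_error")
})

test_that("z and d agree with textbook oracles on randomized inputs", {
  withr::with_seed(14, {
    for (i in 1:50) {
      a <- runif(sample(3:30, 1)); b <- runif(sample(3:30, 1))
      expect_equal(gcuaudit:::welch_z(a, b), oracle_welch_z(a, b),
                   tolerance = 1e-9)
      expect_equal(gcuaudit:::cohens_d_pooled(a, b), oracle_cohens_d(a, b),
                   tolerance = 1e-9)
    }
  })
})

test_that("GCU/non-GCU partition covers all central-C sites passing filters", {
  withr::with_seed(15, {
    cfg <- simulation_config(n_transcripts = 3, length_mean = 300, seed = 21)
    ref <- generate_transcriptome(cfg)
    sim <- simulate_calls(ref, cfg)
    sites <- aggregate_fractions(sim$calls)
    kept <- filter_depth(sites, 50)
    km <- central_kmers(ref, kept)
    cmp <- compare_gcu(sites, ref, min_depth = 50)
    expect_identical(cmp$n_gcu + cmp$n_other, sum(!is.na(km)))
  })
})

test_that("paired comparison is null for identical samples and flags emptiness", {
  sites <- ctx_sites(c(0.1, 0.2, 0.3), c(0.2, 0.3, 0.4))
  p <- paired_sample_compare(sites, sites, ctx_ref(), min_depth = 0,
                             min_fraction = 0)
  for (pk in p$per_kmer) {
    expect_identical(pk$ks_statistic, 0)
    expect_identical(pk$median_difference, 0)
  }
  none <- sites; none$fraction <- 0; none$mod_count <- 0L
  expect_error(paired_sample_compare(sites, none, ctx_ref(), min_depth = 0,
                                     min_fraction = 0),
               class = "gcuaudit_comparison_error")
})

test_that("position matching keeps only sites passing filters in both samples", {
  nat <- ctx_sites(c(0.5, 0.6, 0.7), c(0.2, 0.3, 0.4))
  ivt <- nat
  ivt$depth[1] <- 5L  # GCU site at tx1:2 now fails depth > 10 in IVT
  ivt$mod_count[1] <- 2L; ivt$fraction[1] <- 0.4
  p <- paired_sample_compare(nat, ivt, ctx_ref(), min_depth = 10,
                             min_fraction = 0, position_matched = TRUE)
  expect_identical(p$per_kmer$GCU$native$n, 2L)
  expect_identical(p$per_kmer$GCU$ivt$n, 2L)
  un <- paired_sample_compare(nat, ivt, ctx_ref(), min_depth = 10,
                              min_fraction = 0, position_matched = FALSE)
  expect_identical(un$per_kmer$GCU$native$n, 3L)
})
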