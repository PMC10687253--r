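test_that("transcriptome generation respects GC content and the seed", {
  cfg <- simulation_config(n_transcripts = 4, length_mean = 200, gc = 0.9,
                           seed = 3)
  ref <- generate_transcriptome(cfg)
  expect_length(ref, 4L)
  letters_used <- unique(strsplit(paste(as.character(ref), collapse = ""),
                                  "")[[1]])
  gc_frac <- mean(strsplit(paste(as.character(ref), collapse = ""),
                           "")[[1]] %in% c("G", "C"))
  n_tot <- sum(nchar(as.character(ref)))
  expect_lt(abs(gc_frac - 0.9), 3 * sqrt(0.9 * 0.1 / n_tot))

  expect_identical(as.character(generate_transcriptome(cfg)),
                   as.character(ref))  # same seed, same FASTA
  lens <- nchar(as.character(ref))
  expect_true(all(lens >= 0.8 * 200 - 1 & lens <= 1.2 * 200 + 1))
})

test_that("degenerate call probabilities yield all-zero or all-one fractions", {
  cfg0 <- simulation_config(n_transcripts = 2, length_mean = 150,
                            p_base = 0, p_context = numeric(0), seed = 4)
  ref <- generate_transcriptome(cfg0)
  sim0 <- simulate_calls(ref, cfg0)
  s0 <- aggregate_fractions(sim0$calls)
  expect_true(all(s0$fraction == 0))

  cfg1 <- simulation_config(n_transcripts = 2, length_mean = 150,
                            p_base = 1, p_context = numeric(0), seed = 4)
  s1 <- aggregate_fractions(simulate_calls(ref, cfg1)$calls)
  expect_true(all(s1$fraction == 1))
})

test_that("simulation is bit-reproducible and truth covers every C site", {
  cfg <- simulation_config(n_transcripts = 2, length_mean = 200,
                           n_true_sites = 5, seed = 9)
  ref <- generate_transcriptome(cfg)
  a <- simulate_calls(ref, cfg)
  b <- simulate_calls(ref, cfg)
  expect_identical(a, b)

  chars <- as.character(ref)
  n_c <- sum(vapply(chars, function(s)
    lengths(regmatches(s, gregexpr("C", s))), integer(1)))
  expect_identical(nrow(a$truth), n_c)
  expect_identical(sum(a$truth$is_true_modified), 5L)
  expect_identical(sum(a$truth$depth), nrow(a$calls))
})

test_that("planted context probabilities are recovered at depth", {
  cfg <- simulation_config(n_transcripts = 4, length_mean = 800,
                           depth_mean = 200, p_base = 0.05,
                           p_context = c(GCU = 0.8), seed = 6)
  ref <- generate_transcriptome(cfg)
  sim <- simulate_calls(ref, cfg)
  sites <- aggregate_fractions(sim$calls)
  km <- central_kmers(ref, sites)
  gcu <- sites$fraction[!is.na(km) & km == "GCU"]
  n_reads <- sum(sites$depth[!is.na(km) & km == "GCU"])
  expect_lt(abs(mean(gcu) - 0.8), 3 * sqrt(0.8 * 0.2 / n_reads) + 0.01)
  expect_gt(length(gcu), 30)
})

test_that("true sites reach their planted modified fraction", {
  cfg <- simulation_config(n_transcripts = 4, length_mean = 600,
                           depth_mean = 150, p_base = 0.02,
                           p_context = numeric(0), n_true_sites = 50,
                           true_fraction = 0.9, seed = 11)
  ref <- generate_transcriptome(cfg)
  sim <- simulate_calls(ref, cfg)
  sites <- aggregate_fractions(sim$calls)
  truth <- sim$truth[sim$truth$is_true_modified & sim$truth$depth > 0, ]
  key <- paste(sites$transcript_id, sites$pos)
  fr <- sites$fraction[match(paste(truth$transcript_id, truth$pos), key)]
  n_reads <- sum(truth$depth)
  expect_lt(abs(mean(fr) - 0.9), 3 * sqrt(0.9 * 0.1 / n_reads) + 0.01)
})

test_that("an IVT member with no true sites still shows the planted GCU bias", {
  cfg_nat <- simulation_config(n_transcripts = 5, length_mean = 500,
                               n_true_sites = 20, seed = 31)
  cfg_ivt <- simulation_config(n_transcripts = 5, length_mean = 500,
                               n_true_sites = 0, seed = 32)
  ref <- generate_transcriptome(cfg_nat)
  pair <- simulate_pair(ref, cfg_nat, cfg_ivt)
  expect_false(any(pair$ivt$truth$is_true_modified))
  ivt_sites <- aggregate_fractions(pair$ivt$calls)
  km <- central_kmers(ref, ivt_sites)
  med_gcu <- median(ivt_sites$fraction[!is.na(km) & km == "GCU"])
  med_oth <- median(ivt_sites$fraction[!is.na(km) & km != "GCU"])
  expect_gt(med_gcu, med_oth)
})

test_that("configuration errors are caught", {
  expect_error(simulation_config(p_base = 1.5),
               class = "gcuaudit_config_error")
  expect_error(simulation_config(gc = 0), class = "gcuaudit_config_error")
  cfg <- simulation_config(n_transcripts = 1, length_mean = 60,
                           n_true_sites = 1000, seed = 2)
  ref <- generate_transcriptome(cfg)
  expect_error(simulate_calls(ref, cfg), class = "gcuaudit_config_error")
})
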