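test_that("central k-mer counting reports counts and top ratio", {
  wins <- c("AGCTA", "TGCTC", "AACTG", "GGCTT")
  ke <- count_central_kmers(wins, k = 3)
  expect_identical(ke$counts[["GCU"]], 3L)
  expect_identical(ke$counts[["ACU"]], 1L)
  expect_identical(ke$top_ratio, 3)
  expect_identical(ke$total, 4L)

  empty <- count_central_kmers(character(0))
  expect_identical(empty$total, 0L)
  expect_length(empty$counts, 0L)
})

test_that("central k-mer counting matches a dictionary oracle", {
  withr::with_seed(8, {
    for (i in 1:20) {
      wins <- random_windows(n = sample(5:40, 1), len = 11)
      ke <- count_central_kmers(wins, k = 3)
      ora <- oracle_central_kmer_counts(wins, k = 3)
      expect_identical(sum(ke$counts), ke$total)
      expect_identical(ke$counts[sort(names(ke$counts))],
                       ora[sort(names(ora))])
    }
  })
})

test_that("ZOOPS EM converges on a single sequence with a verifiable likelihood", {
  fit <- em_zoops("AAAA", width = 2)
  expect_gt(fit$pwm["A", 1], 0.7)
  expect_gt(fit$pwm["A", 2], 0.7)
  # reported likelihood equals the model definition evaluated independently
  ora <- oracle_zoops_loglik("AAAA", fit$pwm, fit$occupancy, fit$background)
  expect_equal(fit$loglik, ora, tolerance = 1e-9)
})

test_that("EM likelihood matches the independent oracle on random inputs", {
  withr::with_seed(9, {
    for (i in 1:10) {
      wins <- random_windows(n = sample(10:25, 1), len = 11)
      w <- sample(3:6, 1)
      fit <- em_zoops(wins, width = w)
      ora <- oracle_zoops_loglik(wins, fit$pwm, fit$occupancy, fit$background)
      expect_equal(fit$loglik, ora, tolerance = 1e-8)
      expect_true(all(abs(colSums(fit$pwm) - 1) < 1e-9))
      expect_true(all(fit$pwm > 0))
      expect_true(all(diff(fit$objective_trace) >= -1e-9))
    }
  })
})

test_that("occupancy zero is an EM fixed point that leaves the PWM untouched", {
  init <- matrix(c(0.7, 0.1, 0.1, 0.1,
                   0.1, 0.7, 0.1, 0.1), nrow = 4)
  fit <- em_zoops(c("ACGTACGTA", "TTACGTTAC"), width = 2, lambda0 = 0,
                  init_pwm = init)
  expect_identical(fit$occupancy, 0)
  expect_equal(unname(fit$pwm), init, tolerance = 1e-12)
})

test_that("mononucleotide shuffling preserves per-window composition", {
  wins <- random_windows(5, 11)
  sn <- shuffle_null(wins, function(w) 0, n_shuffles = 19, seed = 3)
  expect_identical(sn$p_empirical, 1)  # ties count as null >= observed
  X <- gcuaudit:::encode_windows(wins)
  withr::with_seed(1, {
    Xs <- gcuaudit:::shuffle_window_matrix(X)
    for (i in seq_len(nrow(X))) {
      expect_identical(tabulate(Xs[i, ] + 1, 4), tabulate(X[i, ] + 1, 4))
    }
  })
})

test_that("permutation p-values follow the add-one rule", {
  wins <- random_windows(12, 9)
  # scoring function that makes the observed windows beat every shuffle
  obs_flag <- paste(wins, collapse = "")
  score_top <- function(w) if (identical(paste(w, collapse = ""), obs_flag)) 1 else 0
  expect_identical(
    shuffle_null(wins, score_top, n_shuffles = 99, seed = 2)$p_empirical,
    1 / 100)
  score_bottom <- function(w) -score_top(w)
  expect_identical(
    shuffle_null(wins, score_bottom, n_shuffles = 99, seed = 2)$p_empirical,
    1)
  expect_error(shuffle_null(wins, score_top, n_shuffles = 5),
               class = "gcuaudit_input_error")
})

test_that("a planted word is recovered as the top motif", {
  wins <- withr::with_seed(42, planted_windows(50, 15, "GCTTAG"))
  motifs <- discover_motifs(wins, nmotifs = 2, minw = 3, maxw = 6,
                            n_shuffles = 100, seed = 1)
  top <- motifs[[1]]
  expect_identical(top$consensus, "GCUUAG")
  expect_gt(top$occupancy, 0.9)
  expect_lte(top$p_empirical, 0.01)
  expect_gte(top$p_empirical, 1 / 101)
})

test_that("motif discovery is deterministic and validates its input", {
  wins <- withr::with_seed(10, random_windows(15, 9))
  m1 <- discover_motifs(wins, nmotifs = 2, n_shuffles = 19, seed = 5)
  m2 <- discover_motifs(wins, nmotifs = 2, n_shuffles = 19, seed = 5)
  expect_identical(m1, m2)
  expect_length(discover_motifs(wins, nmotifs = 1, n_shuffles = 19, seed = 1), 1L)

  expect_error(discover_motifs(wins[1:5], n_shuffles = 19),
               class = "gcuaudit_insufficient_data_error")
  expect_error(discover_motifs(c(wins, "ACGT"), n_shuffles = 19),
               class = "gcuaudit_input_error")
})
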