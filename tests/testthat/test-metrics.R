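test_that("similarity index respects its endpoints and symmetry", {
  expect_equal(similarity_index("123", "456"), 0)
  expect_equal(similarity_index("12345", "12345"), 1)
  # hand evaluation: shared transitions {12, 23} of max 4 transitions
  expect_equal(similarity_index("12345", "12354"), 0.5)
  # length enters through the denominator
  expect_equal(similarity_index("12345", "1234"), 3 / 4)
  expect_equal(similarity_index(c(1, 2, 1, 2), c(1, 2)), 1 / 3)

  set.seed(2)
  for (i in 1:20) {
    a <- sample(5, sample(3:8, 1), replace = TRUE)
    b <- sample(5, sample(3:8, 1), replace = TRUE)
    si <- similarity_index(a, b)
    expect_gte(si, 0); expect_lte(si, 1)
    expect_equal(si, similarity_index(b, a))
    expect_equal(similarity_index(a, a), 1)
  }
  # differing transition multisets stay below 1
  expect_lt(similarity_index("12345", "13245"), 1)
  expect_error(similarity_index(character(0), "12"), "empty")
})

test_that("transition counts accumulate directed flower-to-flower moves", {
  seqs <- list(c(1L, 2L, 3L, 4L, 1L),   # F1 -> F2 -> F3
               c(1L, 4L, 3L, 1L),       # F3 -> F2
               c(1L, 2L, 1L, 3L, 1L))   # nest-interrupted: no F1 -> F2 move
  tc <- transition_counts(seqs)
  expect_equal(tc$n_ij[tc$i == 1 & tc$j == 2], 1L)
  expect_equal(tc$n_ij[tc$i == 2 & tc$j == 3], 1L)
  expect_equal(tc$n_ji[tc$i == 2 & tc$j == 3], 1L)
  expect_error(transition_counts(seqs, window = 1:5), "window")
})

test_that("asymmetry index follows two-tailed binomial arithmetic", {
  balanced <- data.frame(i = 1:3, j = 2:4, n_ij = c(5, 4, 6),
                         n_ji = c(5, 4, 6))
  expect_equal(asymmetry_index(balanced)$value, 0)

  one <- data.frame(i = 1, j = 2, n_ij = 10, n_ji = 0)
  ai <- asymmetry_index(one)
  expect_equal(ai$value, -log(2 * 0.5^10), tolerance = 1e-12)
  expect_equal(ai$value, 6.238325, tolerance = 1e-6)

  # standardisation: duplicating every tested pair changes nothing
  two <- rbind(one, transform(one, i = 3, j = 4))
  expect_equal(asymmetry_index(two)$value, ai$value)

  # relabelling flowers leaves the index unchanged
  counts <- data.frame(i = c(1, 2), j = c(3, 4), n_ij = c(7, 2),
                       n_ji = c(1, 6))
  relab <- data.frame(i = c(4, 3), j = c(2, 1), n_ij = c(7, 2),
                      n_ji = c(1, 6))
  expect_equal(asymmetry_index(counts)$value, asymmetry_index(relab)$value)
  # exchanging direction in every pair (n -> N - n) is a symmetry
  flipped <- transform(counts, n_ij = n_ji, n_ji = n_ij)
  expect_equal(asymmetry_index(counts)$value, asymmetry_index(flipped)$value)

  # below the observation floor the index is undefined, not zero
  sparse <- data.frame(i = 1, j = 2, n_ij = 3, n_ji = 2)
  expect_true(is.na(asymmetry_index(sparse)$value))
  expect_equal(asymmetry_index(sparse)$n_pairs, 0L)
})

test_that("empirical p-values are calibrated rank statistics", {
  null <- as.numeric(1:1000)  # bouts-to-criterion style: smaller is quicker
  # an observation at the 70th-percentile-quickest position scores 0.3
  expect_equal(empirical_pvalue(null, 700.5), 0.3)
  # quicker than every model run: p = 1; slower than all: the floor
  expect_equal(empirical_pvalue(null, 0), 1)
  expect_equal(empirical_pvalue(null, 2000), 0.5 / 1000)
  # monotone in the observation's rank
  ps <- vapply(c(100.5, 300.5, 500.5, 900.5), empirical_pvalue,
               numeric(1), null = null)
  expect_true(all(diff(ps) < 0))
  # ties count one half
  expect_equal(empirical_pvalue(null, 700), (300 + 0.5) / 1000)
  # direction flag
  expect_equal(empirical_pvalue(null, 300.5, better_is_smaller = FALSE), 0.3)
  expect_warning(empirical_pvalue(1:50, 10), "fewer than 100")
})

test_that("cohort summaries report routes, revisits and milestones", {
  pent <- pentagon_field()
  co <- run_cohort(pent, model_params(2, 30), n_bees = 12, seed = 5)
  cs <- cohort_summaries(co)
  expect_equal(nrow(cs$per_bee), 12L)
  expect_equal(nrow(cs$revisits_by_bout), 30L)
  expect_true(all(cs$per_bee$distinct_routes >= 1))
  expect_true(all(diff(cs$fractions_by_bout$frac_stable) >= 0))
  expect_equal(sum(cs$visit_frequency$freq), 1)

  # a locked bee repeats one route: a single distinct route in the window
  arr <- random_uniform_array(5, 10, seed = 21)
  r <- run_bee(arr, model_params(100, 40, rng_seed = 3))
  cs1 <- cohort_summaries(list(r), window = 31:40)
  expect_lte(cs1$per_bee$distinct_routes, 2L)

  # revisits decline with experience on the pentagon
  co2 <- run_cohort(pent, model_params(2, 65), n_bees = 60, seed = 8)
  cs2 <- cohort_summaries(co2)
  early <- mean(cs2$revisits_by_bout$mean_revisits[1:10])
  late <- mean(cs2$revisits_by_bout$mean_revisits[56:65])
  expect_gte(early, late)
})
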