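test_that("initial transition table follows the inverse-square prior", {
  # two targets at equal distance share the probability equally
  sym <- flower_array(c(0, 0), rbind(c(1, 0), c(-1, 0)))
  tab <- init_transition_table(sym)
  expect_equal(unname(tab[1, 2:3]), c(0.5, 0.5))
  expect_equal(unname(diag(tab)), rep(0, 3))
  expect_equal(unname(rowSums(tab)), rep(1, 3))

  # pentagon with nest at the centroid: hand arithmetic from the closed-form
  # geometry (side s, diagonal s*phi, circumradius s / (2 sin 36 deg))
  pent <- regular_polygon_array(5, 5)
  tab <- init_transition_table(pent)
  w_side <- 1 / 25
  w_diag <- 1 / (5 * (1 + sqrt(5)) / 2)^2
  w_nest <- 1 / (5 / (2 * sin(pi / 5)))^2
  p_side <- w_side / (2 * w_side + 2 * w_diag + w_nest)
  expect_equal(unname(tab[2, 3]), p_side, tolerance = 1e-12)
  expect_equal(p_side, 0.2412023, tolerance = 1e-6)

  # normalised inverse-square weights are scale invariant
  big <- regular_polygon_array(5, 50)
  expect_equal(unname(unclass(init_transition_table(big))),
               unname(unclass(tab)), tolerance = 1e-12)

  # the reward boost reshapes only the nest row
  pair <- flower_array(c(0, 0), rbind(c(2, 0), c(0, 2), c(0, 2)),
                       colocated = cbind(2, 3))
  t1 <- init_transition_table(pair, model_params())
  t2 <- init_transition_table(pair, model_params(reward_priority_boost = 3))
  expect_equal(unclass(t1)[-1, ], unclass(t2)[-1, ])
  expect_gt(t2[1, 3], t1[1, 3])
  expect_equal(unname(rowSums(t2)), rep(1, 4))
})

test_that("bout simulation follows the table and the termination rules", {
  one <- flower_array(c(0, 0), rbind(c(3, 4)))
  set.seed(1)
  b <- simulate_bout(init_transition_table(one), one)
  expect_equal(b$sequence, c(1L, 2L, 1L))
  expect_equal(b$length, 10)
  expect_true(b$qualifying)
  expect_equal(b$revisits, 0L)

  # a table that deterministically walks a Hamiltonian cycle reproduces it
  tri <- regular_polygon_array(3, 1, nest_at = c(0, 1))
  cyc <- matrix(0, 4, 4)
  cyc[1, 2] <- 1; cyc[2, 3] <- 1; cyc[3, 4] <- 1; cyc[4, 1] <- 1
  class(cyc) <- class(init_transition_table(tri))
  set.seed(1)
  b <- simulate_bout(cyc, tri)
  expect_equal(b$sequence, c(1L, 2L, 3L, 4L, 1L))
  expect_equal(b$length, route_length(tri, 1:3))
  expect_equal(b$skeleton, 1:3)
})

test_that("mean flower visits match the absorbing-chain oracle", {
  arr <- random_uniform_array(3, 1, seed = 8)
  params <- model_params(enhancement_factor = 1, n_bouts = 100000)
  tab <- unclass(init_transition_table(arr, params))
  n <- 3L; crop <- 3L

  # exact expected flower visits per bout by absorbing-Markov-chain
  # arithmetic over (current flower, visited set) states; the nest absorbs
  subsets <- lapply(1:(2^n - 1), function(m) which(bitwAnd(m, 2^(0:(n - 1))) > 0))
  E <- new.env()
  key <- function(i, S) paste(i, paste(sort(S), collapse = ","))
  for (size in seq(crop - 1, 1)) {
    for (S in subsets[vapply(subsets, length, 1L) == size]) {
      memb <- S
      A <- diag(length(memb)); bvec <- numeric(length(memb))
      for (ii in seq_along(memb)) {
        i <- memb[ii]
        for (j in seq_len(n)) {
          p <- tab[i + 1L, j + 1L]
          if (p == 0) next
          if (j %in% memb) {             # revisit within the same set
            bvec[ii] <- bvec[ii] + p
            A[ii, which(memb == j)] <- A[ii, which(memb == j)] - p
          } else {                       # new flower
            S2 <- sort(c(S, j))
            cont <- if (length(S2) == crop) 0 else get(key(j, S2), envir = E)
            bvec[ii] <- bvec[ii] + p * (1 + cont)
          }
        }
      }
      sol <- solve(A, bvec)
      for (ii in seq_along(memb)) assign(key(memb[ii], S), sol[ii], envir = E)
    }
  }
  e0 <- 0
  for (j in seq_len(n)) {
    p <- tab[1L, j + 1L]
    cont <- if (crop == 1L) 0 else get(key(j, j), envir = E)
    e0 <- e0 + p * (1 + cont)
  }

  run <- run_bee(arr, model_params(enhancement_factor = 1, n_bouts = 100000,
                                   rng_seed = 5),
                 l_opt = NA, keep_sequences = FALSE)
  expect_lt(abs(mean(run$bouts$n_distinct + run$bouts$revisits) - e0) / e0,
            0.01)
})

test_that("reinforcement multiplies route vectors and renormalises rows", {
  # nest row engineered to the weights (0.5, 0.3, 0.2)
  d <- 1 / sqrt(c(0.5, 0.3, 0.2))
  ang <- c(0, pi / 2, pi)
  arr <- flower_array(c(0, 0), cbind(d * cos(ang), d * sin(ang)))
  tab <- init_transition_table(arr)
  expect_equal(unname(tab[1, ]), c(0, 0.5, 0.3, 0.2))

  bout <- structure(list(skeleton = 2L, sequence = c(1L, 3L, 1L),
                         route_length = 2 * d[2], length = 2 * d[2],
                         n_distinct = 1L, revisits = 0L, capped = FALSE,
                         qualifying = TRUE, crop = 1L),
                    class = "bout")
  upd <- reinforce(tab, bout, Inf, model_params(enhancement_factor = 2))
  expect_true(upd$reinforced)
  expect_equal(unname(upd$table[1, ]), c(0, 0.5, 0.6, 0.2) / 1.3,
               tolerance = 1e-12)
  expect_equal(unname(rowSums(upd$table)), rep(1, 4))

  # the identity factor is a bit-exact no-op
  upd1 <- reinforce(tab, bout, Inf, model_params(enhancement_factor = 1))
  expect_identical(unclass(upd1$table), unclass(tab))

  # a longer route than the best so far is not reinforced
  upd2 <- reinforce(tab, bout, bout$route_length / 2, model_params(2))
  expect_false(upd2$reinforced)
  expect_identical(unclass(upd2$table), unclass(tab))

  # repeated reinforcement drives the route's probability monotonically up
  cur <- tab
  prev <- cur[1, 3]
  for (i in 1:50) {
    cur <- reinforce(cur, bout, Inf, model_params(2))$table
    expect_gt(cur[1, 3], prev)
    prev <- cur[1, 3]
  }
  expect_gt(cur[1, 3], 0.999)

  # qualification contract
  expect_true(qualifies_for_comparison(bout))
  expect_false(qualifies_for_comparison(
    structure(list(capped = TRUE, n_distinct = 1L, crop = 1L),
              class = "bout")))
  expect_true(qualifies_for_comparison(
    structure(list(capped = FALSE, n_distinct = 4L, crop = 4L),
              class = "bout")))
  expect_false(qualifies_for_comparison(
    structure(list(capped = FALSE, n_distinct = 3L, crop = 5L),
              class = "bout")))
})

test_that("compiled and pure-R runs are identical on the same RNG stream", {
  pent <- pentagon_field()
  p <- model_params(2, 20, rng_seed = 42)
  a <- run_bee(pent, p)
  b <- run_bee(pent, p, use_compiled = FALSE)
  expect_identical(a$sequences, b$sequences)
  expect_equal(a$bouts, b$bouts)
  expect_equal(as.numeric(a$table), as.numeric(b$table))
  expect_identical(a$stability_bout, b$stability_bout)
  expect_identical(a$first_optimal, b$first_optimal)
  expect_equal(a$l_best, b$l_best)

  arr <- random_uniform_array(6, 10, seed = 4)
  p <- model_params(1.5, 25, crop_capacity = 3, rng_seed = 7)
  a <- run_bee(arr, p)
  b <- run_bee(arr, p, use_compiled = FALSE)
  expect_identical(a$sequences, b$sequences)
  expect_equal(a$bouts, b$bouts)
  expect_equal(as.numeric(a$table), as.numeric(b$table))
})

test_that("runs track the shortest route and the optimality milestones", {
  p0 <- model_params(2, 0)
  empty <- run_bee(pentagon_field(), p0)
  expect_equal(nrow(empty$bouts), 0L)
  expect_true(is.na(empty$l_best))
  expect_true(is.na(empty$first_optimal))

  for (s in 1:5) {
    arr <- random_uniform_array(7, 20, seed = 50 + s)
    r <- run_bee(arr, model_params(2, 40, rng_seed = s))
    q <- r$bouts$qualifying
    # the tracked best equals an independent recomputation from sequences
    skl <- vapply(r$sequences[q], function(sq) {
      fl <- sq[sq > 1L] - 1L
      route_length(arr, fl[!duplicated(fl)])
    }, numeric(1))
    expect_equal(r$l_best, min(skl))
    expect_equal(min(r$bouts$route_length[q]), r$l_best)
    # rows of the final table sum to one after all reinforcements
    expect_equal(unname(rowSums(r$table)), rep(1, 8), tolerance = 1e-9)
    # stability cannot precede the first optimal bout
    if (!is.na(r$stability_bout))
      expect_gte(r$stability_bout, r$first_optimal)
  }
})

test_that("lengths are scale equivariant, probabilities scale invariant", {
  arr <- random_uniform_array(6, 10, seed = 9)
  big <- flower_array(arr$nest * 3, arr$flowers * 3)
  p <- model_params(2, 30, rng_seed = 13)
  a <- run_bee(arr, p)
  b <- run_bee(big, p)
  expect_identical(a$sequences, b$sequences)
  expect_equal(b$bouts$length, 3 * a$bouts$length)
  expect_equal(b$l_best, 3 * a$l_best)
  expect_equal(as.numeric(a$table), as.numeric(b$table))
  expect_identical(a$stability_bout, b$stability_bout)
})

test_that("a very large factor locks the bee onto its best route", {
  arr <- random_uniform_array(5, 10, seed = 21)
  r <- run_bee(arr, model_params(100, 40, rng_seed = 3))
  skels <- vapply(r$sequences[31:40], function(s) {
    fl <- s[s > 1L] - 1L
    paste(fl[!duplicated(fl)], collapse = ",")
  }, "")
  # the final ten bouts repeat a single locked skeleton almost exclusively
  expect_gte(max(table(skels)), 9L)
})

test_that("cohorts derive seeds deterministically and summarise correctly", {
  pent <- pentagon_field()
  co1 <- run_cohort(pent, model_params(2, 20), n_bees = 5, seed = 99)
  co2 <- run_cohort(pent, model_params(2, 20), n_bees = 5, seed = 99)
  expect_equal(co1$summary, co2$summary)
  expect_identical(co1$runs[[3]]$sequences, co2$runs[[3]]$sequences)

  single <- run_cohort(pent, model_params(2, 20), n_bees = 1, seed = 7)
  r <- single$runs[[1]]
  expect_equal(single$summary$frac_found_optimal,
               as.numeric(!is.na(r$first_optimal)))
  expect_equal(single$summary$mean_ratio, r$l_best / r$l_opt)
  expect_gte(single$summary$mean_ratio, 1)
  # cumulative stabilisation can only grow
  expect_true(all(diff(co1$summary$frac_stable_by_bout) >= 0))
})
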