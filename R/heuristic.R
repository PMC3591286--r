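#' Simulation parameters for the traplining heuristic
#'
#' The model bee's behaviour is governed by a handful of parameters. The
#' transition probability between two locations is initialised in inverse
#' proportion to their squared separation (`distance_exponent = 2`) and
#' normalised per origin, so that the next move from any location is a proper
#' categorical draw. After a qualifying bout whose route -- the nest-to-nest
#' circuit over flowers in first-visit order, net of revisit detours -- is no
#' longer than the shortest route experienced so far, each directed
#' transition of that route is multiplied by `enhancement_factor` and the
#' affected rows are renormalised; repeating a short route therefore
#' reinforces it. Larger factors correspond to stronger motivation to
#' optimise and are associated with larger spatial scales (roughly 1.1 in
#' metre-scale flight rooms, 1.5-4 at field scales of tens of metres).
#'
#' @param enhancement_factor multiplicative reinforcement factor f >= 1.
#' @param n_bouts number of consecutive foraging bouts to simulate.
#' @param crop_capacity distinct rewarding flowers needed to fill the crop;
#'   `NULL` (default) means all flowers in the array.
#' @param distance_exponent exponent of the inverse-distance prior.
#' @param reward_priority_boost multiplier applied to the initial
#'   nest-to-high-reward-flower probabilities before row renormalisation.
#' @param max_transitions_per_bout safety cap on sampled transitions per
#'   bout; `NULL` means `20 * n_flowers`. Capped bouts are closed via the
#'   nest, flagged incomplete, and never qualify for comparison.
#' @param rng_seed optional integer seed applied at the start of [run_bee()].
#' @return an object of class `model_params`.
#' @export
model_params <- function(enhancement_factor = 2, n_bouts = 65,
                         crop_capacity = NULL, distance_exponent = 2,
                         reward_priority_boost = 1,
                         max_transitions_per_bout = NULL, rng_seed = NULL) {
  if (!is.numeric(enhancement_factor) || enhancement_factor < 1)
    stop("`enhancement_factor` must be >= 1")
  if (n_bouts < 0) stop("`n_bouts` must be non-negative")
  if (!is.null(crop_capacity) && crop_capacity < 1)
    stop("`crop_capacity` must be at least 1")
  if (reward_priority_boost <= 0)
    stop("`reward_priority_boost` must be positive")
  structure(list(enhancement_factor = enhancement_factor,
                 n_bouts = as.integer(n_bouts),
                 crop_capacity = if (is.null(crop_capacity)) NULL else
                   as.integer(crop_capacity),
                 distance_exponent = distance_exponent,
                 reward_priority_boost = reward_priority_boost,
                 max_transitions_per_bout =
                   if (is.null(max_transitions_per_bout)) NULL else
                     as.integer(max_transitions_per_bout),
                 rng_seed = rng_seed),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params> f =", x$enhancement_factor, "| bouts =", x$n_bouts,
      "| crop =", if (is.null(x$crop_capacity)) "all flowers" else
        x$crop_capacity,
      "| boost =", x$reward_priority_boost, "\n")
  invisible(x)
}

# resolve array-dependent defaults; validates crop and cap against the array
resolve_params <- function(params, array) {
  n <- n_flowers(array)
  crop <- if (is.null(params$crop_capacity)) n else params$crop_capacity
  if (crop > n) stop("`crop_capacity` exceeds the number of flowers")
  cap <- if (is.null(params$max_transitions_per_bout)) 20L * n else
    params$max_transitions_per_bout
  if (cap < n + 2L)
    stop("`max_transitions_per_bout` must be at least n_flowers + 2")
  list(crop = as.integer(crop), cap = as.integer(cap))
}

#' Initial transition probability table
#'
#' Builds the bee's prior over transition vectors: the weight of moving from
#' location i to location j is `1 / d(i,j)^distance_exponent`, the nest being
#' an ordinary location. Self transitions carry zero probability. Transitions
#' within a co-located flower pair (one site holding a double reward) are
#' assigned the weight of the closest distinct pair of locations, keeping the
#' zero-length hop likely but not absorbing and the prior finite.
#' Nest-to-high-reward entries are multiplied by `reward_priority_boost`;
#' each origin row is then normalised to sum to one. The table is invariant
#' under rescaling all coordinates.
#'
#' @param array a [flower_array()].
#' @param params a [model_params()].
#' @return an (n+1) x (n+1) matrix of class `transition_table`, rows = origin.
#' @export
init_transition_table <- function(array, params = model_params()) {
  d <- array$dist
  m <- nrow(d)
  w <- matrix(0, m, m, dimnames = dimnames(d))
  off <- d > 0
  w[off] <- 1 / d[off]^params$distance_exponent
  if (!is.null(array$colocated) && nrow(array$colocated) > 0) {
    # a co-located pair is one perception site holding a double reward: the
    # zero-length hop between its members gets the weight of the tightest
    # real neighbour pair, keeping the inverse-power prior finite without
    # making the pair absorbing
    dpos <- d[d > 0]
    w_pair <- 1 / min(dpos)^params$distance_exponent
    for (r in seq_len(nrow(array$colocated))) {
      i <- array$colocated[r, 1] + 1L
      j <- array$colocated[r, 2] + 1L
      w[i, j] <- w_pair; w[j, i] <- w_pair
    }
  }
  if (length(array$high_reward) > 0)
    w[1, array$high_reward + 1L] <-
      w[1, array$high_reward + 1L] * params$reward_priority_boost
  if (any(!is.finite(w)))
    stop("zero distance between locations that are not a co-located pair")
  tab <- w / rowSums(w)
  class(tab) <- c("transition_table", "matrix", "array")
  tab
}

# defensive check used by the R sampling path
check_table <- function(table) {
  rs <- rowSums(table)
  if (any(abs(rs - 1) > 1e-9))
    stop("transition table rows must sum to 1")
  if (any(table < 0)) stop("negative transition probabilities")
  invisible(TRUE)
}

# one categorical draw, accumulating in row order exactly as the compiled
# path does so both paths consume the same RNG stream identically
sample_transition <- function(row) {
  u <- runif(1)
  acc <- 0
  for (j in seq_along(row)) {
    acc <- acc + row[j]
    if (u < acc) return(j)
  }
  for (j in rev(seq_along(row))) if (row[j] > 0) return(j)
  stop("degenerate transition row: no positive probabilities")
}

#' Simulate a single foraging bout
#'
#' The bee starts at the nest and repeatedly samples its next location from
#' the current origin's row of the transition table. Sampling the nest
#' vector ends the bout: early in learning a bee can head home before its
#' crop is full, producing a complete but non-qualifying bout that visited
#' fewer than all flowers. Once `crop_capacity` distinct flowers have been
#' visited the bee flies straight back to the nest (forced return). Revisits
#' to already emptied flowers are permitted and recorded. If the transition
#' cap is reached first the bout is closed via the nest and flagged `capped`.
#'
#' @param table a [init_transition_table()] output (possibly reinforced).
#' @param array the [flower_array()] the table was built from.
#' @param params a [model_params()].
#' @return an object of class `bout`: list with `sequence` (location indices,
#'   1 = nest), `flower_sequence` (flower indices), `length` (metres),
#'   `n_flower_visits`, `n_distinct`, `revisits`, `early_return`,
#'   `qualifying`, `capped` and `crop`.
#' @export
simulate_bout <- function(table, array, params = model_params()) {
  check_table(table)
  res <- resolve_params(params, array)
  d <- array$dist
  m <- nrow(d)
  cur <- 1L
  seq_ <- 1L
  visited <- logical(m)
  distinct <- 0L; revis <- 0L; steps <- 0L
  L <- 0
  capped <- FALSE; returned <- FALSE
  while (distinct < res$crop) {
    if (steps >= res$cap) { capped <- TRUE; break }
    nxt <- sample_transition(table[cur, ])
    L <- L + d[cur, nxt]
    seq_ <- c(seq_, nxt)
    cur <- nxt
    steps <- steps + 1L
    if (nxt == 1L) { returned <- TRUE; break }
    if (!visited[nxt]) {
      visited[nxt] <- TRUE
      distinct <- distinct + 1L
    } else revis <- revis + 1L
  }
  if (cur != 1L) {
    L <- L + d[cur, 1L]
    seq_ <- c(seq_, 1L)
  }
  fl <- seq_[seq_ > 1L] - 1L
  skel <- fl[!duplicated(fl)]
  structure(list(sequence = seq_,
                 flower_sequence = fl,
                 skeleton = skel,
                 length = L,
                 route_length = if (length(skel) > 0L)
                   route_length(array, skel) else NA_real_,
                 n_flower_visits = distinct + revis,
                 n_distinct = distinct, revisits = revis,
                 early_return = returned && distinct < res$crop,
                 qualifying = !capped && distinct >= res$crop,
                 capped = capped,
                 crop = res$crop),
            class = "bout")
}

#' Does a bout qualify for route comparison?
#'
#' A bout participates in the length comparison (and can therefore be
#' reinforced) only if it filled the crop, i.e. visited at least
#' `crop_capacity` distinct flowers before being capped.
#'
#' @param bout a [simulate_bout()] result.
#' @param crop crop capacity to test against; defaults to the capacity the
#'   bout was simulated with.
#' @return logical flag.
#' @export
qualifies_for_comparison <- function(bout, crop = bout$crop) {
  !bout$capped && bout$n_distinct >= crop
}

#' Reinforce the transitions of a qualifying route
#'
#' If the net length of the bout's route -- the nest-to-nest circuit over its
#' trapline skeleton, net of revisit detours -- does not exceed the shortest
#' net route length experienced so far (ties reinforce, so repeating the
#' shortest route reinforces it), every directed transition of that route,
#' including the return to the nest, has its probability multiplied by the
#' enhancement factor, after which each affected origin row is renormalised.
#' Otherwise the table is returned unchanged. With `enhancement_factor = 1`
#' reinforcement is an exact no-op. `route = "traversed"` instead compares
#' the full travelled length and reinforces every transition sampled during
#' the bout (an exploratory variant; see the package vignette).
#'
#' @param table current transition table.
#' @param bout a qualifying [simulate_bout()] result.
#' @param l_best shortest net route length experienced so far (`Inf` before
#'   the first qualifying bout, so the first one always reinforces).
#' @param params a [model_params()].
#' @param route which memory of the bout is reinforced and compared.
#' @return list with elements `table`, `l_best` and `reinforced`.
#' @export
reinforce <- function(table, bout, l_best = Inf, params = model_params(),
                      route = c("skeleton", "traversed")) {
  route <- match.arg(route)
  cmp <- if (route == "skeleton") bout$route_length else bout$length
  if (!qualifies_for_comparison(bout) || cmp > l_best)
    return(list(table = table, l_best = l_best, reinforced = FALSE))
  s <- if (route == "skeleton") c(1L, bout$skeleton + 1L, 1L) else
    bout$sequence
  if (length(s) >= 2L) {
    edges <- unique(cbind(s[-length(s)], s[-1L]))
    table[edges] <- table[edges] * params$enhancement_factor
    rows <- unique(edges[, 1L])
    table[rows, ] <- table[rows, , drop = FALSE] /
      rowSums(table[rows, , drop = FALSE])
  }
  list(table = table, l_best = cmp, reinforced = TRUE)
}

#' Run one model bee over consecutive foraging bouts
#'
#' Executes `n_bouts` of [simulate_bout()] plus [reinforce()] from a fresh
#' [init_transition_table()]. Flowers replenish between bouts; memory (the
#' table and the shortest net route length experienced) carries across bouts
#' without overnight loss. Each bout's remembered route is its trapline
#' skeleton -- the nest-to-nest circuit over flowers in first-visit order,
#' net of revisit detours. When an exact optimal circuit length is available
#' (supplied via `l_opt` or computed by the oracle for tractable sizes) the
#' run records the first optimal bout and the stability bout: a bout is
#' optimal when its skeleton forms a circuit of the oracle's optimal length
#' (direction-insensitive, since a closed circuit and its reversal have
#' identical length). Stability is reached at the third of three consecutive
#' *identical* optimal visitation orders (a trapline has a habitual
#' direction, so reversals are not merged there).
#'
#' @param array a [flower_array()].
#' @param params a [model_params()]; its `rng_seed`, when non-`NULL`, seeds
#'   the run.
#' @param l_opt exact optimal circuit length for the crop. `NULL` asks the
#'   oracle ([optimal_circuit()] or [best_subset_circuit()]) when the size is
#'   tractable; `NA` disables optimality bookkeeping.
#' @param use_compiled use the compiled core (default) or the pure-R
#'   reference path; both consume the RNG stream identically.
#' @param keep_sequences store every bout's visit sequence.
#' @param route_memory `"skeleton"` (the model's route memory, default) or
#'   `"traversed"`: compare and reinforce the full travelled walk instead
#'   (exploratory variant, documented in the vignette).
#' @return an object of class `bee_run`: list with `bouts` (one data frame
#'   row per bout, including travelled `length` and net `route_length`),
#'   `sequences`, `l_best` (shortest net route length), `best_bout`,
#'   `best_sequence`, `first_optimal`, `stability_bout`, `l_opt`, `table`
#'   (final state) and `n_flowers`.
#' @export
run_bee <- function(array, params = model_params(), l_opt = NULL,
                    use_compiled = TRUE, keep_sequences = TRUE,
                    route_memory = c("skeleton", "traversed")) {
  route_memory <- match.arg(route_memory)
  res <- resolve_params(params, array)
  n <- n_flowers(array)
  if (is.null(l_opt)) {
    l_opt <- if (res$crop == n && n <= 15L) {
      optimal_circuit(array)$length
    } else if (res$crop < n && n <= 12L) {
      best_subset_circuit(array, res$crop)$length
    } else NA_real_
  }
  if (!is.null(params$rng_seed)) set.seed(params$rng_seed)
  tab0 <- init_transition_table(array, params)
  opt_tol <- 1e-9

  if (use_compiled) {
    out <- run_bee_cpp(array$dist, unclass(tab0), params$enhancement_factor,
                       params$n_bouts, res$crop, res$cap,
                       if (is.na(l_opt)) NA_real_ else l_opt, opt_tol,
                       keep_sequences, route_memory == "skeleton")
  } else {
    out <- run_bee_r(array, params, tab0, res, l_opt, opt_tol, keep_sequences,
                     route_memory)
  }

  bouts <- data.frame(bout = seq_len(params$n_bouts),
                      length = as.numeric(out$length),
                      route_length = as.numeric(out$route_length),
                      n_distinct = as.integer(out$n_distinct),
                      revisits = as.integer(out$revisits),
                      early_return = as.logical(out$early_return),
                      qualifying = as.logical(out$qualifying),
                      capped = as.logical(out$capped),
                      optimal = as.logical(out$optimal))
  structure(list(bouts = bouts, sequences = out$sequences,
                 l_best = out$l_best,
                 best_bout = na_int(out$best_bout),
                 best_sequence = out$best_sequence,
                 first_optimal = na_int(out$first_optimal),
                 stability_bout = na_int(out$stability_bout),
                 l_opt = l_opt, table = out$table, n_flowers = n,
                 params = params),
            class = "bee_run")
}

na_int <- function(x) if (is.null(x) || length(x) == 0) NA_integer_ else
  as.integer(x)

# pure-R mirror of the compiled per-bout loop; used for cross-validation
run_bee_r <- function(array, params, tab0, res, l_opt, opt_tol,
                      keep_sequences, route_memory = "skeleton") {
  table <- unclass(tab0)
  nb <- params$n_bouts
  lengths <- numeric(nb); rlengths <- numeric(nb)
  distinct <- integer(nb); revisits <- integer(nb)
  early <- logical(nb); qual <- logical(nb); capped <- logical(nb)
  optimal <- logical(nb)
  sequences <- if (keep_sequences) vector("list", nb) else NULL
  l_best <- Inf; best_bout <- NA_integer_; best_seq <- integer(0)
  first_opt <- NA_integer_; stab <- NA_integer_
  prev_skel <- NULL; prev_opt <- FALSE; run <- 0L
  have_opt <- !is.na(l_opt)

  for (b in seq_len(nb)) {
    bout <- simulate_bout(table, array, params)
    lengths[b] <- bout$length; rlengths[b] <- bout$route_length
    distinct[b] <- bout$n_distinct
    revisits[b] <- bout$revisits; early[b] <- bout$early_return
    qual[b] <- bout$qualifying; capped[b] <- bout$capped
    opt <- bout$qualifying && have_opt && !is.na(bout$route_length) &&
      bout$route_length <= l_opt * (1 + opt_tol)
    optimal[b] <- opt
    cmp <- if (route_memory == "skeleton") bout$route_length else bout$length
    if (bout$qualifying && cmp <= l_best) {
      upd <- reinforce(table, bout, l_best, params, route = route_memory)
      table <- upd$table
      if (cmp < l_best || is.na(best_bout)) {
        best_bout <- b
        best_seq <- bout$sequence
      }
      l_best <- cmp
    }
    if (opt && is.na(first_opt)) first_opt <- b
    if (opt) {
      same <- prev_opt && identical(prev_skel, bout$skeleton)
      run <- if (same) run + 1L else 1L
      if (run >= 3L && is.na(stab)) stab <- b
    } else run <- 0L
    prev_skel <- bout$skeleton; prev_opt <- opt
    if (keep_sequences) sequences[[b]] <- bout$sequence
  }
  list(length = lengths, route_length = rlengths, n_distinct = distinct,
       revisits = revisits,
       early_return = early, qualifying = qual, capped = capped,
       optimal = optimal, sequences = sequences,
       l_best = if (is.finite(l_best)) l_best else NA_real_,
       best_bout = best_bout, best_sequence = best_seq,
       first_optimal = first_opt, stability_bout = stab, table = table)
}

#' @export
print.bee_run <- function(x, ...) {
  nb <- nrow(x$bouts)
  cat("<bee_run>", nb, "bouts over", x$n_flowers, "flowers\n")
  cat("  shortest qualifying route:",
      if (is.na(x$l_best)) "none" else
        paste0(format(x$l_best, digits = 6), " m (bout ", x$best_bout, ")"),
      "\n")
  if (!is.na(x$l_opt))
    cat("  optimal circuit ", format(x$l_opt, digits = 6), " m; first optimal bout: ",
        ifelse(is.na(x$first_optimal), "never", x$first_optimal),
        "; stability bout: ",
        ifelse(is.na(x$stability_bout), "never", x$stability_bout), "\n",
        sep = "")
  invisible(x)
}

#' Run an independent cohort of model bees
#'
#' Runs `n_bees` independent bees on the same array with deterministically
#' derived per-bee seeds, so that cohorts are reproducible and independent of
#' evaluation order. Summary statistics follow the quantities used in the
#' simulation experiments: per-bout fractions of optimal and stabilised
#' bees, mean best-length-to-optimum ratio, and the capped-bout rate (a
#' pathology indicator).
#'
#' @param array a [flower_array()].
#' @param params a [model_params()].
#' @param n_bees cohort size (>= 1).
#' @param seed integer master seed for the cohort.
#' @param l_opt optimal length passed through to [run_bee()]; computed once
#'   for the whole cohort when `NULL` and tractable.
#' @param keep_sequences store per-bout visit sequences for every bee.
#' @return an object of class `bee_cohort`: list with `runs`, `summary`
#'   (list of per-bout and cohort-level statistics), `l_opt` and `params`.
#' @export
run_cohort <- function(array, params = model_params(), n_bees = 100,
                       seed = NULL, l_opt = NULL, keep_sequences = TRUE) {
  if (n_bees < 1) stop("`n_bees` must be at least 1")
  res <- resolve_params(params, array)
  n <- n_flowers(array)
  if (is.null(l_opt)) {
    l_opt <- if (res$crop == n && n <= 15L) {
      optimal_circuit(array)$length
    } else if (res$crop < n && n <= 12L) {
      best_subset_circuit(array, res$crop)$length
    } else NA_real_
  }
  if (!is.null(seed)) set.seed(seed)
  bee_seeds <- sample.int(.Machine$integer.max, n_bees)
  runs <- lapply(seq_len(n_bees), function(i) {
    p <- params
    p$rng_seed <- bee_seeds[i]
    run_bee(array, p, l_opt = l_opt, keep_sequences = keep_sequences)
  })

  nb <- params$n_bouts
  opt_mat <- vapply(runs, function(r) r$bouts$optimal, logical(nb))
  stab <- vapply(runs, function(r) r$stability_bout, integer(1))
  first_opt <- vapply(runs, function(r) r$first_optimal, integer(1))
  l_best <- vapply(runs, function(r) r$l_best, numeric(1))
  capped_rate <- mean(vapply(runs, function(r) mean(r$bouts$capped),
                             numeric(1)))
  frac_stable_by_bout <- if (nb > 0)
    vapply(seq_len(nb), function(b) mean(!is.na(stab) & stab <= b),
           numeric(1)) else numeric(0)
  summary <- list(
    n_bees = n_bees,
    frac_optimal_by_bout = if (nb > 0) rowMeans(matrix(opt_mat, nrow = nb))
      else numeric(0),
    frac_stable_by_bout = frac_stable_by_bout,
    frac_found_optimal = mean(!is.na(first_opt)),
    frac_stable = mean(!is.na(stab)),
    mean_l_best = mean(l_best, na.rm = TRUE),
    mean_ratio = if (!is.na(l_opt)) mean(l_best / l_opt, na.rm = TRUE) else
      NA_real_,
    capped_rate = capped_rate)
  structure(list(runs = runs, summary = summary, l_opt = l_opt,
                 params = params, seed = seed),
            class = "bee_cohort")
}

#' @export
print.bee_cohort <- function(x, ...) {
  s <- x$summary
  cat("<bee_cohort>", s$n_bees, "bees x", x$params$n_bouts, "bouts\n")
  if (!is.na(x$l_opt))
    cat("  found optimal:", format(s$frac_found_optimal, digits = 3),
        "| stabilised:", format(s$frac_stable, digits = 3),
        "| mean L/Lmin:", format(s$mean_ratio, digits = 4), "\n")
  cat("  capped-bout rate:", format(s$capped_rate, digits = 3), "\n")
  invisible(x)
}
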