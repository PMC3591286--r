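#' Length of a nest-to-nest circuit
#'
#' @param array a [flower_array()].
#' @param order integer vector of flower indices giving the visit order.
#' @param from_nest include the nest-to-first and last-to-nest legs.
#' @return circuit length in metres.
#' @export
route_length <- function(array, order, from_nest = TRUE) {
  d <- array$dist
  loc <- c(if (from_nest) 1L, order + 1L, if (from_nest) 1L)
  sum(d[cbind(loc[-length(loc)], loc[-1L])])
}

# all permutations of 1..k as a (k!) x k integer matrix, built by insertion
# and memoised (the same index matrix serves every instance of a given size)
perm_matrix <- function(k) {
  key <- paste0("perm", k)
  if (!is.null(.traplinesim_env[[key]])) return(.traplinesim_env[[key]])
  m <- matrix(1L, 1L, 1L)
  if (k > 1L) for (n in 2:k) {
    blocks <- lapply(seq_len(n), function(pos) {
      left <- m[, seq_len(pos - 1L), drop = FALSE]
      right <- if (pos <= n - 1L) m[, pos:(n - 1L), drop = FALSE] else
        matrix(integer(0), nrow(m), 0L)
      cbind(left, n, right)
    })
    m <- do.call(rbind, blocks)
  }
  storage.mode(m) <- "integer"
  .traplinesim_env[[key]] <- m
  m
}

# lengths of every permutation circuit over `subset` (flower indices);
# vectorised over the permutation matrix
all_circuit_lengths <- function(array, subset) {
  k <- length(subset)
  pm <- perm_matrix(k)
  loc <- matrix(subset[pm] + 1L, nrow = nrow(pm))
  d <- array$dist
  m <- nrow(d)
  len <- d[1L, loc[, 1L]] + d[cbind(loc[, k], 1L)]
  if (k > 1L) for (i in seq_len(k - 1L))
    len <- len + d[(loc[, i + 1L] - 1L) * m + loc[, i]]
  list(perms = pm, loc = loc, lengths = len)
}

# canonical direction: the lexicographically smaller of a circuit order and
# its reversal (a closed circuit's length is direction invariant)
canonical_order <- function(order) {
  rev_ <- rev(order)
  for (i in seq_along(order)) {
    if (rev_[i] < order[i]) return(rev_)
    if (rev_[i] > order[i]) return(order)
  }
  order
}

new_optimal_route <- function(order, length, exact, method) {
  structure(list(order = as.integer(order), length = length, exact = exact,
                 method = method),
            class = "optimal_route")
}

#' @export
print.optimal_route <- function(x, ...) {
  cat("<optimal_route> nest -> ", paste(x$order, collapse = " -> "),
      " -> nest\n  length ", format(x$length, digits = 8), " m (",
      x$method, if (!x$exact) ", heuristic", ")\n", sep = "")
  invisible(x)
}

#' Exact shortest nest-to-nest circuit
#'
#' Computes the exact shortest circuit that leaves the nest, visits each
#' listed flower exactly once and returns to the nest. `"held_karp"` uses
#' dynamic programming over visited subsets (practical up to ~15 flowers);
#' `"brute"` enumerates all permutations (up to 9 flowers) and serves as an
#' independent cross-check of the dynamic program. Ties are broken
#' deterministically towards the lexicographically smallest order, with a
#' circuit and its reversal treated as the same route.
#'
#' @param array a [flower_array()].
#' @param subset optional integer vector of flower indices; default all.
#' @param method `"auto"` (Held-Karp), `"held_karp"` or `"brute"`.
#' @param allow_heuristic if the instance exceeds the exact limits, fall back
#'   to the nearest-neighbour construction (flagged `exact = FALSE`) instead
#'   of erroring.
#' @return an `optimal_route`: list with `order` (flower indices), `length`,
#'   `exact` and `method`.
#' @export
optimal_circuit <- function(array, subset = NULL,
                            method = c("auto", "held_karp", "brute"),
                            allow_heuristic = FALSE) {
  method <- match.arg(method)
  n <- n_flowers(array)
  if (is.null(subset)) subset <- seq_len(n)
  subset <- as.integer(subset)
  if (length(subset) < 1L || any(subset < 1L | subset > n))
    stop("invalid flower subset")
  k <- length(subset)
  if (method == "brute" || (method == "auto" && k <= 2L)) {
    if (k > 9L) stop("brute force limited to 9 flowers")
    res <- all_circuit_lengths(array, subset)
    best <- min(res$lengths)
    cand <- which(res$lengths <= best + 1e-9)
    orders <- lapply(cand, function(i)
      canonical_order(subset[res$perms[i, ]]))
    keys <- vapply(orders, function(o) paste(sprintf("%04d", o),
                                             collapse = ""), "")
    ord <- orders[[order(keys)[1L]]]
    return(new_optimal_route(ord, best, TRUE, "brute"))
  }
  if (k > 15L) {
    if (!allow_heuristic)
      stop(k, " flowers exceed the exact-computation limit; set ",
           "`allow_heuristic = TRUE` for a nearest-neighbour fallback")
    return(nearest_neighbour_circuit(array, subset))
  }
  hk <- held_karp_cpp(array$dist, subset + 1L)
  new_optimal_route(canonical_order(hk$order - 1L), hk$length, TRUE,
                    "held_karp")
}

#' Shortest circuit over the best subset of flowers
#'
#' For crop-limited foraging: minimises the exact circuit length over every
#' size-`subset_size` subset of the flowers, i.e. the shortest way to fill
#' the crop on `subset_size` distinct flowers and return to the nest.
#'
#' @param array a [flower_array()].
#' @param subset_size number of flowers needed to fill the crop.
#' @return an `optimal_route` whose `order` names the winning subset.
#' @export
best_subset_circuit <- function(array, subset_size) {
  n <- n_flowers(array)
  subset_size <- as.integer(subset_size)
  if (subset_size < 1L || subset_size > n)
    stop("`subset_size` must be between 1 and the number of flowers")
  if (n > 12L)
    stop("subset enumeration limited to 12 flowers")
  if (subset_size == n) {
    out <- optimal_circuit(array)
    out$method <- "best_subset"
    return(out)
  }
  subsets <- utils::combn(n, subset_size)
  best <- NULL
  for (s in seq_len(ncol(subsets))) {
    cand <- optimal_circuit(array, subsets[, s])
    if (is.null(best) || cand$length < best$length) best <- cand
  }
  best$method <- "best_subset"
  best
}

#' Nearest-neighbour (greedy) circuit
#'
#' The classic greedy baseline: from the nest, always fly to the closest
#' unvisited flower, then return to the nest once all are visited. Ties go to
#' the lowest flower index. Averaged over uniform-random arrays this
#' construction is the reference against which the learning heuristic's
#' route quality is compared.
#'
#' @param array a [flower_array()].
#' @param subset optional flower subset; default all flowers.
#' @return an `optimal_route` with `exact = FALSE`.
#' @export
nearest_neighbour_circuit <- function(array, subset = NULL) {
  n <- n_flowers(array)
  if (is.null(subset)) subset <- seq_len(n)
  d <- array$dist
  left <- as.integer(subset)
  cur <- 1L
  ord <- integer(0)
  len <- 0
  while (length(left) > 0L) {
    dd <- d[cur, left + 1L]
    nxt <- left[which.min(dd)]   # which.min takes the first = lowest index
    len <- len + d[cur, nxt + 1L]
    ord <- c(ord, nxt)
    cur <- nxt + 1L
    left <- setdiff(left, nxt)
  }
  len <- len + d[cur, 1L]
  new_optimal_route(ord, len, FALSE, "nearest_neighbour")
}

#' Can a route be shortened by transposing two flowers?
#'
#' Tests every pairwise transposition of positions in the visit order (all
#' pairs, not only adjacent ones) and reports whether any strictly shortens
#' the nest-to-nest circuit, e.g. turning the visitation sequence
#' 5-8-7-5-4-3-1 into 5-8-3-5-4-7-1 by exchanging the positions of flowers 3
#' and 7. An exactly optimal route is never improvable this way; the converse
#' does not hold -- transposition-stable routes can still be non-optimal --
#' which is why the statistic is only an upper-bound test of optimality for
#' instances too large for the exact oracles.
#'
#' @param route an `optimal_route`, a `bee_run` (its best sequence is used)
#'   or an integer vector of flower indices.
#' @param array the [flower_array()] the route lives on.
#' @param allow_repeats permit sequences that revisit flowers (positions are
#'   swapped verbatim). The default follows the strict route contract and
#'   rejects repeats.
#' @param tol minimum relative length decrease counted as an improvement.
#' @return list with `improvable` (flag), `positions` (best improving swap,
#'   or `NULL`), `improved_length` and `delta` (largest decrease found).
#' @export
pairwise_switch_improvable <- function(route, array, allow_repeats = FALSE,
                                       tol = 1e-9) {
  if (inherits(route, "optimal_route")) route <- route$order
  if (inherits(route, "bee_run")) {
    s <- route$best_sequence
    route <- s[s > 1L] - 1L
  }
  route <- as.integer(route)
  k <- length(route)
  if (k < 2L) stop("route must visit at least two flowers")
  if (anyDuplicated(route) && !allow_repeats)
    stop("route revisits a flower; set `allow_repeats = TRUE` to test it")
  base <- route_length(array, route)
  best_delta <- 0
  best_pair <- NULL
  best_len <- base
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      if (route[i] == route[j]) next
      cand <- route
      cand[c(i, j)] <- cand[c(j, i)]
      len <- route_length(array, cand)
      delta <- base - len
      if (delta > best_delta) {
        best_delta <- delta
        best_pair <- c(i, j)
        best_len <- len
      }
    }
  }
  improvable <- best_delta > tol * max(1, base)
  list(improvable = improvable,
       positions = if (improvable) best_pair else NULL,
       improved_length = if (improvable) best_len else base,
       delta = best_delta)
}
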