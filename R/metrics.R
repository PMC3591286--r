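as_visit_vector <- function(x) {
  if (is.character(x) && length(x) == 1L) x <- strsplit(x, "")[[1L]]
  x <- as.character(x)
  if (length(x) == 0L) stop("empty visit sequence")
  x
}

#' Similarity index between two visitation sequences
#'
#' Quantifies how much two flower visitation sequences agree, accounting for
#' both visit order and sequence length. The adopted convention (the original
#' formula being unpublished) counts ordered flower-to-flower transitions
#' shared between the two sequences, with multiplicity, and divides by the
#' larger of the two transition counts:
#' \deqn{SI(a, b) = |transitions(a) \cap transitions(b)| / \max(|a|-1, |b|-1)}
#' This is symmetric, lies in \[0, 1\], equals 0 for sequences with no shared
#' transition (e.g. 123 vs 456) and 1 for identical sequences (e.g. 12345 vs
#' 12345). Note that distinct sequences sharing their full transition multiset
#' (cyclic rotations) also score 1; see the package vignette. Alternative
#' formulas can be supplied via `transitions`.
#'
#' @param seq_a,seq_b visit sequences: vectors of flower labels/indices, or a
#'   single string of one-character labels (`"12345"`).
#' @param transitions optional function mapping a label vector to a vector of
#'   transition keys, for plugging in alternative conventions.
#' @return similarity in \[0, 1\].
#' @export
similarity_index <- function(seq_a, seq_b, transitions = NULL) {
  a <- as_visit_vector(seq_a)
  b <- as_visit_vector(seq_b)
  trans <- transitions %||% function(s)
    if (length(s) < 2L) character(0) else
      paste(s[-length(s)], s[-1L], sep = "\r")
  ta <- trans(a)
  tb <- trans(b)
  denom <- max(length(ta), length(tb))
  if (denom == 0L) return(as.numeric(identical(a, b)))
  shared <- 0L
  counts <- table(tb)
  for (key in names(table(ta)))
    if (key %in% names(counts))
      shared <- shared + min(sum(ta == key), counts[[key]])
  shared / denom
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Directed transition counts between flower pairs
#'
#' Accumulates, over a window of bouts, the number of moves from flower i to
#' flower j and from j to i for every unordered flower pair. Moves to or from
#' the nest are not flower-to-flower transitions and are excluded.
#'
#' @param x a `bee_run`, or a list of location sequences (integer vectors,
#'   1 = nest) as stored in a `bee_run`.
#' @param window integer range of bout indices to include; default all.
#' @return data frame with columns `i`, `j` (i < j), `n_ij`, `n_ji`; the
#'   window is recorded as an attribute.
#' @export
transition_counts <- function(x, window = NULL) {
  seqs <- if (inherits(x, "bee_run")) x$sequences else x
  if (is.null(seqs)) stop("no stored sequences; rerun with keep_sequences")
  if (is.null(window)) window <- seq_along(seqs)
  if (any(window < 1L | window > length(seqs)))
    stop("window outside simulated bouts")
  n <- if (inherits(x, "bee_run")) x$n_flowers else
    max(vapply(seqs[window], max, integer(1))) - 1L
  cnt <- matrix(0L, n, n)
  for (b in window) {
    s <- seqs[[b]]
    from <- s[-length(s)]
    to <- s[-1L]
    keep <- from > 1L & to > 1L
    if (any(keep)) {
      idx <- cbind(from[keep] - 1L, to[keep] - 1L)
      for (r in seq_len(nrow(idx)))
        cnt[idx[r, 1L], idx[r, 2L]] <- cnt[idx[r, 1L], idx[r, 2L]] + 1L
    }
  }
  pairs <- which(upper.tri(cnt), arr.ind = TRUE)
  out <- data.frame(i = pairs[, 1L], j = pairs[, 2L],
                    n_ij = cnt[pairs],
                    n_ji = cnt[pairs[, c(2L, 1L), drop = FALSE]])
  out <- out[out$n_ij + out$n_ji > 0L, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "window") <- range(window)
  out
}

#' Standardised asymmetry index of directional transition use
#'
#' Measures the directional bias of flights between flower pairs. For each
#' unordered pair with `N = n_ij + n_ji` recorded transitions, the two-tailed
#' binomial probability of the observed departure from a 1:1 expectation is
#' \eqn{P = \min(1, 2 \Pr(X \ge \max(n_{ij}, n_{ji})))} with
#' \eqn{X \sim Bin(N, 1/2)}. Pairs with fewer than `min_obs` observations are
#' omitted. Each tested pair contributes the score \eqn{-\ln P}, and the
#' index is standardised by the number of pairs tested (their mean), so that
#' duplicating pairs leaves it unchanged. Perfectly balanced counts give an
#' index of 0; a pair with all 10 transitions in one direction alone gives
#' \eqn{-\ln(2 \cdot 2^{-10}) \approx 6.24}.
#'
#' @param counts a [transition_counts()] data frame (columns `i`, `j`,
#'   `n_ij`, `n_ji`).
#' @param min_obs minimum transitions per pair for inclusion (default 6).
#' @return list with `value` (the standardised index, `NA` when no pair meets
#'   `min_obs` -- an explicitly undefined result, not zero), `n_pairs`, and
#'   `pairs` (per-pair `N`, `P` and score).
#' @export
asymmetry_index <- function(counts, min_obs = 6) {
  N <- counts$n_ij + counts$n_ji
  keep <- N >= min_obs
  if (!any(keep))
    return(list(value = NA_real_, n_pairs = 0L,
                pairs = data.frame()))
  n <- pmax(counts$n_ij, counts$n_ji)[keep]
  N <- N[keep]
  P <- pmin(1, 2 * pbinom(n - 1L, N, 0.5, lower.tail = FALSE))
  score <- -log(P)
  list(value = mean(score), n_pairs = sum(keep),
       pairs = data.frame(i = counts$i[keep], j = counts$j[keep],
                          N = N, P = P, score = score))
}

#' Empirical rank p-value against a simulated null distribution
#'
#' Locates an observation within a null distribution generated by model runs
#' and returns the fraction of null values at least as extreme -- i.e. at
#' least as slow/poor -- as the observation, ties counting one half (mid-p).
#' An observation exactly at the 70th-percentile-quickest position of the
#' null yields p = 0.3; an observation quicker than every null value yields
#' p = 1; one slower than all of them yields the smallest attainable value
#' `0.5/n`. The model is conventionally rejected below p = 0.05. Drawing the
#' observation from the null itself makes p uniform on (0, 1].
#'
#' @param null numeric vector of null-model values (>= 100 recommended; the
#'   simulation experiments use 1000 runs).
#' @param observation the observed value.
#' @param better_is_smaller is a smaller value the quicker/better outcome
#'   (e.g. bouts to criterion)? Set `FALSE` for metrics where larger is
#'   better.
#' @return p-value in (0, 1].
#' @export
empirical_pvalue <- function(null, observation, better_is_smaller = TRUE) {
  null <- null[is.finite(null)]
  n <- length(null)
  if (n == 0L) stop("empty null distribution")
  if (n < 100L)
    warning("null distribution has fewer than 100 runs; p-values are coarse")
  worse <- if (better_is_smaller) sum(null > observation) else
    sum(null < observation)
  ties <- sum(null == observation)
  p <- (worse + 0.5 * ties) / n
  min(1, max(p, 0.5 / n))
}

#' Cohort-level route statistics
#'
#' Summarises a cohort the way the simulation experiments report it:
#' per-bee distinct routes within a bout window (routes distinct as flower
#' visitation sequences), revisit counts per bout (experience reduces returns
#' to just-emptied flowers), the per-flower visit-frequency distribution
#' (how often a flower receives n visits in a bout), and per-bout fractions
#' of optimal and stabilised bees.
#'
#' @param runs a `bee_cohort` or list of `bee_run` objects.
#' @param window integer bout range for the distinct-route count and visit
#'   frequencies; default all bouts.
#' @return list with data frames `per_bee`, `revisits_by_bout`,
#'   `visit_frequency` (columns `n_visits`, `freq`) and `fractions_by_bout`.
#' @export
cohort_summaries <- function(runs, window = NULL) {
  if (inherits(runs, "bee_cohort")) runs <- runs$runs
  nb <- nrow(runs[[1L]]$bouts)
  if (is.null(window)) window <- seq_len(nb)
  if (any(window < 1L | window > nb)) stop("window outside simulated bouts")
  nf <- runs[[1L]]$n_flowers

  per_bee <- do.call(rbind, lapply(seq_along(runs), function(i) {
    r <- runs[[i]]
    routes <- vapply(r$sequences[window], function(s)
      paste(s[s > 1L] - 1L, collapse = ","), "")
    data.frame(bee = i,
               distinct_routes = length(unique(routes)),
               l_best = r$l_best,
               ratio = if (!is.na(r$l_opt)) r$l_best / r$l_opt else NA_real_,
               first_optimal = r$first_optimal,
               stability_bout = r$stability_bout,
               mean_revisits = mean(r$bouts$revisits))
  }))

  rev_mat <- vapply(runs, function(r) r$bouts$revisits, integer(nb))
  revisits_by_bout <- data.frame(bout = seq_len(nb),
                                 mean_revisits = rowMeans(matrix(rev_mat,
                                                                 nrow = nb)))

  # visit-frequency histogram: per (bee, bout, flower) visit counts
  visit_counts <- unlist(lapply(runs, function(r) {
    vapply(r$sequences[window], function(s) {
      fl <- s[s > 1L] - 1L
      tabulate(fl, nbins = nf)
    }, integer(nf))
  }))
  tab <- table(visit_counts)
  visit_frequency <- data.frame(n_visits = as.integer(names(tab)),
                                freq = as.numeric(tab) / length(visit_counts))

  opt_mat <- vapply(runs, function(r) r$bouts$optimal, logical(nb))
  stab <- vapply(runs, function(r) r$stability_bout, integer(1L))
  fractions_by_bout <- data.frame(
    bout = seq_len(nb),
    frac_optimal = rowMeans(matrix(opt_mat, nrow = nb)),
    frac_stable = vapply(seq_len(nb), function(b)
      mean(!is.na(stab) & stab <= b), numeric(1L)))

  list(per_bee = per_bee, revisits_by_bout = revisits_by_bout,
       visit_frequency = visit_frequency,
       fractions_by_bout = fractions_by_bout)
}
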