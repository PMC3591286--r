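#' Parameters of the loop-search model
#'
#' Searching bees fly out-and-back loops centred on the search origin (the
#' nest, or the remembered location of a found or missing flower): each loop
#' heads out along a uniformly random bearing for an exponentially distributed
#' distance with mean `mean_leg`, scanning continuously, and is fully retraced
#' if the target flower never comes within the perception radius. The search
#' succeeds the moment the outward leg passes within `perception_radius` of
#' the flower, which sits at distance `target_distance` from the origin.
#'
#' @param mean_leg mean outward leg length (metres), > 0.
#' @param target_distance distance from the search origin to the flower
#'   (metres), > 0.
#' @param perception_radius direct perception distance (metres), >= 0. Values
#'   at or above `target_distance` make the search succeed trivially on the
#'   first loop.
#' @param max_loops cap on loops before the search is abandoned (flagged).
#' @param leg_sampler optional `function(n, mean_leg)` drawing `n` leg
#'   lengths; defaults to the exponential distribution. Supplying e.g. a
#'   gamma sampler probes the robustness of the optimal loop scale.
#' @return object of class `loop_search_params`.
#' @export
loop_search_params <- function(mean_leg, target_distance, perception_radius,
                               max_loops = 100000, leg_sampler = NULL) {
  if (mean_leg <= 0) stop("`mean_leg` must be positive")
  if (target_distance <= 0) stop("`target_distance` must be positive")
  if (perception_radius < 0) stop("`perception_radius` must be non-negative")
  structure(list(mean_leg = mean_leg, target_distance = target_distance,
                 perception_radius = perception_radius,
                 max_loops = as.integer(max_loops),
                 leg_sampler = leg_sampler),
            class = "loop_search_params")
}

# first outward distance at which the ray at relative bearing `delta` comes
# within r of a target at distance R, or NA if the leg of length `len` never
# does; vectorised over loops
leg_hit_distance <- function(delta, len, R, r) {
  cosd <- cos(delta)
  tstar <- pmin(pmax(R * cosd, 0), len)          # closest approach on the leg
  dmin2 <- R^2 + tstar^2 - 2 * tstar * R * cosd
  hit <- dmin2 <= r^2
  disc <- r^2 - R^2 * (1 - cosd^2)
  t_hit <- pmax(R * cosd - sqrt(pmax(disc, 0)), 0)
  ifelse(hit, t_hit, NA_real_)
}

#' Simulate one loop search
#'
#' Runs the loop-search model until the flower is perceived or `max_loops`
#' is exhausted. Perception is evaluated continuously along the outward leg
#' (closest-approach test), not just at its endpoint; retraced inbound legs
#' do not re-trigger perception since the flower would already have been
#' seen outbound along the same line. Unsuccessful legs contribute twice
#' their length (out and back); the successful leg is truncated at first
#' perception.
#'
#' @param params a [loop_search_params()].
#' @param bearing absolute bearing of the flower from the origin (radians);
#'   a random bearing by default (equivalent by symmetry).
#' @param keep_legs store every loop's direction and length.
#' @return object of class `search_path`: list with `loops` (count),
#'   `total_length` (metres), `success`, `final_leg` (outward distance on the
#'   successful leg) and optionally `legs` (data frame).
#' @export
simulate_loop_search <- function(params, bearing = NULL, keep_legs = FALSE) {
  stopifnot(inherits(params, "loop_search_params"))
  R <- params$target_distance
  r <- params$perception_radius
  lam <- params$mean_leg
  sampler <- params$leg_sampler %||% function(n, m) rexp(n, rate = 1 / m)
  if (is.null(bearing)) bearing <- runif(1, 0, 2 * pi)

  chunk <- 256L
  loops <- 0L
  travelled <- 0
  legs_dir <- legs_len <- numeric(0)
  while (loops < params$max_loops) {
    k <- min(chunk, params$max_loops - loops)
    theta <- runif(k, 0, 2 * pi)
    len <- sampler(k, lam)
    t_hit <- leg_hit_distance(theta - bearing, len, R, r)
    hit <- which(!is.na(t_hit))
    if (length(hit) > 0L) {
      h <- hit[1L]
      before <- if (h > 1L) sum(len[seq_len(h - 1L)]) else 0
      travelled <- travelled + 2 * before + t_hit[h]
      loops <- loops + h
      if (keep_legs) {
        legs_dir <- c(legs_dir, theta[seq_len(h)])
        legs_len <- c(legs_len, c(len[seq_len(h - 1L)], t_hit[h]))
      }
      return(structure(list(loops = loops, total_length = travelled,
                            success = TRUE, final_leg = t_hit[h],
                            legs = if (keep_legs)
                              data.frame(direction = legs_dir,
                                         length = legs_len) else NULL),
                       class = "search_path"))
    }
    travelled <- travelled + 2 * sum(len)
    loops <- loops + k
    if (keep_legs) {
      legs_dir <- c(legs_dir, theta)
      legs_len <- c(legs_len, len)
    }
  }
  structure(list(loops = loops, total_length = travelled, success = FALSE,
                 final_leg = NA_real_,
                 legs = if (keep_legs)
                   data.frame(direction = legs_dir, length = legs_len) else
                     NULL),
            class = "search_path")
}

#' @export
print.search_path <- function(x, ...) {
  cat("<search_path>", x$loops, "loops,",
      format(x$total_length, digits = 5), "m,",
      if (x$success) "flower found" else "abandoned", "\n")
  invisible(x)
}

#' Expected total length of a loop search
#'
#' Closed-form estimate of the mean search path length. For exponential legs
#' with mean \eqn{\lambda}, a search persists until the longest loop becomes
#' comparable with the target distance R: requiring a leg longer than R to
#' occur about once, \eqn{n \Pr(\ell > R) \approx 1}, gives
#' \eqn{n = e^{R/\lambda}} loops, and with each loop flown out and back the
#' mean total path is
#' \deqn{\langle L \rangle = 2 n \lambda = 2 \lambda e^{R/\lambda}.}
#' This is an extreme-value, order-of-magnitude argument: simulations agree
#' with it up to the geometric factor set by the perception radius, never bit
#' exactly. The expression is convex in \eqn{\lambda} with a unique minimum
#' \eqn{2 e R} at \eqn{\lambda = R} (set \eqn{d/d\lambda\,[\lambda e^{R/\lambda}]
#' = e^{R/\lambda}(1 - R/\lambda) = 0}): loops much shorter than R almost
#' never reach the flower, loops much longer waste flight beyond it.
#'
#' @param mean_leg mean outward leg length \eqn{\lambda} (> 0); vectorised.
#' @param target_distance expected distance R to the flower (> 0).
#' @return expected total search path length (metres).
#' @seealso [optimal_loop_scale()]
#' @export
mean_search_length <- function(mean_leg, target_distance) {
  if (any(mean_leg <= 0) || any(target_distance <= 0))
    stop("`mean_leg` and `target_distance` must be positive")
  2 * mean_leg * exp(target_distance / mean_leg)
}

#' Optimal mean loop length
#'
#' The mean search path length is minimised when the average outward leg of
#' a loop equals the expected distance to the flower.
#'
#' @param target_distance expected distance R to the flower (> 0).
#' @return the optimal mean leg length, `target_distance` itself.
#' @export
optimal_loop_scale <- function(target_distance) {
  if (any(target_distance <= 0)) stop("`target_distance` must be positive")
  target_distance
}
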