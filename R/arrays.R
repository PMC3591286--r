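#' Flower arrays: the physical world of a foraging simulation
#'
#' A `flower_array` holds the nest position and the coordinates of one or more
#' flowers in a common 2-D Cartesian frame (units: metres), together with the
#' full pairwise distance table over all locations (nest first). All pairwise
#' distances must be strictly positive except for explicitly declared
#' co-located flower pairs, which stand in for a single doubly rewarding
#' flower; the simulator assigns the zero-length within-pair hop the
#' transition weight of the closest distinct pair of locations so that the
#' inverse-square distance prior stays well defined.
#'
#' @param nest numeric length-2 nest coordinates.
#' @param flowers numeric matrix (one row per flower, columns x and y) or a
#'   data frame with columns `x` and `y`.
#' @param labels optional character vector of flower names; defaults to
#'   `"F1"`, `"F2"`, ... The label `"NEST"` is reserved.
#' @param colocated optional two-column matrix of flower index pairs that are
#'   deliberately placed at identical coordinates.
#' @param high_reward integer vector of flower indices flagged as highly
#'   rewarding (targets of [model_params()]'s `reward_priority_boost`).
#'   Defaults to the members of `colocated`.
#' @param patch optional integer vector of per-flower patch memberships.
#' @param reward_unit nectar units delivered by one flower per bout.
#'
#' @return An object of class `flower_array`: a list with elements `nest`,
#'   `flowers`, `labels`, `colocated`, `high_reward`, `patch`, `reward_unit`
#'   and `dist` (the (n+1) x (n+1) distance table, nest in row/column 1).
#' @seealso [regular_polygon_array()], [random_uniform_array()],
#'   [patch_grid_array()], [load_array()], [example_array()]
#' @export
flower_array <- function(nest, flowers, labels = NULL, colocated = NULL,
                         high_reward = NULL, patch = NULL, reward_unit = 1) {
  nest <- as.numeric(nest)
  if (length(nest) != 2L || !all(is.finite(nest)))
    stop("`nest` must be two finite coordinates")
  if (is.data.frame(flowers)) flowers <- as.matrix(flowers[, c("x", "y")])
  flowers <- matrix(as.numeric(flowers), ncol = 2L,
                    dimnames = list(NULL, c("x", "y")))
  n <- nrow(flowers)
  if (n < 1L) stop("at least one flower is required")
  if (!all(is.finite(flowers))) stop("flower coordinates must be finite")
  if (is.null(labels)) labels <- paste0("F", seq_len(n))
  labels <- as.character(labels)
  if (length(labels) != n) stop("`labels` must name every flower")
  if (anyDuplicated(labels)) stop("duplicate flower labels")
  if ("NEST" %in% labels) stop("the label \"NEST\" is reserved for the nest")
  if (!is.null(colocated)) {
    colocated <- matrix(as.integer(colocated), ncol = 2L)
    if (any(colocated < 1L | colocated > n))
      stop("`colocated` indices out of range")
  }
  if (is.null(high_reward)) {
    high_reward <- if (is.null(colocated)) integer(0) else
      sort(unique(as.integer(colocated)))
  }
  high_reward <- as.integer(high_reward)
  if (any(high_reward < 1L | high_reward > n))
    stop("`high_reward` indices out of range")
  if (!is.null(patch) && length(patch) != n)
    stop("`patch` must give one membership per flower")

  coords <- rbind(nest, flowers)
  d <- as.matrix(stats::dist(coords))
  dimnames(d) <- list(c("NEST", labels), c("NEST", labels))

  # zero off-diagonal distances are only legal for flagged co-located pairs
  zero <- which(d < 1e-12 & upper.tri(d), arr.ind = TRUE)
  if (nrow(zero) > 0L) {
    flagged <- if (is.null(colocated)) matrix(integer(0), 0, 2) else
      cbind(pmin(colocated[, 1], colocated[, 2]),
            pmax(colocated[, 1], colocated[, 2]))
    for (r in seq_len(nrow(zero))) {
      i <- zero[r, 1] - 1L; j <- zero[r, 2] - 1L   # flower indices (0 = nest)
      if (i == 0L || j == 0L)
        stop("nest coincides with flower ", max(i, j),
             "; offset the nest from the flowers")
      ok <- any(flagged[, 1] == min(i, j) & flagged[, 2] == max(i, j))
      if (!ok)
        stop("flowers ", i, " and ", j, " are coincident but not declared ",
             "in `colocated`")
    }
  }

  structure(list(nest = nest, flowers = flowers, labels = labels,
                 colocated = colocated, high_reward = high_reward,
                 patch = patch, reward_unit = reward_unit, dist = d),
            class = "flower_array")
}

#' @export
print.flower_array <- function(x, ...) {
  cat("<flower_array> ", n_flowers(x), " flowers", sep = "")
  if (!is.null(x$colocated) && nrow(x$colocated) > 0)
    cat(",", nrow(x$colocated), "co-located pair(s)")
  if (!is.null(x$patch)) cat(",", length(unique(x$patch)), "patches")
  cat("\n  nest at (", format(x$nest[1]), ", ", format(x$nest[2]), ")",
      sep = "")
  ext <- apply(x$flowers, 2, range)
  cat("; extent x [", format(ext[1, 1]), ", ", format(ext[2, 1]),
      "] y [", format(ext[1, 2]), ", ", format(ext[2, 2]), "] m\n", sep = "")
  invisible(x)
}

#' @export
plot.flower_array <- function(x, ...) {
  coords <- rbind(x$nest, x$flowers)
  graphics::plot(coords, asp = 1, xlab = "x (m)", ylab = "y (m)",
                 type = "n", ...)
  graphics::points(x$flowers, pch = 19,
                   col = ifelse(seq_len(n_flowers(x)) %in% x$high_reward,
                                "red", "black"))
  graphics::points(x$nest[1], x$nest[2], pch = 17, col = "blue", cex = 1.4)
  graphics::text(x$flowers, labels = x$labels, pos = 3, cex = 0.7)
  invisible(x)
}

#' Number of flowers in an array
#' @param array a [flower_array()].
#' @return integer count of flowers (excluding the nest).
#' @export
n_flowers <- function(array) nrow(array$flowers)

#' Distance table of an array
#'
#' @param array a [flower_array()].
#' @param flowers_only drop the nest row/column?
#' @return symmetric matrix of pairwise distances in metres; the nest is the
#'   first row/column unless `flowers_only`.
#' @export
location_distances <- function(array, flowers_only = FALSE) {
  if (flowers_only) array$dist[-1, -1, drop = FALSE] else array$dist
}

#' Regular polygon of flowers
#'
#' Places `n_vertices` flowers on a regular polygon with the requested side
#' length, e.g. the pentagonal arrangements used in flight-room and field
#' traplining experiments. The circumradius is `side_length / (2 sin(pi/n))`.
#'
#' @param n_vertices number of polygon vertices (>= 3).
#' @param side_length polygon side length in metres (> 0).
#' @param nest_at `"centroid"` (the default), `"vertex"` (coincident with
#'   flower 1 -- rejected by validation, exists to document the degenerate
#'   contract), or a numeric length-2 point.
#' @return a [flower_array()].
#' @export
regular_polygon_array <- function(n_vertices, side_length,
                                  nest_at = "centroid") {
  n_vertices <- as.integer(n_vertices)
  if (n_vertices < 3L) stop("`n_vertices` must be at least 3")
  if (!is.numeric(side_length) || side_length <= 0)
    stop("`side_length` must be positive")
  rc <- side_length / (2 * sin(pi / n_vertices))
  ang <- pi / 2 + 2 * pi * (seq_len(n_vertices) - 1L) / n_vertices
  flowers <- cbind(x = rc * cos(ang), y = rc * sin(ang))
  nest <- if (is.numeric(nest_at)) {
    nest_at
  } else if (identical(nest_at, "centroid")) {
    c(0, 0)
  } else if (identical(nest_at, "vertex")) {
    flowers[1L, ]  # coincident: flower_array() rejects it, as documented
  } else stop("unknown `nest_at`")
  flower_array(nest, flowers)
}

#' Uniform-random flowers in a square patch
#'
#' Flowers are drawn i.i.d. uniformly over the square `[0, patch_side]^2`.
#' Draws with any inter-location distance (including to the nest) below
#' `min_sep` are resampled so that the inverse-square transition prior is
#' always well defined.
#'
#' @param n_flowers number of flowers (>= 1).
#' @param patch_side side of the square patch (metres).
#' @param nest_at nest coordinates; default the patch corner at the origin.
#' @param seed optional integer seed for reproducible arrays.
#' @param min_sep minimum tolerated pairwise distance; default
#'   `patch_side / 1000`.
#' @return a [flower_array()].
#' @export
random_uniform_array <- function(n_flowers, patch_side, nest_at = c(0, 0),
                                 seed = NULL, min_sep = patch_side / 1000) {
  n_flowers <- as.integer(n_flowers)
  if (n_flowers < 1L) stop("`n_flowers` must be at least 1")
  if (patch_side <= 0) stop("`patch_side` must be positive")
  if (!is.null(seed)) set.seed(seed)
  repeat {
    flowers <- cbind(x = runif(n_flowers, 0, patch_side),
                     y = runif(n_flowers, 0, patch_side))
    d <- stats::dist(rbind(nest_at, flowers))
    if (min(d) >= min_sep) break
  }
  flower_array(nest_at, flowers)
}

#' Clustered flowers on distinct patches
#'
#' Flowers are scattered uniformly within discs of radius `patch_radius`
#' centred on the supplied patch positions, emulating foraging on a few
#' distant patches (e.g. the corners of a square). Patch membership is
#' recorded per flower.
#'
#' @param patch_positions matrix of patch centre coordinates (one row per
#'   patch).
#' @param flowers_per_patch flowers scattered in each patch.
#' @param patch_radius disc radius (metres); patch centres must be separated
#'   by more than `2 * patch_radius`.
#' @param nest_at nest coordinates.
#' @param seed optional integer seed.
#' @return a [flower_array()] with the `patch` field set.
#' @export
patch_grid_array <- function(patch_positions, flowers_per_patch, patch_radius,
                             nest_at, seed = NULL) {
  patch_positions <- matrix(as.numeric(patch_positions), ncol = 2L)
  k <- nrow(patch_positions)
  if (k < 1L) stop("at least one patch is required")
  if (flowers_per_patch < 1L) stop("`flowers_per_patch` must be at least 1")
  if (k > 1L) {
    sep <- min(stats::dist(patch_positions))
    if (sep <= 2 * patch_radius)
      stop("patches overlap: centre separation ", format(sep),
           " is not greater than twice the patch radius")
  }
  if (!is.null(seed)) set.seed(seed)
  pts <- lapply(seq_len(k), function(p) {
    r <- patch_radius * sqrt(runif(flowers_per_patch))
    a <- runif(flowers_per_patch, 0, 2 * pi)
    cbind(x = patch_positions[p, 1] + r * cos(a),
          y = patch_positions[p, 2] + r * sin(a))
  })
  flower_array(nest_at, do.call(rbind, pts),
               patch = rep(seq_len(k), each = flowers_per_patch))
}

#' Read and write flower arrays
#'
#' Arrays round-trip through plain-text files. CSV files carry columns
#' `label,x,y` with the nest in a row labelled `NEST` (coordinates are written
#' with full precision so that save-then-load is bit exact). JSON files carry
#' the complete object including co-location flags, high-reward flags and
#' patch memberships; CSV carries coordinates and labels only.
#'
#' @param path file path ending in `.csv` or `.json`.
#' @param array a [flower_array()].
#' @param colocated optional co-location flags to apply when loading a CSV
#'   that contains coincident flowers.
#' @return `load_array()` returns a [flower_array()]; `save_array()` returns
#'   `path` invisibly.
#' @export
load_array <- function(path, colocated = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("label", "x", "y") %in% names(df)))
      stop("CSV array files need columns label,x,y")
    if (!is.numeric(df$x) || !is.numeric(df$y))
      stop("non-numeric coordinates in ", path)
    nest_row <- which(df$label == "NEST")
    if (length(nest_row) != 1L)
      stop("array file must contain exactly one row labelled NEST")
    flower_array(c(df$x[nest_row], df$y[nest_row]),
                 cbind(x = df$x[-nest_row], y = df$y[-nest_row]),
                 labels = df$label[-nest_row], colocated = colocated)
  } else if (ext == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    colo <- NULL
    if (!is.null(obj$colocated_i) && length(obj$colocated_i) > 0)
      colo <- cbind(obj$colocated_i, obj$colocated_j)
    flower_array(obj$nest, cbind(x = obj$x, y = obj$y),
                 labels = obj$labels, colocated = colo,
                 high_reward = obj$high_reward, patch = obj$patch,
                 reward_unit = if (is.null(obj$reward_unit)) 1 else
                   obj$reward_unit)
  } else stop("unsupported array file extension: ", ext)
}

#' @rdname load_array
#' @export
save_array <- function(array, path) {
  stopifnot(inherits(array, "flower_array"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    lines <- c("label,x,y",
               sprintf("NEST,%.17g,%.17g", array$nest[1], array$nest[2]),
               sprintf("%s,%.17g,%.17g", array$labels,
                       array$flowers[, 1], array$flowers[, 2]))
    writeLines(lines, path)
  } else if (ext == "json") {
    obj <- list(nest = array$nest,
                x = unname(array$flowers[, 1]),
                y = unname(array$flowers[, 2]),
                labels = array$labels,
                colocated_i = array$colocated[, 1],
                colocated_j = array$colocated[, 2],
                high_reward = array$high_reward,
                patch = array$patch, reward_unit = array$reward_unit)
    obj <- obj[!vapply(obj, is.null, logical(1))]
    jsonlite::write_json(obj, path, digits = I(17), auto_unbox = FALSE)
  } else stop("unsupported array file extension: ", ext)
  invisible(path)
}

#' Bundled example arrays
#'
#' Synthetic 10-flower arrays (sub-metre extent) emulating the three classic
#' linkage types between flower proximity and the structure of the optimal
#' circuit: `"positive"` (flowers on a ring -- every short transition lies on
#' the optimal circuit), `"independent"` (an irregularly jittered ring --
#' short transitions only partly aligned with the optimal circuit) and
#' `"negative"` (two interleaved rings of very different radius -- the
#' shortest transitions concentrate among the inner flowers and lead away
#' from the optimal circuit). The original experimental coordinates are
#' unpublished; these hand-authored geometries reproduce the qualitative
#' structure only and are intended for ordering comparisons, not
#' quantitative reproduction.
#'
#' @param name one of `"positive"`, `"independent"`, `"negative"`.
#' @return a [flower_array()].
#' @export
example_array <- function(name = c("positive", "independent", "negative")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, "_array_synthetic.csv"),
                      package = "traplinesim", mustWork = TRUE)
  load_array(path)
}
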