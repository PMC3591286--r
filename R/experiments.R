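#' Define a simulation experiment
#'
#' An experiment specification bundles an array source, model parameters,
#' cohort sizes, an optional parameter sweep and the per-bee metrics to
#' compute, so that a whole simulation campaign is reproducible from a name,
#' a seed and a scale factor. Specs are plain lists and serialise to YAML.
#'
#' @param name experiment name.
#' @param array array source: a [flower_array()], or a list
#'   `list(generator = "random_uniform", args = list(...))` naming one of the
#'   array generators (`"random_uniform"`, `"regular_polygon"`,
#'   `"patch_grid"`, `"reward_pair"`), or `list(fixture = "positive")` naming
#'   a bundled [example_array()].
#' @param params a [model_params()].
#' @param n_arrangements independent random arrays to average over.
#' @param n_bees bees per arrangement.
#' @param metrics character vector among `"ratio"`, `"found_optimal"`,
#'   `"stable"`, `"improvable"`, `"reward_share"`, `"distinct_routes"`,
#'   `"revisits"`, `"patch_order"`.
#' @param sweep named list of parameter vectors crossed into a grid. Names
#'   are [model_params()] fields, or generator arguments prefixed with
#'   `"array."` (e.g. `array.n_flowers`), or `"array.fixture"`.
#' @param improv_windows list of bout windows (2-vectors) at which the
#'   transposition-improvability of the best-found route is evaluated.
#' @param route_window bout window for the distinct-route count.
#' @return object of class `experiment_spec`.
#' @export
experiment_spec <- function(name, array, params = model_params(),
                            n_arrangements = 1, n_bees = 100,
                            metrics = c("ratio", "found_optimal", "stable"),
                            sweep = NULL,
                            improv_windows = NULL, route_window = NULL) {
  structure(list(name = name, array = array, params = params,
                 n_arrangements = as.integer(n_arrangements),
                 n_bees = as.integer(n_bees), metrics = metrics,
                 sweep = sweep, improv_windows = improv_windows,
                 route_window = route_window),
            class = "experiment_spec")
}

#' @export
print.experiment_spec <- function(x, ...) {
  cat("<experiment_spec>", x$name, "--", x$n_arrangements, "arrangement(s) x",
      x$n_bees, "bees;", x$params$n_bouts, "bouts, f =",
      x$params$enhancement_factor, "\n")
  if (!is.null(x$sweep))
    cat("  sweep over:", paste(names(x$sweep), collapse = ", "), "\n")
  invisible(x)
}

# random array with a co-located flower pair standing in for one doubly
# rewarding flower: n - 1 uniform positions, the last duplicated
reward_pair_array <- function(n_flowers, patch_side, nest_at = c(0, 0),
                              seed = NULL) {
  base <- random_uniform_array(n_flowers - 1L, patch_side, nest_at, seed)
  flower_array(base$nest, rbind(base$flowers, base$flowers[n_flowers - 1L, ]),
               colocated = cbind(n_flowers - 1L, n_flowers))
}

build_spec_array <- function(spec_array, arrangement_seed) {
  if (inherits(spec_array, "flower_array")) return(spec_array)
  if (!is.null(spec_array$fixture)) return(example_array(spec_array$fixture))
  gen <- spec_array$generator
  args <- spec_array$args %||% list()
  if (gen %in% c("random_uniform", "patch_grid", "reward_pair"))
    args$seed <- arrangement_seed
  fn <- switch(gen,
               random_uniform = random_uniform_array,
               regular_polygon = regular_polygon_array,
               patch_grid = patch_grid_array,
               reward_pair = reward_pair_array,
               stop("unknown array generator: ", gen))
  do.call(fn, args)
}

# best qualifying route (shortest net trapline skeleton) within a bout window
best_route_in_window <- function(run, window) {
  w <- seq(window[1], min(window[2], nrow(run$bouts)))
  q <- w[run$bouts$qualifying[w]]
  if (length(q) == 0L) return(NULL)
  b <- q[which.min(run$bouts$route_length[q])]
  s <- run$sequences[[b]]
  fl <- s[s > 1L] - 1L
  list(flowers = fl[!duplicated(fl)],
       length = run$bouts$route_length[b], bout = b)
}

#' Patch-level route statistics
#'
#' For arrays whose flowers belong to patches, compares route optimality at
#' the two spatial levels. *Between patches*: among bouts whose collapsed
#' patch visitation order enters each patch exactly once, the fraction
#' following the perimeter order of the patch centres (clockwise or
#' anticlockwise, any starting patch). *Within patches*: among complete
#' single-entry patch traversals (every flower of the patch visited exactly
#' once in one stay), the fraction following the perimeter order of that
#' patch's flowers. Both fractions have the same chance level for equal
#' group sizes, but travel-distance pressure acts on the patch level far
#' more strongly than on the metre-scale order inside a patch, so distant
#' patches end up linked optimally much more often.
#'
#' @param run a `bee_run` on a patch array.
#' @param array the [flower_array()] with its `patch` field set.
#' @param window integer range of bout indices to score; default all.
#' @return named numeric: `inter_frac`, `intra_frac`, `n_inter` and
#'   `n_traversals` (the denominators).
#' @export
patch_route_stats <- function(run, array, window = NULL) {
  if (is.null(array$patch)) stop("array has no patch memberships")
  if (is.null(window)) window <- seq_along(run$sequences)
  k <- length(unique(array$patch))
  ctr <- do.call(rbind, lapply(seq_len(k), function(p)
    colMeans(array$flowers[array$patch == p, , drop = FALSE])))
  perim <- order(atan2(ctr[, 2] - mean(ctr[, 2]),
                       ctr[, 1] - mean(ctr[, 1])))

  is_cyclic <- function(seq_, ref) {
    kk <- length(ref)
    if (length(seq_) != kk) return(FALSE)
    for (r in list(ref, rev(ref)))
      for (s in seq_len(kk))
        if (all(seq_ == r[(seq_len(kk) + s - 2L) %% kk + 1L])) return(TRUE)
    FALSE
  }
  # perimeter order of one patch's flowers around their own centroid
  patch_perim <- lapply(seq_len(k), function(p) {
    members <- which(array$patch == p)
    members[order(atan2(array$flowers[members, 2] - ctr[p, 2],
                        array$flowers[members, 1] - ctr[p, 1]))]
  })

  n_inter <- 0L; inter_ok <- 0L
  n_trav <- 0L; intra_ok <- 0L
  for (b in window) {
    s <- run$sequences[[b]]
    fl <- s[s > 1L] - 1L
    if (length(fl) == 0L) next
    pat <- array$patch[fl]
    coll <- pat[c(TRUE, diff(pat) != 0L)]
    if (length(coll) == k && !anyDuplicated(coll)) {
      n_inter <- n_inter + 1L
      if (is_cyclic(coll, perim)) inter_ok <- inter_ok + 1L
    }
    seg_id <- cumsum(c(1L, diff(pat) != 0L))
    for (g in unique(seg_id)) {
      idx <- which(seg_id == g)
      p <- pat[idx[1L]]
      members <- which(array$patch == p)
      if (length(idx) != length(members) || anyDuplicated(fl[idx]) ||
          !setequal(fl[idx], members)) next
      n_trav <- n_trav + 1L
      if (is_cyclic(fl[idx], patch_perim[[p]])) intra_ok <- intra_ok + 1L
    }
  }
  c(inter_frac = if (n_inter > 0L) inter_ok / n_inter else NA_real_,
    intra_frac = if (n_trav > 0L) intra_ok / n_trav else NA_real_,
    n_inter = n_inter, n_traversals = n_trav)
}

per_bee_metrics <- function(run, array, spec) {
  nb <- nrow(run$bouts)
  out <- list(l_best = run$l_best,
              capped_rate = mean(run$bouts$capped))
  m <- spec$metrics
  if ("ratio" %in% m)
    out$ratio <- if (!is.na(run$l_opt)) run$l_best / run$l_opt else NA_real_
  if ("found_optimal" %in% m)
    out$found_optimal <- !is.na(run$first_optimal)
  if ("stable" %in% m) {
    out$stable <- !is.na(run$stability_bout)
    out$stability_bout <- run$stability_bout
  }
  if ("improvable" %in% m) {
    wins <- spec$improv_windows %||% list(c(1L, nb))
    for (w in wins) {
      best <- best_route_in_window(run, w)
      val <- if (is.null(best)) NA else
        pairwise_switch_improvable(best$flowers, array)$improvable
      out[[paste0("improvable_", w[2])]] <- val
    }
  }
  if ("reward_share" %in% m) {
    hr <- array$high_reward + 1L
    vis <- vapply(run$sequences, function(s) {
      fl <- s[s > 1L]
      c(sum(fl %in% hr), length(fl))
    }, numeric(2))
    out$reward_share <- sum(vis[1, ]) / sum(vis[2, ])
  }
  if ("distinct_routes" %in% m) {
    w <- spec$route_window %||% c(max(1L, nb - 32L), nb)
    routes <- vapply(run$sequences[seq(w[1], w[2])], function(s)
      paste(s[s > 1L] - 1L, collapse = ","), "")
    out$distinct_routes <- length(unique(routes))
  }
  if ("revisits" %in% m) out$mean_revisits <- mean(run$bouts$revisits)
  if ("patch_order" %in% m) {
    w <- spec$route_window %||% c(1L, nb)
    ps <- patch_route_stats(run, array, seq(w[1], min(w[2], nb)))
    out$inter_patch_optimal <- ps[["inter_frac"]]
    out$intra_patch_optimal <- ps[["intra_frac"]]
  }
  out
}

sweep_grid <- function(spec) {
  if (is.null(spec$sweep)) return(data.frame(.cell = 1L))
  g <- do.call(expand.grid,
               c(spec$sweep, list(stringsAsFactors = FALSE)))
  g$.cell <- seq_len(nrow(g))
  g
}

apply_cell <- function(spec, grid_row) {
  params <- spec$params
  arr_spec <- spec$array
  for (nm in setdiff(names(grid_row), ".cell")) {
    val <- grid_row[[nm]]
    if (startsWith(nm, "array.")) {
      anm <- sub("^array\\.", "", nm)
      if (anm == "fixture") arr_spec <- list(fixture = val) else
        arr_spec$args[[anm]] <- val
    } else params[[nm]] <- val
  }
  list(params = params, array = arr_spec)
}

#' Run an experiment
#'
#' Executes a spec's full sweep-by-arrangement grid of cohorts, computes the
#' requested per-bee metrics, and aggregates them per sweep cell. Per-bee
#' seeds are derived deterministically from the master seed, so the same
#' spec, seed and scale always yield identical results. When `out_dir` is
#' given, per-cell chunks are written as they complete
#' (`state/cell<k>_arr<a>.csv`) and reused on a rerun, making interrupted
#' campaigns resumable; the final bundle is `bees.csv`, `cells.csv` and
#' `manifest.json`.
#'
#' @param spec an [experiment_spec()].
#' @param seed master integer seed.
#' @param scale fraction of the spec's cohort sizes to run (arrangements and
#'   bees are scaled and rounded up to at least 1).
#' @param out_dir optional output directory.
#' @param quiet suppress progress messages.
#' @return list of class `experiment_result` with `bees` (one row per bee),
#'   `cells` (aggregates per sweep cell) and `manifest`.
#' @export
run_experiment <- function(spec, seed = 1, scale = 1, out_dir = NULL,
                           quiet = TRUE) {
  stopifnot(inherits(spec, "experiment_spec"))
  n_arr <- max(1L, as.integer(round(spec$n_arrangements * scale)))
  n_bees <- max(1L, as.integer(round(spec$n_bees * scale)))
  grid <- sweep_grid(spec)
  nc <- nrow(grid)

  set.seed(seed)
  arr_seeds <- matrix(sample.int(.Machine$integer.max, nc * n_arr), nc, n_arr)
  coh_seeds <- matrix(sample.int(.Machine$integer.max, nc * n_arr), nc, n_arr)

  state_dir <- NULL
  if (!is.null(out_dir)) {
    state_dir <- file.path(out_dir, "state")
    dir.create(state_dir, recursive = TRUE, showWarnings = FALSE)
  }

  rows <- list()
  for (ci in seq_len(nc)) {
    cell <- apply_cell(spec, grid[ci, , drop = FALSE])
    for (a in seq_len(n_arr)) {
      chunk_file <- if (!is.null(state_dir))
        file.path(state_dir, sprintf("cell%d_arr%d.csv", ci, a)) else NULL
      if (!is.null(chunk_file) && file.exists(chunk_file)) {
        rows[[length(rows) + 1L]] <- utils::read.csv(chunk_file)
        next
      }
      array <- build_spec_array(cell$array, arr_seeds[ci, a])
      cohort <- run_cohort(array, cell$params, n_bees,
                           seed = coh_seeds[ci, a])
      df <- do.call(rbind, lapply(seq_along(cohort$runs), function(i)
        as.data.frame(per_bee_metrics(cohort$runs[[i]], array, spec))))
      df <- cbind(data.frame(cell = ci, arrangement = a,
                             bee = seq_len(n_bees)),
                  grid[ci, setdiff(names(grid), ".cell"), drop = FALSE],
                  df, row.names = NULL)
      if (!is.null(chunk_file)) utils::write.csv(df, chunk_file,
                                                 row.names = FALSE)
      rows[[length(rows) + 1L]] <- df
      if (!quiet) message("cell ", ci, "/", nc, " arrangement ", a, "/",
                          n_arr, " done")
    }
  }
  bees <- do.call(rbind, rows)

  num_cols <- setdiff(names(bees)[vapply(bees, is.numeric, logical(1)) |
                                    vapply(bees, is.logical, logical(1))],
                      c("cell", "arrangement", "bee", "stability_bout"))
  cells <- do.call(rbind, lapply(split(bees, bees$cell), function(g) {
    agg <- lapply(num_cols, function(cn) mean(g[[cn]], na.rm = TRUE))
    names(agg) <- num_cols
    cbind(g[1L, intersect(names(g),
                          c("cell", setdiff(names(grid), ".cell"))),
            drop = FALSE],
          as.data.frame(agg), row.names = NULL)
  }))

  manifest <- list(name = spec$name, seed = seed, scale = scale,
                   n_arrangements = n_arr, n_bees = n_bees,
                   package_version =
                     as.character(utils::packageVersion("traplinesim")))
  if (!is.null(out_dir)) {
    utils::write.csv(bees, file.path(out_dir, "bees.csv"), row.names = FALSE)
    utils::write.csv(cells, file.path(out_dir, "cells.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  structure(list(bees = bees, cells = cells, manifest = manifest),
            class = "experiment_result")
}

#' Bundled experiment recipes
#'
#' Named, seeded specifications for the package's standard simulation
#' campaigns, each runnable at reduced scale:
#' \describe{
#'   \item{factor_sweep}{pentagon (5 m side), enhancement factors 1.01-4:
#'     stability increases with the factor (motivation/spatial scale).}
#'   \item{array_types}{positive / independent / negative synthetic arrays at
#'     factors 1.1 and 1.5: stable optimal traplines form in some spatial
#'     configurations but not others.}
#'   \item{random_tsp}{4-10 flowers uniform in a square, factor 2, 65 bouts:
#'     route quality vs the exact optimum.}
#'   \item{switch20}{20 flowers, 130 bouts: transposition-improvability of
#'     best-found routes after one and two foraging days.}
#'   \item{patches}{4 patches of 3 flowers on square corners: optimal linking
#'     between, but not within, patches.}
#'   \item{crop_selection}{8 flowers, crop capacities 2-7: finding the best
#'     flower subset.}
#'   \item{reward_priority}{8 flowers with a co-located high-reward pair and
#'     boosted initial nest transition: reward prioritisation vs crop size.}
#' }
#'
#' @return named list of [experiment_spec()] objects.
#' @export
shipped_specs <- function() {
  side <- 25
  list(
    factor_sweep = experiment_spec(
      "factor_sweep",
      array = list(generator = "regular_polygon",
                   args = list(n_vertices = 5, side_length = 5,
                               nest_at = c(0, -7))),
      params = model_params(n_bouts = 65),
      n_arrangements = 1, n_bees = 100,
      metrics = c("found_optimal", "stable", "revisits"),
      sweep = list(enhancement_factor = c(1.01, 1.1, 1.5, 2, 3, 4))),
    array_types = experiment_spec(
      "array_types",
      array = list(fixture = "positive"),
      params = model_params(n_bouts = 65),
      n_arrangements = 1, n_bees = 100,
      metrics = c("found_optimal", "stable"),
      sweep = list(array.fixture = c("positive", "independent", "negative"),
                   enhancement_factor = c(1.1, 1.5))),
    random_tsp = experiment_spec(
      "random_tsp",
      array = list(generator = "random_uniform",
                   args = list(n_flowers = 10, patch_side = side)),
      params = model_params(enhancement_factor = 2, n_bouts = 65),
      n_arrangements = 100, n_bees = 100,
      metrics = c("ratio", "found_optimal", "distinct_routes"),
      sweep = list(array.n_flowers = 4:10),
      route_window = c(33, 65)),
    switch20 = experiment_spec(
      "switch20",
      array = list(generator = "random_uniform",
                   args = list(n_flowers = 20, patch_side = side)),
      params = model_params(enhancement_factor = 2, n_bouts = 130),
      n_arrangements = 100, n_bees = 100,
      metrics = "improvable",
      improv_windows = list(c(1, 65), c(1, 130))),
    patches = experiment_spec(
      "patches",
      array = list(generator = "patch_grid",
                   args = list(patch_positions = rbind(c(0, 0), c(4, 0),
                                                       c(4, 4), c(0, 4)),
                               flowers_per_patch = 4, patch_radius = 0.6,
                               nest_at = c(2, -3))),
      params = model_params(enhancement_factor = 2, n_bouts = 65),
      n_arrangements = 20, n_bees = 50,
      metrics = "patch_order", route_window = c(33, 65)),
    crop_selection = experiment_spec(
      "crop_selection",
      array = list(generator = "random_uniform",
                   args = list(n_flowers = 8, patch_side = side)),
      params = model_params(enhancement_factor = 2, n_bouts = 65),
      n_arrangements = 100, n_bees = 100,
      metrics = c("found_optimal", "stable"),
      sweep = list(crop_capacity = 2:7)),
    reward_priority = experiment_spec(
      "reward_priority",
      array = list(generator = "reward_pair",
                   args = list(n_flowers = 8, patch_side = side)),
      params = model_params(enhancement_factor = 2, n_bouts = 65,
                            reward_priority_boost = 10),
      n_arrangements = 50, n_bees = 50,
      metrics = c("reward_share", "found_optimal"),
      sweep = list(crop_capacity = 2:7)))
}

#' Read or write an experiment spec as YAML
#'
#' @param spec an [experiment_spec()].
#' @param path YAML file path.
#' @return `write_spec()` returns `path` invisibly; `read_spec()` an
#'   [experiment_spec()].
#' @export
write_spec <- function(spec, path) {
  obj <- unclass(spec)
  obj$params <- unclass(obj$params)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_spec
#' @export
read_spec <- function(path) {
  obj <- yaml::read_yaml(path)
  params <- do.call(model_params, obj$params[!vapply(obj$params, is.null,
                                                     logical(1))])
  experiment_spec(obj$name, obj$array, params, obj$n_arrangements,
                  obj$n_bees, obj$metrics, obj$sweep,
                  obj$improv_windows, obj$route_window)
}
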