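#' Simulation configuration
#'
#' Bundles everything a run needs: sample size and units, demography,
#' detection threshold, algorithm variant, optional sweep, regime thresholds
#' and the seed. All randomness in a run derives from `seed`; the RNG
#' consumption order (genealogy first, then endpoint draws for events in
#' time order, left before right within each branch) is part of the
#' reproducibility contract, so identical `(seed, config)` give identical
#' output.
#'
#' @param n Sample size, in `units`.
#' @param units `"diploid"` (default; doubled to haploids) or `"haploid"`.
#' @param demography A [demography()] object (or path to a YAML model).
#' @param w Detection threshold in Morgans.
#' @param algorithm One of `"fast"` (pruning and merging), `"prune_only"`,
#'   `"merge_only"`, `"naive"`.
#' @param sweep `NULL`, or a list with `s`, `p0` and optionally
#'   `split = "auto"|"explicit"` and `n_carrier` (haploids; used when
#'   `split = "explicit"`).
#' @param regime A [regime_config()].
#' @param seed Integer seed, or `NULL` to continue the current RNG stream.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n, units = c("diploid", "haploid"),
                       demography = demography_constant(),
                       w = 0.01,
                       algorithm = c("fast", "prune_only", "merge_only", "naive"),
                       sweep = NULL, regime = regime_config(), seed = NULL) {
  units <- match.arg(units)
  algorithm <- match.arg(algorithm)
  if (is.character(demography)) demography <- read_demography(demography)
  stopifnot(inherits(demography, "demography"), inherits(regime, "regime_config"))
  if (w < 0) stop("w must be non-negative", call. = FALSE)
  n_hap <- if (units == "diploid") 2L * as.integer(n) else as.integer(n)
  if (n_hap < 2L) stop("need at least 2 haploids (1 diploid)", call. = FALSE)
  if (!is.null(sweep)) {
    if (is.null(sweep$s) || is.null(sweep$p0)) {
      stop("sweep must supply s and p0", call. = FALSE)
    }
    sweep$split <- sweep$split %||% "auto"
    if (!sweep$split %in% c("auto", "explicit")) {
      stop("sweep$split must be 'auto' or 'explicit'", call. = FALSE)
    }
    if (sweep$split == "explicit" && is.null(sweep$n_carrier)) {
      stop("sweep$split = 'explicit' requires sweep$n_carrier", call. = FALSE)
    }
  }
  structure(list(n = as.integer(n), units = units, n_haploid = n_hap,
                 demography = demography, w = w, algorithm = algorithm,
                 sweep = sweep, regime = regime, seed = seed),
            class = "sim_config")
}

algorithm_flags <- function(algorithm) {
  switch(algorithm,
         fast = list(prune = TRUE, merge = TRUE),
         prune_only = list(prune = TRUE, merge = FALSE),
         merge_only = list(prune = FALSE, merge = TRUE),
         naive = list(prune = FALSE, merge = FALSE),
         stop("unknown algorithm", call. = FALSE))
}

#' Simulate detectable IBD segments end to end
#'
#' Simulates the genealogy (sweep-structured if configured), draws the
#' per-branch recombination endpoint log, and extracts all IBD segments of
#' length at least `w` Morgans overlapping the focal locus.
#'
#' @param config A [sim_config()]; alternatively pass the same arguments
#'   directly through `...`.
#' @param ... Arguments forwarded to [sim_config()] when `config` is
#'   missing.
#' @return An `ibd_sim` object: `$segments` (tibble), `$stats`, `$tree`,
#'   `$config`. Use [generics::tidy()] for the segment table and
#'   [generics::glance()] for the one-row run summary.
#' @examples
#' sim <- simulate_ibd(n = 50, demography = demography_constant(1000),
#'                     w = 0.005, seed = 7)
#' glance(sim)
#' @export
simulate_ibd <- function(config, ...) {
  if (missing(config)) config <- sim_config(...)
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n_hap <- config$n_haploid
  if (is.null(config$sweep)) {
    tree <- simulate_tree(n_hap, config$demography, config$regime)
  } else {
    sw <- sweep_trajectory(config$sweep$s, config$sweep$p0, config$demography)
    if (identical(config$sweep$split, "explicit")) {
      n_car <- as.integer(config$sweep$n_carrier)
    } else if (is.infinite(sw$t_mutation)) {
      n_car <- 0L
    } else {
      n_car <- split_carriers(n_hap, sw)[["carrier"]]
    }
    tree <- simulate_structured_tree(n_car, n_hap - n_car,
                                     config$demography, sw, config$regime)
  }
  flags <- algorithm_flags(config$algorithm)
  res <- extract_detectable_ibd(tree, config$w,
                                prune = flags$prune, merge = flags$merge)
  structure(list(segments = res$segments, stats = res$stats,
                 draw_log = res$draw_log, tree = tree, config = config),
            class = "ibd_sim")
}

#' @export
print.ibd_sim <- function(x, ...) {
  cfg <- x$config
  cat("<ibd_sim> ", cfg$n_haploid, " haploids, w = ", cfg$w,
      " M, algorithm = ", cfg$algorithm, "\n", sep = "")
  cat("  ", x$stats$n_segments, " detectable segment(s), TMRCA ",
      format(tmrca(x$tree), digits = 6), " generations\n", sep = "")
  invisible(x)
}

#' Run a configured simulation and write its outputs
#'
#' End-to-end driver: [simulate_ibd()] plus TSV output. Byte-identical
#' output files for identical `(seed, config)`.
#'
#' @param config A [sim_config()].
#' @param out Path for the segments TSV (optional).
#' @param draw_log_out Path for the branch draw log TSV (optional).
#' @return The `ibd_sim` object, invisibly.
#' @export
run_simulation <- function(config, out = NULL, draw_log_out = NULL) {
  sim <- simulate_ibd(config)
  if (!is.null(out)) write_ibd_segments(sim$segments, out)
  if (!is.null(draw_log_out)) write_draw_log(sim$draw_log, draw_log_out)
  invisible(sim)
}

#' Read or write a simulation configuration (YAML, JSON accepted)
#'
#' @param path File path; `.json` files are parsed as JSON, anything else as
#'   YAML.
#' @param config A [sim_config()].
#' @return `read_config()` returns a [sim_config()]; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    if (!requireNamespace("jsonlite", quietly = TRUE)) {
      stop("jsonlite is required for JSON configs", call. = FALSE)
    }
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  ep <- dplyr::bind_rows(lapply(doc$demography$epochs, function(e) {
    e$end <- if (is.null(e$end) || identical(e$end, "Inf")) Inf else as.numeric(e$end)
    tibble::as_tibble(e)
  }))
  dem <- demography(ep, label = doc$demography$label %||% "from_config",
                    units = doc$demography$units %||% "haploid")
  reg <- do.call(regime_config, doc$regime %||% list())
  sim_config(n = doc$n, units = doc$units %||% "diploid", demography = dem,
             w = doc$w %||% 0.01, algorithm = doc$algorithm %||% "fast",
             sweep = doc$sweep, regime = reg, seed = doc$seed)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  dem <- config$demography
  eps <- lapply(seq_len(nrow(dem)), function(i) {
    list(start = dem$start[i],
         end = if (is.finite(dem$end[i])) dem$end[i] else "Inf",
         size = dem$size[i], growth = dem$growth[i])
  })
  doc <- list(
    n = config$n, units = config$units, w = config$w,
    algorithm = config$algorithm,
    demography = list(label = attr(dem, "label"), units = "haploid",
                      epochs = eps),
    regime = config$regime[c("binomial_min_expected", "binomial_max_ratio",
                             "kingman_max_expected", "use_kingman_tail",
                             "use_poisson_limit", "pseudocode_rule")],
    sweep = config$sweep, seed = config$seed
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

fixture_tree <- function(times, child1, child2, n) {
  n_nodes <- 2L * n - 1L
  parent <- rep(NA_integer_, n_nodes)
  c1 <- rep(NA_integer_, n_nodes); c2 <- rep(NA_integer_, n_nodes)
  for (i in seq_along(child1)) {
    v <- n + i
    c1[v] <- child1[i]; c2[v] <- child2[i]
    parent[child1[i]] <- v; parent[child2[i]] <- v
  }
  structure(list(time = c(rep(0, n), times), parent = parent,
                 child1 = c1, child2 = c2, n_leaves = n,
                 n_multi_merger_groups = 0L, kingman_from = NA_real_),
            class = "coalescent_tree")
}

fixture_draw_log <- function(tree, lr) {
  ev <- event_nodes(tree)
  child <- as.vector(rbind(tree$child1[ev], tree$child2[ev]))
  tibble::new_tibble(list(child_id = as.integer(child),
                          parent_id = rep(ev, each = 2L),
                          l_prime = lr[, 1L], r_prime = lr[, 2L]),
                     nrow = length(child))
}

#' Deterministic fixtures: small trees with recorded endpoint draws
#'
#' Small fixed genealogies for exactness and unit tests. `"two_leaf"` is a
#' cherry with a 100-generation TMRCA; `"three_leaf_merge"` has two leaves
#' coalescing at `u = 50` and their ancestor joining the third leaf at
#' `u + v = 100` (the endpoint-sharing geometry); `"fig_four_leaf"` is a
#' four-leaf caterpillar with ancestors at 50, 120 and 200 generations.
#' Expected segments are precomputed with [naive_oracle()].
#'
#' @param name Fixture name.
#' @param w Detection threshold in Morgans.
#' @param draws `"fixed"` (deterministic recorded values), `"unit"` (every
#'   endpoint 1.0 Morgans) or `"random"` (drawn from the current RNG
#'   stream).
#' @return A list: `tree`, `draw_log`, `w`, `expected_segments`.
#' @examples
#' fx <- make_fixture("two_leaf", w = 0.02)
#' fx$expected_segments
#' @export
make_fixture <- function(name = c("two_leaf", "three_leaf_merge",
                                  "fig_four_leaf"),
                         w = 0, draws = c("fixed", "unit", "random")) {
  name <- match.arg(name)
  draws <- match.arg(draws)
  tree <- switch(name,
    two_leaf = fixture_tree(100, 1L, 2L, 2L),
    three_leaf_merge = fixture_tree(c(50, 100), c(1L, 4L), c(2L, 3L), 3L),
    fig_four_leaf = fixture_tree(c(50, 120, 200), c(1L, 5L, 6L),
                                 c(2L, 3L, 4L), 4L)
  )
  n_branch <- 2L * (tree$n_leaves - 1L)
  lr <- switch(draws,
    unit = matrix(1, nrow = n_branch, ncol = 2L),
    random = NULL,
    fixed = switch(name,
      two_leaf = rbind(c(0.03, 0.02), c(0.01, 0.05)),
      three_leaf_merge = rbind(c(0.04, 0.03), c(0.02, 0.06),
                               c(0.05, 0.01), c(0.015, 0.025)),
      fig_four_leaf = rbind(c(0.030, 0.020), c(0.012, 0.045),
                            c(0.008, 0.016), c(0.020, 0.010),
                            c(0.004, 0.009), c(0.011, 0.007))
    )
  )
  draw_log <- if (is.null(lr)) draw_branch_draws(tree) else fixture_draw_log(tree, lr)
  list(tree = tree, draw_log = draw_log, w = w,
       expected_segments = naive_oracle(tree, draw_log, w))
}
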