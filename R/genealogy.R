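choose2 <- function(k) k * (k - 1) / 2

#' Regime configuration for the hybrid coalescent
#'
#' Controls how the simulator switches between the three genealogy regimes:
#' exact discrete Wright-Fisher parent sampling, the binomial approximation
#' to the number of simultaneous pairwise coalescences, and the continuous
#' Kingman tail.
#'
#' The default rule is: exact WF parent sampling while `k / N(t)` exceeds
#' `binomial_max_ratio` (0.1, i.e. `k^3/N^3 > 1e-3`, the scale at which the
#' binomial independence approximation degrades); otherwise a per-generation
#' binomial coalescence count (with an exact geometric skip across constant
#' epochs when the expected count drops below `binomial_min_expected`); and
#' the Kingman coalescent once the expected count per generation is at most
#' `kingman_max_expected` for all remaining time. `pseudocode_rule = TRUE`
#' selects the inverted threshold rule (binomial whenever `k^3/N^3` is *not*
#' small) for compatibility experiments.
#'
#' @param binomial_min_expected Expected coalescences per generation above
#'   which the per-generation binomial draw is always used (below it the
#'   geometric skip applies). Default 1.
#' @param binomial_max_ratio Cap on `k/N(t)` for the binomial approximation;
#'   above it exact WF parent sampling is used. Default 0.1.
#' @param kingman_max_expected Expected coalescences per generation below
#'   which (for all remaining time) the Kingman tail takes over. Default 0.05.
#' @param use_kingman_tail Enable the continuous Kingman tail. Default TRUE.
#' @param use_poisson_limit Draw the coalescence count as Poisson rather than
#'   binomial. Default FALSE.
#' @param pseudocode_rule Use the literal pseudocode regime branch. Default
#'   FALSE.
#' @return A list of class `regime_config`.
#' @export
regime_config <- function(binomial_min_expected = 1,
                          binomial_max_ratio = 0.1,
                          kingman_max_expected = 0.05,
                          use_kingman_tail = TRUE,
                          use_poisson_limit = FALSE,
                          pseudocode_rule = FALSE) {
  stopifnot(binomial_min_expected > 0, binomial_max_ratio > 0,
            kingman_max_expected > 0)
  if (kingman_max_expected >= binomial_min_expected) {
    stop("kingman_max_expected must be < binomial_min_expected", call. = FALSE)
  }
  structure(list(binomial_min_expected = binomial_min_expected,
                 binomial_max_ratio = binomial_max_ratio,
                 kingman_max_expected = kingman_max_expected,
                 use_kingman_tail = isTRUE(use_kingman_tail),
                 use_poisson_limit = isTRUE(use_poisson_limit),
                 pseudocode_rule = isTRUE(pseudocode_rule)),
            class = "regime_config")
}

#' Number of simultaneous pairwise coalescences in one generation
#'
#' Draws `X ~ Binomial(choose(k,2), 1/N)` (or `Poisson(choose(k,2)/N)` under
#' the Poisson limit), truncated at `floor(k/2)` since no more disjoint pairs
#' can merge.
#'
#' @param k Current lineage count (`>= 2`).
#' @param N Haploid population size in the parental generation.
#' @param regime A [regime_config()].
#' @return A non-negative integer count.
#' @export
draw_coalescence_count <- function(k, N, regime = regime_config()) {
  stopifnot(k >= 2, N >= 2)
  m <- choose2(k)
  x <- if (regime$use_poisson_limit || m > .Machine$integer.max) {
    stats::rpois(1L, m / N)
  } else {
    stats::rbinom(1L, m, 1 / N)
  }
  min(x, floor(k / 2))
}

#' Pair lineages for simultaneous coalescence
#'
#' Samples `X` disjoint pairs uniformly at random without replacement from
#' the lineages present at the start of a generation, so a newly created
#' parent can never coalesce again within the same generation (binary
#' mergers only).
#'
#' @param lineages Vector of lineage ids.
#' @param X Number of pairs (`2 * X <= length(lineages)`).
#' @return A 2-column matrix of ids, one row per coalescing pair (0 rows if
#'   `X == 0`).
#' @export
apply_simultaneous_coalescences <- function(lineages, X) {
  if (2 * X > length(lineages)) {
    stop("cannot coalesce more disjoint pairs than lineages allow", call. = FALSE)
  }
  if (X == 0L) return(matrix(integer(0), ncol = 2))
  sel <- sample(lineages, 2L * X)
  matrix(sel, ncol = 2L, byrow = TRUE)
}

#' One generation of exact Wright-Fisher parent sampling
#'
#' Every lineage draws a parent label uniformly from `1..N`; lineages sharing
#' a parent form a sibling group. Groups of three or more are resolved by the
#' caller into sequential binary mergers within the same generation.
#'
#' @param lineages Vector of lineage ids (`length(lineages) <= N` is not
#'   required; `k > N` forces collisions by pigeonhole and is allowed for
#'   structured models, but the neutral simulator never exceeds `N`).
#' @param N Haploid population size in the parental generation.
#' @return A list of integer vectors, one per sibling group of size >= 2
#'   (empty list when no lineages collide).
#' @export
exact_wf_generation <- function(lineages, N) {
  k <- length(lineages)
  if (k < 2L) return(list())
  parents <- sample.int(max(1, floor(N)), k, replace = TRUE)
  dup <- parents %in% parents[duplicated(parents)]
  if (!any(dup)) return(list())
  unname(split(lineages[dup], parents[dup]))
}

#' Simulate a coalescent tree under a demographic model
#'
#' Simulates the genealogy of `n` haploid samples back to their most recent
#' common ancestor using the hybrid regime logic of [regime_config()]. Node
#' times are in generations before present: integer during the discrete
#' Wright-Fisher phases, continuous real in the Kingman tail. The event loop
#' runs to a single root so that the final cross-pair comparison can still be
#' recorded by the IBD engine.
#'
#' @param n Haploid sample size (`2 <= n <= N(0)`).
#' @param model A [demography()] object.
#' @param regime A [regime_config()].
#' @return A `coalescent_tree`: list with numeric `time`, integer `parent`,
#'   `child1`, `child2` over node ids `1..(2n-1)` (leaves `1..n` at time 0;
#'   internal nodes in non-decreasing time order), plus bookkeeping counters.
#' @examples
#' set.seed(1)
#' tr <- simulate_tree(4, demography_constant(500, units = "haploid"))
#' tmrca(tr)
#' @export
simulate_tree <- function(n, model, regime = regime_config()) {
  stopifnot(inherits(model, "demography"), inherits(regime, "regime_config"))
  if (n < 2) stop("n must be at least 2", call. = FALSE)
  if (n > size_at(model, 0)) stop("sample size exceeds N(0)", call. = FALSE)
  st <- new_tree_state(as.integer(n))
  st$active <- neutral_loop(st, st$active, 0, model, regime)
  finish_tree(st)
}

# Mutable tree-building state shared by the neutral and structured simulators.
new_tree_state <- function(n) {
  st <- new.env(parent = emptyenv())
  n_nodes <- 2L * n - 1L
  st$n <- n
  st$time <- numeric(n_nodes)
  st$parent <- rep(NA_integer_, n_nodes)
  st$child1 <- rep(NA_integer_, n_nodes)
  st$child2 <- rep(NA_integer_, n_nodes)
  st$active <- seq_len(n)
  st$next_id <- n + 1L
  st$n_multi <- 0L
  st$kingman_from <- NA_real_
  st
}

merge_pair <- function(st, a, b, tau) {
  id <- st$next_id
  st$time[id] <- tau
  st$child1[id] <- a; st$child2[id] <- b
  st$parent[a] <- id; st$parent[b] <- id
  st$next_id <- id + 1L
  id
}

merge_group <- function(st, g, tau) {
  # sequential binary mergers within one generation (random order for >2)
  if (length(g) > 2L) {
    st$n_multi <- st$n_multi + 1L
    g <- sample(g)
  }
  cur <- g[1L]
  for (j in 2L:length(g)) cur <- merge_pair(st, cur, g[j], tau)
  cur
}

finish_tree <- function(st) {
  structure(list(time = st$time, parent = st$parent, child1 = st$child1,
                 child2 = st$child2, n_leaves = st$n,
                 n_multi_merger_groups = st$n_multi,
                 kingman_from = st$kingman_from),
            class = "coalescent_tree")
}

# One generation of coalescence among `active` with parental-generation size N
# at backward time tau; returns the updated active set.
wf_step <- function(st, active, N, tau, regime, use_exact) {
  if (use_exact) {
    groups <- exact_wf_generation(active, N)
    if (length(groups)) {
      new_ids <- vapply(groups, function(g) merge_group(st, g, tau), integer(1))
      active <- c(setdiff(active, unlist(groups)), new_ids)
    }
    return(active)
  }
  x <- draw_coalescence_count(length(active), N, regime)
  if (x > 0L) {
    pairs <- apply_simultaneous_coalescences(active, x)
    new_ids <- integer(nrow(pairs))
    for (r in seq_len(nrow(pairs))) {
      new_ids[r] <- merge_pair(st, pairs[r, 1L], pairs[r, 2L], tau)
    }
    active <- c(setdiff(active, as.vector(pairs)), new_ids)
  }
  active
}

# Run the neutral hybrid loop from time t0 until a single lineage remains.
neutral_loop <- function(st, active, t0, model, regime) {
  t <- t0
  repeat {
    k <- length(active)
    if (k <= 1L) break

    if (regime$use_kingman_tail &&
        choose2(k) / min_future_size(model, t) <= regime$kingman_max_expected) {
      st$kingman_from <- t
      lam <- cumulative_rate(model, t)
      while (length(active) > 1L) {
        kk <- length(active)
        lam <- lam + stats::rexp(1L, choose2(kk))
        g <- invert_cumulative_rate(model, lam)
        pick <- sample.int(kk, 2L)
        id <- merge_pair(st, active[pick[1L]], active[pick[2L]], g)
        active <- c(active[-pick], id)
      }
      break
    }

    tnext <- t + 1
    N <- size_at(model, tnext)
    ratio <- k / N
    use_exact <- if (regime$pseudocode_rule) {
      (ratio^3) <= regime$binomial_max_ratio^3 # inverted rule: exact WF only when k^3 << N^3
    } else {
      ratio > regime$binomial_max_ratio
    }

    exp_count <- choose2(k) / N
    ep <- epoch_index(model, tnext)
    if (!use_exact && exp_count < regime$binomial_min_expected &&
        model$growth[ep] == 0) {
      # exact geometric skip to the first generation with >= 1 coalescence,
      # capped at the last integer generation inside this constant epoch
      m <- choose2(k)
      p0 <- (1 - 1 / N)^m # P(X = 0) per generation
      gap <- stats::rgeom(1L, 1 - p0) + 1
      g_last <- if (is.finite(model$end[ep])) ceiling(model$end[ep]) - 1 else Inf
      if (tnext + gap - 1 > g_last) {
        t <- g_last # no event inside this epoch; move on
        next
      }
      tau <- tnext + gap - 1
      u <- stats::runif(1L, p0, 1)
      x <- max(min(stats::qbinom(u, m, 1 / N), floor(k / 2)), 1L)
      pairs <- apply_simultaneous_coalescences(active, x)
      new_ids <- integer(nrow(pairs))
      for (r in seq_len(nrow(pairs))) {
        new_ids[r] <- merge_pair(st, pairs[r, 1L], pairs[r, 2L], tau)
      }
      active <- c(setdiff(active, as.vector(pairs)), new_ids)
      t <- tau
      next
    }

    active <- wf_step(st, active, N, tnext, regime, use_exact)
    t <- tnext
  }
  active
}

#' @export
print.coalescent_tree <- function(x, ...) {
  cat("<coalescent_tree> ", x$n_leaves, " leaves, TMRCA ",
      format(tmrca(x), digits = 6), " generations\n", sep = "")
  invisible(x)
}

#' Time to the most recent common ancestor of the sample
#'
#' @param tree A `coalescent_tree`.
#' @return Root time in generations.
#' @export
tmrca <- function(tree) {
  stopifnot(inherits(tree, "coalescent_tree"))
  max(tree$time)
}

#' Internal event nodes of a tree in time order
#'
#' @param tree A `coalescent_tree`.
#' @return Integer vector of internal node ids sorted by event time
#'   (creation order, which is non-decreasing in time).
#' @keywords internal
event_nodes <- function(tree) {
  seq.int(tree$n_leaves + 1L, 2L * tree$n_leaves - 1L)
}

#' Tidy a coalescent tree into a node table
#'
#' @param x A `coalescent_tree`.
#' @param ... Unused.
#' @return A tibble with one row per node: `id`, `time` (generations),
#'   `parent`, `child1`, `child2`, `is_leaf`.
#' @method tidy coalescent_tree
#' @export
tidy.coalescent_tree <- function(x, ...) {
  n_nodes <- 2L * x$n_leaves - 1L
  tibble::new_tibble(list(
    id = seq_len(n_nodes), time = x$time, parent = x$parent,
    child1 = x$child1, child2 = x$child2,
    is_leaf = seq_len(n_nodes) <= x$n_leaves
  ), nrow = n_nodes)
}

#' Structural validity checks for a coalescent tree
#'
#' Verifies the binary-merger invariants: `n - 1` internal nodes, every
#' internal node's time at least its children's (strictly greater except for
#' ties within one generation's sequential resolution of a multi-child
#' sibling group), leaves at time 0, a single parentless root, and
#' non-decreasing event times.
#'
#' @param tree A `coalescent_tree`.
#' @return `TRUE` (invisibly) or an error describing the violation.
#' @export
validate_tree <- function(tree) {
  stopifnot(inherits(tree, "coalescent_tree"))
  n <- tree$n_leaves
  n_nodes <- 2L * n - 1L
  ev <- event_nodes(tree)
  if (length(tree$time) != n_nodes) stop("wrong node count")
  if (any(tree$time[seq_len(n)] != 0)) stop("leaves must be at time 0")
  if (any(is.na(tree$child1[ev])) || any(is.na(tree$child2[ev]))) {
    stop("internal nodes must have two children")
  }
  for (v in ev) {
    if (tree$time[v] < tree$time[tree$child1[v]] ||
        tree$time[v] < tree$time[tree$child2[v]]) {
      stop("node time below a child's time")
    }
  }
  if (is.unsorted(tree$time[ev])) stop("event times must be non-decreasing")
  root <- which(is.na(tree$parent))
  if (length(root) != 1L || root != n_nodes) stop("root must be the last node")
  kids <- c(tree$child1[ev], tree$child2[ev])
  if (anyDuplicated(kids) || length(kids) != n_nodes - 1L) {
    stop("every non-root node must have exactly one parent")
  }
  invisible(TRUE)
}

#' Export a tree to Newick
#'
#' Branch lengths are in generations; tip labels are the 0-based haploid ids
#' `h0..h(n-1)`. Requires the \pkg{ape} package.
#'
#' @param tree A `coalescent_tree`.
#' @param path Optional file path; if `NULL` the Newick string is returned.
#' @return The Newick string (invisibly when written to a file).
#' @export
write_newick <- function(tree, path = NULL) {
  if (!requireNamespace("ape", quietly = TRUE)) {
    stop("ape is required for Newick export", call. = FALSE)
  }
  phy <- as_phylo(tree)
  str <- ape::write.tree(phy)
  if (is.null(path)) return(str)
  writeLines(str, path)
  invisible(str)
}

#' Convert to an ape phylo object
#'
#' @param tree A `coalescent_tree`.
#' @return An \pkg{ape} `phylo` object with edge lengths in generations.
#' @export
as_phylo <- function(tree) {
  stopifnot(inherits(tree, "coalescent_tree"))
  if (!requireNamespace("ape", quietly = TRUE)) {
    stop("ape is required for phylo conversion", call. = FALSE)
  }
  n <- tree$n_leaves
  n_nodes <- 2L * n - 1L
  # ape wants tips 1..n and the root at n+1; our root is node 2n-1
  ape_id <- function(id) ifelse(id <= n, id, n + (2L * n - id))
  non_root <- setdiff(seq_len(n_nodes), n_nodes)
  edge <- cbind(ape_id(tree$parent[non_root]), ape_id(non_root))
  len <- tree$time[tree$parent[non_root]] - tree$time[non_root]
  phy <- list(edge = edge, edge.length = len,
              tip.label = paste0("h", seq_len(n) - 1L), Nnode = n - 1L)
  class(phy) <- "phylo"
  stats::reorder(phy)
}
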