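#' Draw recombination endpoints for a branch
#'
#' After `t` meioses, the surviving haplotype length to each side of the
#' focal locus is `Exponential(t)` in Morgans, and the left and right
#' distances are independent. One pair is drawn per branch and shared by
#' every sample lineage descending through it.
#'
#' @param branch_length Branch length in generations (`> 0`).
#' @param n Number of pairs to draw (vectorised helper for calibration
#'   checks; the simulator itself uses `n = 1` per branch).
#' @return A tibble with columns `l_prime`, `r_prime` (Morgans). Draws are
#'   consumed from the RNG stream left-then-right within each pair.
#' @examples
#' set.seed(1)
#' colMeans(draw_branch_endpoints(100, n = 1000))  # both near 0.01
#' @export
draw_branch_endpoints <- function(branch_length, n = 1L) {
  if (branch_length <= 0) stop("branch length must be positive", call. = FALSE)
  x <- stats::rexp(2L * n, rate = branch_length)
  tibble::new_tibble(list(l_prime = x[seq(1L, 2L * n, by = 2L)],
                          r_prime = x[seq(2L, 2L * n, by = 2L)]),
                     nrow = as.integer(n))
}

#' Draw the full per-branch endpoint log for a tree
#'
#' One `(l', r')` exponential pair per child branch, in the documented RNG
#' order: events in time order, `child1` before `child2`, left before right.
#' Zero-length branches (same-generation resolution chains) take the
#' `Exponential(0)` limit `+Inf` on both sides and consume no randomness, so
#' every algorithm variant sees the same stream.
#'
#' @param tree A `coalescent_tree`.
#' @return A tibble `child_id`, `parent_id`, `l_prime`, `r_prime`, one row
#'   per branch (2(n-1) rows).
#' @export
draw_branch_draws <- function(tree) {
  stopifnot(inherits(tree, "coalescent_tree"))
  ev <- event_nodes(tree)
  child <- as.vector(rbind(tree$child1[ev], tree$child2[ev]))
  par <- rep(ev, each = 2L)
  blen <- tree$time[par] - tree$time[child]
  l <- rep(Inf, length(child)); r <- rep(Inf, length(child))
  pos <- which(blen > 0)
  if (length(pos)) {
    x <- stats::rexp(2L * length(pos), rate = rep(blen[pos], each = 2L))
    l[pos] <- x[seq(1L, length(x), by = 2L)]
    r[pos] <- x[seq(2L, length(x), by = 2L)]
  }
  tibble::new_tibble(list(child_id = as.integer(child),
                          parent_id = as.integer(par),
                          l_prime = l, r_prime = r),
                     nrow = length(child))
}

new_ibd_result <- function(segments, stats, draw_log) {
  structure(list(segments = segments, stats = stats, draw_log = draw_log),
            class = "ibd_result")
}

#' @export
print.ibd_result <- function(x, ...) {
  cat("<ibd_result> ", x$stats$n_segments, " detectable segment(s); ",
      x$stats$n_comparisons, " record comparison(s), ",
      x$stats$n_pruned, " pruned, ", x$stats$n_merge_events,
      " merge event(s)\n", sep = "")
  invisible(x)
}

segments_tibble <- function(mat) {
  # mat columns: ida, idb (1-based leaf ids), left, right, length, tmrca
  if (is.null(mat) || nrow(mat) == 0L) {
    return(tibble::new_tibble(list(id_a = integer(), id_b = integer(),
                                   left = numeric(), right = numeric(),
                                   length = numeric(), tmrca = numeric()),
                              nrow = 0L))
  }
  dimnames(mat) <- NULL
  o <- order(mat[, 6L], mat[, 1L], mat[, 2L])
  mat <- mat[o, , drop = FALSE]
  tibble::new_tibble(list(id_a = as.integer(mat[, 1L]) - 1L,
                          id_b = as.integer(mat[, 2L]) - 1L,
                          left = mat[, 3L], right = mat[, 4L],
                          length = mat[, 5L], tmrca = mat[, 6L]),
                     nrow = nrow(mat))
}

#' Extract detectable IBD segments around the focal locus
#'
#' Walks the coalescent events in time order, maintaining one record per
#' surviving ancestral lineage with its left/right endpoints in Morgans.
#' At each event the child branch's shared endpoint pair caps every active
#' record beneath it; records whose surviving width falls below `w` are
#' pruned (optional), records with bit-identical endpoints are merged
#' (optional), and every cross pair of records -- one from each child side --
#' is compared exactly once, at the pair's most recent common ancestor.
#' Pruning and merging are exact: the detectable output is identical to the
#' all-pairs computation on the same draw log.
#'
#' @param tree A `coalescent_tree`.
#' @param w Detection threshold in Morgans (`>= 0`); segments of length
#'   `>= w` are emitted.
#' @param prune,merge Enable the pruning / merging optimisations.
#' @param draw_log Optional draw log from [draw_branch_draws()] (for oracle
#'   replay); when `NULL` a fresh log is drawn from the current RNG stream.
#' @param early_exit Stop once at most one active record remains (no further
#'   detectable pair is possible). Defaults to `prune || merge`; the naive
#'   variant runs every event.
#' @return An `ibd_result`: `$segments` (tibble with 0-based haploid ids
#'   `id_a < id_b`, `left`, `right`, `length` in Morgans, `tmrca` in
#'   generations, sorted by `(tmrca, id_a, id_b)`), `$stats` (counters), and
#'   `$draw_log`.
#' @examples
#' set.seed(2)
#' tr <- simulate_tree(8, demography_constant(200, units = "haploid"))
#' extract_detectable_ibd(tr, w = 0.01)
#' @export
extract_detectable_ibd <- function(tree, w, prune = TRUE, merge = TRUE,
                                   draw_log = NULL,
                                   early_exit = prune || merge) {
  stopifnot(inherits(tree, "coalescent_tree"))
  if (w < 0) stop("w must be non-negative", call. = FALSE)
  if (is.null(draw_log)) draw_log <- draw_branch_draws(tree)
  n <- tree$n_leaves
  n_nodes <- 2L * n - 1L
  dl_l <- rep(NA_real_, n_nodes); dl_r <- rep(NA_real_, n_nodes)
  dl_l[draw_log$child_id] <- draw_log$l_prime
  dl_r[draw_log$child_id] <- draw_log$r_prime

  rec_la <- rep(Inf, n); rec_ra <- rep(Inf, n)
  members <- as.list(seq_len(n))
  lin <- vector("list", n_nodes)
  lin[seq_len(n)] <- as.list(seq_len(n))
  n_active <- n
  n_pruned <- 0L; n_merge_events <- 0L; n_comp <- 0
  seg_chunks <- list(); n_chunks <- 0L

  for (v in event_nodes(tree)) {
    if (early_exit && n_active <= 1L) break
    tau <- tree$time[v]
    sides <- list(lin[[tree$child1[v]]], lin[[tree$child2[v]]])
    kids <- c(tree$child1[v], tree$child2[v])
    for (s in 1:2) {
      i <- sides[[s]]
      if (!length(i)) next
      cid <- kids[s]
      if (is.finite(dl_l[cid])) rec_la[i] <- pmin(rec_la[i], dl_l[cid])
      if (is.finite(dl_r[cid])) rec_ra[i] <- pmin(rec_ra[i], dl_r[cid])
      if (prune) {
        keep <- (rec_la[i] + rec_ra[i]) >= w
        nd <- length(i) - sum(keep)
        if (nd) {
          n_pruned <- n_pruned + nd
          n_active <- n_active - nd
          i <- i[keep]
        }
      }
      if (merge && length(i) > 1L) {
        la <- rec_la[i]; ra <- rec_ra[i]
        code <- (match(la, la) - 1) * length(i) + match(ra, ra)
        g <- match(code, code)
        dup <- which(g != seq_along(i))
        if (length(dup)) {
          for (j in dup) {
            tgt <- i[g[j]]
            members[[tgt]] <- c(members[[tgt]], members[[i[j]]])
          }
          n_merge_events <- n_merge_events + length(dup)
          n_active <- n_active - length(dup)
          i <- i[-dup]
        }
      }
      sides[[s]] <- i
    }
    i1 <- sides[[1L]]; i2 <- sides[[2L]]
    n_comp <- n_comp + length(i1) * length(i2)
    if (length(i1) && length(i2)) {
      L <- outer(rec_la[i1], rec_la[i2], pmin)
      R <- outer(rec_ra[i1], rec_ra[i2], pmin)
      W <- L + R
      hit <- which(W >= w & is.finite(W), arr.ind = TRUE)
      if (nrow(hit)) {
        out <- vector("list", nrow(hit))
        for (h in seq_len(nrow(hit))) {
          ma <- members[[i1[hit[h, 1L]]]]
          mb <- members[[i2[hit[h, 2L]]]]
          A <- rep(ma, times = length(mb))
          B <- rep(mb, each = length(ma))
          out[[h]] <- cbind(pmin(A, B), pmax(A, B),
                            L[hit[h, 1L], hit[h, 2L]],
                            R[hit[h, 1L], hit[h, 2L]],
                            W[hit[h, 1L], hit[h, 2L]], tau)
        }
        n_chunks <- n_chunks + 1L
        seg_chunks[[n_chunks]] <- do.call(rbind, out)
      }
    }
    lin[[v]] <- c(i1, i2)
  }

  segs <- if (n_chunks) do.call(rbind, seg_chunks) else NULL
  stats <- list(n_segments = if (is.null(segs)) 0L else nrow(segs),
                n_pruned = n_pruned, n_merge_events = n_merge_events,
                n_comparisons = n_comp, n_active_at_end = n_active)
  new_ibd_result(segments_tibble(segs), stats, draw_log)
}

#' All-pairs oracle for IBD segments
#'
#' Computes, for every haploid pair, the minimum of the left (right) endpoint
#' draws along both paths from leaf to the pair's most recent common
#' ancestor, directly from the draw log -- no pruning, no merging, no early
#' exit. Deterministic given the draw log; used as the independent
#' correctness reference for [extract_detectable_ibd()].
#'
#' @param tree A `coalescent_tree`.
#' @param draw_log A draw log from [draw_branch_draws()] covering every
#'   branch.
#' @param w Detection threshold in Morgans.
#' @return A segments tibble in the same schema and order as
#'   [extract_detectable_ibd()]'s `$segments`.
#' @export
naive_oracle <- function(tree, draw_log, w) {
  stopifnot(inherits(tree, "coalescent_tree"))
  if (w < 0) stop("w must be non-negative", call. = FALSE)
  n <- tree$n_leaves
  n_nodes <- 2L * n - 1L
  dl_l <- rep(NA_real_, n_nodes); dl_r <- rep(NA_real_, n_nodes)
  dl_l[draw_log$child_id] <- draw_log$l_prime
  dl_r[draw_log$child_id] <- draw_log$r_prime
  ev <- event_nodes(tree)
  if (anyNA(dl_l[c(tree$child1[ev], tree$child2[ev])])) {
    stop("draw log does not cover every branch", call. = FALSE)
  }
  # per-node accumulated path minima from each descendant leaf
  acc <- vector("list", n_nodes)
  for (i in seq_len(n)) acc[[i]] <- list(leaf = i, L = Inf, R = Inf)
  seg_chunks <- list(); n_chunks <- 0L
  for (v in ev) {
    tau <- tree$time[v]
    a <- acc[[tree$child1[v]]]; b <- acc[[tree$child2[v]]]
    c1 <- tree$child1[v]; c2 <- tree$child2[v]
    L1 <- pmin(a$L, dl_l[c1]); R1 <- pmin(a$R, dl_r[c1])
    L2 <- pmin(b$L, dl_l[c2]); R2 <- pmin(b$R, dl_r[c2])
    Lp <- outer(L1, L2, pmin); Rp <- outer(R1, R2, pmin)
    Wp <- Lp + Rp
    hit <- which(Wp >= w & is.finite(Wp), arr.ind = TRUE)
    if (nrow(hit)) {
      A <- a$leaf[hit[, 1L]]; B <- b$leaf[hit[, 2L]]
      n_chunks <- n_chunks + 1L
      seg_chunks[[n_chunks]] <- cbind(pmin(A, B), pmax(A, B),
                                      Lp[hit], Rp[hit], Wp[hit], tau)
    }
    acc[[v]] <- list(leaf = c(a$leaf, b$leaf), L = c(L1, L2), R = c(R1, R2))
  }
  segments_tibble(if (n_chunks) do.call(rbind, seg_chunks) else NULL)
}

#' Write or read IBD segments as TSV
#'
#' Schema: `id1_ind id1_hap id2_ind id2_hap left_morgans right_morgans
#' length_morgans tmrca_gen`; haploid `h` (0-based) maps to individual
#' `floor(h/2)` and haplotype `h %% 2`. Floats are written with 10
#' significant digits.
#'
#' @param segments A segments tibble (from an `ibd_result`).
#' @param path File path.
#' @return `write_ibd_segments()` returns `path` invisibly;
#'   `read_ibd_segments()` returns a segments tibble (0-based haploid ids).
#' @export
write_ibd_segments <- function(segments, path) {
  df <- data.frame(
    id1_ind = segments$id_a %/% 2L, id1_hap = segments$id_a %% 2L,
    id2_ind = segments$id_b %/% 2L, id2_hap = segments$id_b %% 2L,
    left_morgans = signif(segments$left, 10),
    right_morgans = signif(segments$right, 10),
    length_morgans = signif(segments$length, 10),
    tmrca_gen = signif(segments$tmrca, 10)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ibd_segments
#' @export
read_ibd_segments <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  tibble::new_tibble(list(
    id_a = as.integer(2L * df$id1_ind + df$id1_hap),
    id_b = as.integer(2L * df$id2_ind + df$id2_hap),
    left = df$left_morgans, right = df$right_morgans,
    length = df$length_morgans, tmrca = df$tmrca_gen
  ), nrow = nrow(df))
}

#' Write or read a branch draw log as TSV
#'
#' @param draw_log A draw log tibble from [draw_branch_draws()].
#' @param path File path.
#' @return The path (write) or the draw log tibble (read).
#' @export
write_draw_log <- function(draw_log, path) {
  utils::write.table(as.data.frame(draw_log), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_draw_log
#' @export
read_draw_log <- function(path) {
  tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "\t"))
}
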