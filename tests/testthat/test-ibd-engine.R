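test_that("branch endpoint draws follow the exponential law, independently", {
  set.seed(10)
  t <- 100
  d <- draw_branch_endpoints(t, n = 30000)
  se <- (1 / t) / sqrt(nrow(d))
  expect_lt(abs(mean(d$l_prime) - 1 / t), 3 * se)
  expect_lt(abs(mean(d$r_prime) - 1 / t), 3 * se)
  # P(r' > w) = exp(-t w)
  p <- exp(-1)
  freq <- mean(d$r_prime > 0.01)
  expect_lt(abs(freq - p), 3 * sqrt(p * (1 - p) / nrow(d)))
  expect_lt(abs(cor(d$l_prime, d$r_prime)), 0.02)
  expect_error(draw_branch_endpoints(0), "positive")
})

test_that("the draw log covers every branch with Inf on zero-length ones", {
  set.seed(11)
  # heavy collisions force same-generation chains with zero-length branches
  tr <- simulate_tree(12, demography_constant(12, units = "haploid"),
                      regime_config(use_kingman_tail = FALSE))
  dl <- draw_branch_draws(tr)
  expect_equal(nrow(dl), 2 * (tr$n_leaves - 1))
  blen <- tr$time[dl$parent_id] - tr$time[dl$child_id]
  expect_true(all(is.infinite(dl$l_prime[blen == 0])))
  expect_true(all(is.finite(dl$l_prime[blen > 0])))
  expect_true(all(dl$l_prime > 0 & dl$r_prime > 0))
})

test_that("fixtures produce the hand-computed segments", {
  fx <- make_fixture("two_leaf", w = 0.02)
  seg <- extract_detectable_ibd(fx$tree, fx$w, draw_log = fx$draw_log)$segments
  expect_equal(nrow(seg), 1)
  expect_equal(seg$left, 0.01)
  expect_equal(seg$right, 0.02)
  expect_equal(seg$length, 0.03)
  expect_equal(seg$tmrca, 100)

  fx4 <- make_fixture("two_leaf", w = 0.04)
  seg4 <- extract_detectable_ibd(fx4$tree, fx4$w, draw_log = fx4$draw_log)$segments
  expect_equal(nrow(seg4), 0)

  unit <- make_fixture("fig_four_leaf", w = 0, draws = "unit")
  segu <- extract_detectable_ibd(unit$tree, 0, draw_log = unit$draw_log)$segments
  expect_equal(nrow(segu), choose(4, 2))
  expect_true(all(segu$length == 2.0))
})

test_that("an infinite threshold prunes every record and emits nothing", {
  set.seed(12)
  tr <- simulate_tree(10, demography_constant(100, units = "haploid"))
  res <- extract_detectable_ibd(tr, w = Inf)
  expect_equal(res$stats$n_segments, 0L)
  # with early exit the last surviving record never reaches an event
  expect_equal(res$stats$n_pruned + res$stats$n_active_at_end, 10L)
  expect_equal(nrow(res$segments), 0)
  # without early exit every record is pruned at its first event
  full <- extract_detectable_ibd(tr, w = Inf, draw_log = res$draw_log,
                                 early_exit = FALSE)
  expect_equal(full$stats$n_pruned, 10L)
  expect_equal(full$stats$n_segments, 0L)
})

test_that("merging unions records that share both shared draws", {
  # force the ancestor branch draws below both individual draws
  fx <- make_fixture("three_leaf_merge")
  dl <- fx$draw_log
  dl$l_prime[dl$child_id == 4] <- 0.001
  dl$r_prime[dl$child_id == 4] <- 0.002
  res <- extract_detectable_ibd(fx$tree, 0, draw_log = dl)
  expect_equal(res$stats$n_merge_events, 1L)
  # the merged pair presents identical segments to the third haplotype
  segs <- res$segments
  ad <- segs[segs$id_a == 0 & segs$id_b == 2, ]
  bd <- segs[segs$id_a == 1 & segs$id_b == 2, ]
  expect_identical(ad$length, bd$length)
  expect_identical(ad$left, bd$left)
})

test_that("pairwise width distribution is consistent with Gamma(2, 2g)", {
  set.seed(13)
  fx <- make_fixture("two_leaf") # TMRCA 100 generations
  g <- 100
  lens <- vapply(1:3000, function(i) {
    extract_detectable_ibd(fx$tree, 0)$segments$length
  }, numeric(1))
  # mean 2/(2g) = 1/g, var 2/(2g)^2
  expect_lt(abs(mean(lens) - 1 / g), 3 * sd(lens) / sqrt(length(lens)))
  expect_gt(ks.test(lens, pgamma, shape = 2, rate = 2 * g)$p.value, 0.01)
})

test_that("fast, prune-only and merge-only match the naive oracle bit-exactly", {
  set.seed(14)
  for (i in 1:40) {
    mod <- random_demography()
    n <- sample(c(2:10, 16, 32, 64), 1)
    n <- max(2, min(n, floor(size_at(mod, 0))))
    tr <- simulate_tree(n, mod, random_regime())
    dl <- draw_branch_draws(tr)
    w <- sample(c(0, 0.005, 0.02), 1)
    ref <- naive_oracle(tr, dl, w)
    for (pr in c(TRUE, FALSE)) for (mg in c(TRUE, FALSE)) {
      got <- extract_detectable_ibd(tr, w, prune = pr, merge = mg,
                                    draw_log = dl)
      expect_same_segments(got, ref)
    }
  }
})

test_that("segment count is monotone non-increasing in the threshold", {
  set.seed(15)
  tr <- simulate_tree(32, demography_constant(500, units = "haploid"))
  dl <- draw_branch_draws(tr)
  counts <- vapply(c(0, 0.001, 0.005, 0.01, 0.05, 0.2),
                   function(w) nrow(extract_detectable_ibd(tr, w,
                                                           draw_log = dl)$segments),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("without pruning or merging every pair is compared exactly once", {
  set.seed(16)
  for (n in c(2, 5, 17)) {
    tr <- simulate_tree(n, demography_constant(200, units = "haploid"))
    res <- extract_detectable_ibd(tr, 0.01, prune = FALSE, merge = FALSE)
    expect_equal(res$stats$n_comparisons, choose(n, 2))
    res0 <- extract_detectable_ibd(tr, 0, prune = FALSE, merge = FALSE)
    expect_equal(nrow(res0$segments), choose(n, 2))
  }
})

test_that("segment counts are exchangeable under leaf relabelling", {
  set.seed(17)
  m <- demography_constant(500, units = "haploid")
  n <- 8
  run_count <- function(permute) {
    tr <- simulate_tree(n, m)
    if (permute) {
      # relabel leaves: apply a random permutation to leaf ids in the tree
      perm <- sample.int(n)
      relab <- function(v) ifelse(!is.na(v) & v <= n, perm[v], v)
      tr$child1 <- relab(tr$child1); tr$child2 <- relab(tr$child2)
      pr <- tr$parent; pr[perm] <- tr$parent[seq_len(n)]; tr$parent <- pr
    }
    nrow(extract_detectable_ibd(tr, 0.005)$segments)
  }
  a <- vapply(1:200, function(i) run_count(FALSE), numeric(1))
  b <- vapply(1:200, function(i) run_count(TRUE), numeric(1))
  expect_gt(suppressWarnings(ks.test(a, b)$p.value), 0.01)
})

test_that("segments and draw logs round-trip through TSV", {
  set.seed(18)
  tr <- simulate_tree(10, demography_constant(300, units = "haploid"))
  res <- extract_detectable_ibd(tr, 0.001)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ibd_segments(res$segments, path)
  back <- read_ibd_segments(path)
  expect_equal(back$id_a, res$segments$id_a)
  expect_equal(back$id_b, res$segments$id_b)
  expect_equal(back$length, res$segments$length, tolerance = 1e-9)
  expect_true(all(back$length >= 0.001))
  expect_true(all(back$id_a < back$id_b))
  # header schema
  hdr <- readLines(path, n = 1)
  expect_equal(hdr, paste("id1_ind", "id1_hap", "id2_ind", "id2_hap",
                          "left_morgans", "right_morgans", "length_morgans",
                          "tmrca_gen", sep = "\t"))
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_draw_log(res$draw_log, path2)
  dl <- read_draw_log(path2)
  expect_equal(dl$child_id, res$draw_log$child_id)
})
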