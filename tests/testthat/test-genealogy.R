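test_that("small trees have the right event structure", {
  set.seed(1)
  m <- demography_constant(50, units = "haploid")
  for (i in 1:20) {
    tr <- simulate_tree(3, m)
    expect_silent(validate_tree(tr))
    ev <- tr$time[4:5]
    expect_length(ev, 2)
    expect_true(ev[2] > ev[1])
  }
  tr2 <- simulate_tree(2, m)
  expect_silent(validate_tree(tr2))
  expect_error(simulate_tree(1, m), "at least 2")
  expect_error(simulate_tree(51, m), "exceeds")
})

test_that("pairwise TMRCA has mean N under the discrete model", {
  set.seed(2)
  N <- 100
  m <- demography_constant(N, units = "haploid")
  reg <- regime_config(use_kingman_tail = FALSE)
  tm <- vapply(1:4000, function(i) tmrca(simulate_tree(2, m, reg)), numeric(1))
  se <- sd(tm) / sqrt(length(tm))
  expect_lt(abs(mean(tm) - N), 3 * se)
  expect_true(all(tm == floor(tm))) # discrete generations
})

test_that("forced exact-WF sampling agrees with the geometric law", {
  set.seed(3)
  N <- 25
  m <- demography_constant(N, units = "haploid")
  reg <- regime_config(use_kingman_tail = FALSE, binomial_max_ratio = 1e-9)
  tm <- vapply(1:5000, function(i) tmrca(simulate_tree(2, m, reg)), numeric(1))
  # chi-square against Geometric(1/N) on mass points 1..20 plus the tail
  obs <- tabulate(pmin(tm, 21), nbins = 21)
  p <- c((1 - 1 / N)^(0:19) / N, (1 - 1 / N)^20)
  expect_gt(suppressWarnings(chisq.test(obs, p = p)$p.value), 0.001)
})

test_that("coalescence-count draws have the binomial mean and truncation", {
  set.seed(4)
  reg <- regime_config()
  k <- 2e4; N <- 2e5
  x <- vapply(1:3000, function(i) draw_coalescence_count(k, N, reg), numeric(1))
  mu <- choose(k, 2) / N # 999.95
  expect_lt(abs(mean(x) - mu), 3 * sqrt(mu / length(x)))
  # truncation contract at tiny N
  xs <- vapply(1:200, function(i) draw_coalescence_count(5, 2, reg), numeric(1))
  expect_true(all(xs <= 2))
  # Poisson limit variant
  regp <- regime_config(use_poisson_limit = TRUE)
  xp <- vapply(1:3000, function(i) draw_coalescence_count(100, 1e4, regp),
               numeric(1))
  expect_lt(abs(mean(xp) - choose(100, 2) / 1e4), 3 * sqrt(0.495 / 3000))
})

test_that("simultaneous coalescences sample uniform disjoint pairings", {
  expect_equal(nrow(apply_simultaneous_coalescences(1:6, 0)), 0)
  forced <- apply_simultaneous_coalescences(c(7L, 9L), 1)
  expect_setequal(as.vector(forced), c(7L, 9L))
  expect_error(apply_simultaneous_coalescences(1:3, 2), "disjoint")
  set.seed(5)
  # with 4 lineages and X = 2 there are 3 perfect matchings; identify each
  # draw by the partner of lineage 1
  partner <- vapply(1:6000, function(i) {
    prs <- apply_simultaneous_coalescences(1:4, 2)
    r <- which(prs == 1L, arr.ind = TRUE)[1]
    sum(prs[r, ]) - 1L
  }, integer(1))
  obs <- tabulate(partner - 1L, nbins = 3)
  expect_gt(chisq.test(obs, p = rep(1 / 3, 3))$p.value, 0.001)
})

test_that("exact WF generation reproduces occupancy expectations", {
  set.seed(6)
  expect_equal(exact_wf_generation(1L, 10), list())
  # k = 2, N = 2: collision probability 1/2
  hit <- mean(vapply(1:20000, function(i) {
    length(exact_wf_generation(1:2, 2)) > 0
  }, logical(1)))
  expect_lt(abs(hit - 0.5), 3 * 0.5 / sqrt(20000))
  # k = N: occupied-parent count has mean N (1 - (1 - 1/N)^N) ~ N (1 - 1/e)
  N <- 40
  distinct <- vapply(1:3000, function(i) {
    gr <- exact_wf_generation(seq_len(N), N)
    mergers <- sum(vapply(gr, length, integer(1))) - length(gr)
    N - mergers
  }, numeric(1))
  mu <- N * (1 - (1 - 1 / N)^N)
  expect_lt(abs(mean(distinct) - mu), 3 * sd(distinct) / sqrt(3000))
})

test_that("the Kingman tail reproduces the expected inter-event times", {
  set.seed(7)
  N <- 1e4; n <- 10
  m <- demography_constant(N, units = "haploid")
  reg <- regime_config(binomial_min_expected = 200, kingman_max_expected = 100)
  R <- 2000
  gaps <- matrix(0, R, n - 1)
  for (i in seq_len(R)) {
    tr <- simulate_tree(n, m, reg)
    gaps[i, ] <- diff(c(0, tr$time[(n + 1):(2 * n - 1)]))
  }
  for (l in n:2) {
    e <- 2 / (l * (l - 1)) * N
    j <- n - l + 1
    expect_lt(abs(mean(gaps[, j]) - e), 3 * sd(gaps[, j]) / sqrt(R))
  }
})

test_that("simulated trees are structurally valid across regimes", {
  set.seed(8)
  for (i in 1:50) {
    mod <- random_demography()
    n <- sample(2:40, 1)
    n <- min(n, floor(size_at(mod, 0)))
    tr <- simulate_tree(max(n, 2), mod, random_regime())
    expect_silent(validate_tree(tr))
  }
  # heavy-collision regime exercises same-generation multi-merger resolution
  m <- demography_constant(10, units = "haploid")
  counts <- vapply(1:50, function(i) {
    tr <- simulate_tree(10, m, regime_config(use_kingman_tail = FALSE))
    validate_tree(tr)
    tr$n_multi_merger_groups
  }, integer(1))
  expect_gt(sum(counts), 0)
})

test_that("trees export to Newick that ape can parse", {
  skip_if_not_installed("ape")
  set.seed(9)
  tr <- simulate_tree(6, demography_constant(100, units = "haploid"))
  phy <- as_phylo(tr)
  expect_s3_class(phy, "phylo")
  str <- write_newick(tr)
  phy2 <- ape::read.tree(text = str)
  expect_equal(ape::Ntip(phy2), 6)
  expect_setequal(phy2$tip.label, paste0("h", 0:5))
  # total tree depth is preserved
  depths <- ape::node.depth.edgelength(phy)
  expect_equal(max(depths), tmrca(tr), tolerance = 1e-8)
})
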