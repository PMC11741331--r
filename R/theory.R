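#' Closed-form results for IBD segment detectability and comparisons
#'
#' Stateless formulas used both as a public API and as oracles in the test
#' suite. Times are expressed in generations (`g`), the product of the
#' coalescent time and the population size, so no separate bookkeeping of
#' coalescent units is needed at this surface.
#'
#' @name theory
NULL

#' Tail probability of the one-sided segment length
#'
#' Probability that the haplotype segment to the right (equivalently left)
#' of the focal locus survives beyond `w` Morgans, given that the common
#' ancestor lived `g` generations ago: `exp(-g * w)`.
#'
#' @param w Threshold in Morgans (`>= 0`).
#' @param g Generations to the common ancestor (`> 0`).
#' @return A probability (vectorised).
#' @examples
#' tail_prob_right(0.01, 100)  # exp(-1)
#' @export
tail_prob_right <- function(w, g) {
  if (any(w < 0)) stop("w must be non-negative", call. = FALSE)
  if (any(g <= 0)) stop("g must be positive", call. = FALSE)
  exp(-g * w)
}

#' Tail probability of the two-sided segment width
#'
#' Probability that the full width (left plus right of the locus, a
#' Gamma(2, g) variate) exceeds `w` Morgans: `exp(-g*w) * (1 + g*w)`.
#'
#' @inheritParams tail_prob_right
#' @return A probability (vectorised); always at least [tail_prob_right()].
#' @export
tail_prob_width <- function(w, g) {
  if (any(w < 0)) stop("w must be non-negative", call. = FALSE)
  if (any(g <= 0)) stop("g must be positive", call. = FALSE)
  exp(-g * w) * (1 + g * w)
}

#' Expected time until a target number of lineages remains
#'
#' Expected time of the `(n - k + 1)`-th coalescent event,
#' `E[T_{n:k+}] = sum_{l=k}^{n} 1/choose(l,2) = 2 (1/(k-1) - 1/n)` in
#' coalescent units; `n = Inf` is accepted symbolically.
#' `expected_coal_time_gen()` multiplies by a constant population size `N`
#' to convert to generations.
#'
#' @param n Sample size (may be `Inf`).
#' @param k Target lineage count (`2 <= k <= n`).
#' @param N Constant haploid population size.
#' @return Time in coalescent units (generations for the `_gen` form).
#' @examples
#' expected_coal_time_gen(Inf, 40, 10000)   # 512.82...
#' expected_coal_time_gen(Inf, 400, 100000) # 501.25...
#' @export
expected_coal_time <- function(n, k) {
  if (any(k < 2)) stop("k must be at least 2", call. = FALSE)
  if (any(k > n)) stop("k must not exceed n", call. = FALSE)
  2 * (1 / (k - 1) - ifelse(is.infinite(n), 0, 1 / n))
}

#' @rdname expected_coal_time
#' @export
expected_coal_time_gen <- function(n, k, N) {
  N * expected_coal_time(n, k)
}

#' Probability that two lineages share a recombination endpoint
#'
#' Haplotypes `a` and `b` coalesce at time `u` into ancestor `c`, which
#' coalesces with another lineage at `u + v`. The probability that `a` and
#' `b` present the same (shared) endpoint at `u + v` -- i.e. that `c`'s
#' endpoint draw `Exponential(v)` beats both individual `Exponential(u)`
#' draws -- is `v / (2u + v)` per side.
#'
#' @param u,v Branch times in generations (`> 0`).
#' @return A probability (vectorised).
#' @examples
#' shared_endpoint_prob(1, 1)  # 1/3
#' @export
shared_endpoint_prob <- function(u, v) {
  if (any(u <= 0) || any(v <= 0)) stop("u and v must be positive", call. = FALSE)
  v / (2 * u + v)
}

#' Limiting probability of a shared endpoint between event ranks
#'
#' Evaluates the shared-endpoint probability with the branch times replaced
#' by twice the expected inter-event times after the `(n-k)`-th and
#' `(n-j)`-th coalescent events:
#' `(k - j) n / (n k + n j - 2 k j)`, which tends to 1 as `j/k -> 0`.
#'
#' @param n Sample size.
#' @param k,j Lineage-count ranks with `j < k <= n`.
#' @return A probability (vectorised).
#' @examples
#' prop1_prob(1000, 100, 10)  # 0.8333...
#' @export
prop1_prob <- function(n, k, j) {
  if (any(j >= k) || any(k > n)) stop("need j < k <= n", call. = FALSE)
  (k - j) * n / (n * k + n * j - 2 * k * j)
}

#' Expected number of endpoint comparisons at a root-ward bifurcation
#'
#' For a random bifurcating tree with `B0 = n` and
#' `Bj ~ Binomial(B(j-1), 1/2)`, the expected number of cross comparisons at
#' level `j` is `E[Bj (B(j-1) - Bj)] = n (n - 1) * 4^(-j)`.
#'
#' @param n Sample size (`>= 2`); a power of 2 matches the worst-case
#'   analysis exactly but is not required by the formula.
#' @param j Bifurcation level (`>= 1`).
#' @return Expected comparison count (vectorised).
#' @examples
#' expected_comparisons(4, 1)  # 3
#' @export
expected_comparisons <- function(n, j) {
  if (any(n < 2)) stop("n must be at least 2", call. = FALSE)
  if (any(j < 1)) stop("j must be at least 1", call. = FALSE)
  n * (n - 1) * 4^(-j)
}

#' Expected number of occupied parents in one Wright-Fisher generation
#'
#' Second-order approximation `E[k'] ~ k - choose(k,2)/N` to the expected
#' number of distinct parents of `k` lineages in a population of `N`
#' haploids; accurate when `k^3 = o(N^3)`.
#'
#' @param k Number of lineages (`>= 2`).
#' @param N Haploid population size (`>= 2`).
#' @return Approximate expected parent count; always below `k`.
#' @export
expected_parents <- function(k, N) {
  if (any(k < 2) || any(N < 2)) stop("need k >= 2 and N >= 2", call. = FALSE)
  k - choose2(k) / N
}

#' Accuracy scale of the binomial approximation
#'
#' Returns `(k/N)^3`, the scale of the error terms neglected by the
#' binomial/second-order approximation; used by the regime selection logic.
#'
#' @param k Number of lineages.
#' @param N Haploid population size.
#' @return `(k/N)^3` (vectorised), increasing in `k`, decreasing in `N`.
#' @examples
#' binomial_validity_ratio(2e4, 2e5)  # 1e-3
#' @export
binomial_validity_ratio <- function(k, N) {
  if (any(k < 1) || any(N < 1)) stop("need k >= 1 and N >= 1", call. = FALSE)
  (k / N)^3
}
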