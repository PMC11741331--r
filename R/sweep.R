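#' Deterministic backward allele-frequency trajectory for a hard sweep
#'
#' The frequency of the favoured allele decreases backward in time under the
#' deterministic logistic decay for genic selection,
#' `p(t+1) = p(t) / (p(t) + (1 - p(t)) * exp(s))`, iterated until the
#' frequency falls to a single copy, `p(t) <= 1 / N(t)`; that generation is
#' the mutation time. `s = 0` gives a constant trajectory and an infinite
#' mutation time (no population structure).
#'
#' @param s Non-negative selection coefficient.
#' @param p0 Present-day allele frequency in `(0, 1]`.
#' @param model A [demography()] object (supplies `N(t)` for the one-copy
#'   boundary).
#' @param one_copy Frequency boundary defining the mutation time; default
#'   `1/N(t)` haploids, set `0.5/N(t)` via `one_copy = "diploid"` for users
#'   thinking in diploid copy numbers.
#' @param trajectory Optional user-supplied numeric vector `p(0), p(1), ...`
#'   overriding the logistic recursion (must be non-increasing, start at
#'   `p0`).
#' @param max_gen Safety cap on the trajectory length.
#' @return A `sweep_model`: list with `s`, `p0`, `p` (frequency per
#'   generation `0..t_mutation`), `t_mutation` (generations; `Inf` when
#'   `s = 0`).
#' @examples
#' sw <- sweep_trajectory(0.04, 0.5, demography_constant(10000))
#' sw$t_mutation
#' @export
sweep_trajectory <- function(s, p0, model, one_copy = c("haploid", "diploid"),
                             trajectory = NULL, max_gen = 1e6) {
  stopifnot(inherits(model, "demography"))
  one_copy <- match.arg(one_copy)
  if (s < 0) stop("s must be non-negative", call. = FALSE)
  if (p0 <= 0 || p0 > 1) stop("p0 must be in (0, 1]", call. = FALSE)
  boundary <- function(t) {
    b <- 1 / size_at(model, t)
    if (one_copy == "diploid") b / 2 else b
  }
  if (s == 0 && is.null(trajectory)) {
    out <- list(s = s, p0 = p0, p = p0, t_mutation = Inf)
    class(out) <- "sweep_model"
    return(out)
  }
  if (is.null(trajectory)) {
    es <- exp(s)
    p <- numeric(0)
    cur <- p0
    t <- 0
    repeat {
      p <- c(p, cur)
      if (cur <= boundary(t)) break
      if (t >= max_gen) stop("trajectory did not reach one copy within max_gen",
                             call. = FALSE)
      cur <- cur / (cur + (1 - cur) * es)
      t <- t + 1
    }
  } else {
    p <- as.numeric(trajectory)
    if (abs(p[1] - p0) > 1e-12 || any(diff(p) > 1e-12)) {
      stop("user trajectory must start at p0 and be non-increasing", call. = FALSE)
    }
    hit <- which(p <= boundary(seq_along(p) - 1))
    if (!length(hit)) stop("user trajectory never reaches one copy", call. = FALSE)
    p <- p[seq_len(hit[1])]
  }
  out <- list(s = s, p0 = p0, p = p, t_mutation = length(p) - 1)
  class(out) <- "sweep_model"
  out
}

#' @export
print.sweep_model <- function(x, ...) {
  cat("<sweep_model> s = ", x$s, ", p0 = ", x$p0, ", mutation at ",
      x$t_mutation, " generations\n", sep = "")
  invisible(x)
}

sweep_freq <- function(sweep, t) {
  # p(t) for integer t; constant at p0 when s = 0
  if (is.infinite(sweep$t_mutation)) return(rep(sweep$p0, length(t)))
  idx <- pmin(t, sweep$t_mutation) + 1
  sweep$p[idx]
}

#' Structured coalescent under a hard selective sweep
#'
#' Splits the sample into carriers of the sweeping allele and non-carriers.
#' Backward in time, each class coalesces only within itself, with effective
#' sizes `N(t) p(t)` and `N(t) (1 - p(t))`; no cross-class merger can happen
#' before the mutation time. At the mutation time all surviving carrier
#' lineages are forced to coalesce (sequential binary mergers within that
#' generation) into the single mutant lineage, which then rejoins the
#' neutral population and simulation continues unstructured. With `s = 0`
#' the model reduces exactly to the neutral single-population simulator.
#'
#' @param n_carrier,n_noncarrier Haploid sample sizes per class (sum >= 2).
#'   Use [split_carriers()] for the default binomial split.
#' @param model A [demography()] object.
#' @param sweep A [sweep_trajectory()] object.
#' @param regime A [regime_config()]; the Kingman tail applies only to the
#'   neutral phase after the mutation time.
#' @return A `coalescent_tree` whose leaves `1..n_carrier` are carriers;
#'   attributes `carriers` (leaf ids) and `t_mutation` are set.
#' @export
simulate_structured_tree <- function(n_carrier, n_noncarrier, model, sweep,
                                     regime = regime_config()) {
  stopifnot(inherits(model, "demography"), inherits(sweep, "sweep_model"),
            inherits(regime, "regime_config"))
  n_carrier <- as.integer(n_carrier); n_noncarrier <- as.integer(n_noncarrier)
  if (n_carrier < 0 || n_noncarrier < 0 || n_carrier + n_noncarrier < 2) {
    stop("class sizes must be non-negative and sum to at least 2", call. = FALSE)
  }
  n <- n_carrier + n_noncarrier
  if (n_carrier > size_at(model, 0) * sweep$p0) {
    stop("carrier sample exceeds the carrier subpopulation", call. = FALSE)
  }
  if (is.infinite(sweep$t_mutation)) {
    tr <- simulate_tree(n, model, regime)
    attr(tr, "carriers") <- seq_len(n_carrier)
    attr(tr, "t_mutation") <- Inf
    return(tr)
  }
  st <- new_tree_state(n)
  carriers <- seq_len(n_carrier)
  act_c <- carriers
  act_n <- setdiff(seq_len(n), carriers)

  class_step <- function(active, N_eff, tau) {
    if (length(active) < 2L) return(active)
    N_eff <- max(N_eff, 2)
    use_exact <- length(active) / N_eff > regime$binomial_max_ratio
    wf_step(st, active, N_eff, tau, regime, use_exact)
  }

  t <- 0
  while (t < sweep$t_mutation &&
         (length(act_c) > 1L || length(act_n) > 1L)) {
    tnext <- t + 1
    N <- size_at(model, tnext)
    p <- sweep_freq(sweep, tnext)
    act_c <- class_step(act_c, N * p, tnext)
    act_n <- class_step(act_n, N * (1 - p), tnext)
    t <- tnext
  }
  # forced coalescence of all surviving carrier lineages at the mutation time
  if (length(act_c) > 1L) {
    act_c <- merge_group(st, act_c, sweep$t_mutation)
  }
  active <- c(act_c, act_n)
  if (length(active) > 1L) {
    active <- neutral_loop(st, active, max(t, sweep$t_mutation), model, regime)
  }
  tr <- finish_tree(st)
  attr(tr, "carriers") <- carriers
  attr(tr, "t_mutation") <- sweep$t_mutation
  tr
}

#' Split a sample into carriers and non-carriers
#'
#' Draws the number of carrier haploids as `Binomial(n, p0)` (the default
#' sampling scheme); an explicit split can instead be passed straight to
#' [simulate_structured_tree()].
#'
#' @param n Total haploid sample size.
#' @param sweep A [sweep_trajectory()] object.
#' @return Named integer vector with elements `carrier`, `noncarrier`.
#' @export
split_carriers <- function(n, sweep) {
  stopifnot(inherits(sweep, "sweep_model"))
  nc <- stats::rbinom(1L, n, sweep$p0)
  c(carrier = nc, noncarrier = n - nc)
}
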