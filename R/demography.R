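#' Piecewise-exponential demographic models
#'
#' A demographic model is an ordered set of epochs tiling backward time
#' `[0, Inf)`. Within an epoch starting at `start` generations before the
#' present with `size` haploids, the haploid population size is
#' `N(t) = size * exp(growth * (t - start))`, so `growth` is the backward-time
#' exponent: a population that grew forward in time has a negative `growth`
#' here. Sizes may jump at epoch boundaries (bottlenecks). The final epoch
#' must be constant (`growth = 0`) so that the cumulative coalescent rate
#' diverges and every sample finds a common ancestor.
#'
#' @param epochs A data frame (or tibble) with columns `start`, `end`
#'   (generations before present, half-open `[start, end)`, last `end = Inf`),
#'   `size` (haploids at `start`) and `growth` (per-generation backward rate).
#' @param label Free-text label for the model.
#' @param units `"haploid"` (default) or `"diploid"`; diploid sizes are
#'   doubled on input and stored as haploids.
#' @return A `demography` object: a tibble of epochs with precomputed
#'   cumulative coalescent-rate offsets.
#' @examples
#' demography(data.frame(start = 0, end = Inf, size = 20000, growth = 0))
#' @export
demography <- function(epochs, label = "custom", units = c("haploid", "diploid")) {
  units <- match.arg(units)
  ep <- as.data.frame(epochs)
  need <- c("start", "end", "size", "growth")
  if (!all(need %in% names(ep))) {
    stop("epochs must have columns start, end, size, growth", call. = FALSE)
  }
  ep <- ep[order(ep$start), need]
  if (units == "diploid") ep$size <- 2 * ep$size
  n <- nrow(ep)
  if (n < 1L) stop("at least one epoch is required", call. = FALSE)
  if (ep$start[1] != 0) stop("first epoch must start at 0", call. = FALSE)
  if (!is.infinite(ep$end[n])) stop("last epoch must end at Inf", call. = FALSE)
  if (any(ep$end <= ep$start)) stop("epoch end must exceed start", call. = FALSE)
  if (n > 1L && any(abs(ep$end[-n] - ep$start[-1]) > 1e-9)) {
    stop("epochs must tile [0, Inf) with no gaps or overlaps", call. = FALSE)
  }
  if (ep$growth[n] != 0) {
    stop("last (infinite) epoch must be constant (growth = 0)", call. = FALSE)
  }
  # minimum size within each epoch is attained at one of its ends
  size_end <- ifelse(is.finite(ep$end),
                     ep$size * exp(ep$growth * (ep$end - ep$start)), ep$size)
  if (any(pmin(ep$size, size_end) < 2)) {
    stop("population size must be >= 2 haploids everywhere", call. = FALSE)
  }
  # cumulative coalescent rate Lambda(g) = int_0^g ds / N(s), closed form
  dur <- ep$end - ep$start
  lam_ep <- ifelse(ep$growth == 0, dur / ep$size,
                   (1 - exp(-ep$growth * dur)) / (ep$size * ep$growth))
  lam0 <- cumsum(c(0, lam_ep[-n]))
  out <- tibble::new_tibble(
    list(start = as.numeric(ep$start), end = as.numeric(ep$end),
         size = as.numeric(ep$size), growth = as.numeric(ep$growth),
         lambda0 = lam0),
    nrow = n
  )
  structure(out, label = label, class = c("demography", class(out)))
}

#' @export
print.demography <- function(x, ...) {
  cat("<demography> '", attr(x, "label"), "': ", nrow(x),
      " epoch(s), sizes in haploids\n", sep = "")
  NextMethod()
  invisible(x)
}

epoch_index <- function(model, t) {
  # last epoch whose start <= t (epochs half-open [start, end))
  findInterval(t, model$start)
}

#' Haploid population size at a time in the past
#'
#' @param model A [demography()] object.
#' @param t Time in generations before present (vectorised, `t >= 0`).
#' @return Haploid population size `N(t)`.
#' @examples
#' m <- demography_constant(10000, units = "diploid")
#' size_at(m, 5)
#' @export
size_at <- function(model, t) {
  stopifnot(inherits(model, "demography"))
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  i <- epoch_index(model, t)
  model$size[i] * exp(model$growth[i] * (t - model$start[i]))
}

#' Cumulative coalescent rate (rescaled time)
#'
#' Computes `Lambda(g) = integral_0^g ds / N(s)` in closed form per epoch
#' (analytic antiderivative of the exponential; no quadrature). This maps
#' generations to the rescaled time in which the Kingman coalescent has
#' pairwise rate 1.
#'
#' @inheritParams size_at
#' @param g Generations before present (vectorised, `g >= 0`).
#' @return Rescaled time, non-decreasing in `g`, `Lambda(0) = 0`.
#' @examples
#' m <- demography_constant(Ne = 10000)
#' cumulative_rate(m, 10000)  # 1 coalescent unit
#' @export
cumulative_rate <- function(model, g) {
  stopifnot(inherits(model, "demography"))
  if (any(g < 0)) stop("g must be non-negative", call. = FALSE)
  i <- epoch_index(model, g)
  dt <- g - model$start[i]
  gr <- model$growth[i]
  within <- ifelse(gr == 0, dt / model$size[i],
                   (1 - exp(-gr * dt)) / (model$size[i] * gr))
  model$lambda0[i] + within
}

#' Invert the cumulative coalescent rate
#'
#' Maps a rescaled (coalescent) time back to generations, the inverse of
#' [cumulative_rate()]. Exact per-epoch closed form; for a constant-size
#' model this is `N * lam` with no iteration error.
#'
#' @inheritParams size_at
#' @param lam Rescaled time (vectorised, `lam >= 0`).
#' @return Generations `g` with `cumulative_rate(model, g) == lam`.
#' @export
invert_cumulative_rate <- function(model, lam) {
  stopifnot(inherits(model, "demography"))
  if (any(lam < 0)) stop("lam must be non-negative", call. = FALSE)
  n <- nrow(model)
  i <- pmin(findInterval(lam, model$lambda0), n)
  # findInterval on ties at epoch-start offsets: fine, zero residual
  resid <- lam - model$lambda0[i]
  gr <- model$growth[i]
  sz <- model$size[i]
  dt <- ifelse(gr == 0, resid * sz, {
    arg <- 1 - resid * sz * gr
    ifelse(arg > 0, -log(arg) / gr, NA_real_)
  })
  if (any(is.na(dt))) {
    stop("lam exceeds the cumulative rate attainable in an epoch", call. = FALSE)
  }
  model$start[i] + dt
}

min_future_size <- function(model, t) {
  # minimum of N(s) over s >= t (each epoch's minimum is at an endpoint)
  i <- epoch_index(model, t)
  n <- nrow(model)
  cand <- size_at(model, t)
  for (j in i:n) {
    s0 <- if (j == i) t else model$start[j]
    cand <- min(cand, model$size[j] * exp(model$growth[j] * (s0 - model$start[j])))
    if (is.finite(model$end[j])) {
      cand <- min(cand, model$size[j] * exp(model$growth[j] * (model$end[j] - model$start[j])))
    }
  }
  cand
}

#' Built-in demographic scenarios
#'
#' Convenience builders for the three study scenarios: a constant-size
#' population, exponential growth interrupted by an instantaneous bottleneck
#' twenty generations before the present, and three phases of increasingly
#' rapid exponential growth from a constant ancestral population. Ancestral
#' sizes follow the study descriptions (bottleneck: 10,000 diploids;
#' three-phase growth: 5,000 diploids); growth rates and the bottleneck
#' magnitude are parameters with documented defaults.
#'
#' @param Ne Diploid or haploid size (see `units`).
#' @param units `"diploid"` (default for builders) or `"haploid"`.
#' @param Ne_anc Ancestral size, in `units`.
#' @param growth Forward-time per-generation exponential growth rate.
#' @param t_bottleneck Generations before present of the instantaneous
#'   reduction.
#' @param reduction Factor (< 1) by which the size is multiplied at the
#'   bottleneck, forward in time.
#' @param t_anc Generations before present at which growth began.
#' @param rates Forward growth rates of the three phases, most recent first.
#' @param breaks Backward-time phase boundaries (generations), increasing.
#' @return A [demography()] object.
#' @examples
#' demography_bottleneck()
#' @name scenarios
NULL

#' @rdname scenarios
#' @export
demography_constant <- function(Ne = 10000, units = c("diploid", "haploid")) {
  units <- match.arg(units)
  demography(data.frame(start = 0, end = Inf, size = Ne, growth = 0),
             label = "constant", units = units)
}

#' @rdname scenarios
#' @export
demography_bottleneck <- function(Ne_anc = 10000, growth = 0.01,
                                  t_bottleneck = 20, reduction = 0.1,
                                  t_anc = 500,
                                  units = c("diploid", "haploid")) {
  units <- match.arg(units)
  if (reduction <= 0 || reduction >= 1) stop("reduction must be in (0,1)", call. = FALSE)
  if (t_anc <= t_bottleneck) stop("t_anc must exceed t_bottleneck", call. = FALSE)
  # forward story: ancestral Ne_anc grows at `growth` from t_anc; at
  # t_bottleneck the size is multiplied by `reduction`; growth continues.
  size_pre_bn <- Ne_anc * exp(growth * (t_anc - t_bottleneck)) # just before crash (older side)
  size_post_bn <- size_pre_bn * reduction                      # just after crash (recent side)
  size_now <- size_post_bn * exp(growth * t_bottleneck)
  demography(
    data.frame(
      start = c(0, t_bottleneck, t_anc),
      end = c(t_bottleneck, t_anc, Inf),
      size = c(size_now, size_pre_bn, Ne_anc),
      growth = c(-growth, -growth, 0)
    ),
    label = "bottleneck", units = units
  )
}

#' @rdname scenarios
#' @export
demography_three_phase <- function(Ne_anc = 5000,
                                   rates = c(0.10, 0.02, 0.005),
                                   breaks = c(20, 100, 300),
                                   units = c("diploid", "haploid")) {
  units <- match.arg(units)
  if (length(rates) != 3 || length(breaks) != 3 || any(diff(breaks) <= 0)) {
    stop("need 3 rates and 3 increasing breaks", call. = FALSE)
  }
  # sizes from the ancestral epoch forward
  s3 <- Ne_anc * exp(rates[3] * (breaks[3] - breaks[2]))
  s2 <- s3 * exp(rates[2] * (breaks[2] - breaks[1]))
  s1 <- s2 * exp(rates[1] * breaks[1])
  demography(
    data.frame(
      start = c(0, breaks),
      end = c(breaks, Inf),
      size = c(s1, s2, s3, Ne_anc),
      growth = c(-rates, 0)
    ),
    label = "three_phase_growth", units = units
  )
}

#' Read or write a demographic model as YAML
#'
#' The document has the form
#' `epochs: [{start: 0, end: 20, size: 1.2e6, growth: 0.14}, ...]` with an
#' optional top-level `units: diploid` (sizes are haploid by default) and
#' `label`.
#'
#' @param path File path.
#' @param model A [demography()] object.
#' @return `read_demography()` returns a [demography()]; `write_demography()`
#'   returns `path` invisibly.
#' @export
read_demography <- function(path) {
  doc <- yaml::read_yaml(path)
  ep <- dplyr::bind_rows(lapply(doc$epochs, function(e) {
    e$end <- if (is.null(e$end) || identical(e$end, "Inf") || identical(e$end, ".inf")) Inf else as.numeric(e$end)
    tibble::as_tibble(e)
  }))
  demography(ep,
             label = doc$label %||% "from_yaml",
             units = doc$units %||% "haploid")
}

#' @rdname read_demography
#' @export
write_demography <- function(model, path) {
  stopifnot(inherits(model, "demography"))
  eps <- lapply(seq_len(nrow(model)), function(i) {
    list(start = model$start[i],
         end = if (is.finite(model$end[i])) model$end[i] else "Inf",
         size = model$size[i], growth = model$growth[i])
  })
  yaml::write_yaml(list(label = attr(model, "label"), units = "haploid",
                        epochs = eps), path)
  invisible(path)
}
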