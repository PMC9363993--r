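#' Divergence between acquisition and first-production orders
#'
#' Mean Manhattan distance between the two rank vectors,
#' `sum(|o_a - o_p|) / (N - 1)`. The divisor excludes the seed agent's
#' first production: the seed is always first to acquire and, in a purely
#' social diffusion, first to produce, so its term is 0 by construction.
#'
#' @param o_a,o_p acquisition and first-production ranks, each a permutation
#'   of `1:N`.
#' @return Non-negative scalar.
#' @export
order_divergence <- function(o_a, o_p) {
  check_permutation(o_a)
  check_permutation(o_p)
  if (length(o_a) != length(o_p)) stop("rank vectors differ in length")
  sum(abs(o_a - o_p)) / (length(o_a) - 1)
}

check_permutation <- function(o) {
  if (!setequal(o, seq_along(o))) stop("ranks must be a permutation of 1:N")
  invisible(o)
}

#' Mean delay between acquisition and first production
#'
#' `mean(|t_a - t_p|)` over all agents.
#'
#' @param t_a,t_p per-agent times of acquisition and first production.
#' @export
time_delay <- function(t_a, t_p) {
  if (length(t_a) != length(t_p)) stop("time vectors differ in length")
  mean(abs(t_a - t_p))
}

#' Proportion of agents with divergent ranks
#'
#' Fraction of agents whose first-production rank differs from their
#' acquisition rank.
#'
#' @inheritParams order_divergence
#' @export
pct_divergent <- function(o_a, o_p) {
  check_permutation(o_a)
  check_permutation(o_p)
  mean(o_a != o_p)
}

#' R-squared between acquisition and first-production ranks
#'
#' Coefficient of determination of the least-squares fit of first-production
#' rank on acquisition rank, computed on agent-level pairs (typically pooled
#' across all replicates of a constellation).
#'
#' @param o_a,o_p paired rank vectors, pooled over runs.
#' @export
r2_orders <- function(o_a, o_p) {
  if (stats::var(o_a) == 0 || stats::var(o_p) == 0) {
    stop("degenerate rank variance")
  }
  summary(stats::lm(o_p ~ o_a))$r.squared
}

#' Diffusion statistics of one run
#'
#' @param record a completed `diffusion_record`.
#' @return List with `ttd`, `ttfp`, `d_order`, `d_time`, `pct_divergent` and
#'   `acquisition_intervals` (gaps between consecutive acquisition events).
#' @export
diffusion_metrics <- function(record) {
  list(
    ttd = record$ttd,
    ttfp = record$ttfp,
    d_order = order_divergence(record$o_a, record$o_p),
    d_time = time_delay(record$t_a, record$t_p),
    pct_divergent = pct_divergent(record$o_a, record$o_p),
    acquisition_intervals = diff(sort(record$t_a))
  )
}

#' Mean, standard error and percentile interval of a batch statistic
#'
#' @param values numeric vector of per-run statistics.
#' @param level central interval mass (default 0.92, i.e. the 4th and 96th
#'   empirical percentiles, linear-interpolation quantiles).
#' @return List with `mean`, `se` (sd / sqrt(n)) and `pi` (length-2 vector).
#' @export
summarize_metric <- function(values, level = 0.92) {
  if (length(values) == 0) stop("empty input")
  tail_p <- (1 - level) / 2
  list(
    mean = mean(values),
    se = stats::sd(values) / sqrt(length(values)),
    pi = unname(stats::quantile(values, c(tail_p, 1 - tail_p), type = 7))
  )
}

#' Per-run and pooled metrics for a batch of runs
#'
#' @param records list of completed `diffusion_record`s from one
#'   constellation.
#' @return List with `per_run` (data frame of per-run ttd/ttfp/d_order/
#'   d_time/pct_divergent), `pooled_r2` (rank pairs pooled across runs),
#'   `pooled_pct_divergent`, and `summary` (a [summarize_metric()] per
#'   column of `per_run`).
#' @export
metrics_table <- function(records) {
  per_run <- do.call(rbind, lapply(records, function(r) {
    m <- diffusion_metrics(r)
    data.frame(
      ttd = m$ttd, ttfp = m$ttfp, d_order = m$d_order,
      d_time = m$d_time, pct_divergent = m$pct_divergent
    )
  }))
  o_a <- unlist(lapply(records, `[[`, "o_a"))
  o_p <- unlist(lapply(records, `[[`, "o_p"))
  list(
    per_run = per_run,
    pooled_r2 = r2_orders(o_a, o_p),
    pooled_pct_divergent = mean(o_a != o_p),
    summary = lapply(per_run, summarize_metric)
  )
}
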