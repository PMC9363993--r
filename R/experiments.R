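#' Run a batch of simulations at one constellation
#'
#' Runs `reps` independent simulations, each on a freshly drawn connected
#' random regular network, with per-run seeds fanned out deterministically
#' from `rng_seed`.
#'
#' @param params a [constellation()].
#' @param reps number of replicate runs.
#' @param rng_seed master seed.
#' @param ... further arguments passed to [run_simulation()].
#' @return List of `diffusion_record`s.
#' @export
run_batch <- function(params, reps = 100, rng_seed = NULL, ...) {
  seeds <- fan_out_seeds(rng_seed, reps)
  lapply(seeds, function(s) run_simulation(params, rng_seed = s, ...))
}

# Deterministic master -> per-task seed fan-out.
fan_out_seeds <- function(rng_seed, n) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  sample.int(.Machine$integer.max - 1, n)
}

#' Replicate the reference condition
#'
#' Runs the reference constellation and returns its batch metrics: mean,
#' standard error and 92% percentile interval for TTD, TTFP, order
#' divergence and time delay, plus the pooled divergent fraction and the
#' pooled rank R-squared.
#'
#' @param reps replicate simulations (100 for the headline summaries).
#' @param rng_seed master seed.
#' @return A [metrics_table()] list, with an added `row`: a one-row data
#'   frame in the style of the sensitivity summary table.
#' @export
reproduce_reference <- function(reps = 100, rng_seed = NULL) {
  tab <- metrics_table(run_batch(reference_constellation(), reps, rng_seed))
  tab$row <- summary_row(reference_constellation(), tab)
  tab
}

summary_row <- function(params, tab) {
  s <- tab$summary
  data.frame(
    label = params$label,
    ttd_mean = s$ttd$mean, ttd_se = s$ttd$se,
    ttd_lo = s$ttd$pi[1], ttd_hi = s$ttd$pi[2],
    ttfp_mean = s$ttfp$mean, ttfp_se = s$ttfp$se,
    ttfp_lo = s$ttfp$pi[1], ttfp_hi = s$ttfp$pi[2],
    pct_divergent = 100 * tab$pooled_pct_divergent,
    d_order_mean = s$d_order$mean, d_order_se = s$d_order$se,
    d_order_lo = s$d_order$pi[1], d_order_hi = s$d_order$pi[2],
    d_time_mean = s$d_time$mean, d_time_se = s$d_time$se,
    d_time_lo = s$d_time$pi[1], d_time_hi = s$d_time$pi[2],
    pooled_r2 = tab$pooled_r2
  )
}

sensitivity_values <- list(
  sigma = c(0.25, 0.5, 0.75),
  f = c(0.33, 1, 3),
  m = c(10, 20, 30),
  rho = c(0.01, 0.10, 0.99),
  alpha = c(0.5, 1, 2)
)

#' One-at-a-time sensitivity sweep of a production parameter
#'
#' Varies a single production parameter over its tested values while holding
#' every other parameter at reference, running a batch at each value.
#'
#' @param vary one of "sigma", "f", "m", "rho", "alpha".
#' @param values values to test; defaults to the standard grid for the
#'   parameter.
#' @param reps replicates per value.
#' @param rng_seed master seed (fanned out per value, then per run).
#' @return List with `rows` (summary data frame, one row per value) and
#'   `tables` (the full [metrics_table()] per value).
#' @export
sensitivity_sweep <- function(vary, values = NULL, reps = 100,
                              rng_seed = NULL) {
  if (!vary %in% names(sensitivity_values)) {
    stop("unknown parameter: ", vary)
  }
  if (is.null(values)) values <- sensitivity_values[[vary]]
  seeds <- fan_out_seeds(rng_seed, length(values))
  tables <- lapply(seq_along(values), function(i) {
    params <- reference_constellation()
    params[[vary]] <- values[i]
    params$label <- sprintf("%s=%g", vary, values[i])
    tab <- metrics_table(run_batch(params, reps, seeds[i]))
    tab$row <- summary_row(params, tab)
    tab
  })
  list(
    rows = do.call(rbind, lapply(tables, `[[`, "row")),
    tables = stats::setNames(tables, sprintf("%s=%g", vary, values))
  )
}

#' TADAc model-comparison battery over the production-parameter grid
#'
#' Generates `reps_per_constellation` datasets for every constellation of
#' [table1_grid()] under the stated data kind and generative mechanism, fits
#' the social and asocial TADAc models to each, and tabulates the AICc
#' comparison. "Ideal" data are times of acquisition generated by the
#' acquisition sub-model alone (knowledge-indicator weights under the social
#' mechanism); "realistic" data are times of first production from the full
#' linked model, fitted with per-agent production-rate weights.
#'
#' @param data_kind `"ideal"` or `"realistic"`.
#' @param mechanism `"social"` or `"asocial"` generative mechanism.
#' @param reps_per_constellation datasets per constellation.
#' @param rng_seed master seed.
#' @param constellations list of [constellation()]s (the full grid by
#'   default).
#' @return List with `table` (one row per dataset: constellation label,
#'   rep, delta AICc, support, estimates, and for realistic data the run's
#'   d_order and d_time), `median_delta_aicc`, `n_social_support`, `n_runs`
#'   and `n_failed` (datasets whose generation or fit failed, excluded).
#' @export
nbda_battery <- function(data_kind = c("ideal", "realistic"),
                         mechanism = c("social", "asocial"),
                         reps_per_constellation = 10,
                         rng_seed = NULL,
                         constellations = table1_grid()) {
  data_kind <- match.arg(data_kind)
  mechanism <- match.arg(mechanism)
  n_total <- length(constellations) * reps_per_constellation
  seeds <- fan_out_seeds(rng_seed, n_total)
  rows <- vector("list", n_total)
  n_failed <- 0
  i <- 0
  for (params in constellations) {
    for (rep in seq_len(reps_per_constellation)) {
      i <- i + 1
      row <- tryCatch(
        {
          dat <- if (data_kind == "ideal") {
            generate_ideal_data(mechanism, params, rng_seed = seeds[i])
          } else {
            generate_realistic_data(mechanism, params, rng_seed = seeds[i])
          }
          fs <- fit_tadac(dat, "social")
          fa <- fit_tadac(dat, "asocial")
          cmp <- delta_aicc(fs, fa)
          out <- data.frame(
            label = params$label, rep = rep,
            delta_aicc = cmp$delta_aicc, support = cmp$support,
            s_hat = fs$s_hat, lambda0_social = fs$lambda0_hat,
            lambda0_asocial = fa$lambda0_hat,
            d_order = NA_real_, d_time = NA_real_
          )
          rec <- attr(dat, "record")
          if (!is.null(rec) && !anyNA(rec$o_p)) {
            out$d_order <- order_divergence(rec$o_a, rec$o_p)
            out$d_time <- time_delay(rec$t_a, rec$t_p)
          }
          out
        },
        error = function(e) NULL
      )
      if (is.null(row)) n_failed <- n_failed + 1 else rows[[i]] <- row
    }
  }
  table <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  list(
    table = table,
    median_delta_aicc = stats::median(table$delta_aicc),
    n_social_support = sum(table$support == "social"),
    n_runs = nrow(table),
    n_failed = n_failed
  )
}

#' Write summary tables of completed experiments to CSV
#'
#' @param results named list; elements may include `reference` (from
#'   [reproduce_reference()]), `sweeps` (a list of [sensitivity_sweep()]
#'   results) and `nbda` (a named list of [nbda_battery()] results).
#' @param dir output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
make_report <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  rows <- list()
  if (!is.null(results$reference)) rows <- c(rows, list(results$reference$row))
  for (sw in results$sweeps) rows <- c(rows, list(sw$rows))
  if (length(rows)) {
    p <- file.path(dir, "summary_table.csv")
    utils::write.csv(do.call(rbind, rows), p, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(results$nbda)) {
    per_run <- do.call(rbind, lapply(names(results$nbda), function(nm) {
      cbind(battery = nm, results$nbda[[nm]]$table)
    }))
    p <- file.path(dir, "nbda_batteries.csv")
    utils::write.csv(per_run, p, row.names = FALSE)
    counts <- do.call(rbind, lapply(names(results$nbda), function(nm) {
      b <- results$nbda[[nm]]
      data.frame(
        battery = nm, median_delta_aicc = b$median_delta_aicc,
        n_social_support = b$n_social_support, n_runs = b$n_runs,
        n_failed = b$n_failed
      )
    }))
    p2 <- file.path(dir, "nbda_summary.csv")
    utils::write.csv(counts, p2, row.names = FALSE)
    paths <- c(paths, p, p2)
  }
  invisible(paths)
}
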