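# Shared fixtures, built in code.

# cycle graph C_n as a social_network
cycle_net <- function(n) generate_ring_lattice(n, 2)

# complete graph K_n
complete_net <- function(n) {
  social_network(matrix(1, n, n) - diag(n), architecture = "complete")
}

# bootstrap standard error of a pooled statistic, resampling whole runs
boot_se_runs <- function(records, stat, n_boot = 200, seed = 1) {
  set.seed(seed)
  vals <- replicate(n_boot, {
    stat(records[sample.int(length(records), replace = TRUE)])
  })
  stats::sd(vals)
}

pooled_r2_stat <- function(records) {
  r2_orders(
    unlist(lapply(records, `[[`, "o_a")),
    unlist(lapply(records, `[[`, "o_p"))
  )
}

pooled_divergent_stat <- function(records) {
  o_a <- unlist(lapply(records, `[[`, "o_a"))
  o_p <- unlist(lapply(records, `[[`, "o_p"))
  mean(o_a != o_p)
}

# bootstrap standard error of a median
boot_se_median <- function(x, n_boot = 400, seed = 1) {
  set.seed(seed)
  stats::sd(replicate(
    n_boot,
    stats::median(x[sample.int(length(x), replace = TRUE)])
  ))
}
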