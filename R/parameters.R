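#' Parameter constellations
#'
#' A `constellation` bundles every parameter of one simulation condition:
#' the acquisition sub-model (baseline learning rate `lambda_b`, social
#' transmission rate `s`, asocial innovation flag `A`), the production
#' sub-model (social information bias `sigma`, frequency-dependent production
#' bias `f`, memory window `m`, recent experience bias `rho`, risk-appetite
#' `alpha`), the population (`N` agents on a degree-`k` network) and the
#' behaviour rewards `r_a`, `r_b`.
#'
#' Parameter meanings, with their admissible ranges:
#' \describe{
#'   \item{sigma}{weight on social versus individual information in the
#'     production mixture, in \[0, 1\].}
#'   \item{f}{exponent on observed behaviour counts; `f > 1` is conformist,
#'     `f < 1` anti-conformist, `f = 1` linear. Must be positive.}
#'   \item{m}{memory window in timesteps (integer, at least 1).}
#'   \item{rho}{weight on the most recent reward in the value update, in
#'     (0, 1).}
#'   \item{alpha}{softmax temperature; small values make choice nearly
#'     deterministic on the highest expected value. Must be positive.}
#'   \item{lambda_b}{baseline per-timestep learning rate, positive.}
#'   \item{s}{social transmission rate, non-negative.}
#'   \item{A}{asocial innovation flag, 0 or 1.}
#' }
#'
#' @param sigma,f,m,rho,alpha production-rule parameters (see Details).
#' @param lambda_b,s,A acquisition parameters.
#' @param N,k population size and network degree.
#' @param r_a,r_b rewards for the established and novel behaviour.
#' @param label free-text name for the condition.
#' @return An object of class `constellation` (a named list).
#' @export
constellation <- function(sigma = 0.5, f = 1, m = 10, rho = 0.1, alpha = 1,
                          lambda_b = 0.05, s = 5, A = 0,
                          N = 24, k = 6, r_a = 1, r_b = 1,
                          label = "reference") {
  x <- list(
    sigma = sigma, f = f, m = m, rho = rho, alpha = alpha,
    lambda_b = lambda_b, s = s, A = A,
    N = as.integer(N), k = as.integer(k), r_a = r_a, r_b = r_b,
    label = label
  )
  validate_constellation(x)
  structure(x, class = "constellation")
}

validate_constellation <- function(x) {
  stopifnot(
    is.numeric(x$sigma), x$sigma >= 0, x$sigma <= 1,
    x$f > 0,
    x$m >= 1, x$m == round(x$m),
    x$rho > 0, x$rho < 1,
    x$alpha > 0,
    x$lambda_b > 0,
    x$s >= 0,
    x$A %in% c(0, 1),
    x$N >= 2, x$k >= 1, x$k < x$N,
    x$r_a >= 0, x$r_b >= 0
  )
  invisible(x)
}

#' @export
print.constellation <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<constellation> '%s'\n",
      "  production:  sigma=%g f=%g m=%d rho=%g alpha=%g\n",
      "  acquisition: lambda_b=%g s=%g A=%g\n",
      "  population:  N=%d k=%d r_a=%g r_b=%g\n"
    ),
    x$label, x$sigma, x$f, x$m, x$rho, x$alpha,
    x$lambda_b, x$s, x$A, x$N, x$k, x$r_a, x$r_b
  ))
  invisible(x)
}

#' The reference parameter constellation
#'
#' The condition against which all sensitivity analyses are compared:
#' sigma = 0.5, f = 1, m = 10, rho = 0.1, alpha = 1, lambda_b = 0.05, s = 5,
#' A = 0, N = 24, k = 6, r_a = r_b = 1.
#'
#' @return A [constellation()].
#' @export
reference_constellation <- function() constellation()

#' The full factorial production-parameter grid
#'
#' The factorial crossing of sigma in \{0.25, 0.5, 0.75\}, f in
#' \{0.33, 1, 3\}, m in \{10, 20, 30\}, rho in \{0.01, 0.10, 0.99\} and
#' alpha in \{0.5, 1, 2\}, with all other fields at reference: 3^5 = 243
#' constellations.
#'
#' @return A list of 243 [constellation()] objects; labels encode the varied
#'   values.
#' @export
table1_grid <- function() {
  grid <- expand.grid(
    sigma = c(0.25, 0.5, 0.75),
    f = c(0.33, 1, 3),
    m = c(10, 20, 30),
    rho = c(0.01, 0.10, 0.99),
    alpha = c(0.5, 1, 2),
    KEEP.OUT.ATTRS = FALSE
  )
  lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    constellation(
      sigma = g$sigma, f = g$f, m = g$m, rho = g$rho, alpha = g$alpha,
      label = sprintf(
        "sigma=%g_f=%g_m=%d_rho=%g_alpha=%g",
        g$sigma, g$f, g$m, g$rho, g$alpha
      )
    )
  })
}

constellation_fields <- c(
  "sigma", "f", "m", "rho", "alpha", "lambda_b", "s", "A",
  "N", "k", "r_a", "r_b", "label"
)

#' Serialize constellations
#'
#' Constellations round-trip through a flat key-value schema (JSON or YAML)
#' with keys sigma, f, m, rho, alpha, lambda_b, s, A, N, k, r_a, r_b, label.
#'
#' @param x a [constellation()].
#' @param path file path; the extension (`.json`, `.yaml`/`.yml`) selects the
#'   format.
#' @export
write_constellation <- function(x, path) {
  vals <- unclass(x)[constellation_fields]
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(vals, path)
  }
  invisible(path)
}

#' @rdname write_constellation
#' @export
read_constellation <- function(path) {
  vals <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(constellation, vals[constellation_fields])
}
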