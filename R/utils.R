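#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

stop_gxe <- function(fmt, ..., class) {
  stop(structure(
    class = c(class, "gxesim_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_gxe("`%s` must be a single finite number", name,
             class = "gxesim_validation_error")
  ok <- if (strict_lower) x > lower else x >= lower
  ok <- ok && if (strict_upper) x < upper else x <= upper
  if (!ok)
    stop_gxe("`%s` = %g is outside its admissible range %s%g, %g%s", name, x,
             if (strict_lower) "(" else "[", lower, upper,
             if (strict_upper) ")" else "]",
             class = "gxesim_validation_error")
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) ||
      x < min)
    stop_gxe("`%s` must be an integer >= %d", name, min,
             class = "gxesim_validation_error")
  invisible(as.integer(x))
}

#' Derive reproducible sub-seeds from one master seed
#'
#' All stochastic stages of a run (haplotype pool, gamete sampling, exposure
#' assignment, status assignment, subsampling) consume their own sub-seed so
#' that any stage can be re-run in isolation and still reproduce the full
#' pipeline bit for bit.  Sub-seeds are derived by a fixed integer recurrence
#' and stay below 2^31.
#'
#' @param seed master integer seed.
#' @param n number of sub-seeds to derive.
#' @return integer vector of length `n`.
#' @examples
#' split_seed(42, 3)
#' @export
split_seed <- function(seed, n) {
  seed <- check_count(seed, "seed", min = 0L)
  n <- check_count(n, "n")
  out <- integer(n)
  s <- as.double(seed)
  for (i in seq_len(n)) {
    # LCG step (Numerical Recipes constants), kept in double precision:
    # exact for all intermediates < 2^53
    s <- (s * 1664525 + 1013904223) %% 2147483647
    out[i] <- as.integer(s)
  }
  out
}

# Gauss-Hermite nodes/weights, cached per node count.
.gh_cache <- new.env(parent = emptyenv())

gh_rule <- function(n_nodes) {
  key <- as.character(n_nodes)
  if (is.null(.gh_cache[[key]]))
    .gh_cache[[key]] <- pracma::gaussHermite(n_nodes)
  .gh_cache[[key]]
}
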