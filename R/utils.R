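#' @keywords internal
"_PACKAGE"

#' @useDynLib visoscil, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards. `seed = NULL` leaves the global stream alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

stop_arg <- function(...) stop(..., call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_arg(sprintf("`%s` must be a single finite number", name))
  bad_lo <- if (strict_lower) x <= lower else x < lower
  if (bad_lo || x > upper)
    stop_arg(sprintf("`%s` = %g is outside its allowed range", name, x))
  invisible(x)
}

# nearest sample index of time `t_ms` on an epoch time axis
time_index <- function(times, t_ms) which.min(abs(times - t_ms))
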