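# Internal helpers: error classes, seeding, rounding.

stop_config <- function(field, msg) {
  stop(structure(
    class = c("actdays_config_error", "error", "condition"),
    list(message = sprintf("invalid configuration field `%s`: %s", field, msg),
         call = sys.call(-1))
  ))
}

stop_input <- function(msg) {
  stop(structure(
    class = c("actdays_input_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

stop_domain <- function(msg) {
  stop(structure(
    class = c("actdays_domain_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# Evaluate `expr` under `seed`, restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# One root seed, one child stream per subject: the child seeds are drawn
# up-front from the root in subject order, so subject i's data depend only on
# root and i (stable under partial regeneration).
child_seeds <- function(root_seed, n) {
  with_seed(root_seed, sample.int(.Machine$integer.max - 1L, n))
}

# Round half away from zero (matches how reported coefficients are printed;
# base round() rounds half to even).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(x, y) if (is.null(x)) y else x

is_count <- function(x, min = 1) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= min && x == floor(x)
}

is_number <- function(x, min = -Inf) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= min
}

# ISO day of week (1 = Monday .. 7 = Sunday).
iso_dow <- function(date) {
  d <- as.integer(format(as.Date(date), "%u"))
  d
}

is_weekend <- function(dow) dow >= 6L
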