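## Small shared helpers: ppm arithmetic, seeding, logging.

#' Parts-per-million difference between two m/z values
#'
#' Signed relative deviation of `observed` from `reference` in ppm.
#'
#' @param observed numeric vector of observed m/z (Th).
#' @param reference numeric vector of reference m/z (Th).
#' @return numeric vector, `(observed - reference) / reference * 1e6`.
#' @export
ppm_error <- function(observed, reference) {
  (observed - reference) / reference * 1e6
}

## Absolute tolerance (Th) corresponding to `ppm` at mass `mz`.
ppm_tol <- function(mz, ppm) mz * ppm * 1e-6

## TRUE where |a - b| is within `ppm` of the larger of the two masses.
## The larger mass is used so the predicate is symmetric.
within_ppm <- function(a, b, ppm) {
  abs(a - b) <= pmax(a, b) * ppm * 1e-6
}

## Evaluate `expr` under a local RNG seeded with `seed`; restores RNG state.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

## Derive a stream of child seeds from a master seed, kept below 2^31.
derive_seeds <- function(seed, n) {
  (as.numeric(seed) * 1009 + 7919 * seq_len(n)) %% 2147483647
}

## Timestamped log line to stderr and, optionally, a file connection/path.
log_msg <- function(..., level = "INFO", file = NULL) {
  line <- sprintf("[%s] %s %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  level, paste0(..., collapse = ""))
  message(line)
  if (!is.null(file)) cat(line, "\n", sep = "", file = file, append = TRUE)
  invisible(line)
}

## stopifnot with a formatted message.
fail_if <- function(cond, fmt, ...) {
  if (isTRUE(cond)) stop(sprintf(fmt, ...), call. = FALSE)
  invisible(NULL)
}
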