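# Internal helpers shared across modules.

N_DOF <- 12L

#' Run code with a private RNG stream
#'
#' Seeds the session RNG with `seed`, runs `expr`, and restores the caller's
#' RNG state on exit, so package functions are deterministic given their seed
#' argument without disturbing user-level reproducibility.
#' @noRd
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Derive a well-spread 31-bit sub-seed from a base seed and integer tags.
# Multiplicative-congruential mix; collisions are astronomically unlikely for
# the handful of (seed, tag) combinations a study uses.
mix_seed <- function(seed, ...) {
  tags <- c(seed, ...)
  h <- 0
  for (t in tags) {
    h <- (h * 48271 + (as.numeric(t) %% 2147483647) + 1) %% 2147483647
  }
  as.integer(h)
}

clamp <- function(x, lo = -1, hi = 1) pmin(pmax(x, lo), hi)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x == round(x) && x >= 0

# Frame count for a duration in seconds at a frame rate.
frames_of <- function(sec, frame_rate) as.integer(round(sec * frame_rate))
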