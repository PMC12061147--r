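#' @keywords internal
"_PACKAGE"

# Valid punch types, in class-index order (1 = jab, 2 = hook, 3 = uppercut).
PUNCH_TYPES <- c("jab", "hook", "uppercut")
HANDS <- c("lead", "rear")

# IMU CSV column dialect shared by simulate and io_sync.
IMU_CSV_COLS <- c("t_utc_s", "ax", "ay", "az", "gx", "gy", "gz", "hand")
CHANNELS <- c("ax", "ay", "az", "gx", "gy", "gz")

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so generators never clobber a user's random stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  code
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x, min = 0L) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= min && x == round(x)
}

is_number <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x)
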