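#' @importFrom rlang %||%
#' @importFrom stats median quantile rnorm runif rbinom rpois rnbinom rgamma
#'   rbeta sd cor lm pf pt coef dhyper p.adjust wilcox.test fisher.test
#'   cor.test setNames complete.cases
#' @importFrom utils head modifyList
NULL

# Polynomial string hash mod 2^31 - 1 (exact in double arithmetic), kept
# below 2^31 so it is a valid R integer seed.
hash_string <- function(x) {
  vapply(x, function(s) {
    h <- 17
    for (b in utf8ToInt(enc2utf8(s))) {
      h <- (h * 8191 + b) %% 2147483647
    }
    as.integer(h)
  }, integer(1), USE.NAMES = FALSE)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG stream is untouched, so per-sample simulation is insertion-order
# independent.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Half-away-from-zero rounding (2.5 -> 3, -2.5 -> -3); base round() is
# banker's rounding which is not what copy-number practice uses.
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

.log_levels <- c(debug = 10L, info = 20L, warn = 30L, error = 40L)

#' Set the logging threshold
#'
#' Messages below the threshold are suppressed. All package logging goes to
#' standard error so result streams stay clean.
#'
#' @param level One of `"debug"`, `"info"`, `"warn"`, `"error"`.
#' @return The previous level, invisibly.
#' @export
set_log_level <- function(level = c("info", "debug", "warn", "error")) {
  level <- match.arg(level)
  old <- getOption("metprime.log_level", "info")
  options(metprime.log_level = level)
  invisible(old)
}

log_msg <- function(level, ...) {
  thr <- .log_levels[[getOption("metprime.log_level", "info")]]
  if (.log_levels[[level]] >= thr) {
    message(sprintf("[%s] %s", toupper(level), paste0(...)))
  }
  invisible(NULL)
}

log_info <- function(...) log_msg("info", ...)
log_debug <- function(...) log_msg("debug", ...)
log_warn <- function(...) log_msg("warn", ...)
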