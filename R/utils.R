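# Internal helpers: seed plumbing and argument checks.

# Stage offsets for the master-seed fan-out. Child seed =
# (master mod 2^20) * 1024 + offset, which stays below 2^31 and gives every
# stage an independently re-runnable stream.
.stage_offsets <- c(
  cohort = 1L, metabolome = 2L, censor = 3L, adiposity = 4L,
  preprocess = 5L, select_pls = 6L, select_rf = 7L, select_lasso = 8L,
  assoc = 9L, adiposity_fit = 10L, enet = 11L
)

#' Derive a per-stage child seed from a master seed
#'
#' Deterministic counter scheme: `(master %% 2^20) * 1024 + offset(stage)`,
#' guaranteed to fit in a 32-bit integer. Stages can therefore be re-run in
#' isolation with the same stream they would see inside [run_pipeline()].
#'
#' @param master integer master seed.
#' @param stage one of `r paste(names(sweetmet:::.stage_offsets), collapse = ", ")`.
#' @return an integer seed.
#' @export
derive_seed <- function(master, stage) {
  stopifnot(length(master) == 1, is.finite(master))
  stage <- match.arg(stage, names(.stage_offsets))
  as.integer((abs(as.numeric(master)) %% 2^20) * 1024 + .stage_offsets[[stage]])
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1 || !is.finite(x) || x < min || x != round(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  }
  invisible(as.integer(x))
}

check_prob <- function(x, name, upper_open = TRUE) {
  ok <- length(x) >= 1 && all(is.finite(x)) && all(x >= 0) &&
    all(if (upper_open) x < 1 else x <= 1)
  if (!ok) {
    stop(sprintf("`%s` must lie in [0, 1%s", name, if (upper_open) ")" else "]"),
         call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
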