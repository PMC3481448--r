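# Internal helpers: seed management and argument checking.

# Named RNG substreams: each stochastic stage of a run draws under its own
# derived seed, so stage-level changes do not perturb unrelated stages.
.STAGE_OFFSETS <- c(
  subsample       = 0L,
  eta             = 1L,
  fold            = 2L,
  samples_train   = 3L,
  samples_test    = 4L,
  efficiency      = 5L,
  noise_train     = 6L,
  noise_test      = 7L,
  ms1_train       = 8L,
  ms1_test        = 9L,
  identifiability = 10L,
  ms2_train       = 11L,
  ms2_test        = 12L
)

#' Derive the seed of a named pipeline stage
#'
#' Each stochastic stage of [run_once()] draws random numbers under its own
#' seed derived deterministically from the run seed. This makes every stage
#' individually reproducible and keeps stages decoupled: inserting draws in
#' one stage cannot shift the random stream of another.
#'
#' @param seed Integer run seed.
#' @param stage Stage name, one of `names(pipesim:::.STAGE_OFFSETS)`.
#' @return An integer seed below 2^31.
#' @export
stage_seed <- function(seed, stage) {
  stage <- match.arg(stage, names(.STAGE_OFFSETS))
  (as.integer(seed) + 1000003L * .STAGE_OFFSETS[[stage]]) %% 2147483629L
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         allow_inf = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (allow_inf || is.finite(x)) && x >= lower && x <= upper
  if (!ok) {
    abort(sprintf("`%s` must be a single number in [%s, %s]",
                  name, format(lower), format(upper)))
  }
  invisible(x)
}

check_count <- function(x, name, lower = 1L) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) && is.finite(x) &&
    x >= lower && x == floor(x)
  if (!ok) abort(sprintf("`%s` must be an integer >= %d", name, lower))
  invisible(as.integer(x))
}
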