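# Small shared helpers.

# Evaluate expr under a given RNG seed, restoring the caller's RNG state.
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

#' Standard error of the mean
#'
#' @param x numeric vector.
#' @return `sd(x)/sqrt(n)`; `NA` for fewer than 2 values.
#' @export
sem <- function(x) {
  n <- length(x)
  if (n < 2) return(NA_real_)
  stats::sd(x) / sqrt(n)
}
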