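#' @keywords internal
"_PACKAGE"

#' @importFrom stats rgamma runif rnorm rexp dexp dlnorm optimize setNames
#' @importFrom utils head tail
NULL

## numerically stable log(sum(exp(x)))
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

softplus <- function(x) {
  # log(1 + exp(x)) without overflow
  ifelse(x > 0, x + log1p(exp(-x)), log1p(exp(x)))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

## Run expr with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
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

stop_input <- function(...) stop(..., call. = FALSE)

## Training loops allocate many short-lived matrices; R's collector tunes
## its heap trigger to the live-set size, so with a small live set it
## collects very frequently and GC dominates wall time.
.gc_headroom <- new.env(parent = emptyenv())

with_gc_headroom <- function(expr, cells = 1.2e8) {
  if (is.null(.gc_headroom$ballast)) {
    ## one allocation per session: the collector sizes its trigger to the
    ## enlarged live set, so the loop's churn no longer forces frequent
    ## collections; paying the page-fault cost once is what matters
    .gc_headroom$ballast <- numeric(cells)
    invisible(gc(verbose = FALSE))
  }
  expr
}
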