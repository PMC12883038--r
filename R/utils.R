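#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm rgamma runif rlnorm plogis dist var cor.test fisher.test quantile
#' @importFrom utils read.csv write.csv read.delim write.table packageVersion
NULL

# Classed error so callers can catch specific failure kinds.
stop_coloc <- function(class, msg, call = sys.call(-1)) {
  cnd <- structure(
    class = c(class, "spotcoloc_error", "error", "condition"),
    list(message = msg, call = call)
  )
  stop(cnd)
}

# Mix a master seed and a stage label into a 31-bit seed, so each pipeline
# stage draws from its own deterministic stream and adding stages (or grid
# points) never perturbs earlier ones.
stage_seed <- function(seed, stage) {
  s <- as.double(seed) %% 2147483647
  for (ch in utf8ToInt(paste0("s:", stage))) {
    s <- (s * 31 + ch) %% 2147483629
  }
  as.integer(s)
}

# Evaluate code under a temporary RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

`%||%` <- function(a, b) if (is.null(a)) b else a
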