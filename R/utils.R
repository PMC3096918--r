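# Evaluate `expr` under a temporary RNG state seeded with `seed`.
# With seed = NULL the expression runs under the ambient RNG stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1) # materialise a RNG state to restore
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Draw from N(mean, sd) truncated below at `floor` by rejection; errors out
# if essentially no mass lies above the floor (infeasible design).
rnorm_floor <- function(n, mean, sd, floor) {
  if (sd == 0) {
    if (any(mean < floor)) stop("degenerate draw below floor", call. = FALSE)
    return(rep_len(mean, n))
  }
  if (stats::pnorm(floor, mean, sd, lower.tail = FALSE) < 1e-6) {
    stop(sprintf(
      "infeasible truncation: mass above floor %g is < 1e-6 for N(%g, %g)",
      floor, mean, sd), call. = FALSE)
  }
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < floor)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}
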