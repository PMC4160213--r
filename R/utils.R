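# internal helpers

# run code with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# truncated-normal draws by rejection (mean/sd of the parent normal; values
# below `lower` are redrawn)
rtrunc_norm <- function(n, mean, sd, lower) {
  if (sd <= 0) return(rep(max(mean, lower), n))
  out <- numeric(n)
  need <- seq_len(n)
  for (i in 1:1000) {
    draw <- stats::rnorm(length(need), mean, sd)
    ok <- draw >= lower
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
    if (!length(need)) return(out)
  }
  out[need] <- lower
  out
}

vec3_norm <- function(v) sqrt(sum(v^2))

unit3 <- function(v) {
  n <- vec3_norm(v)
  if (n == 0) stop("zero vector has no direction")
  v / n
}

`%||%` <- function(a, b) if (is.null(a)) b else a
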