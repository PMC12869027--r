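# internal helpers shared across modules

# run `expr` under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

stop_qpat <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "qpat_error")))
}

# cosine of the angle between two non-zero vectors
cos_sim <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(NA_real_)
  min(1, max(-1, sum(a * b) / (na * nb)))
}

fmt_num <- function(x, digits = 4) formatC(x, digits = digits, format = "g")
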