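# Internal helpers shared across modules. Nothing here is exported.

#' @importFrom methods new validObject is slot slotNames
#' @importFrom stats pnorm qnorm pchisq dnorm rnorm runif rbinom mad median
#'   setNames complete.cases
#' @importFrom utils read.delim write.table packageVersion
NULL

# Evaluate `expr` with a private RNG stream seeded at `seed`, restoring the
# caller's RNG state afterwards. seed = NULL leaves the global stream alone.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a reproducible child seed from a parent seed and a label; keeps the
# result in [0, 2^31 - 2] so set.seed() accepts it on 32-bit integers.
childSeed <- function(seed, label) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587)
}

logSumExp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a > b, stable for a ~ b.
logDiffExp <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

complementAllele <- function(x) unname(DNA_COMPLEMENT[x])

isPalindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

# Two-sided normal p-value for an estimate/se pair.
zPvalue <- function(beta, se) 2 * pnorm(-abs(beta / se))

stopifnotScalarPos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    stop(sprintf("'%s' must be a single positive number", name), call. = FALSE)
  invisible(x)
}
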