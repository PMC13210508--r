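#' @include AllClasses.R
NULL

## Evaluate code under a temporary RNG state, restoring the caller's stream.
withSeed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

## Deterministic per-stream seed below 2^31, exact in double arithmetic.
mixSeed <- function(seed, a = 0L, b = 0L) {
  s <- (as.numeric(seed) %% 2147483647)
  h <- (s * 1000003 + as.numeric(a) * 8191 + as.numeric(b) * 131) %% 2147483629
  as.integer(h + 1)
}

## Population standard deviation (divisor n, not n-1).
popSd <- function(x) sqrt(mean((x - mean(x))^2))

#' Cosine similarity of two vectors
#'
#' `dot(u, v) / (|u| |v|)`. For the non-negative vectors used here
#' (interest vectors, flattened saliency maps) the result lies in [0, 1].
#' A zero vector has no direction, so the similarity is undefined and
#' returned as `NA` with a warning.
#'
#' @param u,v equal-length numeric vectors.
#' @return A number in [-1, 1], or `NA` if either vector is all zero.
#' @examples
#' cosineSimilarity(c(1, 1, 0), c(1, 0, 0))  # 1/sqrt(2)
#' @export
cosineSimilarity <- function(u, v) {
  u <- as.numeric(u); v <- as.numeric(v)
  if (length(u) != length(v)) stop("vectors must have equal length")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    warning("cosine similarity undefined for a zero vector")
    return(NA_real_)
  }
  sum(u * v) / (nu * nv)
}

#' Pairwise similarity matrix
#'
#' Cosine similarities for every pair in a collection of
#' [InterestVector-class]s (or plain numeric vectors), as used for the
#' subject-by-subject interest comparisons.
#'
#' @param vectors a list of InterestVectors or numeric vectors.
#' @return A symmetric matrix with unit diagonal (NA where undefined).
#' @export
similarityMatrix <- function(vectors) {
  vals <- lapply(vectors, function(v) {
    if (is(v, "InterestVector")) as.numeric(interestEntries(v)) else as.numeric(v)
  })
  ids <- vapply(seq_along(vectors), function(i) {
    if (is(vectors[[i]], "InterestVector")) subjectId(vectors[[i]]) else as.character(i)
  }, character(1))
  n <- length(vals)
  out <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in i:n) {
    s <- if (i == j && any(vals[[i]] != 0)) 1 else
      suppressWarnings(cosineSimilarity(vals[[i]], vals[[j]]))
    out[i, j] <- out[j, i] <- s
  }
  out
}
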