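#' Permutation test for a difference of means
#'
#' Nonparametric two-sample test of the difference of means that does not
#' assume normality: group labels are re-assigned at random (preserving
#' group sizes) to build the null distribution of
#' \code{T = mean(x) - mean(y)}. Monte-Carlo p-values carry the +1
#' small-sample correction, \code{p = (#{|T_perm| >= |T_obs|} + 1) /
#' (nPermutations + 1)}, guaranteeing p in (0, 1]; a one-sided test drops
#' the absolute values (alternative: mean(x) > mean(y)). When the total
#' number of distinct label assignments is at most
#' \code{exhaustiveLimit}, all of them are enumerated instead and the
#' p-value is exact.
#'
#' @param x,y numeric samples, each of size >= 2.
#' @param nPermutations number of random label permutations.
#' @param seed RNG seed (Monte-Carlo mode).
#' @param twoSided two-sided test (default) or one-sided.
#' @param exhaustiveLimit enumerate exhaustively when
#'   \code{choose(nx+ny, nx) <= exhaustiveLimit}.
#' @return A \linkS4class{PermutationResult}.
#' @examples
#' set.seed(1)
#' res <- permutationTestMeans(rnorm(20, 1), rnorm(20), seed = 2)
#' pValue(res)
#' @export
permutationTestMeans <- function(x, y, nPermutations = 10000, seed = 1,
                                 twoSided = TRUE, exhaustiveLimit = 20000) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2L || length(y) < 2L)
    stop("each group must contain at least two observations")
  stopifnot(all(is.finite(x)), all(is.finite(y)))
  nx <- length(x); ny <- length(y); n <- nx + ny
  z <- c(x, y)
  tot <- sum(z)
  obs <- mean(x) - mean(y)
  # T from the x-group sum: T = s/nx - (tot - s)/ny
  tFromSum <- function(s) s / nx - (tot - s) / ny
  exceeds <- if (twoSided) {
    function(tp) abs(tp) >= abs(obs) - 1e-12
  } else {
    function(tp) tp >= obs - 1e-12
  }
  exhaustive <- is.finite(choose(n, nx)) && choose(n, nx) <= exhaustiveLimit
  if (exhaustive) {
    sums <- utils::combn(n, nx, FUN = function(i) sum(z[i]))
    hits <- sum(exceeds(tFromSum(sums)))
    p <- hits / length(sums) # the observed assignment is enumerated
    nPerm <- as.integer(length(sums))
  } else {
    sums <- .withSeed(seed, vapply(seq_len(nPermutations),
                      function(i) sum(z[sample.int(n, nx)]), numeric(1)))
    p <- (sum(exceeds(tFromSum(sums))) + 1) / (nPermutations + 1)
    nPerm <- as.integer(nPermutations)
  }
  new("PermutationResult", observedDiff = obs, pValue = p,
      nPermutations = nPerm, seed = as.integer(seed),
      twoSided = isTRUE(twoSided), exhaustive = exhaustive,
      nX = nx, nY = ny)
}

#' Cholesterol efflux percentage
#'
#' Fraction of radiolabeled cholesterol transferred to the medium,
#' as a percentage of total counts:
#' \code{100 * countsMedia / (countsCells + countsMedia)}.
#'
#' @param countsMedia,countsCells non-negative scintillation counts;
#'   their sum must be positive. Vectorized.
#' @return Efflux percentage in [0, 100].
#' @examples
#' effluxPercent(2500, 7500)  # 25
#' @export
effluxPercent <- function(countsMedia, countsCells) {
  stopifnot(all(countsMedia >= 0), all(countsCells >= 0))
  if (any(countsMedia + countsCells <= 0))
    stop("total counts must be positive")
  100 * countsMedia / (countsCells + countsMedia)
}
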