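#' Derive named substream seeds from one root seed
#'
#' All randomness in the synthetic herd flows from a single root seed through
#' named substreams, so individual stages (pedigree, design, traits, OTU
#' tables) can be regenerated independently and deterministically.
#'
#' @param seed integer root seed.
#' @param streams character vector of substream names.
#' @return named integer vector of seeds, one per stream.
#' @export
substream_seeds <- function(seed, streams = c("pedigree", "design", "traits", "otu")) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  s <- sample.int(2147483646L, length(streams))
  names(s) <- streams
  s
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded helpers do not
#' perturb the global stream.
#'
#' @param seed integer seed; `NULL` leaves the RNG untouched.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  force(expr)
}

#' Draw from a Dirichlet distribution
#'
#' @param n number of draws.
#' @param alpha concentration vector (all > 0).
#' @return matrix `n` x `length(alpha)`, rows summing to 1.
#' @keywords internal
rdirichlet <- function(n, alpha) {
  stopifnot(all(alpha > 0))
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  g / rowSums(g)
}

#' Bend a correlation matrix to the nearest positive semi-definite one
#'
#' Eigenvalue clipping followed by rescaling to unit diagonal. Used for
#' user-specified genetic correlation matrices that are not quite PSD.
#'
#' @param R square symmetric matrix with unit diagonal.
#' @param min_eig floor applied to eigenvalues.
#' @return PSD correlation matrix.
#' @export
make_psd_corr <- function(R, min_eig = 1e-8) {
  stopifnot(isSymmetric(unname(R), tol = 1e-8))
  e <- eigen((R + t(R)) / 2, symmetric = TRUE)
  if (all(e$values >= min_eig)) return(R)
  v <- pmax(e$values, min_eig)
  M <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(M))
  M <- M / tcrossprod(d)
  diag(M) <- 1
  dimnames(M) <- dimnames(R)
  M
}

#' Adjusted Rand index between two partitions
#'
#' Standard chance-corrected agreement between two labelings of the same
#' samples; 1 means identical partitions, 0 is the chance level.
#'
#' @param a,b label vectors of equal length.
#' @return numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  expected <- sum_a * sum_b / ch2(n)
  mx <- (sum_a + sum_b) / 2
  if (mx == expected) return(1)
  (sum_ij - expected) / (mx - expected)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# dense -> sparse via explicit triplets, skipping the O(n^2)
# symmetry-detection pass that Matrix's coercions run on dense input
.sparsify <- function(M) {
  if (inherits(M, "sparseMatrix")) return(Matrix::drop0(M))
  nz <- which(M != 0)
  n <- nrow(M)
  Matrix::sparseMatrix(i = ((nz - 1L) %% n) + 1L, j = ((nz - 1L) %/% n) + 1L,
                       x = M[nz], dims = dim(M), dimnames = dimnames(M))
}
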