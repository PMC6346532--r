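#' Seeded randomized SVD by subspace iteration
#'
#' Computes the top `k` singular triplets of a dense matrix with the
#' randomized range-finder scheme: a Gaussian sketch of `k + oversample`
#' columns, orthonormalized power (subspace) iterations, and an exact SVD of
#' the small projected matrix. Power iterations continue past the fixed
#' minimum until the top-`k` score vectors (left singular vectors scaled by
#' their singular values) stabilize, so the result matches an exact
#' decomposition to near machine precision whenever the spectrum has a gap —
#' the regime a similarity map is useful in. The whole procedure is
#' deterministic given `seed`.
#'
#' @param x numeric matrix.
#' @param k number of singular triplets to return.
#' @param oversample extra sketch columns beyond `k` (default 10).
#' @param min_power_iter minimum number of power iterations (default 2).
#' @param max_power_iter iteration cap for gap-free spectra (default 200).
#' @param tol relative score-stabilization tolerance (default 1e-10).
#' @param seed integer seed for the Gaussian sketch.
#' @return List with `u` (n × k), `d` (length k), `v` (p × k), `iterations`.
#' @export
randomized_svd <- function(x, k = 2L, oversample = 10L, min_power_iter = 2L,
                           max_power_iter = 200L, tol = 1e-10, seed = 1L) {
  stopifnot(is.matrix(x), is.numeric(x))
  n <- nrow(x); p <- ncol(x)
  k <- as.integer(k)
  if (k < 1L || k > min(n, p))
    abort(sprintf("k must be in [1, %d]", min(n, p)), class = "descope_validation_error")
  l <- min(k + as.integer(oversample), n, p)

  Omega <- with_seed(seed, matrix(stats::rnorm(p * l), p, l))
  Q <- qr.Q(qr(x %*% Omega))
  scores_prev <- NULL
  s <- NULL
  for (it in seq_len(max_power_iter)) {
    Q <- qr.Q(qr(crossprod(x, Q)))   # range of t(x)
    Q <- qr.Q(qr(x %*% Q))           # back to range of x
    B <- crossprod(Q, x)             # l x p
    s <- svd(B, nu = k, nv = k)
    scores <- (Q %*% s$u) %*% diag(s$d[seq_len(k)], k)
    # sign-normalize columns before comparing across iterations
    for (j in seq_len(k)) {
      m <- which.max(abs(scores[, j]))
      if (scores[m, j] < 0) scores[, j] <- -scores[, j]
    }
    if (it >= min_power_iter && !is.null(scores_prev) &&
        max(abs(scores - scores_prev)) <= tol * max(s$d[1L], .Machine$double.eps))
      break
    scores_prev <- scores
  }
  list(u = Q %*% s$u, d = s$d[seq_len(k)], v = s$v, iterations = it)
}
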