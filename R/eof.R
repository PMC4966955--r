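#' Delay-embed a space-time field (multichannel SSA)
#'
#' Builds the augmented trajectory matrix used by the expanded EOF
#' analysis: for every pixel, the length-\code{N} series
#' \eqn{(a_1, \dots, a_N)} is arranged into a \code{W x (N - W + 1)} Hankel
#' block whose entry \code{(i, j)} is \eqn{a_{j + i - 1}}; the \code{P}
#' per-pixel blocks are stacked vertically, giving a matrix of dimension
#' \code{(P * W) x (N - W + 1)}. \code{W = 1} is the plain (non-embedded)
#' EOF and returns the original \code{P x N} matrix unchanged.
#'
#' @param x a gap-free \code{\link{space_time_field}} or a plain numeric
#'   \code{P x N} matrix.
#' @param W window length in time steps, \code{1 <= W <= N}. Gapped fields
#'   must be gap-filled first (or use \code{W = 1}).
#' @return a numeric matrix of class \code{"delay_matrix"} with attributes
#'   \code{W}, \code{P}, \code{N}.
#' @seealso \code{\link{de_embed}} for the inverse.
#' @examples
#' delay_embed(matrix(1:4, 1), W = 2)
#' @export
delay_embed <- function(x, W) {
  A <- if (inherits(x, "space_time_field")) x$values else x
  W <- as.integer(W)
  if (inherits(x, "space_time_field") && any(x$mask) && W > 1L)
    stop("field has missing entries; gap-fill before delay embedding (or use W = 1)")
  if (!is.matrix(A)) stop("`x` must be a matrix or space_time_field")
  P <- nrow(A); N <- ncol(A)
  if (W < 1L || W > N)
    stop(sprintf("window W = %d outside [1, N = %d]", W, N))
  K <- N - W + 1L
  out <- matrix(NA_real_, P * W, K)
  for (i in seq_len(W))
    out[(seq_len(P) - 1L) * W + i, ] <- A[, i:(i + K - 1L), drop = FALSE]
  structure(out, W = W, P = P, N = N, class = c("delay_matrix", "matrix", "array"))
}

#' Invert a delay embedding by anti-diagonal averaging
#'
#' Maps a (reconstructed) trajectory matrix back to a \code{P x N} field
#' matrix. Each source time \code{t} is represented by between 1 and
#' \code{W} entries on a Hankel anti-diagonal of the pixel's block; their
#' uniform average is returned (the standard SSA de-embedding, exact on
#' consistent Hankel matrices, least-squares otherwise).
#'
#' @param x a \code{"delay_matrix"} (or plain matrix with \code{W},
#'   \code{P}, \code{N} supplied).
#' @param W,P,N embedding metadata; default taken from attributes of \code{x}.
#' @return a numeric \code{P x N} matrix.
#' @export
de_embed <- function(x, W = attr(x, "W"), P = attr(x, "P"), N = attr(x, "N")) {
  if (is.null(W) || is.null(P) || is.null(N))
    stop("validation error: delay metadata (W, P, N) missing")
  W <- as.integer(W); P <- as.integer(P); N <- as.integer(N)
  K <- N - W + 1L
  if (!is.matrix(x) || nrow(x) != P * W || ncol(x) != K)
    stop(sprintf("validation error: matrix is %dx%d, expected %dx%d for W=%d, P=%d, N=%d",
                 nrow(x), ncol(x), P * W, K, W, P, N))
  vals <- matrix(0, P, N)
  cnt <- numeric(N)
  for (i in seq_len(W)) {
    idx <- i:(i + K - 1L)
    vals[, idx] <- vals[, idx] + x[(seq_len(P) - 1L) * W + i, , drop = FALSE]
    cnt[idx] <- cnt[idx] + 1
  }
  sweep(vals, 2L, cnt, `/`)
}

#' EOF decomposition of a space-time matrix
#'
#' Removes the per-row mean (each pixel's, or embedded lag-row's,
#' climatology) and computes the singular value decomposition
#' \eqn{A_c = Z S H^T}: columns of \code{Z} are the spatial modes (EOFs),
#' columns of \code{H} the temporal principal components, and the squared
#' singular values give each mode's share of the total variance.
#'
#' Sign convention: each mode is flipped so that its largest-magnitude
#' spatial loading is non-negative (SVD signs are otherwise arbitrary).
#' Tied singular values keep the factorization's ordering.
#'
#' @param x a \code{\link{space_time_field}}, \code{"delay_matrix"}, or
#'   plain numeric matrix with finite entries.
#' @return an object of class \code{"eof_decomposition"}: list with
#'   \code{Z}, \code{S} (non-negative, descending), \code{H},
#'   \code{mean_row}, \code{variance_fraction} (sums to 1),
#'   \code{total_variance} (Frobenius norm squared of the centred matrix
#'   divided by its column count), and embedding metadata \code{W},
#'   \code{P}, \code{N} when applicable.
#' @export
eof_decompose <- function(x) {
  A <- if (inherits(x, "space_time_field")) x$values else unclass(x)
  attrs <- if (inherits(x, "delay_matrix"))
    attributes(x)[c("W", "P", "N")] else NULL
  if (!is.matrix(A)) stop("`x` must be matrix-like")
  if (any(!is.finite(A))) stop("numeric error: non-finite entries in input matrix")
  m <- rowMeans(A)
  Ac <- A - m
  sv <- svd(Ac)
  ## deterministic signs: leading-magnitude loading of each mode >= 0
  for (k in seq_along(sv$d)) {
    j <- which.max(abs(sv$u[, k]))
    if (sv$u[j, k] < 0) {
      sv$u[, k] <- -sv$u[, k]
      sv$v[, k] <- -sv$v[, k]
    }
  }
  tot <- sum(sv$d^2)
  vf <- if (tot > 0) sv$d^2 / tot else rep(0, length(sv$d))
  structure(
    list(Z = sv$u, S = sv$d, H = sv$v, mean_row = m,
         variance_fraction = vf,
         total_variance = tot / ncol(Ac),
         n_row = nrow(A), n_col = ncol(A),
         W = attrs$W, P = attrs$P, N = attrs$N),
    class = "eof_decomposition")
}

#' @export
print.eof_decomposition <- function(x, ...) {
  nz <- sum(x$S > 1e-10 * max(x$S, 1e-300))
  cat(sprintf("<eof_decomposition> %d x %d matrix, numerical rank %d\n",
              x$n_row, x$n_col, nz))
  k <- min(5L, length(x$S))
  cat("  leading variance fractions:",
      paste(sprintf("%.3f", x$variance_fraction[seq_len(k)]), collapse = " "), "\n")
  invisible(x)
}

#' Number of leading modes reaching a cumulative variance threshold
#'
#' @param decomp an \code{\link{eof_decompose}} result.
#' @param cumulative_threshold fraction in (0, 1]; the default 0.8 retains
#'   the modes explaining about 80\% of the total variance, the share used
#'   for the primary product in the fusion.
#' @return the smallest \code{k} whose leading-\code{k} cumulative variance
#'   fraction reaches the threshold (0 for a zero-variance matrix).
#' @export
select_components <- function(decomp, cumulative_threshold = 0.8) {
  stopifnot(inherits(decomp, "eof_decomposition"))
  if (!is.numeric(cumulative_threshold) || length(cumulative_threshold) != 1L ||
      cumulative_threshold <= 0 || cumulative_threshold > 1)
    stop("parameter error: cumulative_threshold must be in (0, 1]")
  cs <- cumsum(decomp$variance_fraction)
  k <- which(cs >= cumulative_threshold - 1e-12)[1]
  if (is.na(k)) 0L else as.integer(k)
}

#' Truncated EOF reconstruction
#'
#' Returns \eqn{\bar{A} + \sum_{k \in set} S_k Z_k H_k^T}: the mean field
#' plus the rank-one contributions of the requested modes. An empty
#' component set gives the mean field alone.
#'
#' @param decomp an \code{\link{eof_decompose}} result.
#' @param components integer vector of mode indices (may be empty).
#' @param include_mean if \code{FALSE}, omit the mean field (used when
#'   adding a second product's anomaly modes on top of another
#'   reconstruction).
#' @return a numeric matrix the size of the decomposed input; embedding
#'   metadata is carried over so the result can be passed to
#'   \code{\link{de_embed}}.
#' @export
eof_reconstruct <- function(decomp, components, include_mean = TRUE) {
  stopifnot(inherits(decomp, "eof_decomposition"))
  components <- as.integer(components)
  if (length(components) &&
      (any(components < 1L) || any(components > length(decomp$S))))
    stop(sprintf("parameter error: component index outside [1, %d]",
                 length(decomp$S)))
  R <- if (include_mean)
    matrix(decomp$mean_row, decomp$n_row, decomp$n_col)
  else
    matrix(0, decomp$n_row, decomp$n_col)
  if (length(components)) {
    idx <- components
    R <- R + decomp$Z[, idx, drop = FALSE] %*%
      (decomp$S[idx] * t(decomp$H[, idx, drop = FALSE]))
  }
  if (!is.null(decomp$W))
    R <- structure(R, W = decomp$W, P = decomp$P, N = decomp$N,
                   class = c("delay_matrix", "matrix", "array"))
  R
}
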