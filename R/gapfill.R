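#' DINEOF-style iterative gap filling
#'
#' Fills the missing entries of a space-time field by the data
#' interpolating EOF iteration: missing cells are initialised to zero,
#' then repeatedly replaced by a truncated \code{k}-mode EOF
#' reconstruction (mean plus leading modes) of the current completed
#' matrix until the RMS change on the missing set falls below \code{tol}
#' or \code{max_iter} is reached. Observed entries are never modified:
#' they are bit-identical between input and output. The subtracted row
#' mean is recomputed every iteration from the current completed matrix.
#'
#' @param field a \code{\link{space_time_field}}; every pixel row and time
#'   column must contain at least one observed entry.
#' @param k number of leading EOF modes for the reconstruction,
#'   \code{1 <= k <= min(P, N)}. Default (\code{NULL}): chosen by
#'   cross-validation on held-out observed entries
#'   (\code{\link{choose_k_crossval}} with a fixed internal holdout seed,
#'   so the default remains a deterministic function of the input).
#' @param tol convergence threshold on the RMS change of the filled values
#'   between successive iterations, in W/m2 (default 0.01).
#' @param max_iter iteration cap (default 500).
#' @return an object of class \code{"gapfill_result"}: list with
#'   \code{filled} (a gap-free field), \code{n_iterations},
#'   \code{convergence_trace} (per-iteration RMS change on the missing
#'   set) and \code{k_used}. A gap-free input is returned unchanged with
#'   \code{n_iterations = 1}.
#' @export
gapfill <- function(field, k = NULL, tol = 0.01, max_iter = 500L) {
  stopifnot(inherits(field, "space_time_field"))
  mask <- field$mask
  if (!any(mask)) {
    return(structure(list(filled = field, n_iterations = 1L,
                          convergence_trace = numeric(0),
                          k_used = if (is.null(k)) NA_integer_ else as.integer(k)),
                     class = "gapfill_result"))
  }
  P <- nrow(mask); N <- ncol(mask)
  empty_rows <- which(rowSums(!mask) == 0L)
  if (length(empty_rows))
    stop(sprintf("precondition error: pixel row(s) fully missing: %s",
                 paste(utils::head(empty_rows, 5L), collapse = ", ")))
  empty_cols <- which(colSums(!mask) == 0L)
  if (length(empty_cols))
    stop(sprintf("precondition error: time column(s) fully missing: %s",
                 paste(utils::head(empty_cols, 5L), collapse = ", ")))
  if (is.null(k)) {
    k <- choose_k_crossval(field, holdout_fraction = 0.05,
                           k_max = min(8L, P, N), seed = 20231L,
                           tol = tol, max_iter = min(max_iter, 100L))
  }
  X <- field$values
  X[mask] <- 0                       # zero initialisation
  k <- as.integer(k)
  if (k < 1L || k > min(P, N))
    stop(sprintf("parameter error: k = %d outside [1, min(P, N) = %d]",
                 k, min(P, N)))
  trace <- numeric(0)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    dec <- eof_decompose(X)
    R <- eof_reconstruct(dec, seq_len(min(k, length(dec$S))))
    delta <- sqrt(mean((R[mask] - X[mask])^2))
    X[mask] <- R[mask]
    trace <- c(trace, delta)
    if (delta <= tol || iter >= max_iter) break
  }
  if (length(trace) > 2L) {
    steps <- diff(trace[-1L])
    if (any(steps > 1e-8 + 1e-6 * trace[-c(1L, length(trace))]))
      warning("gapfill convergence trace is not monotone non-increasing")
  }
  filled <- field_with_values(field, X)
  structure(list(filled = filled, n_iterations = iter,
                 convergence_trace = trace, k_used = k),
            class = "gapfill_result")
}

#' @export
print.gapfill_result <- function(x, ...) {
  cat(sprintf("<gapfill_result> k = %s, %d iteration(s), final RMS change %.4g W/m2\n",
              x$k_used, x$n_iterations,
              if (length(x$convergence_trace)) utils::tail(x$convergence_trace, 1) else 0))
  invisible(x)
}

#' Choose the gap-fill truncation rank by cross-validation
#'
#' Holds out a random fraction of the observed entries, gap-fills with
#' each candidate rank \code{k = 1, ..., k_max}, and returns the rank
#' minimising the RMS error on the held-out entries. Deterministic given
#' \code{seed}.
#'
#' @param field a \code{\link{space_time_field}} with gaps (or without).
#' @param holdout_fraction fraction of observed entries to withhold
#'   (default 0.05); must be below the observed fraction.
#' @param k_max largest rank to try.
#' @param seed integer seed for the holdout draw.
#' @param tol,max_iter passed to \code{\link{gapfill}}.
#' @return the selected \code{k}, with attributes \code{rms} (per-k
#'   held-out RMS) and \code{holdout_n}.
#' @export
choose_k_crossval <- function(field, holdout_fraction = 0.05, k_max = 5L,
                              seed = 1L, tol = 0.01, max_iter = 500L) {
  stopifnot(inherits(field, "space_time_field"))
  obs <- which(!field$mask)
  obs_frac <- length(obs) / length(field$mask)
  if (holdout_fraction >= obs_frac)
    stop(sprintf("parameter error: holdout_fraction %.3f >= observed fraction %.3f",
                 holdout_fraction, obs_frac))
  n_hold <- max(1L, round(holdout_fraction * length(obs)))
  hold <- with_seed(seed, sample(obs, n_hold))
  aug_mask <- field$mask
  aug_mask[hold] <- TRUE
  ## keep the gapfill precondition: drop holdout cells that would empty a
  ## whole pixel row or time column
  bad_rows <- which(rowSums(!aug_mask) == 0L)
  bad_cols <- which(colSums(!aug_mask) == 0L)
  if (length(bad_rows) || length(bad_cols)) {
    rc <- arrayInd(hold, dim(aug_mask))
    keep_back <- rc[, 1] %in% bad_rows | rc[, 2] %in% bad_cols
    aug_mask[hold[keep_back]] <- FALSE
    hold <- hold[!keep_back]
  }
  truth <- field$values[hold]
  aug <- space_time_field(field$values, grid_shape = field$grid_shape,
                          mask = aug_mask, times = field$times,
                          pixel_size = field$pixel_size)
  k_max <- min(as.integer(k_max), nrow(field$values), ncol(field$values))
  ## candidate ranks above the data's effective rank oscillate mildly;
  ## their non-monotone-trace warnings are expected during selection
  rms <- vapply(seq_len(k_max), function(k) {
    gf <- suppressWarnings(gapfill(aug, k = k, tol = tol, max_iter = max_iter))
    sqrt(mean((gf$filled$values[hold] - truth)^2))
  }, numeric(1))
  k_best <- which.min(rms)
  structure(as.integer(k_best), rms = rms, holdout_n = length(hold))
}
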