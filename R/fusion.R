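#' Fusion configuration
#'
#' Collects the tunable parameters of the EOF component-mixing fusion.
#' Defaults follow the reference configuration: window \code{W = 4},
#' primary product contributing the modes that explain 80\% of its total
#' variance, secondary product contributing the modes at the following
#' index positions until 20\% of its variance is reached (capped at 12
#' components), processed in 200 x 200-pixel tiles.
#'
#' @param W delay-embedding window length in time steps (>= 1; 1 disables
#'   temporal embedding).
#' @param tau_primary cumulative-variance threshold for product A's
#'   retained leading modes, in (0, 1].
#' @param tau_secondary variance share drawn from product B's
#'   complementary modes, in [0, 1).
#' @param k_secondary_cap maximum number of secondary components.
#' @param tile_rows,tile_cols tile size in pixels.
#' @param gapfill_k truncation rank for gap filling (\code{NULL}: chosen
#'   per tile from the 80\% variance rule, see \code{\link{gapfill}}).
#' @param gapfill_tol,gapfill_max_iter gap-fill convergence settings
#'   (W/m2, iterations).
#' @param seed optional integer seed recorded with the configuration.
#' @return an object of class \code{"fusion_config"}.
#' @export
fusion_config <- function(W = 4L, tau_primary = 0.8, tau_secondary = 0.2,
                          k_secondary_cap = 12L, tile_rows = 200L,
                          tile_cols = 200L, gapfill_k = NULL,
                          gapfill_tol = 0.01, gapfill_max_iter = 500L,
                          seed = NULL) {
  if (W < 1) stop("parameter error: W must be >= 1")
  if (tau_primary <= 0 || tau_primary > 1)
    stop("parameter error: tau_primary must be in (0, 1]")
  if (tau_secondary < 0 || tau_secondary >= 1)
    stop("parameter error: tau_secondary must be in [0, 1)")
  structure(list(W = as.integer(W), tau_primary = tau_primary,
                 tau_secondary = tau_secondary,
                 k_secondary_cap = as.integer(k_secondary_cap),
                 tile_rows = as.integer(tile_rows),
                 tile_cols = as.integer(tile_cols),
                 gapfill_k = gapfill_k, gapfill_tol = gapfill_tol,
                 gapfill_max_iter = as.integer(gapfill_max_iter),
                 seed = seed),
            class = "fusion_config")
}

#' @export
print.fusion_config <- function(x, ...) {
  cat(sprintf(paste0("<fusion_config> W = %d, tau_primary = %.2f, ",
                     "tau_secondary = %.2f (cap %d), tiles %dx%d\n"),
              x$W, x$tau_primary, x$tau_secondary, x$k_secondary_cap,
              x$tile_rows, x$tile_cols))
  invisible(x)
}

## Fuse one (already extracted) tile pair. Returns values + diagnostics.
fuse_tile <- function(a, b, config) {
  ga <- gapfill(a, k = config$gapfill_k, tol = config$gapfill_tol,
                max_iter = config$gapfill_max_iter)
  gb <- gapfill(b, k = config$gapfill_k, tol = config$gapfill_tol,
                max_iter = config$gapfill_max_iter)
  da <- eof_decompose(delay_embed(ga$filled, config$W))
  db <- eof_decompose(delay_embed(gb$filled, config$W))
  k_a <- max(1L, select_components(da, config$tau_primary))
  rank_full <- min(nrow(da$Z), ncol(da$H))
  degenerate <- k_a >= rank_full
  if (degenerate) {
    warning(sprintf(
      "primary product needs all %d modes for tau_primary = %.2f; falling back to its truncated reconstruction",
      rank_full, config$tau_primary))
    k_b <- 0L
  } else {
    ## secondary modes: positions k_a+1, k_a+2, ... of product B until
    ## their summed variance fraction reaches tau_secondary (capped)
    avail <- length(db$S) - k_a
    k_b <- 0L
    if (avail > 0L && config$tau_secondary > 0) {
      vf <- db$variance_fraction[(k_a + 1L):length(db$S)]
      reach <- which(cumsum(vf) >= config$tau_secondary - 1e-12)[1]
      k_b <- if (is.na(reach)) avail else reach
      k_b <- min(k_b, config$k_secondary_cap, avail)
    }
  }
  fused_emb <- eof_reconstruct(da, seq_len(k_a))
  if (k_b > 0L)
    fused_emb <- fused_emb +
      eof_reconstruct(db, (k_a + 1L):(k_a + k_b), include_mean = FALSE)
  fused_vals <- de_embed(fused_emb, W = config$W,
                         P = nrow(a$values), N = ncol(a$values))
  k_b_main <- max(1L, select_components(db, config$tau_primary))
  fallback_vals <- de_embed(eof_reconstruct(db, seq_len(min(k_b_main, length(db$S)))),
                            W = config$W, P = nrow(b$values), N = ncol(b$values))
  repl <- replace_negatives(fused_vals, fallback_vals)
  list(values = repl,
       diag = data.frame(k_primary = k_a, k_secondary = k_b,
                         k_fallback = k_b_main,
                         n_negative_replaced = attr(repl, "n_replaced"),
                         n_clamped = attr(repl, "n_clamped"),
                         gapfill_iter_a = ga$n_iterations,
                         gapfill_iter_b = gb$n_iterations))
}

#' EOF component-mixing fusion of two LE products
#'
#' The package's core algorithm. Per tile: both products are gap-filled
#' (DINEOF), delay-embedded with window \code{W} and decomposed into
#' EOFs. From the primary product A the leading \code{k_a} modes reaching
#' \code{tau_primary} (default 80\%) cumulative variance are retained,
#' including A's mean field (its climatology). From the secondary product
#' B, the modes at the following index positions \code{k_a + 1, ...} are
#' added (without B's mean, to avoid double-counting the baseline) until
#' their summed variance fraction in B reaches \code{tau_secondary}
#' (default 20\%), capped at \code{k_secondary_cap} components. The sum
#' of the two truncated reconstructions is de-embedded back to field
#' space, and any negative LE cell is replaced by the secondary product's
#' main-pattern value at that cell (see \code{\link{replace_negatives}}).
#'
#' The output is gap-free and deterministic given inputs and
#' configuration. If A needs its full rank to reach \code{tau_primary}
#' the method degenerates to A's truncated reconstruction, with a
#' warning.
#'
#' @param product_a primary \code{\link{space_time_field}} (the product
#'   whose large-scale patterns are trusted most).
#' @param product_b secondary \code{\link{space_time_field}},
#'   co-registered with \code{product_a} (same grid and time axis).
#' @param config a \code{\link{fusion_config}}.
#' @return an object of class \code{"eof_fusion"}: list with
#'   \code{fused} (gap-free \code{space_time_field}), \code{diagnostics}
#'   (one row per tile: retained component counts, negative-replacement
#'   counts, gap-fill iterations), \code{config}, \code{layout} and
#'   \code{call}. Methods: \code{print}, \code{summary}, \code{plot},
#'   \code{fitted}.
#' @seealso \code{\link{simple_average}} for the constant-weight
#'   baseline.
#' @examples
#' syn <- synthetic_benchmark(synthetic_config(grid_shape = c(8, 8), n_times = 24),
#'                            seed = 1)
#' fit <- eof_fuse(syn$product_a, syn$product_b, fusion_config(W = 2))
#' fit
#' @export
eof_fuse <- function(product_a, product_b, config = fusion_config()) {
  stopifnot(inherits(product_a, "space_time_field"),
            inherits(product_b, "space_time_field"),
            inherits(config, "fusion_config"))
  stopifnot_coregistered(product_a, product_b)
  if (ncol(product_a$values) < config$W + 1L)
    stop(sprintf("parameter error: need at least W + 1 = %d time steps",
                 config$W + 1L))
  layout <- make_layout(product_a$grid_shape, config$tile_rows,
                        config$tile_cols)
  out_vals <- product_a$values
  diags <- vector("list", length(layout$tiles))
  for (t in seq_along(layout$tiles)) {
    tile <- layout$tiles[[t]]
    res <- fuse_tile(extract_tile(product_a, tile),
                     extract_tile(product_b, tile), config)
    idx <- pixel_rows(product_a$grid_shape, tile["r0"]:tile["r1"],
                      tile["c0"]:tile["c1"])
    out_vals[idx, ] <- res$values
    diags[[t]] <- cbind(tile = t, res$diag)
  }
  fused <- space_time_field(out_vals, grid_shape = product_a$grid_shape,
                            times = product_a$times,
                            pixel_size = product_a$pixel_size)
  structure(list(fused = fused, diagnostics = do.call(rbind, diags),
                 config = config, layout = layout, call = match.call()),
            class = "eof_fusion")
}

#' @export
print.eof_fusion <- function(x, ...) {
  d <- x$diagnostics
  cat("EOF component-mixing fusion\n")
  cat(sprintf("  grid %d x %d, %d time steps, %d tile(s)\n",
              x$fused$grid_shape[1], x$fused$grid_shape[2],
              ncol(x$fused$values), nrow(d)))
  cat(sprintf("  W = %d; primary modes %s; secondary modes %s; %d negative cell(s) replaced\n",
              x$config$W, paste(unique(d$k_primary), collapse = "/"),
              paste(unique(d$k_secondary), collapse = "/"),
              sum(d$n_negative_replaced)))
  invisible(x)
}

#' @export
summary.eof_fusion <- function(object, ...) {
  structure(list(diagnostics = object$diagnostics, config = object$config,
                 fused_range = range(object$fused$values),
                 fused_mean = mean(object$fused$values)),
            class = "summary.eof_fusion")
}

#' @export
print.summary.eof_fusion <- function(x, ...) {
  print(x$config)
  cat(sprintf("fused LE: mean %.2f W/m2, range [%.2f, %.2f]\n",
              x$fused_mean, x$fused_range[1], x$fused_range[2]))
  cat("per-tile diagnostics:\n")
  print(x$diagnostics, row.names = FALSE)
  invisible(x)
}

#' @export
fitted.eof_fusion <- function(object, ...) object$fused

#' @export
plot.eof_fusion <- function(x, ...) {
  gs <- x$fused$grid_shape
  tm <- rowMeans(x$fused$values)
  img <- t(matrix(tm, nrow = gs[1], ncol = gs[2], byrow = TRUE))
  graphics::image(seq_len(gs[2]), seq_len(gs[1]), img[, rev(seq_len(gs[1])), drop = FALSE],
                  col = grDevices::hcl.colors(64, "YlGnBu", rev = TRUE),
                  xlab = "grid column", ylab = "grid row",
                  main = "time-mean fused LE (W/m2)", ...)
  invisible(x)
}

#' Replace negative LE cells by a fallback product's values
#'
#' Truncated reconstructions can go negative where the primary product's
#' seasonal low is deep; those cells are physically impossible for LE and
#' are replaced by the secondary product's main-pattern value at the same
#' cell. A cell where the fallback is itself negative is clamped to 0 and
#' counted separately. All other cells are untouched.
#'
#' @param fused numeric matrix or \code{\link{space_time_field}}.
#' @param fallback same shape as \code{fused}.
#' @return \code{fused} with negatives replaced; attributes
#'   \code{n_replaced} (cells taken from the fallback) and
#'   \code{n_clamped} (double-negative cells set to 0).
#' @export
replace_negatives <- function(fused, fallback) {
  fv <- if (inherits(fused, "space_time_field")) fused$values else fused
  bv <- if (inherits(fallback, "space_time_field")) fallback$values else fallback
  if (!identical(dim(fv), dim(bv)))
    stop("validation error: fused and fallback shapes differ")
  neg <- fv < 0
  fv[neg] <- bv[neg]
  still <- fv < 0
  fv[still] <- 0
  out <- if (inherits(fused, "space_time_field"))
    field_with_values(fused, fv, mask = fused$mask)
  else fv
  structure(out, n_replaced = sum(neg), n_clamped = sum(still))
}

#' Simple-average fusion baseline
#'
#' Constant-weight average of two co-registered products:
#' \code{weight * a + (1 - weight) * b} where both are observed. A cell
#' missing in one product takes the other product's value; a cell missing
#' in both stays missing.
#'
#' @param product_a,product_b co-registered
#'   \code{\link{space_time_field}}s.
#' @param weight weight on \code{product_a}, in [0, 1] (default 0.5).
#' @return a \code{\link{space_time_field}}.
#' @export
simple_average <- function(product_a, product_b, weight = 0.5) {
  stopifnot(inherits(product_a, "space_time_field"),
            inherits(product_b, "space_time_field"))
  stopifnot_coregistered(product_a, product_b)
  if (!is.numeric(weight) || length(weight) != 1L || weight < 0 || weight > 1)
    stop("parameter error: weight must be in [0, 1]")
  a <- product_a$values; b <- product_b$values
  ma <- product_a$mask; mb <- product_b$mask
  out <- matrix(NA_real_, nrow(a), ncol(a))
  both <- !ma & !mb
  out[both] <- weight * a[both] + (1 - weight) * b[both]
  only_a <- !ma & mb
  out[only_a] <- a[only_a]
  only_b <- ma & !mb
  out[only_b] <- b[only_b]
  space_time_field(out, grid_shape = product_a$grid_shape,
                   mask = ma & mb, times = product_a$times,
                   pixel_size = product_a$pixel_size)
}
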