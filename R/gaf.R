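#' Min–max normalize a sequence to \[-1, 1\]
#'
#' `x_hat_i = (2 x_i - max - min) / (max - min)`, so the minimum maps to
#' -1 and the maximum to +1.  A constant sequence has no scale; by
#' convention it returns all zeros with a warning (downstream it yields
#' an all-zero Gramian field).
#'
#' @param x numeric sequence, length >= 2.
#' @return Numeric vector in \[-1, 1\].
#' @examples
#' minmax_normalize(c(0, 5, 10))  # -1 0 1
#' @export
minmax_normalize <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 2)
  rng <- range(x)
  if (rng[1] == rng[2]) {
    warning("degenerate (constant) signal; returning zeros")
    return(numeric(length(x)))
  }
  (2 * x - rng[2] - rng[1]) / (rng[2] - rng[1])
}

#' Gramian Angular Difference Field of a normalized sequence
#'
#' Each value is mapped to an angle `Phi_i = arccos(x_hat_i)` and the
#' field is `M[i, j] = sin(Phi_i - Phi_j)`, computed via the equivalent
#' algebraic form
#' `x_hat_j * sqrt(1 - x_hat_i^2) - x_hat_i * sqrt(1 - x_hat_j^2)`.
#' The matrix is antisymmetric with zero diagonal; values lie in
#' \[-1, 1\], negative where the signal's phase decreases between the two
#' time points and positive where it increases.
#'
#' @param x_hat numeric sequence with all values in \[-1, 1\].
#' @return N x N numeric matrix.
#' @examples
#' gadf(c(1, 0))  # rbind(c(0, -1), c(1, 0))
#' @export
gadf <- function(x_hat) {
  if (any(abs(x_hat) > 1 + 1e-12))
    stop("gadf input outside [-1, 1]: normalize first")
  x_hat <- pmin(1, pmax(-1, x_hat))
  s <- sqrt(1 - x_hat^2)
  # sin(Phi_i - Phi_j) = cos(Phi_j) sin(Phi_i) - cos(Phi_i) sin(Phi_j)
  outer(s, x_hat) - outer(x_hat, s)
}

#' Mean-pool a sequence to a working length
#'
#' Averages within `len` nearly equal contiguous bins.  Sequences not
#' longer than `len` are returned unchanged.  Full-resolution Gramian
#' fields scale as T^2 per channel, so long recordings are pooled before
#' encoding.
#'
#' @param x numeric sequence.
#' @param len target length.
#' @return Numeric vector of length `min(len, length(x))`.
#' @export
mean_pool <- function(x, len) {
  n <- length(x)
  if (n <= len) return(x)
  bin <- as.integer(floor(seq_len(n) * len / (n + 1)))  # 0..len-1, balanced
  bin <- pmin(bin, len - 1L)
  as.numeric(rowsum(x, bin) / tabulate(bin + 1L, len))
}

#' Bilinear resize of a square matrix
#'
#' Separable linear interpolation with corner alignment; resizing to the
#' input size is the identity.
#'
#' @param m numeric matrix.
#' @param side target side length.
#' @return `side` x `side` matrix.
#' @export
resize_bilinear <- function(m, side) {
  n_r <- nrow(m); n_c <- ncol(m)
  interp_mat <- function(n_in, n_out) {
    if (n_in == n_out) return(diag(n_in))
    pos <- if (n_out == 1) (n_in - 1) / 2 else
      seq(0, n_in - 1, length.out = n_out)
    lo <- pmin(floor(pos), n_in - 2); w <- pos - lo
    A <- matrix(0, n_out, n_in)
    A[cbind(seq_len(n_out), lo + 1)] <- 1 - w
    A[cbind(seq_len(n_out), lo + 2)] <- w
    A
  }
  Ar <- interp_mat(n_r, side)
  Ac <- interp_mat(n_c, side)
  Ar %*% m %*% t(Ac)
}

#' Encode one participant's masked AU series as a 3-channel GADF image
#'
#' Per AU channel: optional mean-pooling to `work_len`, min–max
#' normalization to \[-1, 1\] over the analyzed window (after masking, so
#' inserted zeros participate in the min/max), GADF, then bilinear resize
#' to `side` x `side`.  Channels are stacked in fixed order AU4 (R),
#' AU6 (G), AU12 (B).  An all-constant channel (e.g. fully masked) is
#' encoded as an all-zero channel with a warning.
#'
#' @param series an `au_series`, typically already passed through
#'   [mask_speech()]; length >= 2.
#' @param side output image side (default 224).
#' @param work_len series length used for the Gramian field (default
#'   1024); longer series are mean-pooled down to it first.
#' @return An object of class `gaf_image`: `side` x `side` x 3 array in
#'   \[-1, 1\] with attributes `participant_id`, `triad_id`, `condition`.
#' @examples
#' s <- new_au_series(matrix(runif(300), 100, 3), fps = 25)
#' img <- encode_participant(s, side = 32, work_len = 64)
#' dim(img)  # 32 32 3
#' @export
encode_participant <- function(series, side = 224, work_len = 1024) {
  stopifnot(inherits(series, "au_series"), nrow(series$values) >= 2,
            side >= 2, work_len >= 2)
  chans <- lapply(1:3, function(j) {
    x <- mean_pool(series$values[, j], work_len)
    if (min(x) == max(x)) {
      warning("degenerate (constant) channel ", colnames(series$values)[j],
              "; encoding as zeros")
      return(matrix(0, side, side))
    }
    resize_bilinear(gadf(minmax_normalize(x)), side)
  })
  img <- array(0, dim = c(side, side, 3))
  for (j in 1:3) img[, , j] <- pmin(1, pmax(-1, chans[[j]]))
  structure(img, class = "gaf_image",
            participant_id = series$participant_id,
            triad_id = series$triad_id, condition = series$condition)
}

#' @export
print.gaf_image <- function(x, ...) {
  cat(sprintf("GADF image %dx%dx3 (%s, triad %s), range [%.3f, %.3f]\n",
              dim(x)[1], dim(x)[2], attr(x, "participant_id"),
              attr(x, "triad_id"), min(x), max(x)))
  invisible(x)
}

#' Plot one channel of a GADF image
#'
#' @param x a `gaf_image`.
#' @param channel 1 (AU4), 2 (AU6) or 3 (AU12).
#' @param ... passed to [graphics::image()].
#' @export
plot.gaf_image <- function(x, channel = 3, ...) {
  m <- x[, , channel]
  graphics::image(t(m[nrow(m):1, ]), zlim = c(-1, 1), axes = FALSE,
                  col = grDevices::hcl.colors(64, "RdBu", rev = TRUE),
                  main = sprintf("%s  AU%s GADF", attr(x, "participant_id"),
                                 c("4", "6", "12")[channel]), ...)
  invisible(x)
}

#' Encode every participant of a dataset
#'
#' Applies [mask_speech()] (unless `mask = FALSE`) and
#' [encode_participant()] to every participant, optionally after a
#' transformation of each series (used by the control analyses).
#'
#' @param dataset an `au_dataset`.
#' @param side,work_len see [encode_participant()].
#' @param mask apply the participant's own speech mask first.
#' @param transform optional `function(series) -> series` applied after
#'   masking (e.g. [binarize_speech()] or [permute_series()]).
#' @return List of `gaf_image`, one per participant, with a
#'   `"triad_id"`/`"condition"` attribute per element.
#' @export
encode_dataset <- function(dataset, side = 64, work_len = 256,
                           mask = TRUE, transform = NULL) {
  stopifnot(inherits(dataset, "au_dataset"))
  out <- list()
  for (tr in dataset) {
    for (p in tr$participants) {
      s <- p
      if (mask) {
        s$values[s$speech_mask, ] <- 0
      }
      if (!is.null(transform)) s <- transform(s)
      out[[s$participant_id]] <-
        suppressWarnings(encode_participant(s, side = side,
                                            work_len = work_len))
    }
  }
  out
}
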