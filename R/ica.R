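# Deflationary FastICA with the logcosh contrast, seeded and deterministic.
#
# Returns the unmixing matrix applied to the (centered) data, the component
# time courses and the mixing matrix, or NULL when the fixed-point iteration
# fails to converge.
fastica_decompose <- function(x, n_comp = nrow(x), seed = 1L,
                              max_iter = 200L, tol = 1e-5,
                              max_samples = 10000L) {
  nch <- nrow(x); n <- ncol(x)
  mu <- rowMeans(x)
  xc <- x - mu
  cv <- tcrossprod(xc) / n
  eg <- eigen(cv, symmetric = TRUE)
  keep <- which(eg$values > 1e-12)[seq_len(min(n_comp, sum(eg$values > 1e-12)))]
  K <- diag(1 / sqrt(eg$values[keep]), length(keep)) %*% t(eg$vectors[, keep])
  # fit the unmixing matrix on an evenly decimated subset for speed; the
  # final components are computed on the full-rate data
  fit_idx <- if (n > max_samples)
    seq(1L, n, by = ceiling(n / max_samples)) else seq_len(n)
  z <- K %*% xc[, fit_idx, drop = FALSE]
  nfit <- ncol(z)
  m <- nrow(z)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  # deflationary fastICA (logcosh contrast): components are extracted one at
  # a time with Gram-Schmidt orthogonalization against those already found.
  # Strongly non-Gaussian sources (blinks) converge in a few iterations;
  # a background component that stalls keeps its last iterate, and only a
  # decomposition where nothing converges is treated as a failure.
  W <- matrix(0, m, m)
  n_converged <- 0L
  for (comp in seq_len(m)) {
    w <- stats::rnorm(m)
    if (comp > 1) {
      prev <- W[seq_len(comp - 1), , drop = FALSE]
      w <- w - t(prev) %*% (prev %*% w)
    }
    w <- w / sqrt(sum(w^2))
    ok <- FALSE
    for (it in seq_len(max_iter)) {
      wz <- drop(crossprod(w, z))
      g <- tanh(wz)
      w1 <- (z %*% g) / nfit - mean(1 - g^2) * w
      if (comp > 1) {
        prev <- W[seq_len(comp - 1), , drop = FALSE]
        w1 <- w1 - t(prev) %*% (prev %*% w1)
      }
      nrm <- sqrt(sum(w1^2))
      if (nrm < 1e-12) break
      w1 <- w1 / nrm
      conv <- abs(abs(sum(w1 * w)) - 1)
      w <- drop(w1)
      if (conv < tol) { ok <- TRUE; break }
    }
    W[comp, ] <- w
    if (ok) n_converged <- n_converged + 1L
  }
  if (n_converged == 0L) return(NULL)
  U <- W %*% K                         # components = U %*% centered data
  A <- MASS_ginv(U)                    # channels x components mixing
  list(unmixing = U, mixing = A, sources = U %*% xc, center = mu)
}

# Moore-Penrose pseudoinverse via SVD (small matrices only).
MASS_ginv <- function(m, tol = 1e-10) {
  s <- svd(m)
  pos <- s$d > tol * s$d[1]
  s$v[, pos, drop = FALSE] %*% diag(1 / s$d[pos], sum(pos)) %*%
    t(s$u[, pos, drop = FALSE])
}

#' Remove eye-blink components by ICA
#'
#' Decomposes the recording with a seeded deflationary FastICA and zeroes
#' components that look like blinks: the component time course must
#' correlate with the mean of the frontal-polar channels (FP1, FP2) at
#' `|r| >= cor_threshold`, and its scalp projection must load on the
#' frontal pole more than twice as strongly as the average of the other
#' channels. If the fixed-point iteration does not converge the recording
#' is passed through unmodified with a warning.
#'
#' @param rec a filtered `eeg_recording` (>= 60 s of data recommended).
#' @param seed integer seed for the ICA initialization.
#' @param cor_threshold frontal-correlation threshold (default 0.8).
#' @return list with `recording` (cleaned) and `n_removed` (component count).
#' @export
remove_blinks_ica <- function(rec, seed = 1L, cor_threshold = 0.8) {
  fp <- which(toupper(rec$channels) %in% c("FP1", "FP2"))
  if (length(fp) == 0) stop("montage has no frontal-polar channels")
  dec <- fastica_decompose(rec$data, seed = seed)
  if (is.null(dec)) {
    warning("ICA did not converge; recording passed through unmodified")
    return(list(recording = rec, n_removed = 0L))
  }
  fp_mean <- colMeans(rec$data[fp, , drop = FALSE])
  m <- nrow(dec$sources)
  is_blink <- logical(m)
  for (k in seq_len(m)) {
    src <- dec$sources[k, ]
    if (stats::sd(src) < 1e-12 || stats::sd(fp_mean) < 1e-12) next
    r <- stats::cor(src, fp_mean)
    topo <- abs(dec$mixing[, k])
    frontal <- mean(topo[fp])
    others <- mean(topo[-fp])
    is_blink[k] <- abs(r) >= cor_threshold && frontal > 2 * others
  }
  n_removed <- sum(is_blink)
  out <- rec$data
  if (n_removed > 0) {
    blink_part <- dec$mixing[, is_blink, drop = FALSE] %*%
      dec$sources[is_blink, , drop = FALSE]
    out <- out - blink_part
  }
  list(recording = eeg_recording(out, fs = rec$fs, channels = rec$channels,
                                 subject_id = rec$subject_id),
       n_removed = as.integer(n_removed))
}
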