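# Internal helpers shared across modules.

# Clip correlations just inside (-1, 1) so atanh stays finite on degenerate
# (perfectly collinear) toy inputs. The bound matches the documented
# fisher_z clipping rule.
R_CLIP <- 1 - 1e-7

clip_r <- function(r) pmin(pmax(r, -R_CLIP), R_CLIP)

# Standardize the columns of a frames x voxels matrix to zero mean and unit
# Euclidean norm, so crossprod() of the result gives Pearson correlations.
# Constant columns are returned as NA with attr "constant" marking them.
unit_norm_columns <- function(X) {
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu, "-")
  nrm <- sqrt(colSums(Xc^2))
  const <- nrm <= 0 | !is.finite(nrm)
  nrm[const] <- NA_real_
  U <- sweep(Xc, 2L, nrm, "/")
  attr(U, "constant") <- const
  U
}

# Legendre polynomial basis P_0..P_order evaluated on n points spread over
# [-1, 1]; used as the detrending baseline (well-conditioned, spans the same
# space as raw powers).
legendre_basis <- function(n, order) {
  stopifnot(n >= 2L, order >= 0L)
  x <- seq(-1, 1, length.out = n)
  P <- matrix(0, n, order + 1L)
  P[, 1L] <- 1
  if (order >= 1L) P[, 2L] <- x
  if (order >= 2L) {
    for (k in 2:order) {
      P[, k + 1L] <- ((2 * k - 1) * x * P[, k] - (k - 1) * P[, k - 1L]) / k
    }
  }
  colnames(P) <- paste0("poly", 0:order)
  P
}

# FNV-1a 32-bit hash over a character scalar, in double arithmetic (the
# 2^40-scale intermediates are exact in doubles). Returns 8 hex digits.
fnv1a_hash <- function(s) {
  bytes <- utf8ToInt(enc2utf8(paste(s, collapse = "\n")))
  h <- 2166136261
  m <- 16777619
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- (((h1 * m) %% 65536) * 65536 + h0 * m) %% 4294967296
  }
  paste0(sprintf("%04x", h %/% 65536), sprintf("%04x", h %% 65536))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Draw a sub-seed usable with set.seed() from the current RNG stream.
draw_subseed <- function(n = 1L) sample.int(.Machine$integer.max, n)
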