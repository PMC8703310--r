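# Active-set least squares with nonnegativity on a subset of coefficients
# (Lawson-Hanson style, warm-started from the fully passive set: in a
# spectral fit most amplitudes are strictly positive, so starting from the
# unconstrained solution converges in a handful of passes).
#
# Minimizes ||A x - b||^2 subject to x[j] >= 0 for j in nonneg; remaining
# coefficients are free-signed.  A may contain penalty rows.
bounded_ls <- function(A, b, nonneg = integer(), max_pass = 200L) {
  p <- ncol(A)
  passive <- rep(TRUE, p)
  x <- numeric(p)
  tol <- 1e-10 * max(1, sum(abs(A)) / length(A))
  solve_passive <- function() {
    xs <- numeric(p)
    idx <- which(passive)
    if (length(idx))
      xs[idx] <- qr.coef(qr(A[, idx, drop = FALSE]), b)
    xs[is.na(xs)] <- 0
    xs
  }
  for (it in seq_len(max_pass)) {
    x <- solve_passive()
    viol <- intersect(nonneg, which(passive & x < -tol))
    if (length(viol)) {
      passive[viol[which.min(x[viol])]] <- FALSE
      next
    }
    x[nonneg] <- pmax(x[nonneg], 0)
    # KKT: allow a clamped coefficient back in if its gradient is positive
    w <- drop(crossprod(A, b - A %*% x))
    cand <- intersect(nonneg, which(!passive))
    cand <- cand[w[cand] > tol * max(1, max(abs(w)))]
    if (!length(cand)) return(list(x = x, passive = passive, iters = it))
    passive[cand[which.max(w[cand])]] <- TRUE
  }
  list(x = x, passive = passive, iters = max_pass, warning = "max passes")
}
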