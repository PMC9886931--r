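# Oblique gradient-projection rotation (direct oblimin family).

## Oblimin criterion value and gradient at pattern matrix L.
## gamma = 0 is direct quartimin.
oblimin_vg <- function(L, gamma = 0) {
  p <- nrow(L); m <- ncol(L)
  L2 <- L^2
  N <- matrix(1, m, m) - diag(m)
  B <- L2 %*% N
  if (gamma != 0) B <- B - (gamma / p) * matrix(colSums(L2 %*% N), p, m,
                                                byrow = TRUE)
  list(f = sum(L2 * B) / 4, Gq = L * B)
}

## Gradient-projection minimization over oblique rotations (unit-length
## columns of T; pattern L = A T'^-1, factor correlation Phi = T'T).
gpa_oblique <- function(A, gamma = 0, Tmat = diag(ncol(A)),
                        maxit = 1000, tol = 1e-6) {
  Tm <- Tmat
  Ti <- solve(Tm)
  L <- A %*% t(Ti)
  vg <- oblimin_vg(L, gamma)
  f <- vg$f
  G <- -t(t(L) %*% vg$Gq %*% Ti)
  al <- 1
  converged <- FALSE
  for (iter in seq_len(maxit)) {
    Gp <- G - Tm %*% diag(colSums(Tm * G), ncol(Tm))
    s <- sqrt(sum(Gp^2))
    if (s < tol) { converged <- TRUE; break }
    al <- 2 * al
    ok <- FALSE
    for (half in 0:30) {
      X <- Tm - al * Gp
      X <- X %*% diag(1 / sqrt(colSums(X^2)), ncol(X))
      Ti2 <- tryCatch(solve(X), error = function(e) NULL)
      if (!is.null(Ti2)) {
        L2 <- A %*% t(Ti2)
        vg2 <- oblimin_vg(L2, gamma)
        if (vg2$f < f - 0.5 * s^2 * al) { ok <- TRUE; break }
      }
      al <- al / 2
    }
    if (!ok) { converged <- s < 1e-4; break }
    Tm <- X; Ti <- Ti2; L <- L2; f <- vg2$f
    G <- -t(t(L) %*% vg2$Gq %*% Ti)
  }
  list(pattern = L, Tmat = Tm, Phi = t(Tm) %*% Tm, f = f,
       converged = converged)
}

#' Oblimin rotation of an unrotated loading matrix
#'
#' Gradient-projection minimization of the oblimin criterion (default
#' `gamma = 0`, direct quartimin) over oblique rotations. Factors in the
#' result are reordered by descending explained variance (sums of squared
#' structure loadings) and sign-aligned so each column of the pattern sums to
#' a non-negative value. Per-variable communalities are preserved by the
#' rotation.
#'
#' @param loadings unrotated p x m loading matrix (m >= 1).
#' @param gamma oblimin family parameter.
#' @param n_starts random restarts (first start is the identity).
#' @param seed seed for the random restarts.
#' @return list with `pattern`, `Phi` (factor correlations), `structure`,
#'   `f` (criterion value), `converged`.
#' @export
oblimin_rotate <- function(loadings, gamma = 0, n_starts = 10, seed = 1) {
  A <- as.matrix(loadings)
  m <- ncol(A)
  if (m == 1) {
    sgn <- if (sum(A) < 0) -1 else 1
    return(list(pattern = A * sgn, Phi = matrix(1, 1, 1),
                structure = A * sgn, f = 0, converged = TRUE))
  }
  set.seed(seed)
  best <- NULL
  for (s in seq_len(n_starts)) {
    T0 <- if (s == 1) diag(m) else {
      Q <- qr.Q(qr(matrix(stats::rnorm(m * m), m, m)))
      Q %*% diag(1 / sqrt(colSums(Q^2)), m)
    }
    res <- gpa_oblique(A, gamma, T0)
    if (res$converged && (is.null(best) || res$f < best$f)) best <- res
  }
  if (is.null(best))
    vn_stop("oblimin rotation failed to converge from all starts",
            "varnet_convergence_error")
  ## Order by explained variance, align signs.
  L <- best$pattern; Phi <- best$Phi
  S <- L %*% Phi
  ord <- order(colSums(S^2), decreasing = TRUE)  # SS structure loadings
  L <- L[, ord, drop = FALSE]; Phi <- Phi[ord, ord, drop = FALSE]
  sgn <- ifelse(colSums(L) < 0, -1, 1)
  L <- sweep(L, 2, sgn, `*`)
  Phi <- diag(sgn) %*% Phi %*% diag(sgn)
  dimnames(L) <- dimnames(loadings)
  dimnames(Phi) <- list(colnames(L), colnames(L))
  list(pattern = L, Phi = Phi, structure = L %*% Phi, f = best$f,
       converged = TRUE)
}
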