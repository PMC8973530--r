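# Small shared utilities.

# Run code under a given seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Orthogonal Procrustes residual between two configurations
#'
#' Measures how far two coordinate matrices are from agreeing up to
#' translation, orthogonal rotation/reflection and (optionally) a global
#' scale: both are centered, the optimal orthogonal map (and scale) from
#' `Y` onto `Z` is computed from the SVD of the cross-covariance, and the
#' residual is the remaining squared error relative to the total variance
#' of `Z`. Zero means exact agreement up to the allowed transforms.
#'
#' @param Y,Z numeric matrices of equal shape (n x d).
#' @param scale allow a global scale factor (default TRUE).
#' @return Relative residual `||s Yc R - Zc||_F^2 / ||Zc||_F^2`.
#' @export
procrustes_residual <- function(Y, Z, scale = TRUE) {
  Y <- as.matrix(Y); Z <- as.matrix(Z)
  stopifnot(all(dim(Y) == dim(Z)))
  Yc <- sweep(Y, 2, colMeans(Y))
  Zc <- sweep(Z, 2, colMeans(Z))
  sv <- svd(crossprod(Yc, Zc))
  R <- sv$u %*% t(sv$v)
  s <- if (scale) sum(sv$d) / sum(Yc^2) else 1
  sum((s * (Yc %*% R) - Zc)^2) / sum(Zc^2)
}

#' Affine-map residual between two configurations
#'
#' Relative residual of the best affine map from `Y` onto `Z` (ordinary
#' least squares with intercept), measured against the centered variance
#' of `Z`. Zero means `Z` is exactly an affine image of `Y` — the right
#' notion of recovery for eigenvector embeddings, whose columns are
#' individually normalized and so differ from the latent coordinates by a
#' general linear map, not merely a rotation.
#'
#' @param Y,Z numeric matrices with the same number of rows.
#' @return Relative residual in `[0, 1]`.
#' @export
affine_residual <- function(Y, Z) {
  Y <- as.matrix(Y); Z <- as.matrix(Z)
  stopifnot(nrow(Y) == nrow(Z))
  fit <- stats::lm.fit(cbind(1, Y), Z)
  Zc <- sweep(Z, 2, colMeans(Z))
  sum(as.matrix(fit$residuals)^2) / sum(Zc^2)
}
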