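# Landmark-based geometric morphometrics: generalised Procrustes
# superimposition, thin-plate-spline partial warps with the uniform
# (affine) component, permutation regression of shape on a covariate,
# and the classical univariate body-shape ratios.
#
# Shapes are stored the way landmark packages store them: a k x 2 x n
# array of n configurations of k two-dimensional landmarks.

as_shape_array <- function(configs) {
  if (is.array(configs) && length(dim(configs)) == 3L) return(configs)
  if (is.list(configs)) {
    k <- nrow(configs[[1L]])
    arr <- array(NA_real_, c(k, 2L, length(configs)),
                 dimnames = list(NULL, c("x", "y"),
                                 names(configs) %||%
                                   paste0("spec", seq_along(configs))))
    for (i in seq_along(configs)) {
      m <- as.matrix(configs[[i]])
      if (nrow(m) != k) stop("all configurations must have the same ",
                             "number of landmarks", call. = FALSE)
      arr[, , i] <- m
    }
    return(arr)
  }
  stop("`configs` must be a k x 2 x n array or a list of k x 2 matrices",
       call. = FALSE)
}

centroid_size <- function(m) {
  cm <- colMeans(m)
  sqrt(sum(sweep(m, 2, cm)^2))
}

center_scale <- function(m) {
  cm <- colMeans(m)
  m <- sweep(m, 2, cm)
  cs <- sqrt(sum(m^2))
  if (cs <= 0) stop("degenerate configuration: all landmarks coincide",
                    call. = FALSE)
  list(coords = m / cs, size = cs)
}

# proper rotation aligning X onto C (Kabsch)
optimal_rotation <- function(X, C) {
  M <- crossprod(X, C)
  sv <- svd(M)
  d <- sign(det(sv$u %*% t(sv$v)))
  sv$u %*% diag(c(1, d)) %*% t(sv$v)
}

#' Generalised Procrustes alignment
#'
#' Iterative least-squares superimposition: each configuration is
#' centred, scaled to unit centroid size and rotated to the current
#' consensus; the consensus is re-estimated and renormalised until it
#' stabilises. Scaling beyond unit centroid size is not re-optimised in
#' the rotation step (partial Procrustes superimposition); set
#' `scale_full = TRUE` for full-Procrustes scaling of each specimen to
#' the consensus.
#'
#' @param configs k x 2 x n array (or list of k x 2 matrices) of
#'   landmark configurations with consistent landmark ordering.
#' @param tol Convergence threshold on the consensus change
#'   (root-summed-squared difference; default 1e-10).
#' @param max_iter Iteration cap.
#' @param scale_full Re-scale each aligned specimen by its cosine to the
#'   consensus (full Procrustes) instead of keeping unit size.
#' @return A `gpa_fit`: list with `consensus` (k x 2, centred, unit
#'   centroid size), `aligned` (k x 2 x n), `centroid_sizes`.
#' @export
gpa_align <- function(configs, tol = 1e-10, max_iter = 200,
                      scale_full = FALSE) {
  arr <- as_shape_array(configs)
  n <- dim(arr)[3L]; k <- dim(arr)[1L]
  if (n < 2L) stop("need at least 2 configurations", call. = FALSE)
  if (k < 4L) stop("need at least 4 landmarks", call. = FALSE)
  sizes <- numeric(n)
  aligned <- array(NA_real_, dim(arr), dimnames = dimnames(arr))
  for (i in seq_len(n)) {
    cs <- center_scale(arr[, , i])
    aligned[, , i] <- cs$coords
    sizes[i] <- cs$size
  }
  consensus <- aligned[, , 1L]
  for (iter in seq_len(max_iter)) {
    for (i in seq_len(n)) {
      R <- optimal_rotation(aligned[, , i], consensus)
      Xr <- aligned[, , i] %*% R
      if (scale_full) Xr <- Xr * sum(Xr * consensus) / sum(Xr^2)
      aligned[, , i] <- Xr
    }
    new_consensus <- apply(aligned, c(1, 2), mean)
    new_consensus <- center_scale(new_consensus)$coords
    delta <- sqrt(sum((new_consensus - consensus)^2))
    consensus <- new_consensus
    if (delta < tol) break
  }
  structure(list(consensus = consensus, aligned = aligned,
                 centroid_sizes = sizes, iterations = iter),
            class = "gpa_fit")
}

#' Procrustes distance between two configurations
#'
#' Partial Procrustes distance: both configurations are centred, scaled
#' to unit centroid size and optimally rotated; the distance is the
#' square root of the summed squared landmark differences.
#'
#' @param a,b k x 2 landmark matrices.
#' @return Non-negative distance (0 for shapes identical up to a
#'   similarity transform).
#' @export
procrustes_distance <- function(a, b) {
  A <- center_scale(as.matrix(a))$coords
  B <- center_scale(as.matrix(b))$coords
  R <- optimal_rotation(A, B)
  sqrt(sum((A %*% R - B)^2))
}

# Bending-energy matrix of a reference configuration; its null space is
# the affine subspace spanned by {1, x, y}.
bending_energy <- function(ref) {
  k <- nrow(ref)
  d2 <- as.matrix(stats::dist(ref))^2
  K <- ifelse(d2 > 0, d2 * log(d2), 0)
  Q <- cbind(1, ref)
  L <- rbind(cbind(K, Q), cbind(t(Q), matrix(0, 3, 3)))
  Li <- tryCatch(solve(L), error = function(e) {
    stop("singular bending-energy system: reference landmarks are ",
         "degenerate (collinear or coincident)", call. = FALSE)
  })
  Be <- Li[seq_len(k), seq_len(k)]
  (Be + t(Be)) / 2
}

# Orthonormal basis (2k x 2) of the uniform shape subspace of a centred,
# unit-size reference: affine deformations minus the similarity
# directions (isotropic scaling and rotation of the reference).
uniform_basis <- function(ref) {
  cx <- ref[, 1L]; cy <- ref[, 2L]
  z <- numeric(length(cx))
  aff <- cbind(c(cx, z), c(cy, z), c(z, cx), c(z, cy))
  s <- c(cx, cy); s <- s / sqrt(sum(s^2))
  ro <- c(-cy, cx); ro <- ro / sqrt(sum(ro^2))
  P <- aff - s %*% crossprod(s, aff) - ro %*% crossprod(ro, aff)
  sv <- svd(P)
  sv$u[, 1:2, drop = FALSE]
}

#' Thin-plate-spline partial warp and uniform scores
#'
#' The bending-energy matrix of the consensus is eigen-decomposed; its
#' k-3 non-null eigenvectors (principal warps) give, per coordinate,
#' 2(k-3) partial-warp scores for each specimen's Procrustes residual.
#' The 2-dimensional uniform (affine) component is computed on the
#' complementary affine subspace, so the squared scores of a specimen
#' sum exactly to its squared tangent-space Procrustes residual.
#' Residuals are projected into the tangent space (component along the
#' consensus removed) before scoring.
#'
#' @param gpa A `gpa_fit` from [gpa_align()].
#' @return A `shape_scores`: list with `partial_warp_scores`
#'   (n x 2(k-3)), `uniform` (n x 2), `scores` (n x (2k-4), partial
#'   warps then uniform), `consensus`, `bending_eigenvalues`.
#' @export
tps_partial_warps <- function(gpa) {
  stopifnot(inherits(gpa, "gpa_fit"))
  C <- gpa$consensus
  k <- nrow(C); n <- dim(gpa$aligned)[3L]
  if (k < 4L) stop("need at least 4 landmarks", call. = FALSE)
  Be <- bending_energy(C)
  eg <- eigen(Be, symmetric = TRUE)
  nw <- k - 3L
  E <- eg$vectors[, seq_len(nw), drop = FALSE]   # non-null principal warps
  U <- uniform_basis(C)
  s <- c(C[, 1L], C[, 2L]); s <- s / sqrt(sum(s^2))
  ro <- c(-C[, 2L], C[, 1L]); ro <- ro / sqrt(sum(ro^2))
  pw <- matrix(NA_real_, n, 2L * nw)
  un <- matrix(NA_real_, n, 2L)
  resid_norm2 <- numeric(n)
  for (i in seq_len(n)) {
    d <- c(gpa$aligned[, 1L, i] - C[, 1L], gpa$aligned[, 2L, i] - C[, 2L])
    d <- d - s * sum(s * d) - ro * sum(ro * d)   # tangent projection
    resid_norm2[i] <- sum(d^2)
    dx <- d[seq_len(k)]; dy <- d[k + seq_len(k)]
    pw[i, ] <- c(crossprod(E, dx), crossprod(E, dy))
    un[i, ] <- crossprod(U, d)
  }
  rownames(pw) <- rownames(un) <- dimnames(gpa$aligned)[[3L]]
  structure(
    list(partial_warp_scores = pw, uniform = un,
         scores = cbind(pw, un), consensus = C,
         bending_eigenvalues = eg$values[seq_len(nw)],
         tangent_resid_norm2 = resid_norm2),
    class = "shape_scores"
  )
}

#' Permutation regression of shape on a covariate
#'
#' Goodall-style statistic: the partial-warp + uniform score matrix is
#' regressed on a single covariate; `F` is the ratio of explained to
#' residual Procrustes sums of squares, each over its degrees of
#' freedom, and the p-value is the proportion of covariate permutations
#' (observed included) whose `F` meets or exceeds the observed one. The
#' statistic does not require more specimens than shape variables.
#'
#' @param scores A `shape_scores`, or a numeric matrix of shape
#'   variables (rows = specimens).
#' @param covariate Numeric vector, one value per specimen.
#' @param n_perm Number of permutations (>= 99; default 999).
#' @param seed Optional integer seed for the permutations.
#' @return List with `F`, `p`, `df1`, `df2`, `n_perm`.
#' @export
shape_regression <- function(scores, covariate, n_perm = 999,
                             seed = NULL) {
  Y <- if (inherits(scores, "shape_scores")) scores$scores else
    as.matrix(scores)
  n <- nrow(Y)
  if (length(covariate) != n) {
    stop("`covariate` must have one value per specimen", call. = FALSE)
  }
  if (!is.numeric(covariate) || stats::var(covariate) == 0) {
    stop("`covariate` must be numeric and non-constant", call. = FALSE)
  }
  check_count(n_perm, "n_perm", min = 99L)
  if (n < 3L) stop("need at least 3 specimens", call. = FALSE)
  Yc <- sweep(Y, 2L, colMeans(Y))
  goodall_f <- function(xv) {
    xc <- xv - mean(xv)
    b <- crossprod(Yc, xc) / sum(xc^2)        # per-column slope
    ss_exp <- sum(xc^2) * sum(b^2)
    ss_tot <- sum(Yc^2)
    ss_res <- ss_tot - ss_exp
    (ss_exp / 1) / (ss_res / (n - 2))
  }
  f_obs <- goodall_f(covariate)
  maybe_seed(seed)
  hits <- 1L                                   # observed included
  for (b in seq_len(n_perm - 1L)) {
    if (goodall_f(sample(covariate)) >= f_obs - 1e-12) hits <- hits + 1L
  }
  list(F = f_obs, p = hits / n_perm, df1 = 1L, df2 = n - 2L,
       n_perm = n_perm)
}

#' Univariate body-shape ratios
#'
#' The classical streamlining descriptors: fineness ratio
#' `FR = body length / body depth`, caudal fin aspect ratio
#' `AR = caudal fin height^2 / caudal fin area`, relative caudal
#' peduncle depth `CPH = 100 * caudal peduncle depth / body length` (%),
#' and the caudal peduncle depth factor `CPD_BD = caudal peduncle
#' depth / body depth`.
#'
#' @param body_length,body_depth,caudal_fin_height,caudal_fin_area,caudal_peduncle_depth
#'   Positive measurements in a common length unit (area in its square).
#' @return Data frame with columns `FR`, `AR`, `CPH`, `CPD_BD`.
#' @examples
#' morpho_ratios(8, 1.6, 2, 1, 0.6)
#' @export
morpho_ratios <- function(body_length, body_depth, caudal_fin_height,
                          caudal_fin_area, caudal_peduncle_depth) {
  args <- list(body_length = body_length, body_depth = body_depth,
               caudal_fin_height = caudal_fin_height,
               caudal_fin_area = caudal_fin_area,
               caudal_peduncle_depth = caudal_peduncle_depth)
  for (nm in names(args)) {
    if (any(!is.finite(args[[nm]])) || any(args[[nm]] <= 0)) {
      stop(sprintf("`%s` must be positive", nm), call. = FALSE)
    }
  }
  data.frame(
    FR = body_length / body_depth,
    AR = caudal_fin_height^2 / caudal_fin_area,
    CPH = 100 * caudal_peduncle_depth / body_length,
    CPD_BD = caudal_peduncle_depth / body_depth
  )
}

#' The packaged 17-landmark template
#'
#' A stylised, synthetic 17-point outline of a small cyprinid in left
#' lateral view (snout, eye, dorsal and ventral fin bases, caudal
#' peduncle and fork). It is the reference shape of the landmark
#' generator, not a digitisation of any real specimen.
#'
#' @return 17 x 2 matrix with landmark names as row names.
#' @export
template_landmarks <- function() {
  path <- system.file("extdata", "landmark_template_synthetic.csv",
                      package = "swimphys", mustWork = TRUE)
  tab <- utils::read.csv(path)
  m <- as.matrix(tab[, c("x", "y")])
  rownames(m) <- tab$landmark
  m
}
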