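#' Tissue elasticity parameters
#'
#' Linear elastic, isotropic, quasi-static tissue model. Literature shear
#' moduli are used for white (2.7 kPa) and gray (3.1 kPa) matter; CSF is
#' assigned a small positive shear modulus (it bears negligible shear but a
#' zero value would make the system singular). Poisson's ratio 0.45 reflects
#' nearly incompressible tissue, and `lambda2` couples the tumor-fraction
#' gradient into the equilibrium equation as a growth-induced body force.
#'
#' @param G_white,G_gray,G_csf shear moduli, kPa.
#' @param nu Poisson's ratio, in (0, 0.5).
#' @param lambda2 tumor-fraction forcing coupling constant (dimensionless,
#'   default 1).
#' @return An object of class `elasticity_params`.
#' @export
elasticity_params <- function(G_white = 2.7, G_gray = 3.1, G_csf = 0.1,
                              nu = 0.45, lambda2 = 1) {
  if (any(!is.finite(c(G_white, G_gray, G_csf))) ||
      any(c(G_white, G_gray, G_csf) <= 0))
    stop("invalid parameters: shear moduli must be > 0")
  if (!is.finite(nu) || nu <= 0 || nu >= 0.5)
    stop("invalid parameters: Poisson ratio must satisfy 0 < nu < 0.5")
  structure(list(G_white = G_white, G_gray = G_gray, G_csf = G_csf,
                 nu = nu, lambda2 = lambda2), class = "elasticity_params")
}

## shear-modulus field from tissue labels (kPa); zero outside the brain
shear_field <- function(tissue_labels, brain_mask, params) {
  G <- array(0, dim(tissue_labels))
  G[tissue_labels == TISSUE_CODES["white"]] <- params$G_white
  G[tissue_labels == TISSUE_CODES["gray"]] <- params$G_gray
  G[tissue_labels == TISSUE_CODES["csf"]] <- params$G_csf
  G[!brain_mask] <- 0
  G
}

## shift an array along one axis: result[i] = a[i + by], zero-filled
shift3 <- function(a, axis, by) {
  array(cpp_shift3(as.numeric(a), dim(a), as.integer(axis), as.integer(by)),
        dim(a))
}

## central difference along one axis with zero padding beyond the grid
grad_central <- function(a, axis, h) {
  (shift3(a, axis, 1L) - shift3(a, axis, -1L)) / (2 * h)
}

## sparse central-difference matrix (n x n over the full grid, column-major
## voxel order); exactly skew-symmetric with zero padding at grid edges
central_diff_matrix <- function(grid, axis) {
  d <- grid$shape
  n <- prod(d)
  h <- grid$spacing[axis]
  idx <- array(seq_len(n), d)
  stride <- c(1L, d[1], d[1] * d[2])[axis]
  coord <- slice.index(idx, axis)
  has_next <- which(coord < d[axis])
  Matrix::sparseMatrix(
    i = c(has_next, has_next + stride),
    j = c(has_next + stride, has_next),
    x = c(rep(1 / (2 * h), length(has_next)),
          rep(-1 / (2 * h), length(has_next))),
    dims = c(n, n))
}

## forward-difference matrix mapping voxels to faces along one axis
forward_diff_matrix <- function(grid, axis) {
  d <- grid$shape
  n <- prod(d)
  h <- grid$spacing[axis]
  idx <- array(seq_len(n), d)
  stride <- c(1L, d[1], d[1] * d[2])[axis]
  coord <- slice.index(idx, axis)
  rows <- which(coord < d[axis])
  Matrix::sparseMatrix(
    i = c(rows, rows), j = c(rows, rows + stride),
    x = c(rep(-1 / h, length(rows)), rep(1 / h, length(rows))),
    dims = c(n, n))
}

## harmonic face average; one-sided where a neighbour lies outside the medium
face_harmonic <- function(g, axis) {
  gn <- shift3(g, axis, 1L)
  num <- 2 * g * gn
  den <- g + gn
  out <- ifelse(g > 0 & gn > 0, num / pmax(den, .Machine$double.eps),
                pmax(g, gn))
  out
}

#' Assemble and factor the discrete elasticity operator
#'
#' Discretizes the quasi-static equilibrium
#' `div(G grad u) + grad[G/(1-2 nu)] (div u) = lambda2 grad(phi)` with
#' second-order central differences on the (anisotropic) image grid:
#' flux-form differences with harmonic face averaging for the shear term and
#' skew-symmetric central differences for the dilatational coupling term. The
#' skull is rigid: displacement is pinned to zero outside the brain mask, so
#' only brain voxels carry unknowns. The resulting symmetric positive
#' definite system is factored once (sparse Cholesky) and re-used for every
#' forcing field on the same geometry.
#'
#' @param grid an [image_grid()].
#' @param tissue_labels integer label array (0 background, 1 white, 2 gray,
#'   3 csf).
#' @param brain_mask logical array.
#' @param params an [elasticity_params()] object.
#' @return A `mechanics_operator` (Cholesky factor + geometry), accepted by
#'   [solve_displacement()] and [von_mises()].
#' @export
build_mechanics_operator <- function(grid, tissue_labels, brain_mask, params) {
  stopifnot(inherits(params, "elasticity_params"))
  check_field(tissue_labels, grid, "tissue_labels")
  check_field(brain_mask, grid, "brain_mask")
  brain_mask <- array(as.logical(brain_mask), grid$shape)
  labeled <- tissue_labels != TISSUE_CODES["background"]
  if (any(brain_mask & !labeled))
    stop("tissue labels do not cover the brain mask")
  G <- shear_field(tissue_labels, brain_mask, params)
  cfield <- G / (1 - 2 * params$nu)
  n <- prod(grid$shape)
  bidx <- which(brain_mask)
  if (length(bidx) == 0L) stop("brain mask is empty")

  LG <- Matrix::Matrix(0, n, n, sparse = TRUE)
  for (ax in 1:3) {
    Df <- forward_diff_matrix(grid, ax)
    gf <- as.vector(face_harmonic(G, ax))
    LG <- LG - Matrix::t(Df) %*% (gf * Df)
  }
  C <- lapply(1:3, function(ax) central_diff_matrix(grid, ax))
  cv <- as.vector(cfield)
  blocks <- vector("list", 9)
  for (a in 1:3) for (b in 1:3) {
    blk <- C[[a]] %*% (cv * C[[b]])
    if (a == b) blk <- blk + LG
    blocks[[(a - 1) * 3 + b]] <- blk[bidx, bidx, drop = FALSE]
  }
  A <- rbind(cbind(blocks[[1]], blocks[[2]], blocks[[3]]),
             cbind(blocks[[4]], blocks[[5]], blocks[[6]]),
             cbind(blocks[[7]], blocks[[8]], blocks[[9]]))
  M <- Matrix::forceSymmetric(-(A + Matrix::t(A)) / 2, uplo = "U")
  ch <- tryCatch(Matrix::Cholesky(M, LDL = FALSE, super = TRUE),
                 error = function(e)
                   stop("elasticity system is singular or ill-conditioned: ",
                        conditionMessage(e)))
  structure(list(grid = grid, brain_idx = bidx, nb = length(bidx),
                 chol = ch, M = M, G = G, nu = params$nu,
                 lambda2 = params$lambda2, brain_mask = brain_mask),
            class = "mechanics_operator")
}

#' Solve for tissue displacement driven by the tumor-fraction gradient
#'
#' Solves the discretized equilibrium equation for the displacement field
#' `u` (mm) given the current tumor volume fraction `phi`. Accepts either a
#' prebuilt [build_mechanics_operator()] (preferred inside time loops) or the
#' raw geometry, from which the operator is assembled on the fly.
#'
#' @param phi tumor volume fraction array in [0, 1] (total burden for the
#'   two-species model).
#' @param op a `mechanics_operator`, or `NULL`.
#' @param tissue_labels,params,brain_mask,grid geometry used when `op` is
#'   `NULL`.
#' @return list of three 3-D arrays `u1`, `u2`, `u3` (mm; zero outside the
#'   brain) with attribute `"operator"` carrying the operator used.
#' @export
solve_displacement <- function(phi, op = NULL, tissue_labels = NULL,
                               params = elasticity_params(),
                               brain_mask = NULL, grid = NULL) {
  if (is.null(op))
    op <- build_mechanics_operator(grid, tissue_labels, brain_mask, params)
  check_field(phi, op$grid, "phi")
  if (min(phi) < -1e-12 || max(phi) > 1 + 1e-12)
    stop("phi must lie in [0, 1]")
  b <- numeric(3 * op$nb)
  for (ax in 1:3) {
    g <- grad_central(phi, ax, op$grid$spacing[ax])
    ## A u = lambda2 grad(phi)  with M = -A  =>  M u = -lambda2 grad(phi)
    b[(ax - 1) * op$nb + seq_len(op$nb)] <- -op$lambda2 * g[op$brain_idx]
  }
  x <- as.numeric(Matrix::solve(op$chol, b))
  u <- lapply(1:3, function(ax) {
    a <- zeros_like(op$grid)
    a[op$brain_idx] <- x[(ax - 1) * op$nb + seq_len(op$nb)]
    a
  })
  names(u) <- c("u1", "u2", "u3")
  attr(u, "operator") <- op
  u
}

#' Von Mises stress of a displacement field
#'
#' Computes the linear-elastic stress tensor from the displacement field by
#' central differences and summarizes its deviatoric part as the von Mises
#' stress (kPa), the scalar used to dampen tumor cell diffusion.
#'
#' @param u displacement as returned by [solve_displacement()].
#' @param op the `mechanics_operator` (or `NULL` to take it from `u`).
#' @return 3-D array of von Mises stress, kPa, >= 0, zero outside the brain.
#' @export
von_mises <- function(u, op = NULL) {
  if (is.null(op)) op <- attr(u, "operator")
  if (is.null(op)) stop("need the mechanics operator (geometry and moduli)")
  vm <- array(cpp_von_mises(as.numeric(u$u1), as.numeric(u$u2),
                            as.numeric(u$u3), as.numeric(op$G),
                            op$grid$shape, op$grid$spacing, op$nu),
              op$grid$shape)
  vm[!op$brain_mask] <- 0
  if (any(!is.finite(vm))) stop("non-finite von Mises stress")
  vm
}

#' Mechanically dampen a diffusion field
#'
#' D = D0 * exp(-lambda1 * sigma_vm): local tissue stress exponentially
#' inhibits tumor cell diffusion.
#'
#' @param D0 uninhibited diffusion coefficient field, mm^2/day, >= 0.
#' @param sigma_vm von Mises stress field, kPa, >= 0.
#' @param lambda1 stress-diffusion coupling constant, 1/kPa, >= 0.
#' @return damped diffusion field with 0 <= D <= D0 everywhere.
#' @export
damp_diffusion <- function(D0, sigma_vm, lambda1) {
  if (!is.finite(lambda1) || lambda1 < 0)
    stop("invalid parameters: lambda1 must be >= 0")
  if (lambda1 == 0) return(D0)
  D0 * exp(-lambda1 * sigma_vm)
}
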