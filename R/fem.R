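#' @import Matrix
#' @importFrom methods as is
#' @importFrom stats setNames
NULL

# Linear-triangle geometry: areas and shape-function gradients.
# For element nodes (1,2,3): grad(phi_a) = (by[,a], bz[,a]).
fem_geom <- function(coords, tri) {
  y1 <- coords[tri[, 1], 1]; z1 <- coords[tri[, 1], 2]
  y2 <- coords[tri[, 2], 1]; z2 <- coords[tri[, 2], 2]
  y3 <- coords[tri[, 3], 1]; z3 <- coords[tri[, 3], 2]
  twoA <- (y2 - y1) * (z3 - z1) - (y3 - y1) * (z2 - z1)
  list(
    area = twoA / 2,
    by = cbind(z2 - z3, z3 - z1, z1 - z2) / twoA,
    bz = cbind(y3 - y2, y1 - y3, y2 - y1) / twoA
  )
}

n_nodes <- function(mesh) nrow(mesh$X)

# lumped mass vector (row-sum lumping = vertex-rule mass)
mass_lumped <- function(geom, tri, n) {
  m <- numeric(n)
  w <- geom$area / 3
  for (a in 1:3) {
    acc <- tapply(w, tri[, a], sum)
    m[as.integer(names(acc))] <- m[as.integer(names(acc))] + acc
  }
  m
}

# consistent P1 mass matrix (A/6 diagonal, A/12 off-diagonal per element)
mass_consistent <- function(geom, tri, n) {
  ii <- jj <- xx <- vector("list", 9L)
  k <- 0L
  for (a in 1:3) for (b in 1:3) {
    k <- k + 1L
    ii[[k]] <- tri[, a]; jj[[k]] <- tri[, b]
    xx[[k]] <- geom$area * (if (a == b) 1 / 6 else 1 / 12)
  }
  sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
               dims = c(n, n))
}

# weighted stiffness: K_ij = sum_e w_e A_e grad(phi_i).grad(phi_j)
stiffness_weighted <- function(geom, tri, w_elem, n) {
  ii <- jj <- xx <- vector("list", 9L)
  k <- 0L
  for (a in 1:3) for (b in 1:3) {
    k <- k + 1L
    ii[[k]] <- tri[, a]; jj[[k]] <- tri[, b]
    xx[[k]] <- w_elem * geom$area *
      (geom$by[, a] * geom$by[, b] + geom$bz[, a] * geom$bz[, b])
  }
  sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
               dims = c(n, n))
}

# chemotaxis operator by the vertex quadrature rule:
# C_ij = chi * sum_e A_e/3 * grad(c)(node j) . grad(phi_i)|_e   (j in e)
chemotaxis_matrix <- function(geom, tri, grad_c, chi, n) {
  ii <- jj <- xx <- vector("list", 9L)
  k <- 0L
  for (a in 1:3) for (b in 1:3) {
    k <- k + 1L
    nb <- tri[, b]
    ii[[k]] <- tri[, a]; jj[[k]] <- nb
    xx[[k]] <- chi * geom$area / 3 *
      (grad_c[nb, 1] * geom$by[, a] + grad_c[nb, 2] * geom$bz[, a])
  }
  sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
               dims = c(n, n))
}

#' Variational gradient recovery
#'
#' Projects the piecewise-constant element gradients of a nodal field onto
#' the nodal linear basis with the (lumped) mass matrix, giving a nodal
#' gradient estimate that is exact for globally linear fields (also at the
#' boundary).
#'
#' @param mesh a `scar_mesh`.
#' @param z nodal field values.
#' @param current use current (deformed) coordinates.
#' @return n x 2 matrix of recovered nodal gradients.
#' @export
recover_gradient <- function(mesh, z, current = TRUE) {
  coords <- if (current) mesh$cur else mesh$X
  tri <- mesh$tri
  g <- fem_geom(coords, tri)
  n <- nrow(coords)
  gy <- g$by[, 1] * z[tri[, 1]] + g$by[, 2] * z[tri[, 2]] +
    g$by[, 3] * z[tri[, 3]]
  gz <- g$bz[, 1] * z[tri[, 1]] + g$bz[, 2] * z[tri[, 2]] +
    g$bz[, 3] * z[tri[, 3]]
  m <- numeric(n); ry <- numeric(n); rz <- numeric(n)
  w <- g$area / 3
  for (a in 1:3) {
    ix <- tri[, a]
    m <- m + tabulate0(ix, w, n)
    ry <- ry + tabulate0(ix, w * gy, n)
    rz <- rz + tabulate0(ix, w * gz, n)
  }
  cbind(ry / m, rz / m)
}

# scatter-add helper: sum val over index groups into a length-n vector
tabulate0 <- function(index, val, n) {
  out <- numeric(n)
  acc <- rowsum(val, index, reorder = FALSE)
  out[as.integer(rownames(acc))] <- acc[, 1]
  out
}

# discrete-upwinding artificial diffusion for a transport operator K
# (M dz/dt = K z): D_ij = max(0, -K_ij, -K_ji), zero row sums.
artificial_diffusion <- function(K) {
  Koff <- K - Diagonal(x = diag(K))
  P1 <- Koff
  P1@x <- pmax(-P1@x, 0)
  P2 <- t(P1)
  D <- (P1 + P2 + abs(P1 - P2)) / 2   # elementwise max of two >=0 matrices
  D <- D - Diagonal(x = diag(D))
  D - Diagonal(x = rowSums(D))
}

#' Zalesak flux-corrected-transport limiter
#'
#' Given the positivity-preserving low-order solution and the
#' antidiffusive fluxes `F` (a sparse antisymmetric matrix, `F_ij = -F_ji`)
#' that would restore the high-order (Galerkin) solution, limits each flux
#' by a coefficient `alpha_ij` in \[0, 1\] such that no nodal value leaves
#' the local bounds set by the low-order solution and the previous time
#' level. Fluxes that would steepen existing gradients are pre-limited to
#' zero. Nodes flagged `fixed` (Dirichlet) take no correction.
#'
#' @param z_low low-order solution (non-negative).
#' @param z_old previous time-level solution.
#' @param F sparse antisymmetric antidiffusive flux matrix (mass units per
#'   day).
#' @param m lumped mass vector.
#' @param dt time-step size, day.
#' @param fixed logical mask of Dirichlet nodes.
#' @return list with the limited solution `z` and the limiter coefficients
#'   `alpha` (sparse, same pattern as `F`).
#' @export
fct_limit <- function(z_low, z_old, F, m, dt, fixed = NULL) {
  n <- length(z_low)
  Ft <- as(F, "TsparseMatrix")
  i <- Ft@i + 1L; j <- Ft@j + 1L; f <- Ft@x
  keep <- i != j
  i <- i[keep]; j <- j[keep]; f <- f[keep]
  if (!is.null(fixed) && any(fixed)) {
    keep <- !(fixed[i] | fixed[j])
    i <- i[keep]; j <- j[keep]; f <- f[keep]
  }
  if (!length(f)) {
    return(list(z = z_low,
                alpha = sparseMatrix(i = integer(), j = integer(),
                                     x = numeric(), dims = c(n, n))))
  }
  core <- fct_core(i, j, f, z_low, z_old, m, dt)
  list(z = core$z,
       alpha = sparseMatrix(i = i, j = j, x = core$alpha, dims = c(n, n)))
}

# two-point Gauss rule on a segment [0, L]: exact through cubics
edge_gauss2 <- function() {
  s <- 1 / sqrt(3)
  list(t = c((1 - s) / 2, (1 + s) / 2), w = c(0.5, 0.5))
}

# boundary edge geometry on given coordinates: lengths and outward normals
# (edges are stored counterclockwise, so n = (t_z, -t_y))
edge_geom <- function(coords, edges) {
  p1 <- coords[edges$n1, , drop = FALSE]
  p2 <- coords[edges$n2, , drop = FALSE]
  d <- p2 - p1
  len <- sqrt(rowSums(d^2))
  list(len = len, nx = d[, 2] / len, ny = -d[, 1] / len)
}
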