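# Pattern-cached assembly. The mesh connectivity never changes while the
# nodes move, so the sparsity pattern, the element-to-slot aggregation
# operator, the transpose permutation and the node neighbor lists are all
# computed once per mesh and reused by every assembly.

mesh_cache_env <- function(mesh) {
  env <- mesh$cache
  if (is.null(env)) stop("mesh has no cache environment")
  env
}

transport_cache <- function(mesh) {
  env <- mesh_cache_env(mesh)
  if (!is.null(env$tp)) return(env$tp)
  tri <- mesh$tri
  n <- nrow(mesh$X); m <- nrow(tri)
  ii <- jj <- integer(9L * m)
  k <- 0L
  for (a in 1:3) for (b in 1:3) {
    idx <- (k * m + 1L):((k + 1L) * m)
    ii[idx] <- tri[, a]; jj[idx] <- tri[, b]
    k <- k + 1L
  }
  key <- (as.double(ii) - 1) * n + as.double(jj)
  uk <- sort(unique(key))
  pos <- match(key, uk)
  np <- length(uk)
  pat_i <- as.integer((uk - 1) %/% n) + 1L
  pat_j <- as.integer((uk - 1) %% n) + 1L
  tt <- match((as.double(pat_j) - 1) * n + as.double(pat_i), uk)
  dslot <- match((as.double(1:n) - 1) * n + as.double(1:n), uk)
  off <- which(pat_i != pat_j)
  Agg <- sparseMatrix(i = pos, j = seq_along(pos), x = 1,
                      dims = c(np, length(pos)))
  dir <- dirichlet_nodes(mesh)
  fixed <- logical(n); fixed[dir] <- TRUE
  dir_slots <- which(pat_i %in% dir)
  # off-diagonal fluxes whose end points are free (not Dirichlet)
  off_free <- off[!(fixed[pat_i[off]] | fixed[pat_j[off]])]
  # per-node neighbor lists of the free flux pattern, for limiter bounds
  nbr <- vector("list", n)
  sp <- split(pat_j[off_free], pat_i[off_free])
  nbr[as.integer(names(sp))] <- sp
  # fast scatter-add operators (0/1 sparse matrices, fixed per mesh)
  AggM <- sparseMatrix(i = c(tri[, 1], tri[, 2], tri[, 3]),
                       j = seq_len(3L * m), x = 1, dims = c(n, 3L * m))
  AggDi <- sparseMatrix(i = pat_i[off], j = seq_along(off), x = 1,
                        dims = c(n, length(off)))
  AggI <- sparseMatrix(i = pat_i[off_free], j = seq_along(off_free),
                       x = 1, dims = c(n, length(off_free)))
  # padded neighbor-index matrix for vectorized local bounds
  kmax <- max(c(1L, lengths(nbr)))
  nbr_mat <- matrix(rep(seq_len(n), kmax), n, kmax)
  for (r in seq_len(n)) {
    nb <- nbr[[r]]
    if (length(nb)) nbr_mat[r, seq_along(nb)] <- nb
  }
  env$tp <- list(n = n, m = m, np = np, jj = jj, pat_i = pat_i,
                 pat_j = pat_j, tt = tt, dslot = dslot, off = off,
                 off_free = off_free, Agg = Agg, dir = dir,
                 fixed = fixed, dir_slots = dir_slots, nbr = nbr,
                 AggM = AggM, AggDi = AggDi, AggI = AggI,
                 nbr_mat = nbr_mat)
  env$tp
}

# 9-block geometric products on the current coordinates; shared by the
# diffusion and mass assemblies of all constituents within one pass
transport_geometry <- function(mesh, tp) {
  geom <- fem_geom(mesh$cur, mesh$tri)
  m <- tp$m
  gprod <- numeric(9L * m)   # area * grad(phi_a).grad(phi_b)
  mcv <- numeric(9L * m)     # consistent mass values
  chem <- numeric(9L * m)    # area/3 * grad(phi_a) (y,z parts filled later)
  k <- 0L
  for (a in 1:3) for (b in 1:3) {
    idx <- (k * m + 1L):((k + 1L) * m)
    gprod[idx] <- geom$area *
      (geom$by[, a] * geom$by[, b] + geom$bz[, a] * geom$bz[, b])
    mcv[idx] <- geom$area * (if (a == b) 1 / 6 else 1 / 12)
    k <- k + 1L
  }
  m_new <- as.numeric(tp$AggM %*% rep(geom$area / 3, 3L))
  mc_slots <- as.numeric(tp$Agg %*% mcv)
  list(geom = geom, gprod = gprod, m_new = m_new, mc = mc_slots)
}

# chemotaxis block values for given recovered nodal gradient
chemo_values <- function(geom, tri, tp, grad_c, chi) {
  m <- tp$m
  out <- numeric(9L * m)
  k <- 0L
  for (a in 1:3) for (b in 1:3) {
    idx <- (k * m + 1L):((k + 1L) * m)
    nb <- tri[, b]
    out[idx] <- chi * geom$area / 3 *
      (grad_c[nb, 1] * geom$by[, a] + grad_c[nb, 2] * geom$bz[, a])
    k <- k + 1L
  }
  out
}

# core Zalesak limiter on triplet flux arrays. `tp` (the mesh transport
# cache) supplies vectorized neighbor bounds and scatter operators when
# the fluxes live on the cached free pattern; without it a generic path
# is used (public fct_limit on arbitrary patterns).
fct_core <- function(i, j, f, z_low, z_old, m, dt, tp = NULL) {
  n <- length(z_low)
  f[f * (z_low[j] - z_low[i]) > 0] <- 0   # prelimiting
  zs <- pmax(z_low, z_old)
  zi <- pmin(z_low, z_old)
  if (!is.null(tp)) {
    zmax <- pmax(zs, pad_row_max(zs, tp$nbr_mat))
    zmin <- pmin(zi, pad_row_min(zi, tp$nbr_mat))
    Pp <- as.numeric(tp$AggI %*% pmax(f, 0))
    Pm <- as.numeric(tp$AggI %*% pmin(f, 0))
  } else {
    nbr <- vector("list", n)
    sp <- split(j, i)
    nbr[as.integer(names(sp))] <- sp
    nb_max <- vapply(seq_len(n), function(k)
      if (length(nbr[[k]])) max(zs[nbr[[k]]]) else -Inf, 0)
    nb_min <- vapply(seq_len(n), function(k)
      if (length(nbr[[k]])) min(zi[nbr[[k]]]) else Inf, 0)
    zmax <- pmax(zs, nb_max)
    zmin <- pmin(zi, nb_min)
    Pp <- tabulate0(i, pmax(f, 0), n)
    Pm <- tabulate0(i, pmin(f, 0), n)
  }
  Qp <- m / dt * (zmax - z_low)
  Qm <- m / dt * (zmin - z_low)
  Rp <- ifelse(Pp > 0, pmin(1, Qp / Pp), 1)
  Rm <- ifelse(Pm < 0, pmin(1, Qm / Pm), 1)
  alpha <- ifelse(f > 0, pmin(Rp[i], Rm[j]), pmin(Rm[i], Rp[j]))
  dz <- if (!is.null(tp)) as.numeric(tp$AggI %*% (alpha * f)) * dt / m
        else tabulate0(i, alpha * f, n) * dt / m
  z <- z_low + dz
  bad <- !is.finite(dz)
  z[bad] <- z_low[bad]
  list(z = z, alpha = alpha)
}

# column-wise max/min of z over a padded neighbor-index matrix
pad_row_max <- function(z, idx) {
  out <- z[idx[, 1]]
  if (ncol(idx) > 1L)
    for (k in 2:ncol(idx)) out <- pmax(out, z[idx[, k]])
  out
}

pad_row_min <- function(z, idx) {
  out <- z[idx[, 1]]
  if (ncol(idx) > 1L)
    for (k in 2:ncol(idx)) out <- pmin(out, z[idx[, k]])
  out
}
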