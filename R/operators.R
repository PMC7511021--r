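# Sparse finite-volume operators on a bu_mesh, memoized in the mesh cache.
#
# All operators act on concentrations (umol/L) and return concentration
# rates, so litre/m^3 factors cancel everywhere except in the BBB coupling,
# where the face flux density (umol m^-2 s^-1) meets cell volumes; the
# scatter matrices G are built volume-raw (area / m^3) and the caller divides
# by the litre conversion factor (1e3 L/m^3 in dimensional runs).

.mesh_operators <- function(mesh) {
  stopifnot(inherits(mesh, "bu_mesh"))
  if (!is.null(mesh$cache$ops)) return(mesh$cache$ops)

  ncell <- mesh$ncell
  plasma <- mesh$plasma
  vol <- mesh$vol
  w3 <- mesh$w3
  faces <- mesh$faces
  nb <- mesh$nb
  ec <- which(!plasma)
  ne <- length(ec)
  le_of <- integer(ncell); le_of[ec] <- seq_len(ne)
  pl_dyn <- setdiff(which(plasma), c(mesh$in_id, mesh$out_id))

  # --- plasma upwind advection operator M (full-cell indexing) -------------
  ti <- integer(0); tj <- integer(0); tv <- numeric(0)
  add <- function(i, j, v) {
    ti <<- c(ti, i); tj <<- c(tj, j); tv <<- c(tv, v)
  }
  for (p in pl_dyn) {
    ax <- mesh$flow_axis[p]
    w <- w3[p, ax]
    q <- mesh$upwind[p]
    if (!is.na(q)) {
      add(p, q, 1 / w); add(p, p, -1 / w)
    } else {
      fd <- mesh$feeders[[p]]
      k <- length(fd)
      if (k > 0L) {
        for (f in fd) add(p, f, 1 / (k * w))
        add(p, p, -1 / w)
      }
      # no upwind and no feeders: zero-gradient ghost, advection rate zero
    }
  }
  M <- Matrix::sparseMatrix(i = ti, j = tj, x = tv, dims = c(ncell, ncell))

  # inlet faces: first cells of the ribs leaving U_in (cross-section areas)
  qin <- which(!is.na(mesh$upwind) & mesh$upwind == mesh$in_id)
  a_cross <- function(cells) {
    vapply(cells, function(q) {
      ax <- mesh$flow_axis[q]
      tr <- setdiff(1:3, ax)
      w3[q, tr[1]] * w3[q, tr[2]]
    }, numeric(1))
  }
  in_faces <- list(cells = qin, area = a_cross(qin))
  ofd <- mesh$feeders[[mesh$out_id]]
  out_faces <- list(cells = ofd, area = a_cross(ofd))

  # junction imbalance weights: sum_p V_p (M C)_p = t(M) %*% vol . C
  jw_pl <- as.numeric(Matrix::crossprod(M, vol))

  # --- ECF diffusion operator L (local ECF indexing) -----------------------
  ti <- integer(0); tj <- integer(0); tv <- numeric(0)
  ctr_d <- function(a, b, ax) abs(mesh$coords[a, ax] - mesh$coords[b, ax])
  for (ax in 1:3) {
    plus <- nb[[c("xp", "yp", "zp")[ax]]]
    a <- which(!is.na(plus))
    b <- plus[a]
    keep <- !plasma[a] & !plasma[b]
    a <- a[keep]; b <- b[keep]
    tr <- setdiff(1:3, ax)
    af <- w3[a, tr[1]] * w3[a, tr[2]]
    d <- ctr_d(a, b, ax)
    la <- le_of[a]; lb <- le_of[b]
    ti <- c(ti, la, la, lb, lb)
    tj <- c(tj, lb, la, la, lb)
    tv <- c(tv, af / (d * vol[a]), -af / (d * vol[a]),
            af / (d * vol[b]), -af / (d * vol[b]))
  }
  L <- Matrix::sparseMatrix(i = ti, j = tj, x = tv, dims = c(ne, ne))

  # --- ECF x-directed upwind advection A (local indexing) ------------------
  # zero-gradient ghosts on the cube faces (inflow at local concentration);
  # faces shared with plasma are closed to advection (no transmural flow)
  afc <- w3[ec, 2] * w3[ec, 3]          # x-face area per ECF cell
  lid <- le_of[ec]
  qm <- nb$xm[ec]; qp <- nb$xp[ec]
  m_bnd <- is.na(qm)                    # cube face at x = 0
  m_ecf <- !m_bnd & !plasma[ifelse(m_bnd, 1L, qm)]
  p_bnd <- is.na(qp)                    # cube face at x = x_r
  p_ecf <- !p_bnd & !plasma[ifelse(p_bnd, 1L, qp)]
  ti <- c(lid[m_bnd], lid[m_ecf], lid[p_bnd | p_ecf])
  tj <- c(lid[m_bnd], le_of[qm[m_ecf]], lid[p_bnd | p_ecf])
  tv <- c(afc[m_bnd] / vol[ec[m_bnd]], afc[m_ecf] / vol[ec[m_ecf]],
          -afc[p_bnd | p_ecf] / vol[ec[p_bnd | p_ecf]])
  A <- Matrix::sparseMatrix(i = ti, j = tj, x = tv, dims = c(ne, ne))
  ecf_bnd_in <- list(cells = ec[m_bnd], area = afc[m_bnd])
  ecf_bnd_out <- list(cells = ec[p_bnd], area = afc[p_bnd])
  jw_ecf <- as.numeric(Matrix::crossprod(A, vol[ec]))

  # --- BBB coupling scatter matrices (volume-raw: area / m^3) --------------
  nf <- nrow(faces)
  Gp_raw <- Matrix::sparseMatrix(i = faces$plasma, j = seq_len(nf),
                                 x = faces$area / vol[faces$plasma],
                                 dims = c(ncell, nf))
  face_le <- le_of[faces$ecf]
  Ge_raw <- Matrix::sparseMatrix(i = face_le, j = seq_len(nf),
                                 x = faces$area / vol[faces$ecf],
                                 dims = c(ne, nf))

  ops <- list(M = M, L = L, A = A, Gp_raw = Gp_raw, Ge_raw = Ge_raw,
              ec = ec, ne = ne, le_of = le_of, pl_dyn = pl_dyn,
              face_p = faces$plasma, face_le = face_le, face_area = faces$area,
              in_faces = in_faces, out_faces = out_faces,
              jw_pl = jw_pl, jw_ecf = jw_ecf,
              ecf_bnd_in = ecf_bnd_in, ecf_bnd_out = ecf_bnd_out)
  mesh$cache$ops <- ops
  ops
}

# Sparsity pattern of the coupled Jacobian in compressed-column (ian/jan)
# form for lsodes: supplying it avoids the neq+1 structure-probing calls.
# The pattern is a superset of the true structure (full diagonal included).
.jac_pattern <- function(ops, naux, clamp_ecf = FALSE) {
  np <- length(ops$pl_dyn); ne <- ops$ne
  nst <- np + 3L * ne + naux
  ncell <- length(ops$le_of)
  st_pl <- integer(ncell); st_pl[ops$pl_dyn] <- seq_len(np)
  o_ce <- np; o_b1 <- np + ne; o_b2 <- np + 2L * ne

  Mt <- as(as(ops$M, "generalMatrix"), "TsparseMatrix")
  keep <- st_pl[Mt@i + 1L] > 0L & st_pl[Mt@j + 1L] > 0L
  ri <- st_pl[Mt@i[keep] + 1L]; ci <- st_pl[Mt@j[keep] + 1L]

  Lt <- as(as(ops$L, "generalMatrix"), "TsparseMatrix")
  At <- as(as(ops$A, "generalMatrix"), "TsparseMatrix")
  f_pl <- st_pl[ops$face_p]            # always dynamic rib cells
  f_ce <- ops$face_le
  ii <- c(ri,                               # plasma advection
          f_pl, f_pl,                       # d dCpl / d(u, v) via BBB flux
          seq_len(nst))                     # full diagonal
  jj <- c(ci,
          f_pl, o_ce + f_ce,
          seq_len(nst))
  if (!clamp_ecf) {
    # free-ECF rows couple through diffusion/advection stencils, the BBB
    # faces and the local binding kinetics; with the concentration clamped
    # those rows are identically zero and only the diagonal remains
    ii <- c(ii,
            o_ce + Lt@i + 1L, o_ce + At@i + 1L,
            o_ce + f_ce, o_ce + f_ce,       # d dCe / d(u, v)
            o_ce + seq_len(ne), o_ce + seq_len(ne),   # d dCe / d(B1, B2)
            o_b1 + seq_len(ne), o_b2 + seq_len(ne))
    jj <- c(jj,
            o_ce + Lt@j + 1L, o_ce + At@j + 1L,
            st_pl[ops$face_p], o_ce + f_ce,
            o_b1 + seq_len(ne), o_b2 + seq_len(ne),
            o_ce + seq_len(ne), o_ce + seq_len(ne))
  } else {
    ii <- c(ii, o_b1 + seq_len(ne), o_b2 + seq_len(ne))
    jj <- c(jj, o_ce + seq_len(ne), o_ce + seq_len(ne))
  }
  if (naux > 0L) {
    # audit integrals depend on face concentrations, the outlet feeders and
    # the junction/boundary weight vectors
    o_ax <- np + 3L * ne
    jw_pl_cells <- intersect(which(ops$jw_pl != 0), ops$pl_dyn)
    jw_ecf_le <- which(ops$jw_ecf != 0)
    out_st <- st_pl[ops$out_faces$cells]
    bi <- ops$le_of[ops$ecf_bnd_in$cells]
    bo <- ops$le_of[ops$ecf_bnd_out$cells]
    ii <- c(ii, rep(o_ax + 1L, 2L * length(f_pl)),
            rep(o_ax + 3L, length(out_st)),
            rep(o_ax + 4L, length(jw_pl_cells) + length(out_st)),
            rep(o_ax + 5L, length(bi)), rep(o_ax + 6L, length(bo)),
            rep(o_ax + 7L, length(jw_ecf_le) + length(bi) + length(bo)))
    jj <- c(jj, f_pl, o_ce + f_ce,
            out_st,
            st_pl[jw_pl_cells], out_st,
            o_ce + bi, o_ce + bo,
            o_ce + jw_ecf_le, o_ce + bi, o_ce + bo)
  }
  Jp <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(nst, nst))
  Jp <- as(Jp, "CsparseMatrix")
  list(inz = c(Jp@p + 1L, Jp@i + 1L), nnz = length(Jp@i))
}

.plasma_operator <- function(mesh) {
  ops <- .mesh_operators(mesh)
  list(M = ops$M, Gp = ops$Gp_raw / 1e3)
}

.ecf_operator <- function(mesh) {
  ops <- .mesh_operators(mesh)
  list(L = ops$L, A = ops$A, Ge = ops$Ge_raw / 1e3)
}
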