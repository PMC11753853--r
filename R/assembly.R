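# Staggered-grid (MAC) finite-volume discretization of steady
# incompressible Stokes / Navier-Stokes flow on a tagged tensor mesh.
#
# Velocity components live on the faces normal to their direction
# (u on x-faces, v on y-faces, w on z-faces), pressure at cell centers.
# This pairing is inf-sup stable: there are no spurious pressure modes and
# no stabilization terms. Pressure boundary conditions at the open x-ends
# enter the normal-momentum equation of the boundary faces through a
# mirrored ghost pressure (second-order), with zero tangential velocity on
# the end planes; tangential no-slip walls use a one-sided quadratic flux
# so that fully developed Poiseuille flow is reproduced to machine
# precision on a uniform grid. Planar meshes have no v unknowns and
# symmetry (zero-flux) side planes.
#
# Unknown ordering: [u | v | w | p].

face_dims <- function(mesh, comp) {
  d <- c(mesh$nx, mesh$ny, mesh$nz)
  d[comp] <- d[comp] + 1L
  d
}

# Status codes per face: >0 unknown id, -1 wall (value 0), 0 nonexistent.
# Out-of-range gathers return -9.
build_dofs <- function(mesh) {
  A <- mesh$active
  comps <- if (mesh$planar) c(1L, 3L) else 1:3
  status <- vector("list", 3L)
  n_unk <- 0L
  for (comp in 1:3) {
    fd <- face_dims(mesh, comp)
    S <- array(0L, fd)
    if (!(comp %in% comps)) { status[[comp]] <- S; next }
    Am <- array(FALSE, fd); Ap <- array(FALSE, fd)
    dm <- dp <- list(seq_len(fd[1]), seq_len(fd[2]), seq_len(fd[3]))
    dm[[comp]] <- 2:fd[comp]
    dp[[comp]] <- 1:(fd[comp] - 1L)
    Am[dm[[1]], dm[[2]], dm[[3]]] <- A   # cell on minus side active
    Ap[dp[[1]], dp[[2]], dp[[3]]] <- A   # cell on plus side active
    unk <- Am & Ap
    if (comp == 1L) {                    # open pressure ends
      unk[1, , ] <- A[1, , ]
      unk[fd[1], , ] <- A[mesh$nx, , ]
    }
    wall <- (Am | Ap) & !unk
    S[wall] <- -1L
    nu <- sum(unk)
    S[unk] <- n_unk + seq_len(nu)
    n_unk <- n_unk + nu
    status[[comp]] <- S
  }
  pid <- array(0L, dim(A))
  pid[A] <- n_unk + seq_len(sum(A))
  list(status = status, pid = pid, n = n_unk + sum(A), n_vel = n_unk,
       comps = comps)
}

gather_status <- function(S, i, j, k) {
  fd <- dim(S)
  ok <- i >= 1L & i <= fd[1] & j >= 1L & j <= fd[2] & k >= 1L & k <= fd[3]
  st <- rep(-9L, length(i))
  if (any(ok)) st[ok] <- S[cbind(i[ok], j[ok], k[ok])]
  st
}

gather_value <- function(V, i, j, k) {
  fd <- dim(V)
  ok <- i >= 1L & i <= fd[1] & j >= 1L & j <= fd[2] & k >= 1L & k <= fd[3]
  v <- numeric(length(i))
  if (any(ok)) v[ok] <- V[cbind(i[ok], j[ok], k[ok])]
  v
}

safe_at <- function(v, idx) {
  out <- rep(NA_real_, length(idx))
  ok <- idx >= 1L & idx <= length(v)
  out[ok] <- v[idx[ok]]
  out
}

with_axis <- function(idx3, axis, val) { idx3[[axis]] <- val; idx3 }

new_triplets <- function() {
  e <- new.env(parent = emptyenv())
  e$i <- list(); e$j <- list(); e$x <- list()
  e
}
add_trip <- function(tr, rows, cols, vals, mask = NULL) {
  if (!is.null(mask)) { rows <- rows[mask]; cols <- cols[mask]; vals <- vals[mask] }
  keep <- cols > 0L & vals != 0
  if (!any(keep)) return(invisible())
  n <- length(tr$i) + 1L
  tr$i[[n]] <- rows[keep]; tr$j[[n]] <- cols[keep]; tr$x[[n]] <- vals[keep]
  invisible()
}
trip_matrix <- function(tr, n) {
  if (!length(tr$i))
    return(Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                dims = c(n, n)))
  Matrix::sparseMatrix(i = unlist(tr$i), j = unlist(tr$j), x = unlist(tr$x),
                       dims = c(n, n))
}

# Static solver context shared by all assembly passes.
solver_context <- function(mesh, dofs, props) {
  ctx <- list(
    mesh = mesh, dofs = dofs,
    mu = props$dynamic_viscosity, rho = props$density,
    csz = list(mesh$dx, mesh$dy, mesh$dz),
    ccc = list(mesh$xc, mesh$yc, mesh$zc),
    cfc = list(mesh$xf, mesh$yf, mesh$zf),
    nax = c(mesh$nx, mesh$ny, mesh$nz))
  ctx$faces <- lapply(1:3, function(comp) {
    S <- dofs$status[[comp]]
    fidx <- which(S > 0L)
    if (!length(fidx)) return(NULL)
    sub <- arrayInd(fidx, dim(S))
    idx3 <- list(sub[, 1], sub[, 2], sub[, 3])
    m <- idx3[[comp]]
    fd <- dim(S)
    inlet <- outlet <- rep(FALSE, length(fidx))
    if (comp == 1L) { inlet <- m == 1L; outlet <- m == fd[1] }
    cc_n <- ctx$ccc[[comp]]
    hn <- ifelse(inlet, ctx$csz[[comp]][1L],
          ifelse(outlet, ctx$csz[[comp]][ctx$nax[comp]],
                 safe_at(cc_n, m) - safe_at(cc_n, m - 1L)))
    list(fidx = fidx, idx3 = idx3, m = m, row = S[fidx],
         inlet = inlet, outlet = outlet, hn = hn)
  })
  ctx$tang <- lapply(1:3, function(comp)
    setdiff(dofs$comps, comp))
  ctx
}

# ---- linear (Stokes) operator --------------------------------------------

# Returns A (n x n sparse), and unit load vectors b_in, b_out such that the
# linear residual is A %*% U - (p_in * b_in + p_out * b_out).
assemble_stokes <- function(ctx) {
  dofs <- ctx$dofs
  n <- dofs$n
  tr <- new_triplets()
  b_in <- numeric(n); b_out <- numeric(n)
  mu <- ctx$mu

  for (comp in dofs$comps) {
    fc <- ctx$faces[[comp]]
    if (is.null(fc)) next
    S <- dofs$status[[comp]]
    idx3 <- fc$idx3; m <- fc$m; row <- fc$row; hn <- fc$hn
    nfc <- length(row)
    fd <- dim(S)

    # pressure gradient: (p_plus - p_minus)/hn, ghost-mirrored at open ends
    pp_idx <- with_axis(idx3, comp, pmin(m, ctx$nax[comp]))
    pm_idx <- with_axis(idx3, comp, pmax(m - 1L, 1L))
    pidp <- dofs$pid[cbind(pp_idx[[1]], pp_idx[[2]], pp_idx[[3]])]
    pidm <- dofs$pid[cbind(pm_idx[[1]], pm_idx[[2]], pm_idx[[3]])]
    add_trip(tr, row, pidp, ifelse(fc$inlet, 2, 1) / hn, mask = !fc$outlet)
    add_trip(tr, row, pidm, -ifelse(fc$outlet, 2, 1) / hn, mask = !fc$inlet)
    if (comp == 1L) {
      b_in[row[fc$inlet]] <- 2 / hn[fc$inlet]
      b_out[row[fc$outlet]] <- -2 / hn[fc$outlet]
    }

    # normal diffusion (zero-gradient ghost beyond open ends)
    cfn <- ctx$cfc[[comp]]
    for (side in c(-1L, 1L)) {
      nb <- with_axis(idx3, comp, m + side)
      st <- gather_status(S, nb[[1]], nb[[2]], nb[[3]])
      dist <- if (side == 1L) safe_at(cfn, m + 1L) - safe_at(cfn, m)
              else safe_at(cfn, m) - safe_at(cfn, m - 1L)
      ok <- st != -9L                  # in range; walls/none count as value 0
      coefd <- mu / (hn * dist)
      add_trip(tr, row, row, coefd, mask = ok)
      add_trip(tr, row, st, -coefd, mask = ok & st > 0L)
    }

    # tangential diffusion with quadratic wall fluxes
    for (t in ctx$tang[[comp]]) {
      jt <- idx3[[t]]
      cc_t <- ctx$ccc[[t]]
      h_t <- ctx$csz[[t]][jt]
      for (side in c(-1L, 1L)) {
        nb <- with_axis(idx3, t, jt + side)
        st <- gather_status(S, nb[[1]], nb[[2]], nb[[3]])
        exists <- st > 0L | st == -1L
        dist <- if (side == 1L) safe_at(cc_t, jt + 1L) - safe_at(cc_t, jt)
                else safe_at(cc_t, jt) - safe_at(cc_t, jt - 1L)
        coefd <- mu / (h_t * dist)
        add_trip(tr, row, row, coefd, mask = exists)
        add_trip(tr, row, st, -coefd, mask = exists & st > 0L)

        # wall at the face plane: quadratic one-sided flux when a second
        # interior point is available, linear otherwise
        wall <- !exists
        if (any(wall)) {
          a <- h_t / 2
          nb2 <- with_axis(idx3, t, jt - side)
          st2 <- gather_status(S, nb2[[1]], nb2[[2]], nb2[[3]])
          dist2 <- if (side == 1L) safe_at(cc_t, jt) - safe_at(cc_t, jt - 1L)
                   else safe_at(cc_t, jt + 1L) - safe_at(cc_t, jt)
          b2 <- a + dist2
          quad <- wall & (st2 > 0L | st2 == -1L) & is.finite(b2)
          lin <- wall & !quad
          alpha <- b2 / (a * (b2 - a))
          beta <- -a / (b2 * (b2 - a))
          add_trip(tr, row, row, mu * alpha / h_t, mask = quad)
          add_trip(tr, row, st2, mu * beta / h_t, mask = quad & st2 > 0L)
          add_trip(tr, row, row, mu / (a * h_t), mask = lin)
        }
      }
    }
  }

  # continuity: sum of face fluxes / cell volume
  cells <- which(ctx$mesh$active)
  sub <- arrayInd(cells, dim(ctx$mesh$active))
  cidx3 <- list(sub[, 1], sub[, 2], sub[, 3])
  prow <- dofs$pid[cells]
  for (comp in dofs$comps) {
    S <- dofs$status[[comp]]
    hi <- ctx$csz[[comp]][cidx3[[comp]]]
    stm <- S[cbind(cidx3[[1]], cidx3[[2]], cidx3[[3]])]
    plus <- with_axis(cidx3, comp, cidx3[[comp]] + 1L)
    stp <- S[cbind(plus[[1]], plus[[2]], plus[[3]])]
    add_trip(tr, prow, stp, 1 / hi, mask = stp > 0L)
    add_trip(tr, prow, stm, -1 / hi, mask = stm > 0L)
  }

  list(A = trip_matrix(tr, n), b_in = b_in, b_out = b_out)
}

# ---- convective terms (and stagnation-pressure inlet) --------------------

# First-order upwind advective form rho (u . grad) u, plus the dynamic-head
# reduction of the inlet pressure for stagnation ("total") pressure BCs.
# Returns the nonlinear residual vector and (optionally) Jacobian triplets.
assemble_convection <- function(ctx, U, bc, want_jac = TRUE) {
  dofs <- ctx$dofs
  n <- dofs$n
  rho <- ctx$rho
  res <- numeric(n)
  tr <- if (want_jac) new_triplets() else NULL

  V <- lapply(1:3, function(comp) {
    S <- dofs$status[[comp]]
    Va <- array(0, dim(S))
    idx <- S > 0L
    Va[idx] <- U[S[idx]]
    Va
  })

  for (comp in dofs$comps) {
    fc <- ctx$faces[[comp]]
    if (is.null(fc)) next
    S <- dofs$status[[comp]]
    idx3 <- fc$idx3; m <- fc$m; row <- fc$row; hn <- fc$hn
    uf <- V[[comp]][fc$fidx]
    cfn <- ctx$cfc[[comp]]

    # normal term u_f * du/dn, upwind on sign(u_f)
    pos <- uf >= 0
    nb_m <- with_axis(idx3, comp, m - 1L)
    nb_p <- with_axis(idx3, comp, m + 1L)
    st_m <- gather_status(S, nb_m[[1]], nb_m[[2]], nb_m[[3]])
    st_p <- gather_status(S, nb_p[[1]], nb_p[[2]], nb_p[[3]])
    v_m <- gather_value(V[[comp]], nb_m[[1]], nb_m[[2]], nb_m[[3]])
    v_p <- gather_value(V[[comp]], nb_p[[1]], nb_p[[2]], nb_p[[3]])
    d_m <- safe_at(cfn, m) - safe_at(cfn, m - 1L)
    d_p <- safe_at(cfn, m + 1L) - safe_at(cfn, m)
    use_m <- pos & st_m != -9L
    use_p <- !pos & st_p != -9L
    Dn <- numeric(length(uf))
    Dn[use_m] <- (uf[use_m] - v_m[use_m]) / d_m[use_m]
    Dn[use_p] <- (v_p[use_p] - uf[use_p]) / d_p[use_p]
    res[row] <- res[row] + rho * uf * Dn
    if (want_jac) {
      dself <- Dn
      dself[use_m] <- dself[use_m] + uf[use_m] / d_m[use_m]
      dself[use_p] <- dself[use_p] - uf[use_p] / d_p[use_p]
      add_trip(tr, row, row, rho * dself)
      add_trip(tr, row, st_m, -rho * uf / d_m, mask = use_m & st_m > 0L)
      add_trip(tr, row, st_p, rho * uf / d_p, mask = use_p & st_p > 0L)
    }

    # cross terms qbar * du/dt for each tangential axis
    for (t in ctx$tang[[comp]]) {
      jt <- idx3[[t]]
      cc_t <- ctx$ccc[[t]]
      St <- dofs$status[[t]]
      Vt <- V[[t]]

      # advecting velocity: average of the surrounding t-faces
      qsum <- numeric(length(uf)); navg <- numeric(length(uf))
      qpos <- list()
      for (dc in c(-1L, 0L)) for (dt in c(0L, 1L)) {
        ci <- m + dc                     # cell index along comp axis
        okc <- ci >= 1L & ci <= ctx$nax[comp]
        p3 <- with_axis(with_axis(idx3, comp, ci), t, jt + dt)
        st <- gather_status(St, p3[[1]], p3[[2]], p3[[3]])
        vv <- gather_value(Vt, p3[[1]], p3[[2]], p3[[3]])
        vv[!okc] <- 0
        qsum <- qsum + vv
        navg <- navg + as.numeric(okc)
        qpos[[length(qpos) + 1L]] <- list(st = ifelse(okc, st, -9L))
      }
      qbar <- qsum / navg

      posq <- qbar >= 0
      side <- ifelse(posq, -1L, 1L)
      nb <- with_axis(idx3, t, jt + side)
      st <- gather_status(S, nb[[1]], nb[[2]], nb[[3]])
      exists <- st > 0L | st == -1L
      dist <- ifelse(posq, safe_at(cc_t, jt) - safe_at(cc_t, jt - 1L),
                           safe_at(cc_t, jt + 1L) - safe_at(cc_t, jt))
      dist[!exists] <- ctx$csz[[t]][jt[!exists]] / 2   # wall at face plane
      val <- gather_value(V[[comp]], nb[[1]], nb[[2]], nb[[3]])
      val[!exists] <- 0
      Dt <- ifelse(posq, (uf - val) / dist, (val - uf) / dist)
      res[row] <- res[row] + rho * qbar * Dt
      if (want_jac) {
        add_trip(tr, row, row, rho * qbar * ifelse(posq, 1, -1) / dist)
        add_trip(tr, row, st, -rho * qbar * ifelse(posq, 1, -1) / dist,
                 mask = st > 0L)
        for (qp in qpos)
          add_trip(tr, row, qp$st, rho * Dt / navg, mask = qp$st > 0L)
      }
    }

    # stagnation-pressure inlet: effective static pressure
    # p_in - rho u^2 / 2 for inflow; adds + rho u^2 / hn to the residual
    if (comp == 1L && identical(bc$pressure_type, "total")) {
      sel <- fc$inlet & uf > 0
      if (any(sel)) {
        res[row[sel]] <- res[row[sel]] + rho * uf[sel]^2 / hn[sel]
        if (want_jac)
          add_trip(tr, row[sel], row[sel], 2 * rho * uf[sel] / hn[sel])
      }
    }
  }

  list(res = res, jac = if (want_jac) trip_matrix(tr, n) else NULL)
}
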