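## Axisymmetric total-Lagrangian finite-strain solver.
##
## Deformation gradient components are ordered (rR, rZ, zR, zZ, tT); the
## hoop stretch is 1 + u_r / R evaluated at the element centroid (one-point
## quadrature; in-plane gradients of the linear triangle are constant, so
## the reduced rule is exact for them). Passive response is compressible
## neo-Hookean, P = mu (F - F^-T) + lambda ln J F^-T; active Cauchy stress
## sigma_a adds P_a = J sigma_a F^-T with its exact geometric tangent.

## element kinematic operator B (m x 5 x 6), dof order (ur1..3, uz1..3)
.buildB <- function(mesh) {
  m <- nrow(mesh$tri)
  B <- array(0, c(m, 5, 6))
  for (a in 1:3) {
    B[, 1, a] <- mesh$dNdR[, a]
    B[, 2, a] <- mesh$dNdZ[, a]
    B[, 3, a + 3] <- mesh$dNdR[, a]
    B[, 4, a + 3] <- mesh$dNdZ[, a]
    B[, 5, a] <- 1 / (3 * mesh$Rc)
  }
  B
}

.defGrad <- function(mesh, u) {
  ur <- matrix(u[2 * mesh$tri - 1], ncol = 3)
  uz <- matrix(u[2 * mesh$tri], ncol = 3)
  list(F1 = 1 + rowSums(mesh$dNdR * ur),
       F2 = rowSums(mesh$dNdZ * ur),
       F3 = rowSums(mesh$dNdR * uz),
       F4 = 1 + rowSums(mesh$dNdZ * uz),
       F5 = 1 + rowMeans(ur) / mesh$Rc)
}

## active Cauchy stress components per element: (rr, rz, zz, tt)
.activeStress <- function(model, rhoIso, rhoPol, sigmaMT, n) {
  mesh <- model@mesh
  m <- nrow(mesh$tri)
  s <- list(rr = numeric(m), rz = numeric(m), zz = numeric(m),
            tt = numeric(m))
  cyto <- mesh$region == "cytoplasm"
  if (rhoIso != 0) {
    ## unassembled actomyosin is distributed throughout the cytoplasm
    s$rr[cyto] <- s$rr[cyto] + rhoIso
    s$zz[cyto] <- s$zz[cyto] + rhoIso
    s$tt[cyto] <- s$tt[cyto] + rhoIso
  }
  if (rhoPol != 0 && !is.null(n)) {
    ## mature myofibrils avoid the microtubule-rich perinuclear space at
    ## the nuclear poles: no polarized contractility inside the scaled
    ## cage ellipsoid
    pol <- cyto
    vs <- model@active$voidScale
    if (!is.null(vs) && vs > 0) {
      ax <- model@geometry$cageSemiAxes * vs
      pol <- pol & ((mesh$centroid[, 1] / ax[1])^2 +
                      (mesh$centroid[, 2] / ax[2])^2 > 1)
    }
    lamH <- model@active$lambda
    trans <- (1 - lamH) / 2
    nr <- n[, 1]; nz <- n[, 2]
    s$rr[pol] <- s$rr[pol] +
      rhoPol * (lamH * nr[pol]^2 + trans * (1 - nr[pol]^2))
    s$zz[pol] <- s$zz[pol] +
      rhoPol * (lamH * nz[pol]^2 + trans * (1 - nz[pol]^2))
    s$rz[pol] <- s$rz[pol] +
      rhoPol * (lamH - trans) * nr[pol] * nz[pol]
    s$tt[pol] <- s$tt[pol] + rhoPol * trans
  }
  cage <- mesh$region == "cage"
  if (sigmaMT != 0) {
    s$rr[cage] <- s$rr[cage] - sigmaMT
    s$zz[cage] <- s$zz[cage] - sigmaMT
    s$tt[cage] <- s$tt[cage] - sigmaMT
  }
  s
}

## first Piola-Kirchhoff stress (m x 5) and material tangent (m x 5 x 5)
.stressTangent <- function(mesh, Fc, act, wantTangent = TRUE) {
  det2 <- Fc$F1 * Fc$F4 - Fc$F2 * Fc$F3
  if (any(det2 <= 0) || any(Fc$F5 <= 0)) return(NULL)
  J <- det2 * Fc$F5
  lnJ <- log(J)
  ## F^-T components aligned with (rR, rZ, zR, zZ, tT)
  G1 <- Fc$F4 / det2; G2 <- -Fc$F3 / det2
  G3 <- -Fc$F2 / det2; G4 <- Fc$F1 / det2; G5 <- 1 / Fc$F5
  mu <- mesh$mu; lam <- mesh$lam
  Fv <- cbind(Fc$F1, Fc$F2, Fc$F3, Fc$F4, Fc$F5)
  Gv <- cbind(G1, G2, G3, G4, G5)
  P <- mu * (Fv - Gv) + lam * lnJ * Gv
  ## S = sigma_a F^-T
  S1 <- act$rr * G1 + act$rz * G3
  S2 <- act$rr * G2 + act$rz * G4
  S3 <- act$rz * G1 + act$zz * G3
  S4 <- act$rz * G2 + act$zz * G4
  S5 <- act$tt * G5
  Sv <- cbind(S1, S2, S3, S4, S5)
  P <- P + J * Sv
  if (!wantTangent) return(list(P = P, J = J, Fv = Fv))
  ## index maps for components (rR, rZ, zR, zZ, tT): spatial i, reference J
  iOf <- c(1L, 1L, 2L, 2L, 3L)
  JOf <- c(1L, 2L, 1L, 2L, 3L)
  zero <- numeric(nrow(P))
  Gm <- list(list(G1, G2, zero), list(G3, G4, zero),
             list(zero, zero, G5))
  Sm <- list(list(S1, S2, zero), list(S3, S4, zero),
             list(zero, zero, S5))
  A <- array(0, c(nrow(P), 5, 5))
  for (p in 1:5) for (q in 1:5) {
    ip <- iOf[p]; Jp <- JOf[p]; kq <- iOf[q]; Lq <- JOf[q]
    a <- (mu - lam * lnJ) * Gm[[ip]][[Lq]] * Gm[[kq]][[Jp]] +
      lam * Gm[[ip]][[Jp]] * Gm[[kq]][[Lq]] +
      J * (Gm[[kq]][[Lq]] * Sm[[ip]][[Jp]] -
             Sm[[ip]][[Lq]] * Gm[[kq]][[Jp]])
    if (p == q) a <- a + mu
    A[, p, q] <- a
  }
  list(P = P, A = A, J = J, Fv = Fv)
}

.internalForce <- function(mesh, B, P) {
  m <- nrow(P)
  fe <- matrix(0, m, 6)
  for (a in 1:6)
    for (p in 1:5)
      fe[, a] <- fe[, a] + B[, p, a] * P[, p]
  fe <- fe * mesh$weight
  f <- numeric(2 * mesh$nNodes)
  rs <- rowsum(as.vector(fe), as.vector(mesh$edof))
  f[as.integer(rownames(rs))] <- rs
  f
}

.stiffness <- function(mesh, B, A) {
  m <- dim(A)[1]
  T1 <- array(0, c(m, 5, 6))
  for (p in 1:5) for (b in 1:6) {
    acc <- numeric(m)
    for (q in 1:5) acc <- acc + A[, p, q] * B[, q, b]
    T1[, p, b] <- acc
  }
  Kv <- matrix(0, m, 36)
  for (a in 1:6) for (b in 1:6) {
    acc <- numeric(m)
    for (p in 1:5) acc <- acc + B[, p, a] * T1[, p, b]
    Kv[, (a - 1) * 6 + b] <- acc * mesh$weight
  }
  Matrix::sparseMatrix(i = mesh$Ki, j = mesh$Kj, x = as.vector(t(Kv)),
                       dims = rep(2 * mesh$nNodes, 2))
}

## Newton solve at fixed load; returns updated u or NULL on failure
.newton <- function(model, B, u, act, rtol = 1e-8, maxIter = 30) {
  mesh <- model@mesh
  free <- mesh$free
  st <- .stressTangent(mesh, .defGrad(mesh, u), act)
  if (is.null(st)) return(NULL)
  f <- .internalForce(mesh, B, st$P)
  ref <- max(sqrt(sum(f[free]^2)), 1e-10)
  for (it in seq_len(maxIter)) {
    rn <- sqrt(sum(f[free]^2))
    if (rn <= rtol * ref) return(u)
    K <- .stiffness(mesh, B, st$A)
    du <- tryCatch(as.numeric(Matrix::solve(K[free, free], -f[free])),
                   error = function(e) NULL)
    if (is.null(du) || anyNA(du)) return(NULL)
    ## backtracking line search on the residual norm
    step <- 1
    repeat {
      uTry <- u
      uTry[free] <- u[free] + step * du
      stTry <- .stressTangent(mesh, .defGrad(mesh, uTry), act)
      if (!is.null(stTry)) {
        fTry <- .internalForce(mesh, B, stTry$P)
        if (sqrt(sum(fTry[free]^2)) < rn || step < 0.1) break
      }
      step <- step / 2
      if (step < 1 / 64) return(NULL)
    }
    u <- uTry; st <- stTry; f <- fTry
  }
  NULL
}

## Cauchy stress components (m x 4): rr, zz, rz, tt
.cauchy <- function(mesh, u, act) {
  st <- .stressTangent(mesh, .defGrad(mesh, u), act, wantTangent = FALSE)
  P <- st$P; Fv <- st$Fv; J <- st$J
  cbind(rr = (P[, 1] * Fv[, 1] + P[, 2] * Fv[, 2]) / J,
        zz = (P[, 3] * Fv[, 3] + P[, 4] * Fv[, 4]) / J,
        rz = (P[, 1] * Fv[, 3] + P[, 2] * Fv[, 4]) / J,
        tt = P[, 5] * Fv[, 5] / J)
}

## in-plane maximum-principal-stress directions (m x 2 unit vectors)
.principalDirs <- function(sig) {
  ## 0.5 atan2(2 s_rz, s_rr - s_zz) is the angle of the major in-plane
  ## principal direction measured from the r axis
  theta <- 0.5 * atan2(2 * sig[, "rz"], sig[, "rr"] - sig[, "zz"])
  cbind(cos(theta), sin(theta))
}

.maxPrincipal <- function(sig) {
  half <- (sig[, "rr"] - sig[, "zz"]) / 2
  inplane <- (sig[, "rr"] + sig[, "zz"]) / 2 + sqrt(half^2 + sig[, "rz"]^2)
  pmax(inplane, sig[, "tt"])
}

.makeSolution <- function(model, u, act, loadFactor = 1, converged = TRUE) {
  mesh <- model@mesh
  sig <- .cauchy(mesh, u, act)
  U <- cbind(r = u[seq(1, 2 * mesh$nNodes, 2)],
             z = u[seq(2, 2 * mesh$nNodes, 2)])
  nucEl <- mesh$region %in% c("nucleoplasm", "lamina")
  nucNodes <- unique(as.vector(mesh$tri[nucEl, ]))
  def <- mesh$nodes + U
  len <- 2 * max(def[nucNodes, 2])
  wid <- 2 * max(def[nucNodes, 1])
  Fc <- .defGrad(mesh, u)
  J <- (Fc$F1 * Fc$F4 - Fc$F2 * Fc$F3) * Fc$F5
  dV <- 100 * (sum(mesh$weight[nucEl] * J[nucEl]) /
                 sum(mesh$weight[nucEl]) - 1)
  lamEl <- which(mesh$region == "lamina")
  mp <- .maxPrincipal(sig[lamEl, , drop = FALSE])
  best <- lamEl[which.max(mp)]
  sArc <- atan2(mesh$centroid[best, 2], mesh$centroid[best, 1]) / (pi / 2)
  new("MechSolution", model = model, U = U, stress = sig,
      nuclearAspectRatio = len / wid, nuclearVolumeChange = dV,
      probes = .probeValues(model, sig),
      laminaStressLocation = sArc, tipInstability = sArc > 0.8,
      converged = converged, loadFactor = loadFactor)
}

## element-averaged axial stresses at the four named probe sites; the
## myofibril probes average the 3 um of contractile material nearest the
## cage tips, the microtubule probes the cage within 1 um of the nucleus
.probeValues <- function(model, sig, window = 3) {
  mesh <- model@mesh
  g <- model@geometry
  cen <- mesh$centroid
  w <- mesh$weight
  cyto <- mesh$region == "cytoplasm"
  cage <- mesh$region == "cage"
  avg <- function(sel, comp) {
    if (!any(sel)) return(NA_real_)
    sum(sig[sel, comp] * w[sel]) / sum(w[sel])
  }
  ## myofibril probes sit just outside the myofibril void, i.e. in the
  ## nearest contractile material to the cage tips
  vs <- model@active$voidScale
  ax <- g$cageSemiAxes * if (!is.null(vs) && vs > 0) vs else 1
  shortTip <- cyto & cen[, 2] < 1 & cen[, 1] > ax[1] &
    cen[, 1] < ax[1] + window
  longTip <- cyto & cen[, 1] < 1 & cen[, 2] > ax[2] &
    cen[, 2] < ax[2] + window
  nucLong <- cage & cen[, 1] < 1 & cen[, 2] > g$nucleusRadius &
    cen[, 2] < g$nucleusRadius + 1
  nucShort <- cage & cen[, 2] < 1 & cen[, 1] > g$nucleusRadius
  c(myofibril_tension_cage_short_tip = avg(shortTip, "zz"),
    myofibril_tension_cage_long_tip = avg(longTip, "zz"),
    mt_axial_compression_nucleus_long_tip = -avg(nucLong, "zz"),
    mt_axial_compression_nucleus_short_tip = -avg(nucShort, "zz"))
}

#' Solve a quasi-static active-stress loading schedule
#'
#' Ramps the active loads through the legs of a schedule with Newton
#' iteration at every increment (relative residual 1e-8) and automatic step
#' halving on non-convergence. Each leg interpolates linearly from the
#' previous load state to its target \code{c(rhoIso, rhoPol, sigmaMT)}.
#' When a leg first activates the polarized contractility, the fibre
#' directions are frozen from the maximum-principal-stress field of the
#' current state.
#'
#' @param model a \linkS4class{MechModel}.
#' @param legs list of lists with fields \code{target} (length-3 numeric)
#'   and \code{nSteps}.
#' @param u optional initial displacement vector.
#' @param polarDirs optional fibre directions (m x 2), normally computed
#'   internally.
#' @param keep "final" or "legs" (one solution per leg end).
#' @return A \linkS4class{MechSolution} or list of them; on failure the last
#'   converged state is attached to the error condition.
#' @export
solveSchedule <- function(model, legs, u = NULL, polarDirs = NULL,
                          keep = c("final", "legs")) {
  keep <- match.arg(keep)
  stopifnot(is(model, "MechModel"))
  mesh <- model@mesh
  B <- .buildB(mesh)
  if (is.null(u)) u <- numeric(2 * mesh$nNodes)
  cur <- c(0, 0, 0)
  out <- list()
  legIdx <- 0
  for (leg in legs) {
    legIdx <- legIdx + 1
    tgt <- leg$target
    if (tgt[2] > 0 && is.null(polarDirs)) {
      sig <- .cauchy(mesh, u, do.call(.activeStress,
        c(list(model), as.list(cur), list(n = NULL))))
      polarDirs <- .principalDirs(sig)
    }
    ## adaptive incrementation within the leg
    sDone <- 0
    ds <- 1 / leg$nSteps
    fails <- 0
    while (sDone < 1 - 1e-12) {
      s <- min(sDone + ds, 1)
      load <- cur + s * (tgt - cur)
      act <- .activeStress(model, load[1], load[2], load[3], polarDirs)
      uNew <- .newton(model, B, u, act)
      if (is.null(uNew)) {
        ds <- ds / 2
        fails <- fails + 1
        if (fails > 8) {
          cond <- simpleError(sprintf(
            "solver failed in leg %d at load fraction %.3f (target %s) after step halving",
            legIdx, sDone, paste(signif(tgt, 3), collapse = "/")))
          cond$lastState <- list(u = u, load = cur + sDone * (tgt - cur))
          stop(cond)
        }
        next
      }
      u <- uNew
      sDone <- s
    }
    cur <- tgt
    if (keep == "legs") {
      act <- .activeStress(model, cur[1], cur[2], cur[3], polarDirs)
      out[[length(out) + 1]] <- .makeSolution(model, u, act)
    }
  }
  act <- .activeStress(model, cur[1], cur[2], cur[3], polarDirs)
  final <- .makeSolution(model, u, act)
  if (keep == "legs") out else final
}

#' Probe stresses of a converged solution
#'
#' Element-averaged axial Cauchy stresses at the four named sites: the
#' myofibril tension just outside the cage short (equatorial) and long
#' (axial) tips, and the microtubule axial compression in the cage at the
#' nucleus long and short tips; plus the normalized arc location of the
#' maximum principal stress on the lamina (0 = equator, 1 = tip).
#'
#' @param solution a \linkS4class{MechSolution}.
#' @return list with \code{probes} (named numeric, kPa) and
#'   \code{laminaStressLocation}.
#' @export
probeStresses <- function(solution) {
  stopifnot(is(solution, "MechSolution"))
  list(probes = solution@probes,
       laminaStressLocation = solution@laminaStressLocation)
}
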