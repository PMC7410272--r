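# Newton-Euler intersegmental loads at the bone-implant interface.
#
# With a locked elbow the whole distal chain is one rigid body: every segment
# shares the angular velocity/acceleration of the humerus. The interface force
# is F = sum_i m_i (a_i - g) over all bodies distal to the plane (handheld
# point mass included) and the interface moment about the interface point p is
# M = sum_i [(r_i - p) x m_i (a_i - g) + I_i alpha + omega x I_i omega].
# Loads are resolved against the humeral long-axis unit vector u (pointing
# proximally) into axial force F.u (tensile positive), torsion |M.u| and
# bending |M - (M.u)u|.

GRAVITY <- c(0, 0, -9.81)

# Body-frame geometry of the distal chain for a locked elbow angle.
# Body frame: distal humeral direction (0,0,-1); elbow flexion rotates the
# forearm branch about the body x axis.
chain_geometry <- function(model, elbow_flexion) {
  segs <- distal_segments(model)
  d_hum <- c(0, 0, -1)
  d_fa <- c(0, sin(elbow_flexion), -cos(elbow_flexion))
  elbow <- model$upper_arm_length * d_hum
  k <- nrow(segs)
  coms <- matrix(0, k, 3)
  axes <- matrix(0, k, 3)
  for (i in seq_len(k)) {
    s <- segs[i, ]
    arc <- s$attach + s$com_offset * s$length
    if (s$branch == "humerus") {
      coms[i, ] <- arc * d_hum
      axes[i, ] <- d_hum
    } else {
      coms[i, ] <- elbow + arc * d_fa
      axes[i, ] <- d_fa
    }
  }
  hand <- which(segs$role == "hand")
  handheld_point <- if (length(hand)) {
    coms[hand[1], ] + model$handheld_offset * d_fa
  } else {
    elbow
  }
  list(segments = segs, coms = coms, axes = axes,
       interface = model$interface_position * d_hum,
       handheld_point = handheld_point)
}

cylinder_inertia <- function(mass, length, radius) {
  c(transverse = mass * (3 * radius^2 + length^2) / 12,
    axial = mass * radius^2 / 2)
}

#' Differentiate a motion trial into a kinematic state
#'
#' Computes, per sample, the world positions and accelerations of every
#' segment COM distal to the interface plane (forward kinematics from the
#' humerus pose and the locked elbow angle), the angular velocity and
#' acceleration of the rigid distal chain, the proximally-pointing humeral
#' long-axis direction and the interface point. Pose signals (shoulder
#' position and quaternion components, sign-continuous and renormalized) are
#' zero-phase low-pass filtered before central differencing. Angular velocity
#' comes from the quaternion derivative (`omega = 2 qdot q*`), angular
#' acceleration from differencing omega, and COM accelerations from the rigid
#' body relation `a = a_shoulder + (skew(alpha) + skew(omega)^2) R c`, so the
#' whole kinematic state is self-consistent.
#'
#' @param trial a [motion_trial()].
#' @param model a `limb_model` with an interface plane.
#' @param filter_cutoff low-pass cutoff, Hz (default 6; `Inf` disables).
#' @return object of class `kinematic_state`.
#' @export
differentiate_poses <- function(trial, model, filter_cutoff = 6) {
  stopifnot(inherits(trial, "motion_trial"), inherits(model, "limb_model"))
  n <- nrow(trial$position)
  if (n < 5) stop("trial too short: need at least 5 samples", call. = FALSE)
  dt <- diff(trial$time)
  if (max(abs(dt - dt[1])) > 1e-9 * dt[1] + 1e-12) {
    stop("trial must be uniformly sampled", call. = FALSE)
  }
  dt <- dt[1]
  fs <- 1 / dt

  q <- quat_normalize(trial$quaternion)
  # enforce sign continuity before filtering (q and -q are the same rotation)
  flips <- cumsum(c(FALSE, rowSums(q[-1, , drop = FALSE] *
                                     q[-n, , drop = FALSE]) < 0)) %% 2
  q <- q * (1 - 2 * flips)
  pf <- filter_lowpass(trial$position, filter_cutoff, fs)
  qf <- quat_normalize(filter_lowpass(q, filter_cutoff, fs))
  Rf <- quat_to_rotmat9(qf)

  a_sh <- fdiff2(pf, dt)

  # omega from the quaternion derivative: omega = 2 * vec(qdot x q*)
  qd <- fdiff(qf, dt)
  qconj <- cbind(qf[, 1], -qf[, 2], -qf[, 3], -qf[, 4])
  omega <- 2 * quat_multiply(qd, qconj)[, 2:4, drop = FALSE]
  alpha <- fdiff(omega, dt)

  # rigid-body-consistent rotational acceleration:
  # Rdd = (skew(alpha) + skew(omega)^2) R
  wx <- omega[, 1]; wy <- omega[, 2]; wz <- omega[, 3]
  ax <- alpha[, 1]; ay <- alpha[, 2]; az <- alpha[, 3]
  w2 <- wx^2 + wy^2 + wz^2
  B <- cbind(wx * wx - w2, wx * wy - az, wx * wz + ay,
             wx * wy + az, wy * wy - w2, wy * wz - ax,
             wx * wz - ay, wy * wz + ax, wz * wz - w2)
  Rdd <- cbind(
    B[, 1] * Rf[, 1] + B[, 2] * Rf[, 4] + B[, 3] * Rf[, 7],
    B[, 1] * Rf[, 2] + B[, 2] * Rf[, 5] + B[, 3] * Rf[, 8],
    B[, 1] * Rf[, 3] + B[, 2] * Rf[, 6] + B[, 3] * Rf[, 9],
    B[, 4] * Rf[, 1] + B[, 5] * Rf[, 4] + B[, 6] * Rf[, 7],
    B[, 4] * Rf[, 2] + B[, 5] * Rf[, 5] + B[, 6] * Rf[, 8],
    B[, 4] * Rf[, 3] + B[, 5] * Rf[, 6] + B[, 6] * Rf[, 9],
    B[, 7] * Rf[, 1] + B[, 8] * Rf[, 4] + B[, 9] * Rf[, 7],
    B[, 7] * Rf[, 2] + B[, 8] * Rf[, 5] + B[, 9] * Rf[, 8],
    B[, 7] * Rf[, 3] + B[, 8] * Rf[, 6] + B[, 9] * Rf[, 9])

  u_hat <- cbind(Rf[, 3], Rf[, 6], Rf[, 9])

  geom <- chain_geometry(model, trial$elbow_flexion)
  segs <- geom$segments
  seg_kin <- lapply(seq_len(nrow(segs)), function(i) {
    cb <- geom$coms[i, ]
    inr <- cylinder_inertia(segs$mass[i], segs$length[i],
                            segs$transverse_radius[i])
    list(name = segs$name[i], mass = segs$mass[i],
         com_body = cb, axis_body = geom$axes[i, ],
         length = segs$length[i], com_offset = segs$com_offset[i],
         It = inr[["transverse"]], Ia = inr[["axial"]],
         pos = pf + rotmat9_apply(Rf, cb),
         acc = a_sh + rotmat9_apply(Rdd, cb),
         axis = rotmat9_apply(Rf, geom$axes[i, ]))
  })

  structure(
    list(time = trial$time, dt = dt, n = n,
         p_sh = pf, R9 = Rf, a_sh = a_sh, Rdd = Rdd,
         omega = omega, alpha = alpha, u_hat = u_hat,
         p_interface = pf + rotmat9_apply(Rf, geom$interface),
         segments = seg_kin,
         handheld_body = geom$handheld_point,
         handheld_pos = pf + rotmat9_apply(Rf, geom$handheld_point),
         handheld_acc = a_sh + rotmat9_apply(Rdd, geom$handheld_point),
         handheld_mass = trial$handheld_mass,
         elbow_flexion = trial$elbow_flexion,
         filter_cutoff = filter_cutoff),
    class = "kinematic_state"
  )
}

#' Resolve interface loads into bending, torsion and axial components
#'
#' @param F n x 3 force matrix (N), global frame.
#' @param M n x 3 moment matrix (N.m) about the interface point.
#' @param u_hat n x 3 (or length-3) unit humeral long-axis direction pointing
#'   proximally.
#' @return data.frame with columns `bending` (N.m, >= 0), `torsion`
#'   (N.m, >= 0) and `axial` (N, tensile/pullout positive).
#' @export
resolve_components <- function(F, M, u_hat) {
  F <- rbind(F); M <- rbind(M)
  if (is.null(dim(u_hat)) || nrow(rbind(u_hat)) == 1L) {
    u_hat <- matrix(u_hat, nrow(F), 3, byrow = TRUE)
  }
  nrm <- sqrt(rowSums(u_hat^2))
  if (any(abs(nrm - 1) > 1e-6)) {
    stop("`u_hat` must be unit length", call. = FALSE)
  }
  axial <- rowdot(F, u_hat)
  Mu <- rowdot(M, u_hat)
  bending <- sqrt(pmax(0, rowSums(M^2) - Mu^2))
  data.frame(bending = bending, torsion = abs(Mu), axial = axial)
}

load_series_frame <- function(time, F, M, res) {
  structure(
    data.frame(time = time,
               Fx = F[, 1], Fy = F[, 2], Fz = F[, 3],
               Mx = M[, 1], My = M[, 2], Mz = M[, 3],
               bending = res$bending, torsion = res$torsion,
               axial = res$axial),
    class = c("load_series", "data.frame")
  )
}

#' Interface force and moment series
#'
#' Newton-Euler summation over every body distal to the interface plane,
#' with gravity and the handheld point mass, expressed in the global frame
#' and resolved per sample against the humeral long axis.
#'
#' @param model the `limb_model` used to build `kin`.
#' @param kin a `kinematic_state` from [differentiate_poses()].
#' @param handheld_mass kg; defaults to the trial's value captured in `kin`.
#' @param gravity gravity vector, m/s^2.
#' @return a `load_series` data.frame: `time, Fx..Mz, bending, torsion, axial`.
#' @export
interface_loads <- function(model, kin, handheld_mass = kin$handheld_mass,
                            gravity = GRAVITY) {
  stopifnot(inherits(kin, "kinematic_state"))
  n <- kin$n
  g <- matrix(gravity, n, 3, byrow = TRUE)
  F <- matrix(0, n, 3)
  M <- matrix(0, n, 3)
  p <- kin$p_interface
  om <- kin$omega; al <- kin$alpha
  for (s in kin$segments) {
    if (anyNA(s$acc)) {
      stop("NaN in kinematics at sample ",
           which(rowSums(is.na(s$acc)) > 0)[1], call. = FALSE)
    }
    f <- s$mass * (s$acc - g)
    F <- F + f
    M <- M + cross3(s$pos - p, f)
    if (s$It > 0 || s$Ia > 0) {
      a_dot <- rowdot(al, s$axis)
      w_dot <- rowdot(om, s$axis)
      M <- M + s$It * al + (s$Ia - s$It) * (a_dot * s$axis) +
        (s$Ia - s$It) * (w_dot * cross3(om, s$axis))
    }
  }
  if (handheld_mass > 0) {
    f <- handheld_mass * (kin$handheld_acc - g)
    F <- F + f
    M <- M + cross3(kin$handheld_pos - p, f)
  }
  load_series_frame(kin$time, F, M, resolve_components(F, M, kin$u_hat))
}

#' Brute-force point-mass oracle for interface loads
#'
#' Independent recomputation of the interface force and moment by
#' discretizing every distal segment into `n_points` point masses distributed
#' uniformly along the segment axis, centred on the segment COM, and summing
#' `m (a - g)` and `(r - p) x m (a - g)` per point -- no inertia tensors. A
#' line discretization reproduces the rod (zero transverse radius) inertia
#' model in the limit, with an O(1/n^2) discretization error in the
#' length-wise second moment.
#'
#' @inheritParams interface_loads
#' @param n_points points per segment (>= 10).
#' @return a `load_series` data.frame.
#' @export
point_mass_oracle <- function(model, kin, n_points = 100,
                              handheld_mass = kin$handheld_mass,
                              gravity = GRAVITY) {
  stopifnot(inherits(kin, "kinematic_state"), n_points >= 10)
  n <- kin$n
  g <- matrix(gravity, n, 3, byrow = TRUE)
  F <- matrix(0, n, 3)
  M <- matrix(0, n, 3)
  p <- kin$p_interface
  for (s in kin$segments) {
    if (s$length > 0 && s$mass > 0) {
      u <- (seq_len(n_points) - 0.5) / n_points - 0.5
      offs <- u * s$length
      mj <- s$mass / n_points
      for (o in offs) {
        cj <- s$com_body + o * s$axis_body
        rj <- kin$p_sh + rotmat9_apply(kin$R9, cj)
        aj <- kin$a_sh + rotmat9_apply(kin$Rdd, cj)
        fj <- mj * (aj - g)
        F <- F + fj
        M <- M + cross3(rj - p, fj)
      }
    } else if (s$mass > 0) {
      rj <- kin$p_sh + rotmat9_apply(kin$R9, s$com_body)
      aj <- kin$a_sh + rotmat9_apply(kin$Rdd, s$com_body)
      fj <- s$mass * (aj - g)
      F <- F + fj
      M <- M + cross3(rj - p, fj)
    }
  }
  if (handheld_mass > 0) {
    fj <- handheld_mass * (kin$handheld_acc - g)
    F <- F + fj
    M <- M + cross3(kin$handheld_pos - p, fj)
  }
  load_series_frame(kin$time, F, M, resolve_components(F, M, kin$u_hat))
}

#' Export a load series to CSV
#'
#' Full-precision CSV with columns
#' `time, Fx, Fy, Fz, Mx, My, Mz, bending, torsion, axial`.
#' @param loads a `load_series`.
#' @param path file path.
#' @export
write_loads_csv <- function(loads, path) {
  utils::write.csv(format(as.data.frame(loads), digits = 17, trim = TRUE,
                          scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
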