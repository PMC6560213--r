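# Independent isochromat Bloch-ensemble oracle for flow-free EPG signals:
# nspin spins with uniform intravoxel dephasing phases, full 3x3
# right-handed rotations about the in-plane RF axis, exponential
# relaxation, one unit of gradient dephasing per repetition.
iso_simulate <- function(design, T1, T2, nspin = 256) {
  ph <- 2 * pi * (seq_len(nspin) - 0.5) / nspin
  M <- matrix(rep(c(0, 0, 1), each = nspin), nspin, 3)
  rot <- function(M, a, p = 0) {
    ca <- cos(a); sa <- sin(a); cp <- cos(p); sp <- sin(p)
    R <- rbind(c(ca + (1 - ca) * cp^2, (1 - ca) * cp * sp,  sa * sp),
               c((1 - ca) * cp * sp,   ca + (1 - ca) * sp^2, -sa * cp),
               c(-sa * sp,             sa * cp,              ca))
    M %*% t(R)
  }
  relax <- function(M, dt) {
    e1 <- exp(-dt / T1); e2 <- exp(-dt / T2)
    M[, 1:2] <- M[, 1:2] * e2
    M[, 3] <- M[, 3] * e1 + (1 - e1)
    M
  }
  if (design$invert) M <- rot(M, pi)
  s <- complex(design$N)
  for (t in seq_len(design$N)) {
    M <- rot(M, design$flip_deg[t] * pi / 180, design$phase_deg[t] * pi / 180)
    M <- relax(M, design$TE)
    s[t] <- mean(complex(real = M[, 1], imaginary = M[, 2]))
    M <- relax(M, design$TR - design$TE)
    z <- complex(real = M[, 1], imaginary = M[, 2]) * exp(1i * ph)
    M[, 1] <- Re(z); M[, 2] <- Im(z)
  }
  s
}

rel_l2 <- function(a, b) sqrt(sum(Mod(a - b)^2) / sum(Mod(b)^2))

random_design <- function(N, invert = TRUE, phases = FALSE) {
  acquisition_design(runif(N, 1, 85), TR = 14, TE = 2, d = 2,
                     invert = invert,
                     phase_deg = if (phases) runif(N, 0, 360) else 0)
}

small_prior <- function() tissue_class_prior()
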