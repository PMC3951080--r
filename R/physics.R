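# Charged-particle physics: collision stopping power, CSDA range,
# multiple-scattering and energy-straggling widths, and the tabulated form
# consumed by the transport core.
#
# Protons: Bethe collision formula without shell or density corrections,
# adequate over the 1-300 MeV band used here (SPE protons are 20-80 MeV).
# Electrons: Berger-Seltzer collision term (Moller scattering on atomic
# electrons); radiative losses are modeled as E_total / X0 and removed from
# the particle but never deposited (photon transport is out of scope).

.MEC2 <- 0.51099895    # electron rest energy, MeV
.MPC2 <- 938.2720882   # proton rest energy, MeV
.K_BETHE <- 0.307075   # 4 pi N_A r_e^2 m_e c^2, MeV cm^2 / mol
.BOHR_K <- 0.1569      # Bohr straggling constant, MeV^2 cm^2 / g (z = 1)

.particle_mass <- function(particle) {
  switch(particle, proton = .MPC2, electron = .MEC2,
         stop("unknown particle: ", particle))
}

# tabulation floors (MeV); the declared validity floor for the proton Bethe
# formula is 1 MeV (= the transport cutoff), tables extend a little below
.energy_floor <- function(particle) {
  switch(particle, proton = 0.1, electron = 0.01)
}

.kinematics <- function(particle, energy) {
  M <- .particle_mass(particle)
  tau <- energy / M
  gamma <- 1 + tau
  beta2 <- 1 - 1 / gamma^2
  b2g2 <- tau * (tau + 2)           # beta^2 gamma^2
  pc <- sqrt(energy * (energy + 2 * M))
  list(M = M, tau = tau, gamma = gamma, beta2 = beta2, b2g2 = b2g2, pc = pc)
}

# mass collision stopping power, MeV cm^2 / g
.mass_stopping_power <- function(mat, particle, energy) {
  k <- .kinematics(particle, energy)
  I <- mat$I_eV * 1e-6  # MeV
  if (particle == "proton") {
    arg <- 2 * .MEC2 * k$b2g2 / I
    s <- .K_BETHE * mat$Z_over_A / k$beta2 * (log(arg) - k$beta2)
  } else {
    tau <- k$tau
    Fm <- 1 - k$beta2 +
      (tau^2 / 8 - (2 * tau + 1) * log(2)) / (tau + 1)^2
    s <- 0.5 * .K_BETHE * mat$Z_over_A / k$beta2 *
      (log(tau^2 * (tau + 2) / (2 * (I / .MEC2)^2)) + Fm)
  }
  pmax(s, 1e-12)  # clamp: formula can turn over below the validity floor
}

#' Collision stopping power
#'
#' Linear collision stopping power of a proton or electron in a material,
#' in MeV/cm.  Protons use the Bethe formula without shell or density
#' corrections; electrons use the Berger-Seltzer collision term.  Scales
#' exactly linearly with density at fixed composition.
#'
#' @param material a `material`.
#' @param particle `"proton"` or `"electron"`.
#' @param energy kinetic energy in MeV (vectorized); must exceed the
#'   validity floor (0.05 MeV protons, 0.005 MeV electrons).
#' @return stopping power in MeV/cm, same length as `energy`.
#' @export
collision_stopping_power <- function(material, particle = c("proton", "electron"),
                                     energy) {
  particle <- match.arg(particle)
  if (any(!is.finite(energy)) || any(energy <= 0))
    stop("energy must be positive and finite")
  floor_e <- .energy_floor(particle) / 2
  if (any(energy < floor_e))
    stop("energy below the validity floor (", floor_e, " MeV) for ", particle)
  .mass_stopping_power(material, particle, energy) * material$density
}

# radiative mass stopping power for electrons, MeV cm^2/g (complete
# screening approximation: total energy / radiation length)
.mass_radiative_stopping_power <- function(mat, energy) {
  (energy + .MEC2) / mat$X0
}

# adaptive trapezoid with interval bisection to a relative tolerance
.adaptive_trapezoid <- function(f, a, b, rtol = 1e-4, max_depth = 30) {
  rec <- function(a, b, fa, fb, whole, depth) {
    m <- (a + b) / 2
    fm <- f(m)
    left <- (fa + fm) * (m - a) / 2
    right <- (fm + fb) * (b - m) / 2
    if (depth <= 0 ||
        abs(left + right - whole) <= rtol * abs(left + right) + 1e-300)
      return(left + right)
    rec(a, m, fa, fm, left, depth - 1) + rec(m, b, fm, fb, right, depth - 1)
  }
  fa <- f(a); fb <- f(b)
  rec(a, b, fa, fb, (fa + fb) * (b - a) / 2, max_depth)
}

#' CSDA range
#'
#' Continuous-slowing-down-approximation range: the integral of the
#' reciprocal collision stopping power from the tabulation floor up to the
#' given kinetic energy, by adaptive trapezoid quadrature (relative
#' tolerance 1e-4).  Strictly increasing in energy.
#'
#' @inheritParams collision_stopping_power
#' @param energy kinetic energy in MeV (vectorized, >= 0).
#' @return range in cm.
#' @export
csda_range <- function(material, particle = c("proton", "electron"), energy) {
  particle <- match.arg(particle)
  if (any(!is.finite(energy)) || any(energy < 0))
    stop("energy must be >= 0 and finite")
  e0 <- .energy_floor(particle)
  vapply(energy, function(E) {
    if (E <= e0) return(0)
    .adaptive_trapezoid(
      function(e) 1 / .mass_stopping_power(material, particle, e),
      e0, E, rtol = 1e-4) / material$density
  }, numeric(1))
}

#' Multiple-scattering angular width (Highland)
#'
#' Standard deviation of the projected scattering angle accumulated over a
#' condensed-history step, from the Highland parameterization
#' sigma = 13.6 MeV / (beta c p) * sqrt(t) * (1 + 0.038 ln t), with
#' t = step * rho / X0 the step thickness in radiation lengths.  The
#' logarithmic bracket is clamped at 0.25 so sigma stays real and monotone
#' for very thin steps; sigma -> 0 as step -> 0 through sqrt(t).
#'
#' @inheritParams collision_stopping_power
#' @param energy kinetic energy in MeV.
#' @param step step length in cm (> 0).
#' @return sigma in radians.
#' @export
scattering_sigma <- function(material, particle = c("proton", "electron"),
                             energy, step) {
  particle <- match.arg(particle)
  if (any(step <= 0)) stop("step must be > 0")
  k <- .kinematics(particle, energy)
  t <- step * material$density / material$X0
  bracket <- pmax(1 + 0.038 * log(t), 0.25)
  13.6 / (sqrt(k$beta2) * k$pc) * sqrt(t) * bracket
}

#' Energy-loss straggling width (Bohr)
#'
#' Gaussian energy-loss straggling over a step:
#' sigma_E^2 = 0.1569 (Z/A) rho step  (MeV^2, unit charge), so sigma_E
#' grows like sqrt(step).  A Gaussian model is adequate for the many-
#' collision condensed-history steps used here; Landau/Vavilov tails are
#' out of scope.
#'
#' @inheritParams scattering_sigma
#' @return sigma_E in MeV.
#' @export
straggling_sigma <- function(material, particle = c("proton", "electron"),
                             energy, step) {
  particle <- match.arg(particle)
  if (any(step <= 0)) stop("step must be > 0")
  sqrt(.BOHR_K * material$Z_over_A * material$density * step)
}

# ---------------------------------------------------------------------------
# Tabulated physics for the transport core.
#
# Per material and particle: mass collision stopping power (MeV cm^2/g) and
# mass CSDA range (g/cm^2) on a shared log-energy grid of 200 knots,
# interpolated log-log in the core.  Ranges are accumulated by trapezoid on
# a 10x refined grid.  Tables are cached per (material, particle).

.N_KNOTS <- 200

.table_emax <- function(particle) switch(particle, proton = 300, electron = 100)

physics_table_1mat <- function(mat, particle) {
  e0 <- .energy_floor(particle)
  emax <- .table_emax(particle)
  loge <- seq(log(e0), log(emax), length.out = .N_KNOTS)
  # refined grid for the range integral
  logf <- seq(log(e0), log(emax), length.out = 10 * .N_KNOTS)
  ef <- exp(logf)
  sf <- .mass_stopping_power(mat, particle, ef)
  inv <- 1 / sf
  dr <- diff(ef) * (inv[-1] + inv[-length(inv)]) / 2
  rf <- c(0, cumsum(dr)) + e0 * inv[1]  # below-floor remainder, linear S
  r_knots <- exp(approx(logf, log(rf), xout = loge)$y)
  s_knots <- .mass_stopping_power(mat, particle, exp(loge))
  srad <- if (particle == "electron")
    .mass_radiative_stopping_power(mat, exp(loge)) else rep(0, .N_KNOTS)
  list(loge = loge, logS = log(s_knots), logR = log(r_knots),
       logSrad = log(pmax(srad, 1e-300)))
}

# Assemble the table bundle for a grid's material set; cached in the
# package environment keyed by material names + particle.
physics_tables <- function(material_names, particle,
                           materials = material_library()) {
  key <- paste(particle, paste(material_names, collapse = "|"), sep = "::")
  if (!is.null(.voxdose_env$phys_cache[[key]]))
    return(.voxdose_env$phys_cache[[key]])
  mats <- lapply(material_names, function(nm) {
    if (!nm %in% names(materials)) stop("unknown material: ", nm)
    materials[[nm]]
  })
  tabs <- lapply(mats, physics_table_1mat, particle = particle)
  bundle <- list(
    loge = tabs[[1]]$loge,
    logS = vapply(tabs, `[[`, numeric(.N_KNOTS), "logS"),
    logR = vapply(tabs, `[[`, numeric(.N_KNOTS), "logR"),
    logSrad = vapply(tabs, `[[`, numeric(.N_KNOTS), "logSrad"),
    Z_over_A = vapply(mats, `[[`, numeric(1), "Z_over_A"),
    X0 = vapply(mats, `[[`, numeric(1), "X0"),
    ref_density = vapply(mats, `[[`, numeric(1), "density"),
    particle = particle, materials = material_names)
  if (is.null(.voxdose_env$phys_cache)) .voxdose_env$phys_cache <- list()
  .voxdose_env$phys_cache[[key]] <- bundle
  bundle
}
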