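#' Strength-duration activation of afferent fibers
#'
#' The amount of peripheral activation produced by a square pulse of
#' amplitude `A` and width `PW` in a fiber with membrane time constant
#' `tau1` is `f_A = A * (1 - exp(-PW / tau1))`. For long pulses `f_A`
#' saturates to the rheobase level `A`; for short pulses it scales roughly
#' with the delivered charge.
#'
#' @param A Amplitude in mA (vectorised, `>= 0`).
#' @param PW Pulse width in ms (`> 0`).
#' @param tau1 Fiber time constant in ms (`> 0`).
#' @return Activation `f_A` in mA, same length as the recycled inputs.
#' @export
#' @examples
#' fiber_activation(A = 1, PW = 0.42, tau1 = 0.1)
fiber_activation <- function(A, PW, tau1) {
  if (any(PW <= 0)) abort("PW must be > 0")
  if (any(tau1 <= 0)) abort("tau1 must be > 0")
  if (any(A < 0)) abort("A must be >= 0")
  A * (1 - exp(-PW / tau1))
}

#' Threshold-linear recruitment of afferent drive
#'
#' Converts peripheral activation into the recruited synaptic drive through
#' the threshold-linear map `[z]_+ = pi * z * H(z)` applied to
#' `f_A - alpha1`. The factor `pi` is part of the definition (it is
#' inherited from the area of the recruited disc of nerve endings in the
#' physical layer); omitting it would silently rescale `alpha2`, `sigma`,
#' `alphaL` and `sigmaL` by `pi`.
#'
#' @param f_A Peripheral activation in mA (vectorised, `>= 0`).
#' @param alpha1 Activation threshold in mA (`> 0`).
#' @return Recruited drive `pi * (f_A - alpha1)` where positive, else 0.
#' @export
#' @examples
#' recruitment(fiber_activation(1, 0.42, 0.1), alpha1 = 0.5)
recruitment <- function(f_A, alpha1) {
  if (any(alpha1 <= 0)) abort("alpha1 must be > 0")
  z <- f_A - alpha1
  pi * z * (z > 0)
}

#' Physical-layer parameters of peripheral recruitment
#'
#' The physical quantities behind the lumped peripheral layer: skin
#' conductivity `c0`, nerve-ending resistance per unit length `c1` (the
#' product `c = c0 * c1` is what enters the equations), nerve-ending
#' capacitance `C1` and conductance `G1`, firing threshold `Vth` (volts),
#' areal density of nerve endings `rho`, and the minimal ending depth `h`.
#' All quantities must be positive; any consistent unit system works as
#' long as `h` and distances `r` share a length unit.
#'
#' @param c0,c1,C1,G1,Vth,rho,h Strictly positive scalars, see description.
#' @return An object of class `physical_params`.
#' @export
#' @examples
#' physical_params(c0 = 1, c1 = 1, C1 = 0.1, G1 = 1, Vth = 1 / (4 * pi), rho = 2, h = 0.3)
physical_params <- function(c0, c1, C1, G1, Vth, rho, h) {
  vals <- list(c0 = c0, c1 = c1, C1 = C1, G1 = G1, Vth = Vth, rho = rho, h = h)
  for (nm in names(vals)) check_pos(vals[[nm]], nm)
  structure(vals, class = "physical_params")
}

#' Peak membrane potential of a nerve ending at distance r
#'
#' Closed-form maximum over the pulse of the leaky-integrator membrane
#' potential of a nerve ending at distance `r` from the point-source
#' electrode: `V_m(r) = G1^-1 A (1 - exp(-PW / (C1/G1))) / (4 pi c r^2)`
#' with `c = c0 * c1`. Monotone decreasing in `r` (inverse-square).
#'
#' @param r Distance from the electrode (`> 0`, vectorised).
#' @param A Amplitude in mA.
#' @param PW Pulse width in ms.
#' @param phys A [physical_params()] object.
#' @return Peak potential `V_m(r)` in volts.
#' @export
membrane_peak <- function(r, A, PW, phys) {
  stopifnot(inherits(phys, "physical_params"))
  if (any(r <= 0)) abort("r must be > 0 (point-source singularity at r = 0)")
  cc <- phys$c0 * phys$c1
  tau1 <- phys$C1 / phys$G1
  (A / phys$G1) * (1 - exp(-PW / tau1)) / (4 * pi * cc * r^2)
}

#' Critical recruitment radius
#'
#' The distance at which the peak membrane potential equals the firing
#' threshold: endings closer than `r_c` spike, endings further away do not.
#' Scales with the square root of the amplitude.
#'
#' @inheritParams membrane_peak
#' @return Critical radius `r_c` (same length unit as `phys$h`).
#' @export
critical_radius <- function(A, PW, phys) {
  stopifnot(inherits(phys, "physical_params"))
  if (any(A < 0)) abort("A must be >= 0")
  cc <- phys$c0 * phys$c1
  tau1 <- phys$C1 / phys$G1
  sqrt((A / phys$G1) * (1 - exp(-PW / tau1)) / (4 * pi * cc * phys$Vth))
}

#' Number of recruited nerve endings
#'
#' Continuous approximation of the number of nerve endings recruited within
#' the critical radius, given a homogeneous areal density `rho` and a
#' minimal depth `h`: `N_r = pi * rho * (r_c^2 - h^2)` when `r_c >= h`,
#' else 0. The integer count is deliberately approximated by this
#' continuous quantity.
#'
#' @param r_c Critical radius (vectorised, `>= 0`).
#' @param rho Areal density of nerve endings (`> 0`).
#' @param h Minimal ending depth (`> 0`).
#' @return Continuous recruited count `N_r >= 0`.
#' @export
recruited_count <- function(r_c, rho, h) {
  check_pos(rho, "rho"); check_pos(h, "h")
  pi * rho * (r_c^2 - h^2) * (r_c >= h)
}

#' Lumped peripheral parameters implied by the physical layer
#'
#' Collapses the physical recruitment geometry into the lumped peripheral
#' parameters: `alpha1 = 4 pi c G1 Vth h^2`, `tau1 = C1 / G1` and the
#' peripheral gain `kappa = rho / (4 pi c G1 Vth)`, under which
#' `N_r = kappa * [f_A - alpha1]_+` reproduces [recruited_count()] exactly.
#'
#' @param phys A [physical_params()] object.
#' @return A list with elements `alpha1`, `tau1`, `kappa`.
#' @export
lumped_from_physical <- function(phys) {
  stopifnot(inherits(phys, "physical_params"))
  cc <- phys$c0 * phys$c1
  base <- 4 * pi * cc * phys$G1 * phys$Vth
  list(alpha1 = base * phys$h^2, tau1 = phys$C1 / phys$G1, kappa = phys$rho / base)
}
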