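#' Parameters of the spoiled-gradient-echo ROI signal simulator
#'
#' Defaults reproduce the acquisition protocol this pipeline targets: echo
#' times 2.38 / 4.76 / 7.14 ms (opposed / in / opposed phase at 1.5 T), TR
#' 88 ms, flip angle 70 degrees. The T1 defaults (water/liver 586 ms, fat
#' 343 ms) are literature-typical 1.5 T values chosen by this package, not
#' protocol constants, and can be overridden.
#'
#' @param te1,te2,te3 Echo times in ms, strictly increasing.
#' @param tr Repetition time in ms.
#' @param flip_angle Flip angle in degrees.
#' @param t1_water,t1_fat Longitudinal relaxation times in ms.
#' @param t2star Effective transverse relaxation time in ms (shared by both
#'   compartments; mono-exponential decay).
#' @param proton_density Total proton density in arbitrary units; fat and
#'   water split it according to the simulated fat fraction.
#' @param noise_sd Standard deviation of additive Gaussian noise per echo, in
#'   the same arbitrary units; 0 gives a closed-form noiseless signal.
#' @param seed Optional integer seed controlling the noise draws.
#' @return An object of class `mri_signal_params`.
#' @export
mri_signal_params <- function(te1 = 2.38, te2 = 4.76, te3 = 7.14,
                              tr = 88, flip_angle = 70,
                              t1_water = 586, t1_fat = 343,
                              t2star = 25, proton_density = 100,
                              noise_sd = 0, seed = NULL) {
  .check_num(tr, "tr", lo = 1e-9)
  .check_num(flip_angle, "flip_angle", lo = 1e-9, hi = 180)
  .check_num(t1_water, "t1_water", lo = 1e-9)
  .check_num(t1_fat, "t1_fat", lo = 1e-9)
  .check_num(t2star, "t2star", lo = 1e-9)
  .check_num(proton_density, "proton_density", lo = 0)
  .check_num(noise_sd, "noise_sd", lo = 0)
  if (!(te1 < te2 && te2 < te3)) {
    stop("echo times must satisfy te1 < te2 < te3", call. = FALSE)
  }
  structure(list(te1 = te1, te2 = te2, te3 = te3, tr = tr,
                 flip_angle = flip_angle, t1_water = t1_water,
                 t1_fat = t1_fat, t2star = t2star,
                 proton_density = proton_density, noise_sd = noise_sd,
                 seed = seed),
            class = "mri_signal_params")
}

# steady-state weight of a spoiled gradient echo (Ernst formula), per unit
# proton density
.sge_weight <- function(t1, tr, flip_deg) {
  th <- flip_deg * pi / 180
  e1 <- exp(-tr / t1)
  sin(th) * (1 - e1) / (1 - cos(th) * e1)
}

#' Simulate triple-echo ROI intensities from a two-compartment model
#'
#' Water and fat magnetizations are weighted by the spoiled-gradient-echo
#' steady state `w = rho * sin(theta) * (1 - E1) / (1 - cos(theta) * E1)`
#' with `E1 = exp(-TR/T1)`, and the magnitude signal at echo time `TE` is
#' `|W -/+ F| * exp(-TE/T2*)` with the minus sign at the opposed-phase echoes
#' (TE1, TE3) and the plus sign at the in-phase echo (TE2). Gaussian noise of
#' sd `noise_sd` is added per echo.
#'
#' `fat_fraction` is the fat share of total proton density. It is restricted
#' to `[0, 0.5]`: opposed-phase imaging cannot distinguish water-dominant from
#' fat-dominant voxels, and the analysis pipeline assumes water protons always
#' outnumber fat protons.
#'
#' @param fat_fraction Fat proton-density fraction in `[0, 0.5]`.
#' @param params An [mri_signal_params()] object.
#' @return An [echo_triple()] carrying the simulated intensities and the echo
#'   times of `params`.
#' @examples
#' p <- mri_signal_params(flip_angle = 90, tr = 1e9, t2star = 20)
#' simulate_roi_signals(0.40, p)
#' @export
simulate_roi_signals <- function(fat_fraction, params = mri_signal_params()) {
  .check_num(fat_fraction, "fat_fraction", lo = 0)
  stopifnot(inherits(params, "mri_signal_params"))
  if (fat_fraction > 0.5) {
    stop("`fat_fraction` > 0.5 is outside the water-dominant regime this model assumes",
         call. = FALSE)
  }
  W <- (1 - fat_fraction) * params$proton_density *
    .sge_weight(params$t1_water, params$tr, params$flip_angle)
  F_ <- fat_fraction * params$proton_density *
    .sge_weight(params$t1_fat, params$tr, params$flip_angle)
  te <- c(params$te1, params$te2, params$te3)
  signal <- abs(W + c(-1, 1, -1) * F_) * exp(-te / params$t2star)
  if (params$noise_sd > 0) {
    signal <- .with_seed(params$seed,
                         signal + rnorm(3, sd = params$noise_sd))
    signal <- pmax(signal, 0)
  }
  echo_triple(op1 = signal[1], ip = signal[2], op2 = signal[3],
              te1 = params$te1, te2 = params$te2, te3 = params$te3)
}
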