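#' Genomic offsets of the seven E. coli rrn operons from oriC
#'
#' Distances (kb) of each ribosomal RNA operon from the replication origin
#' along its replication arm, on a 2320 kb arm (half of the 4.64 Mb genome).
#' rrnC, rrnB and rrnE values are the ones used throughout the analysis;
#' the remaining operons carry MG1655-annotation distances.
#'
#' @return Named numeric vector (kb).
#' @examples
#' rrn_operon_offsets()[c("rrnC", "rrnB", "rrnE")]
#' @export
rrn_operon_offsets <- function() {
  c(rrnC = 42, rrnA = 110, rrnB = 265, rrnE = 306,
    rrnD = 497, rrnH = 940, rrnG = 1196)
}

#' Strain profiles of the rrn occupancy model
#'
#' Per-strain growth and copy-number bookkeeping for wild type and the
#' rrn-deletion strains in minimal (M9Glu) and rich defined (RDM) medium:
#' doubling time (min), rRNA-engaged RNAPs per cell (`n_rrnap`), oriC and rrn
#' copies per cell, and the remaining operons' genomic offsets.
#'
#' @return Tibble with one row per strain x medium, `operons` as a
#'   list-column of offsets (kb).
#' @export
rrn_strain_profiles <- function() {
  offs <- rrn_operon_offsets()
  tibble::tibble(
    strain = rep(c("WT", "D5", "D6"), 2),
    medium = rep(c("M9Glu", "RDM"), each = 3),
    doubling_time = c(47, 57, 73, 36, 46, 51),
    n_rrnap = c(397, 238, 122, 805, 420, 320),
    ori_copies = c(2.9, 2.5, 2.2, 3.7, 2.9, 2.7),
    rrn_copies = c(17.5, 4.8, 2.0, 22.0, 5.6, 2.5),
    operons = list(offs, offs[c("rrnC", "rrnB")], offs["rrnE"],
                   offs, offs[c("rrnC", "rrnB")], offs["rrnE"])
  )
}

#' Interpolate rRNA-engaged RNAP numbers across growth rates
#'
#' The number of RNAPs engaged on rrn operons per cell, N_r, rises steeply
#' with growth rate. `rrnap_interpolation()` fits a single exponential in log
#' growth rate -- equivalently a power law N_r = alpha * mu^beta with
#' mu = 60/tau doublings per hour -- by least squares on log N_r; on this
#' axis the calibration data are collinear to about 1%, whereas a fit linear
#' in mu misses held-out points by over 30%. `fit_rrnap_exponential()` is the
#' one-call convenience wrapper returning predictions at query doubling
#' times.
#'
#' @param calibration Tibble with columns `doubling_time` (min) and `n_rrnap`
#'   (> 0); at least two rows.
#' @param tau Query doubling times (min).
#' @return `rrnap_interpolation()` returns an object of class `rrnap_exp`
#'   with `alpha`, `beta` and the underlying `lm`; its `predict()` method and
#'   `fit_rrnap_exponential()` return N_r predictions.
#' @examples
#' fit_rrnap_exponential(rrn_strain_profiles(), tau = 47)
#' @export
rrnap_interpolation <- function(calibration) {
  if (nrow(calibration) < 2) abort("at least two calibration points required")
  if (any(calibration$n_rrnap <= 0)) abort("calibration N_r must be positive")
  if (any(calibration$doubling_time <= 0)) abort("doubling times must be positive")
  mu <- 60 / calibration$doubling_time
  fit <- lm(log(n_rrnap) ~ log(mu), data = data.frame(
    n_rrnap = calibration$n_rrnap, mu = mu
  ))
  structure(
    list(alpha = exp(coef(fit)[[1]]), beta = coef(fit)[[2]], lm = fit),
    class = "rrnap_exp"
  )
}

#' @rdname rrnap_interpolation
#' @param object An `rrnap_exp` fit.
#' @param ... Unused.
#' @export
predict.rrnap_exp <- function(object, tau, ...) {
  if (any(tau <= 0)) abort("doubling times must be positive")
  object$alpha * (60 / tau)^object$beta
}

#' @rdname rrnap_interpolation
#' @export
fit_rrnap_exponential <- function(calibration, tau) {
  predict(rrnap_interpolation(calibration), tau)
}

#' Replication-dependent gene dosage
#'
#' Average copies per cell of a gene at relative map position `m_prime`
#' (0 at oriC, 1 at the terminus) for cells with replication period `C`,
#' division period `D` and doubling time `tau` (all minutes):
#' `2^((C * (1 - m_prime) + D) / tau)`. At `m_prime = 0` this is the oriC
#' copy number `2^((C + D)/tau)`; dosage decreases monotonically toward the
#' terminus and increases with C + D.
#'
#' @param tau Doubling time (min).
#' @param m_prime Relative map position(s) in \[0, 1\].
#' @param C Replication period (min).
#' @param D Division period (min).
#' @return Copies per cell (vectorized over `m_prime`).
#' @examples
#' gene_dosage(47, 0, C = 48.1, D = 24.1) # oriC copies
#' @export
gene_dosage <- function(tau, m_prime, C, D) {
  if (any(tau <= 0)) abort("tau must be positive")
  if (any(m_prime < 0 | m_prime > 1)) abort("m_prime must lie in [0, 1]")
  if (any(C < 0) || any(D < 0)) abort("C and D must be non-negative")
  2^((C * (1 - m_prime) + D) / tau)
}

#' Total rrn copies per cell from measured oriC copies
#'
#' Inverts the oriC copy number for the combined cell-cycle period
#' `C + D = tau * log2(ori_copies)`, splits it `C:D = cd_ratio:1`, and sums
#' [gene_dosage()] over the strain's operon offsets.
#'
#' @param tau Doubling time (min).
#' @param ori_copies Measured/expected oriC copies per cell.
#' @param offsets_kb Operon offsets from oriC (kb).
#' @param arm_length_kb Replication arm length (kb).
#' @param cd_ratio C:D period ratio (default 2, i.e. C = 2D).
#' @return Summed rrn copies per cell.
#' @examples
#' rrn_copy_number(36, 3.7, rrn_operon_offsets())
#' @export
rrn_copy_number <- function(tau, ori_copies, offsets_kb,
                            arm_length_kb = 2320, cd_ratio = 2) {
  if (any(ori_copies < 1)) abort("ori_copies must be >= 1")
  cd <- tau * log2(ori_copies)
  C <- cd * cd_ratio / (1 + cd_ratio)
  D <- cd - C
  sum(gene_dosage(tau, offsets_kb / arm_length_kb, C, D))
}

#' Per-operon RNAP loading and fractional occupancy
#'
#' Divides the cell's rRNA-engaged RNAPs over its rrn copies and expresses
#' the loading as a percentage of the occupancy at the maximal growth rate
#' (72 RNAPs per operon). Ratios are computed unrounded; `*_rounded` columns
#' apply report-time integer rounding (half away from zero).
#'
#' @param n_rrnap RNAPs engaged on rrn per cell.
#' @param rrn_copies rrn operon copies per cell (> 0).
#' @param max_ref Reference occupancy defining 100% (RNAPs per operon).
#' @return Tibble with `rnap_per_rrn`, `occupancy_pct` and rounded variants.
#' @examples
#' rnap_per_rrn_occupancy(397, 17.5)
#' @export
rnap_per_rrn_occupancy <- function(n_rrnap, rrn_copies, max_ref = 72) {
  if (any(rrn_copies <= 0)) abort("rrn_copies must be positive")
  per <- n_rrnap / rrn_copies
  occ <- 100 * per / max_ref
  tibble::tibble(
    rnap_per_rrn = per, occupancy_pct = occ,
    rnap_per_rrn_rounded = round_half_away(per),
    occupancy_pct_rounded = round_half_away(occ)
  )
}

# integer rounding, halves away from zero (report-time convention)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Maximal physical RNAP occupancy of an operon
#'
#' Number of elongating RNAPs that physically fit on an operon given the DNA
#' footprint per polymerase: `floor(operon_length_bp / footprint_bp)`. With
#' the ~5.4 kb rRNA operon and a 40 bp footprint this is 135 RNAPs, well
#' above the 72 observed at maximal growth.
#'
#' @param operon_length_bp Operon length (bp).
#' @param footprint_bp Footprint per elongating RNAP (bp).
#' @return Integer count.
#' @export
physical_max_occupancy <- function(operon_length_bp = 5400, footprint_bp = 40) {
  if (operon_length_bp <= 0 || footprint_bp <= 0) {
    abort("operon length and footprint must be positive")
  }
  floor(operon_length_bp / footprint_bp)
}

#' ori:ter ratio from qPCR cycle thresholds
#'
#' Comparative cycle-threshold arithmetic: `2^(ct_ter - ct_ori)`
#' (the 2^-delta-Ct method with the terminus amplicon as reference).
#'
#' @param ct_ori,ct_ter Cycle thresholds of the origin and terminus
#'   amplicons.
#' @return ori:ter ratio.
#' @examples
#' ori_ter_from_ct(20, 21) # one cycle earlier at ori: ratio 2
#' @export
ori_ter_from_ct <- function(ct_ori, ct_ter) {
  if (any(!is.finite(ct_ori)) || any(!is.finite(ct_ter))) {
    abort("Ct values must be finite")
  }
  2^(ct_ter - ct_ori)
}

#' rrn occupancy table across strains and media
#'
#' Reproduces the occupancy bookkeeping for each strain profile: RNAPs per
#' operon and fractional occupancy relative to the maximal-growth-rate
#' reference. With `rrn_copies = "printed"` the tabulated per-cell rrn copy
#' numbers are used directly; with `rrn_copies = "model"` they are recomputed
#' from the gene-dosage formula with C + D inverted from the oriC copies.
#'
#' @param profiles Strain table as [rrn_strain_profiles()].
#' @param rrn_copies `"printed"` or `"model"`.
#' @param max_ref Reference occupancy (RNAPs per operon) defining 100%.
#' @param arm_length_kb,cd_ratio Passed to [rrn_copy_number()] in model mode.
#' @return The profiles tibble with `rnap_per_rrn`, `occupancy_pct` and
#'   rounded report columns appended.
#' @examples
#' occupancy_table()[, c("strain", "medium", "rnap_per_rrn_rounded",
#'                       "occupancy_pct_rounded")]
#' @export
occupancy_table <- function(profiles = rrn_strain_profiles(),
                            rrn_copies = c("printed", "model"),
                            max_ref = 72, arm_length_kb = 2320,
                            cd_ratio = 2) {
  rrn_copies <- match.arg(rrn_copies)
  copies <- if (rrn_copies == "model") {
    purrr::pmap_dbl(
      list(profiles$doubling_time, profiles$ori_copies, profiles$operons),
      function(tau, ori, offs) {
        rrn_copy_number(tau, ori, offs, arm_length_kb = arm_length_kb,
                        cd_ratio = cd_ratio)
      }
    )
  } else {
    profiles$rrn_copies
  }
  dplyr::bind_cols(
    dplyr::mutate(profiles, rrn_copies_used = copies),
    rnap_per_rrn_occupancy(profiles$n_rrnap, copies, max_ref = max_ref)
  )
}
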