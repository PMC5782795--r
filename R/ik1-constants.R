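# Rate and equilibrium constants of the time-dependent inward-rectifier
# (I_K1 / Kir2.1) formulation used for real-time injection.
#
# The model follows the Ishihara-type description of strong inward
# rectification: conduction is gated by instantaneous block of the pore by
# intracellular Mg2+ and by intracellular spermine acting in two modes --
# a fast, low-affinity mode treated as instantaneous, and a slow,
# high-affinity mode carried by a single gate `y` (the only state
# variable).  All block equilibria and rates depend on the driving
# potential V - EK, which is what makes the rectification track the K+
# reversal potential when extracellular K+ is changed.
#
# Every other file references these values symbolically; no literal from
# this table may be duplicated elsewhere.
#
# Units: voltages mV, rates s^-1, [Mg2+]i mmol/L, [SPM]i umol/L.

.ik1_constants <- list(
  # Instantaneous Mg2+ block.  The channel carries `mg_sites` equivalent
  # blocking sites; only channels with all sites free conduct, so the
  # conducting fraction is (a/(a+b))^mg_sites with
  #   a = mg_alpha * exp(mg_alpha_slope * (V - EK))
  #   b = mg_beta  * [Mg2+]i * exp(mg_beta_slope * (V - EK))
  # Only the ratio a/b matters (the block is equilibrated within a tick).
  mg_alpha       = 12.0,
  mg_alpha_slope = -0.025,   # per mV
  mg_beta        = 0.28,     # per mmol/L
  mg_beta_slope  = 0.025,    # per mV
  mg_sites       = 3,

  # Mode 1: fast (instantaneous) low-affinity spermine block.
  # Kd(V) = spm1_kd0 * exp(-(V - EK) * spm1_kd_slope), in mmol/L;
  # blocked fraction = SPM / (SPM + Kd).
  spm1_kd0      = 0.04,      # mmol/L at V = EK
  spm1_kd_slope = 1 / 9.1,   # per mV

  # Mode 2: slow high-affinity spermine block, the gate y
  # (y = fraction of mode-2 channels free of spermine).
  # Rates use the Mg2+-shifted driving potential u = (V - EK) + 8*[Mg2+]i:
  #   alpha_y = spm2_alpha * exp(-0.07 u) / (1 + 0.01 exp(0.12 u))   [s^-1]
  #   beta_y  = spm2_beta * [SPM]i * exp(0.15 u) / (1 + 0.01 exp(0.13 u))
  spm2_alpha       = 0.68,   # s^-1
  spm2_alpha_slope = 0.07,   # per mV
  spm2_alpha_sat   = 0.12,   # per mV (saturation term)
  spm2_beta        = 1.12,   # s^-1 per umol/L spermine
  spm2_beta_slope  = 0.15,   # per mV
  spm2_beta_sat    = 0.13,   # per mV (saturation term)
  spm2_mg_shift    = 8,      # mV shift per mmol/L [Mg2+]i

  # Maximal conductance scales with extracellular K+ as
  # (Ko / ko_ref)^ko_exponent.  The user-facing conductance density is
  # defined at the reference Ko, so the scale factor is exactly 1 under
  # the default ionic configuration.
  ko_ref      = 4,           # mmol/L
  ko_exponent = 0.4
)

# RT/F in mV at a given temperature (degrees C).
rtf_mv <- function(temperature = 20) {
  1000 * 8.314462618 * (temperature + 273.15) / 96485.332
}
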