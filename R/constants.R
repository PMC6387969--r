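## Physical constants (SI).  Temperature enters through RT/F; the recording
## temperature is room temperature, 293 K, giving RT/F ~ 25.25 mV.
FARADAY <- 96485      # C mol-1
GAS_CONSTANT <- 8.314 # J mol-1 K-1
DEFAULT_TEMPERATURE <- 293 # K

## Internal unit regime: volts, A m-2, S m-2, mol m-3 (== mM), seconds.
## Interfaces speak mV and uM; conversions are centralized here.
mv_to_v <- function(mv) mv / 1000
v_to_mv <- function(v) v * 1000
um_to_molm3 <- function(um) um * 1e-3  # 1 uM = 1e-3 mol m-3

rt_over_f <- function(temperature = DEFAULT_TEMPERATURE) {
  GAS_CONSTANT * temperature / FARADAY  # volts
}
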