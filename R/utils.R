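# Internal physical constants and small numeric helpers shared across modules.

.const <- list(
  sigma    = 5.670374419e-8, # Stefan-Boltzmann constant, W m-2 K-4
  cp       = 1005,           # specific heat of air at constant pressure, J kg-1 K-1
  rho_air  = 1.2,            # bulk air density, kg m-3 (held fixed)
  vonk     = 0.41,           # von Karman constant
  lambda_f = 0.334e6,        # latent heat of fusion, J kg-1
  lambda_v = 2.45e6,         # latent heat of vaporization, J kg-1
  S0       = 1361,           # solar constant, W m-2
  T0       = 273.15          # freezing point, K
)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Saturation vapour pressure (kPa) over water, Tetens form; T in Kelvin.
.esat <- function(T_K) {
  tc <- T_K - 273.15
  0.6108 * exp(17.27 * tc / (tc + 237.3))
}

# d esat / dT (kPa/K)
.desat <- function(T_K) {
  tc <- T_K - 273.15
  .esat(T_K) * 17.27 * 237.3 / (tc + 237.3)^2
}

# Psychrometric constant (kPa/K) for pressure in kPa.
.gamma_psy <- function(pressure_kPa) 0.000665 * pressure_kPa

# Trailing running mean over a window of w samples (expanding at the start).
.trailing_mean <- function(x, w) {
  n <- length(x)
  if (n == 0L) return(numeric(0))
  w <- min(w, n)
  cs <- cumsum(x)
  lag <- c(rep(0, w), cs[seq_len(n - w)])
  (cs - lag) / pmin(seq_len(n), w)
}

.is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
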