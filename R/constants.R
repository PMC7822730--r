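## Physical constants and unit conversions.
## Internal unit conventions across the analysis layer:
##   DLS lag times in microseconds, q in 1/nm, temperatures in K,
##   viscosities in mPa s, diffusion coefficients in m^2/s,
##   NSE times in ns, SAXS q declared as 1/nm or 1/angstrom per curve.

.KB <- 1.380649e-23 # J/K

# q declared in 1/angstrom -> 1/nm
.q_to_per_nm <- function(q, unit = c("per_nm", "per_angstrom")) {
  unit <- match.arg(unit)
  if (unit == "per_angstrom") q * 10 else q
}
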