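# Shared physical constants (CODATA) and acquisition conventions.

# Acquisition m/z range, Da.
MZ_RANGE <- c(50, 1000)

.PROTON_MASS <- 1.00727645
.ELECTRON_MASS <- 0.00054857990
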