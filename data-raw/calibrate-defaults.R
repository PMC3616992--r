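# Regenerates the calibrated default parameter set shipped in
# R/apoptosis-model.R (.calibrated_values).  Run from the repo root after
# installing the package:  Rscript data-raw/calibrate-defaults.R
library(bcl2dyn)
fit <- calibrate_apoptosis(seed = 42L)
print(fit)
cat("endpoints:", 80 + fit$residuals[1], 80 + fit$residuals[2],
    99 + fit$residuals[3], "\n")
dput(unlist(unclass(fit$params)))
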