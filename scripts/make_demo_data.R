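## Writes the small synthetic demonstration dataset shipped in inst/extdata.
## The data are generated by the package's own two-subgroup generator and are
## a synthetic look-alike of a digital-pathology cohort (no real cohort data).
library(clusso)
truth <- generate_truth(q = 4, s_beta = 0.5, G_true = 2, seed = 2024)
dat <- generate_dataset(40, 4, truth, "two_cluster", sigma2_R = 1,
                        mu_M = 12, sigma2_M = 5, seed = 2024)
tub <- as.data.frame(dat$tubules)
names(tub) <- c("subject_id", "object_id",
                "tubule_area", "lumen_thickness", "tbm_thickness", "epithelium_area")
tub[3:6] <- lapply(tub[3:6], round, 4)
out <- dat$outcomes
out$y <- round(out$y, 4)
write.csv(tub, "inst/extdata/synthetic_tubules.csv", row.names = FALSE, quote = FALSE)
write.csv(out, "inst/extdata/synthetic_outcomes.csv", row.names = FALSE, quote = FALSE)
cat("rows:", nrow(tub), "\n")
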