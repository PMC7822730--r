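#!/usr/bin/env Rscript
# Local-scale diffusion from spin-echo data: initial-slope fits of the
# intermediate scattering function, the diffusion function D(q), band
# averages (high-q self-diffusion, cage diffusion at the structure-factor
# peak), and the sticky-sphere short-time prediction.
# Writes results/nse_dq.csv.

suppressPackageStartupMessages(library(colloidcrowd))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(i <- which(args == "--seed"))) as.integer(args[i + 1]) else 1L
dir.create("results", showWarnings = FALSE)

d0 <- 3.04e-11
phi <- 0.2 # crowded sample; phi = c * nu_eff with nu_eff = 1.7 mL/g
d_short <- d0 * shs_self_diffusion(phi, 0.774)

## synthetic spin-echo set: constant D(q) at high q plus a low-q upturn
## from rotational/internal motion
curves <- synth_nse_set(d_short, q_list = seq(0.3, 2.1, by = 0.15),
                        upturn = 0.5, noise = 0.005, seed = seed + 40)
slopes <- lapply(curves, nse_initial_slope)
dq <- data.frame(q = vapply(slopes, `[[`, numeric(1), "q"),
                 D = vapply(slopes, `[[`, numeric(1), "D"))
write.csv(dq, "results/nse_dq.csv", row.names = FALSE)

high <- band_average_diffusion(dq, "high_q")
cage <- band_average_diffusion(dq, c(0.9, 1.3)) # around the weak peak
cat(sprintf("high-q self-diffusion D = %.3g m^2/s (band 1.8-2.2 1/nm)\n",
            high$D))
cat(sprintf("cage diffusion        D = %.3g m^2/s (band 0.9-1.3 1/nm)\n",
            cage$D))
cat(sprintf("sticky-sphere prediction at phi = %.2f: Ds/D0 = %.3f -> %.3g m^2/s\n",
            phi, shs_self_diffusion(phi, 0.774), d_short))
cat("the low-q upturn (rotational/internal contributions) is visible as\n")
cat("D(q) above the high-q plateau below ~0.7 1/nm.\n")
cat("written: results/nse_dq.csv\n")
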