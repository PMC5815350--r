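#!/usr/bin/env Rscript
# Stage 1: build the synthetic study cohort.
#
# Generates junction phantoms for a thick-PSD (excitatory-like) and a
# thin-PSD (inhibitory-like) group with known ground truth, one example
# tomogram on disk as MRC2014, and the cohort ground-truth table that the
# later stages are scored against.

library(cryosynapse)
set.seed(1)
dir.create("results", showWarnings = FALSE)

n_thick <- 20; n_thin <- 8   # scaled-down cohort; one tomogram each
cohort <- rbind(
  data.frame(group = "thick",
             d1 = rnorm(n_thick, 14.7, 3.0),
             lambda = pmax(rnorm(n_thick, 18.0, 7.0), 3),
             cleft = rnorm(n_thick, 26, 1)),
  data.frame(group = "thin",
             d1 = rnorm(n_thin, 9.1, 1.1),
             lambda = pmax(rnorm(n_thin, 3.2, 1.5), 1.5),
             cleft = rnorm(n_thin, 26, 1)))
cohort$id <- sprintf("syn%02d", seq_len(nrow(cohort)))
cohort$seed <- 100 + seq_len(nrow(cohort))
write.csv(cohort, "results/cohort_truth.csv", row.names = FALSE)

# one phantom written out as MRC to demonstrate the volume interface
spec1 <- phantom_spec(psd_d1 = cohort$d1[1], psd_lambda = cohort$lambda[1],
                      cleft_width = cohort$cleft[1], noise_sigma = 2,
                      seed = cohort$seed[1])
ph1 <- make_synapse_phantom(spec1)
write_mrc(ph1$tomogram, "results/example_synapse_phantom.mrc")
back <- read_mrc("results/example_synapse_phantom.mrc")
stopifnot(max(abs(back$data - ph1$tomogram$data)) < 1e-5)

jsonlite::write_json(
  list(voxel_size_nm = spec1$voxel_size,
       volume_shape = spec1$volume_shape,
       d1_nm = spec1$psd_d1, lambda_nm = spec1$psd_lambda,
       cleft_width_nm = spec1$cleft_width,
       noise_sigma = spec1$noise_sigma),
  "results/example_synapse_truth.json", auto_unbox = TRUE, digits = NA)

cat(sprintf("cohort: %d thick-PSD + %d thin-PSD synapses\n", n_thick, n_thin))
cat(sprintf("example phantom: %d x %d x %d voxels @ %.3f nm, MRC round-trip ok\n",
            dim(ph1$tomogram)[1], dim(ph1$tomogram)[2], dim(ph1$tomogram)[3],
            spec1$voxel_size))
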