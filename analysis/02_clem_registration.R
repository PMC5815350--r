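#!/usr/bin/env Rscript
# Stage 2: correlative LM <-> EM <-> stage registration.
#
# Simulates the hole-pattern landmark workflow: ~15 carbon holes picked in
# the LM image and the low-magnification EM image, the LM->EM transform
# estimated by least squares, and fluorescent punctum positions converted
# to EM stage coordinates through a second pixel->stage calibration.

library(cryosynapse)
set.seed(2)
dir.create("results", showWarnings = FALSE)

# ground-truth LM->EM map: slight anisotropic magnification + rotation
lm_to_em <- affine2d(matrix(c(2.05, 0.12, -0.10, 1.98), 2, 2), c(310, -42))
holes <- make_landmark_pairs(lm_to_em, 15, noise_sigma_px = 1.5, seed = 21)
fit <- estimate_transform(holes$source, holes$target)
write_transform_json(fit, "results/lm_to_em_transform.json")
write.csv(data.frame(lm_x = holes$source[, 1], lm_y = holes$source[, 2],
                     em_x = holes$target[, 1], em_y = holes$target[, 2],
                     residual_px = attr(fit, "residuals")),
          "results/landmark_residuals.csv", row.names = FALSE)

# pixel -> stage (um) calibration from the same holes re-picked at higher
# magnification, then mapping of synapse candidate puncta
em_to_stage <- affine2d(matrix(c(0.082, 0.001, -0.001, 0.081), 2, 2),
                        c(250, 310))
cal <- make_landmark_pairs(em_to_stage, 15, noise_sigma_px = 0.5, seed = 22)
puncta <- cbind(runif(6, 100, 900), runif(6, 100, 900))
mapped <- pixel_to_stage(puncta, cal$source, cal$target)
write.csv(data.frame(px_x = puncta[, 1], px_y = puncta[, 2],
                     stage_x_um = mapped$stage[, 1],
                     stage_y_um = mapped$stage[, 2]),
          "results/puncta_stage_coordinates.csv", row.names = FALSE)

truth_err <- sqrt(mean(rowSums(
  (map_points(fit, holes$source) - map_points(lm_to_em, holes$source))^2)))
cat(sprintf("LM->EM fit: RMSE %.2f px against picks, %.2f px against truth\n",
            fit$fit_rmse, truth_err))
cat(sprintf("worst landmark residual: %.2f px (hole %d) - candidate for re-picking\n",
            max(attr(fit, "residuals")), which.max(attr(fit, "residuals"))))
cat(sprintf("pixel->stage calibration RMSE: %.3f um; %d puncta mapped\n",
            mapped$rmse, nrow(puncta)))
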