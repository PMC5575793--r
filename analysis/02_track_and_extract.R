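#!/usr/bin/env Rscript
# Read the demonstration scene back from disk, track the soma on the
# red (calcium-independent) channel, extract the background-subtracted
# ratiometric trace, normalize to the pre-stimulus baseline, and
# compare against the generator's ground truth.

library(touchtrace)

stacks <- read_split_stack("scratch/scene_demo/scene.tif")
truth <- read.csv("scratch/scene_demo/ground_truth.csv")
meta <- stacks$metadata
protocol <- do.call(stim_protocol, meta$protocol[
  c("onsets", "durations", "pressures", "baseline_window",
    "record_duration")])

start <- locate_neuron(stacks$red[, , 1])
traj <- track_neuron(stacks$red, start)
pos_err <- sqrt((traj$row - truth$row)^2 + (traj$col - truth$col)^2)

spec <- roi_spec(background_center = pick_background(stacks$red[, , 1],
                                                     avoid = start))
trace <- normalize_trace(ratio_trace(traj, stacks$green, stacks$red,
                                     spec, protocol))
rmse <- sqrt(mean((trace$data$dRR - truth$true_dRR)^2))
mt <- trial_metrics(trace)

write_trajectory(traj, "results/02_trajectory.csv")
write_trace(trace, "results/02_trace.csv")
write.csv(cbind(mt, trace_rmse = rmse,
                tracker_median_err_px = median(pos_err)),
          "results/02_trial_metrics.csv", row.names = FALSE)

cat(sprintf("Tracking: median error %.2f px (max %.2f px), %d/%d coasted\n",
            median(pos_err), max(pos_err),
            sum(traj$confidence == "coasted"), nrow(traj)))
cat(sprintf("Trace recovery RMSE %.4f dR/R0 vs ground truth\n", rmse))
cat(sprintf(paste0("Trial metrics: peak dR/R0 %.3f at %.1f s, delay %.2f s,",
                   " half-life %.2f s, responder %s\n"),
            mt$max_dRR, mt$t_peak, mt$delay_time, mt$half_life,
            mt$responder))
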