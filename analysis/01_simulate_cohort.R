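#!/usr/bin/env Rscript
# Generates one example synthetic cell of every modality and writes the raw
# data files (delimited-text traces and sweeps, TIFF+YAML volumes) plus the
# ground-truth tables under results/raw/. Everything downstream can be
# reproduced from these files alone.

library(myoequiv)

out <- "results/raw"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 1L

# paced Fura-2 ratio trace on the full 0.5-4 Hz ladder, 5% noise
ca <- gen_transient_trace(transient_sim_spec(noise_sd = 0.025,
                                             missed_beat_prob = 0.05,
                                             seed = seed))
write_timeseries(ca$recording, file.path(out, "fura_trace.tsv"))
write.csv(ca$truth, file.path(out, "fura_truth.csv"), row.names = FALSE)

# simultaneous sarcomere-length trace
sl <- gen_sarcomere_trace(transient_sim_spec(noise_sd = 0.005, seed = seed),
                          resting_sl = 1.8, shortening = 0.1)
write_timeseries(sl$recording, file.path(out, "sarcomere_trace.tsv"))
write.csv(sl$truth, file.path(out, "sarcomere_truth.csv"), row.names = FALSE)

# membrane-dye z-stack with tubule lattice
ph <- gen_tats_volume(tats_phantom_spec(seed = seed))
write_volume(ph$image, file.path(out, "tats_stack.tif"))

# dual-channel mitochondrial z-stack
mv <- gen_mito_volume(mito_phantom_spec(seed = seed))
write_volume(mv$mtg, file.path(out, "mito_mtg.tif"))
write_volume(mv$tmrm, file.path(out, "mito_tmrm.tif"))

# voltage-clamp sweep families
es <- ephys_sim_spec(noise_sd = 20, seed = seed)
iv <- gen_vclamp_sweeps(es, "iv")
write_sweeps(iv$sweeps, file.path(out, "iv"))
k1 <- gen_vclamp_sweeps(es, "ik1")
write_sweeps(k1$control, file.path(out, "ik1_control"))
write_sweeps(k1$blocked, file.path(out, "ik1_blocked"))

cat("simulated one cell per modality ->", out, "\n")
cat(sprintf("  Fura trace: %d samples, %d stimuli (%.0f%% captured in truth)\n",
            length(ca$recording$time), nrow(ca$truth),
            100 * mean(ca$truth$captured)))
cat(sprintf("  TATS stack: %s voxels, true tubule fraction %.2f%%\n",
            paste(dim(ph$image$voxels), collapse = "x"),
            100 * sum(ph$truth$tats_mask) / sum(ph$truth$cell_mask)))
cat(sprintf("  mito stack: target r %.2f, realized %.3f\n",
            mv$truth$target_r, mv$truth$realized_r))
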