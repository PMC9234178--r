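## Lazily computed simulated studies shared by the acceptance tests,
## so the 1 Mb designs are generated once per seed rather than once per
## criterion.

.study_cache <- new.env(parent = emptyenv())

## Full-scale planted study at the default study conditions
## (1 Mb, 3 vs 3, depth 25, 50 planted CG windows, delta +0.4).
planted_study <- function(seed) {
  key <- paste0("planted_", seed)
  if (!is.null(.study_cache[[key]])) return(.study_cache[[key]])
  cfg <- sim_config(seed = seed)
  gen <- simulate_genome(cfg)
  met <- simulate_methylome(gen$genome, cfg)
  tiles <- tile_windows(gen$genome)[chrom != cfg$control_name]
  samp_ctrl <- met$samples[met$groups == "ctrl"]
  samp_case <- met$samples[met$groups == "case"]
  w <- window_stats(samp_case, samp_ctrl, tiles, context = "CG")
  scan <- call_dmrs(w, return_windows = TRUE)
  res <- list(cfg = cfg, gen = gen, met = met,
              samp_ctrl = samp_ctrl, samp_case = samp_case,
              scan = scan)
  .study_cache[[key]] <- res
  res
}

## Same design with no planted signal.
null_study <- function(seed) {
  key <- paste0("null_", seed)
  if (!is.null(.study_cache[[key]])) return(.study_cache[[key]])
  cfg <- sim_config(seed = seed, planted_dmrs = NULL)
  gen <- simulate_genome(cfg)
  met <- simulate_methylome(gen$genome, cfg)
  res <- list(cfg = cfg, gen = gen, met = met)
  .study_cache[[key]] <- res
  res
}
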