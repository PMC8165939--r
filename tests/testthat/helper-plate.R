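# The full-plate study fixture used by the acceptance properties: a 36-well
# phantom plate (18 round / 18 branched, 96 hourly timepoints, 256x256),
# segmented and measured well by well. Built once per test run and cached;
# frames are dropped after each well to bound memory.

.plate_cache <- new.env(parent = emptyenv())

acceptance_study <- function() {
  if (!is.null(.plate_cache$study)) return(.plate_cache$study)
  plate <- generate_plate(phantom_config(),
                          phantom_config(phenotype = "branched"),
                          n_wells_per_condition = 18L, base_seed = 1L)
  feats <- list(); crops <- list()
  residue <- numeric(0)
  n_frames <- integer(0)
  for (w in names(plate$wells)) {
    s <- plate$wells[[w]]
    n_frames[[w]] <- length(s$frames)
    masks <- segment_series(s)
    art <- plate$truth[[w]]$artifact_mask
    residue[[w]] <- max(vapply(masks, function(m) sum(m$mask & art),
                               numeric(1))) / sum(art)
    r <- measure_series(masks)
    r$well <- w
    feats[[w]] <- r
    crops[[w]] <- build_crop_dataset(s, masks, output_size = 96L)
    plate$wells[[w]] <- NULL
  }
  study <- list(layout = plate$layout,
                table = assemble_table(do.call(rbind, feats), plate$layout),
                crops = bind_crop_datasets(crops),
                artifact_residue = residue,
                n_series = length(n_frames),
                n_frames = n_frames)
  .plate_cache$study <- study
  study
}
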