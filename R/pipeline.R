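# Umbrella pipeline: DIMR -> (optional) DeepSNiF over a channel manifest,
# with a JSON provenance record per run.

#' Run the full denoising pipeline over a channel manifest
#'
#' For every row of the manifest: read the channel TIFF, run DIMR, then
#' (unless `skip_deepsnif`) train one DeepSNiF model for the channel on
#' its DIMR output and predict. Denoised TIFFs and a JSON provenance
#' record (package version, seeds, parameters, per-stage hot-pixel
#' fractions) are written to `out_dir`.
#'
#' @param manifest_path channel manifest CSV (`file,channel,metal`).
#' @param out_dir output directory.
#' @param config nested configuration list from [read_run_config()].
#' @param skip_deepsnif stop after hot-pixel removal (the DIMR-only
#'   comparator arm).
#' @return invisible list with per-channel output paths and the
#'   provenance record.
#' @export
run_pipeline <- function(manifest_path, out_dir,
                         config = read_run_config(),
                         skip_deepsnif = isTRUE(config$deepsnif$skip)) {
  manifest <- read_manifest(manifest_path)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  dcfg <- config$dimr
  ncfg <- config$deepsnif
  outputs <- list()
  provenance <- list(
    package = "imcdenoise",
    version = as.character(utils::packageVersion("imcdenoise")),
    config = config, skip_deepsnif = skip_deepsnif, channels = list())
  for (i in seq_len(nrow(manifest))) {
    ch <- manifest$channel[i]
    stage <- "read"
    res <- tryCatch({
      img <- read_tiff(manifest$file[i])
      stage <- "dimr"
      dr <- dimr(img, n_iter = dcfg$n_iter, l = dcfg$l,
                 bg_cutoff = dcfg$bg_cutoff,
                 round_output = isTRUE(dcfg$round_output))
      restored <- dr$pixels
      model_path <- NULL
      if (!skip_deepsnif) {
        stage <- "deepsnif-train"
        patches <- extract_patches(restored, rho = ncfg$rho,
                                   percentile = ncfg$percentile,
                                   patch_size = ncfg$patch_size,
                                   seed = ncfg$seed, channel_id = ch)
        model <- deepsnif_train(
          patches, base_filters = ncfg$base_filters,
          epochs = ncfg$epochs, batch_size = ncfg$batch_size,
          lr = ncfg$lr, lr_decay = ncfg$lr_decay,
          lr_patience = ncfg$lr_patience,
          lambda_hessian = ncfg$lambda_hessian,
          masking_rate = ncfg$masking_rate, seed = ncfg$seed)
        model_path <- file.path(out_dir, paste0(ch, "_model.rds"))
        deepsnif_save(model, model_path)
        stage <- "deepsnif-predict"
        restored <- deepsnif_predict(model, restored)
      }
      out_path <- file.path(out_dir, paste0(ch, "_denoised.tiff"))
      write_tiff(restored, out_path, dtype = "float32")
      list(path = out_path, model = model_path,
           hot_fraction = dr$report$fraction_flagged,
           iterations = dr$report$iterations_run)
    }, error = function(e) {
      stop(sprintf("pipeline failed at stage '%s' for channel '%s' (%s): %s",
                   stage, ch, manifest$file[i], conditionMessage(e)),
           call. = FALSE)
    })
    outputs[[ch]] <- res
    provenance$channels[[ch]] <- list(
      input = manifest$file[i], output = res$path, model = res$model,
      dimr_hot_fraction = res$hot_fraction,
      dimr_iterations = res$iterations)
  }
  prov_path <- file.path(out_dir, "provenance.json")
  jsonlite::write_json(provenance, prov_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(list(outputs = outputs, provenance = provenance,
                 provenance_path = prov_path))
}
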