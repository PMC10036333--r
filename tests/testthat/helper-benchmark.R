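# Shared benchmark harnesses for the acceptance suite. Simulation
# results used by several criteria are computed once per test run and
# memoised in this environment.

.bench_env <- new.env(parent = emptyenv())

# DIMR benchmark: 10 seeded 256x256 blob images (lambda_fg 20,
# lambda_bg 1) with 1% injected single hot pixels.
dimr_benchmark <- function(n_seeds = 10) {
  key <- paste0("dimr_", n_seeds)
  if (!is.null(.bench_env[[key]])) return(.bench_env[[key]])
  cfg <- sim_config(size = 256, lambda_fg = 20, lambda_bg = 1,
                    hot_pixel_density = 0.01)
  runs <- lapply(seq_len(n_seeds), function(s) {
    trip <- simulate_imc(cfg, seed = s)
    res <- dimr(trip$hot)
    det <- res$report$total_mask
    list(trip = trip, dimr = res,
         recall = sum(det & trip$hot_mask) / sum(trip$hot_mask),
         false_rate = sum(det & !trip$hot_mask) / length(det),
         rmse_in = img_rmse(trip$hot, trip$noisy),
         rmse_out = img_rmse(res$pixels, trip$noisy))
  })
  .bench_env[[key]] <- runs
  runs
}

# Desk-scale DeepSNiF experiment: train a small-capacity network on
# >= 512 synthetic patches for 30 epochs, then score PSNR gain and
# background STDB on 3 held-out images. The background-patch threshold
# rho is set at the tile zero-fraction median for this generator (a
# pure-background tile has zero fraction ~ exp(-lambda_bg)); batch 16
# suits the ~500-patch desk training set.
desk_denoise_run <- function(seed, epochs = 30, base_filters = 8,
                             n_train_imgs = 12, n_test = 3) {
  cfg <- sim_config(size = 256, lambda_fg = 20, lambda_bg = 1,
                    hot_pixel_density = 0)
  train_imgs <- lapply(seed * 100 + seq_len(n_train_imgs),
                       function(s) simulate_imc(cfg, seed = s)$noisy)
  ps <- suppressWarnings(
    extract_patches(train_imgs, rho = 0.27, seed = seed, max_base = 64))
  stopifnot(dim(ps$patches)[3] >= 512)
  model <- deepsnif_train(ps, base_filters = base_filters,
                          epochs = epochs, batch_size = 16, seed = seed)
  tests <- lapply(seed * 100 + 50 + seq_len(n_test), function(s) {
    trip <- simulate_imc(cfg, seed = s)
    den <- deepsnif_predict(model, trip$noisy)
    pk <- max(trip$clean)
    list(psnr_gain = img_psnr(den, trip$clean, pk) -
           img_psnr(trip$noisy, trip$clean, pk),
         stdb_noisy = stdb(trip$noisy, trip$bg_mask),
         stdb_denoised = stdb(den, trip$bg_mask))
  })
  list(model = model, tests = tests,
       gains = vapply(tests, `[[`, numeric(1), "psnr_gain"),
       stdb_decreased = vapply(tests, function(t)
         t$stdb_denoised < t$stdb_noisy, logical(1)))
}
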