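# Cached micro training run shared by the engine tests: 20 images per
# class, 64 x 64, two epochs of the tiny preset.
micro_run <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    dat <- micro_dataset(20L)
    cfg <- run_config("tiny", epochs = 2L, seed = 5L)
    ck <- train(cfg, dat$manifest, dat$dir, val_split = "test",
                verbose = FALSE)
    cache <<- list(dat = dat, cfg = cfg, ckpt = ck)
    cache
  }
})
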