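# Shared trained-model fixture for the stochastic recovery tests.
#
# Training the localizer and both U-Nets on 64 phantoms dominates the test
# run, so the fixture is built lazily once and reused by every test that
# needs trained models (localization recovery, segmentation recovery,
# end-to-end index recovery).

.bc_fixture_env <- new.env(parent = emptyenv())

trained_fixture <- function() {
  if (!is.null(.bc_fixture_env$fix)) return(.bc_fixture_env$fix)
  cfg <- phantom_scale_config()
  ds <- generate_dataset(80, seed = 11)
  train <- ds[1:64]
  test <- ds[65:80]
  models <- list(localizer = train_localizer(train, cfg),
                 l1 = train_segmenter(train, "L1", cfg),
                 l3 = train_segmenter(train, "L3", cfg))
  .bc_fixture_env$fix <- list(config = cfg, train = train, test = test,
                              models = models)
  .bc_fixture_env$fix
}
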