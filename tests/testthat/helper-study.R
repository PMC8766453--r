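# The desk-scale foam study shared by the acceptance checks. Run once and
# memoised for the session; every block reads the same paired comparison.
study_cache <- new.env(parent = emptyenv())

tiny_study <- function() {
  if (is.null(study_cache$cmp)) {
    config <- preset_tiny(seed = 1)
    study_cache$config <- config
    study_cache$cmp <- run_comparison(
      config,
      methods = c("complete", "angular_bicubic", "cycloidal_bicubic",
                  "cycloidal_msd"))
  }
  study_cache$cmp
}

tiny_metric <- function(method, what) {
  rep <- tiny_study()$report
  rep[rep$method == method, what]
}
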