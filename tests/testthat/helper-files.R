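# temp-file helper: a named file inside a test-scoped temp directory
withr_local_file <- function(name, env = parent.frame()) {
  file.path(withr::local_tempdir(.local_envir = env), name)
}
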