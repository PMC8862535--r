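.onLoad <- function(libname, pkgname) {
  # classifier objects deserialized from model bundles dispatch into these
  # namespaces; make sure their S3 methods are registered up front
  requireNamespace("Matrix", quietly = TRUE)
  requireNamespace("e1071", quietly = TRUE)
  requireNamespace("nnet", quietly = TRUE)
  invisible()
}
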