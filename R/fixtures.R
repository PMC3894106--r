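#' Bundled synthetic source model
#'
#' A Cs-137-like line source (active length 1.48 cm, capsule diameter
#' 0.3 cm) with a smooth polynomial radial dose function and a mildly
#' asymmetric anisotropy table (lower F on the cable/channel side of the
#' long axis).  The numbers are synthetic -- plausible for a Cs-137
#' intracavitary source but not taken from any published characterization --
#' and exist so the simulator and extraction pipeline can be exercised
#' end to end.
#'
#' @return A [source_model()].
#' @export
synthetic_source_model <- function() {
  read_source_model(synthetic_source_path())
}

#' @rdname synthetic_source_model
#' @export
synthetic_source_path <- function() {
  system.file("extdata", "source_cs137like_synthetic.yaml",
              package = "tg43dosim", mustWork = TRUE)
}
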