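#' Packaged synthetic signature fixtures
#'
#' Synthetic stand-ins shaped like the published transcription-factor
#' signatures the pipeline is exercised against: an NRF2-style signature with
#' 68 up- plus 75 down-regulated genes (143 total) and a RELA (NF-kB) target
#' set with 304 activated plus 85 suppressed genes (389 total). Gene IDs follow
#' the synthetic universe naming (`G00001`...), so the sets intersect simulated
#' experiments; the member lists are synthetic and carry no biological content
#' beyond their sizes and directions.
#'
#' @return named list of [signature_set()] objects: `NRF2_UP_SYNTHETIC`,
#'   `NRF2_DOWN_SYNTHETIC`, `RELA_ACTIVATED_SYNTHETIC`,
#'   `RELA_SUPPRESSED_SYNTHETIC`.
#' @export
packaged_signatures <- function() {
  nrf2 <- read_gmt(system.file("extdata", "nrf2_signature_synthetic.gmt",
                               package = "modscape", mustWork = TRUE))
  rela <- read_gmt(system.file("extdata", "rela_signature_synthetic.gmt",
                               package = "modscape", mustWork = TRUE))
  c(nrf2, rela)
}
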