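#' The ten-gene IFN-gamma response signature
#'
#' Gene cluster marking tumors with an active IFN-gamma response, used to
#' score per-sample immune activity. "HLA-D" is not a single gene symbol;
#' the default surrogate is HLA-DRA and can be swapped for any HLA-DR
#' family member.
#'
#' @param hlaSurrogate gene symbol standing in for the HLA-D component.
#' @return character vector of 10 unique gene symbols.
#' @export
ifngSignature <- function(hlaSurrogate = "HLA-DRA") {
    sig <- c("IFNG", "STAT1", "CCR5", "CXCL9", "CXCL10", "CXCL11",
             "IDO1", "PRF1", "GZMA", hlaSurrogate)
    if (anyDuplicated(sig)) stop("signature genes must be unique")
    sig
}

#' The 48-member nuclear receptor candidate panel
#'
#' Human nuclear receptor gene symbols screened by the cascade.
#'
#' @return character vector of 48 unique gene symbols.
#' @export
nrPanel <- function() {
    c("NR2F6", "ESRRA", "NR1H3", "NR3C1", "RORC", "ESR1", "ESRRB",
      "NR6A1", "THRA", "THRB", "RARA", "RARB", "RARG", "PPARA",
      "PPARD", "PPARG", "NR1D1", "NR1D2", "RORA", "RORB", "NR1H2",
      "NR1H4", "NR1I2", "NR1I3", "HNF4A", "HNF4G", "RXRA", "RXRB",
      "RXRG", "NR2C1", "NR2C2", "NR2E1", "NR2E3", "NR2F1", "NR2F2",
      "ESR2", "ESRRG", "NR3C2", "PGR", "AR", "NR4A1", "NR4A2",
      "NR4A3", "NR5A1", "NR5A2", "NR0B1", "NR0B2", "VDR")
}
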