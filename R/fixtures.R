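#' Packaged diagnostic-panel fixtures
#'
#' The published allele-frequency and genotype-quality matrices of the
#' four-species parasitoid wasp panel (samples PA03 = *Palmistichus
#' elaeisis*, TD01 = *Trichospilus diatraeae*, TP02 = *Trichogramma
#' pretiosum*, and two replicate pools of TH04 = *Tetrastichus
#' howardi*): 15 species-specific variants, 12 pairwise-differentiating
#' variants, with the published call labels for cross-checking.
#'
#' @param which `"table4"` (species-specific set), `"table5"` (pairwise
#'   set) or `"both"` (default; 27 variants).
#' @return list with `dosage` (a [DosageMatrix-class], 5 sample columns
#'   with the TH04 replicates sharing one species label), `gq` (matching
#'   GQ matrix) and `expected` (published call labels: `specific`, or
#'   `low`/`high`).
#' @export
#' @examples
#' fx <- diagFixture()
#' dim(dosage(fx$dosage))
diagFixture <- function(which = c("both", "table4", "table5")) {
  which <- match.arg(which)
  load1 <- function(tab) {
    path <- system.file("extdata", paste0(tab, "_variants.tsv"),
                        package = "diagSNP", mustWork = TRUE)
    df <- utils::read.delim(path, check.names = FALSE)
    fcols <- grep("^freq_", names(df))
    gcols <- grep("^gq_", names(df))
    freq <- as.matrix(df[fcols])
    gq <- as.matrix(df[gcols])
    samples <- sub("^freq_", "", names(df)[fcols])
    dimnames(freq) <- list(df$variant_id, samples)
    dimnames(gq) <- list(df$variant_id, samples)
    expected <- df[setdiff(names(df), names(df)[c(fcols, gcols)])]
    list(freq = freq, gq = gq, expected = expected)
  }
  parts <- switch(which,
    table4 = list(load1("table4")),
    table5 = list(load1("table5")),
    both = list(load1("table4"), load1("table5")))
  freq <- do.call(rbind, lapply(parts, `[[`, "freq"))
  gq <- do.call(rbind, lapply(parts, `[[`, "gq"))
  expected <- do.call(rbind, lapply(parts, function(p) {
    e <- p$expected
    for (col in c("specific", "low", "high"))
      if (!col %in% names(e)) e[[col]] <- NA_character_
    e[c("variant_id", "specific", "low", "high")]
  }))
  species <- sub("[ab]$", "", sub("^TH04.*", "TH04", colnames(freq)))
  list(dosage = DosageMatrix(freq, species = species),
       gq = gq, expected = expected)
}
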