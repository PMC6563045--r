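#' Driver gene catalog (hg19, approximate)
#'
#' A static catalog of oesophagogastric adenocarcinoma driver loci used to
#' annotate focal amplification calls and to place simulated amplification
#' events. Coordinates are approximate hg19 gene spans (synthetic fixture;
#' not a downloaded annotation).
#'
#' @return data.frame with columns `gene`, `chrom`, `start`, `end`
#'   (0-based half-open).
#' @export
driver_genes <- function() {
  g <- data.frame(
    gene = c("EGFR", "ERBB2", "KRAS", "MET", "MYC", "MAPK1", "CCND1",
             "GATA4", "CDK6", "CDK4", "FBXW7", "FGFR2", "VEGFA", "CCNE1",
             "MCPH1", "PIK3CA", "ERBB4", "CDKN2A", "PTEN", "TP53",
             "FHIT", "WWOX"),
    chrom = c("chr7", "chr17", "chr12", "chr7", "chr8", "chr22", "chr11",
              "chr8", "chr7", "chr12", "chr4", "chr10", "chr6", "chr19",
              "chr8", "chr3", "chr2", "chr9", "chr10", "chr17",
              "chr3", "chr16"),
    start = c(55086725, 37844393, 25358180, 116312444, 128748315, 22113947,
              69455873, 11561717, 92234235, 58141510, 153242410, 123237844,
              43737946, 30302805, 6264113, 178866311, 212240442, 21967751,
              89623195, 7571720, 59735036, 78133310),
    end = c(55275031, 37884915, 25403854, 116438440, 128753680, 22221970,
            69469242, 11617509, 92465908, 58146230, 153456185, 123357972,
            43754224, 30315215, 6501140, 178952497, 213403352, 21995300,
            89728532, 7590868, 61237133, 79246564),
    stringsAsFactors = FALSE
  )
  stopifnot(!anyDuplicated(g$gene))
  g
}
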