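#' The 54 variants observed in the Argentinean LHON screening cohort
#'
#' The published spectrum for the 100-patient cohort: five variants listed
#' as disease-causing in MitoMap (the three worldwide primary LHON
#' mutations m.3460G>A, m.11778G>A and m.14484T>C, plus the rare
#' m.11253T>C and m.3395A>G) and 49 variants listed as benign.  Carrier
#' counts are patients carrying the variant out of 100; five of the benign
#' variants are established haplogroup markers (B2, C, AE, JT).
#'
#' @return A tibble with columns `variant`, `gene`, `protein_change`,
#'   `carriers`, `mitomap_status` (`"disease_causing"` or `"benign"`) and
#'   `haplogroup_tag` (`NA` when the variant is not a marker).
#' @examples
#' lhon_variant_table()
#' @export
lhon_variant_table <- function() {
  dc <- tibble::tribble(
    ~variant,      ~protein_change, ~carriers, ~haplogroup_tag,
    "m.3395A>G",   "p.Tyr30Cys",     1L,       NA_character_,
    "m.3460G>A",   "p.Ala52Thr",     9L,       NA_character_,
    "m.11253T>C",  "p.Ile165Thr",    3L,       NA_character_,
    "m.11778G>A",  "p.Arg340His",   17L,       NA_character_,
    "m.14484T>C",  "p.Met64Val",     2L,       NA_character_
  )
  dc$mitomap_status <- "disease_causing"

  bn <- tibble::tribble(
    ~variant,      ~protein_change, ~carriers, ~haplogroup_tag,
    "m.3308T>C",   "p.Met1Thr",      1L, NA,
    "m.3316G>A",   "p.Ala4Thr",      1L, NA,
    "m.3372T>C",   "p.Leu22Leu",     1L, NA,
    "m.3397A>G",   "p.Met31Val",     2L, NA,
    "m.3438G>A",   "p.Gly44Gly",     3L, NA,
    "m.3447A>G",   "p.Gln47Gln",     1L, NA,
    "m.3480A>G",   "p.Lys58Lys",     1L, NA,
    "m.3483G>A",   "p.Glu59Glu",     1L, NA,
    "m.3504T>C",   "p.Ser66Ser",     1L, NA,
    "m.3535T>C",   "p.Leu77Leu",     1L, NA,
    "m.3547A>G",   "p.Ile81Val",    15L, "B2",
    "m.3548T>C",   "p.Ile81Thr",     1L, NA,
    "m.3552T>A",   "p.Ala82Ala",    12L, "C",
    "m.3591G>A",   "p.Leu95Leu",     1L, NA,
    "m.3594C>T",   "p.Val96Val",     1L, NA,
    "m.3666G>A",   "p.Gly120Gly",    1L, NA,
    "m.3693G>A",   "p.Leu129Leu",    1L, NA,
    "m.3746C>T",   "p.Ala147Val",    3L, NA,
    "m.3808A>G",   "p.Thr168Ala",    1L, NA,
    "m.3915G>A",   "p.Gly203Gly",    2L, NA,
    "m.3918G>A",   "p.Glu204Glu",    1L, NA,
    "m.3992C>T",   "p.Thr229Met",    1L, NA,
    "m.3999T>C",   "p.Ile231Ile",    1L, NA,
    "m.4024A>G",   "p.Thr240Ala",    1L, NA,
    "m.4092G>A",   "p.Lys262Lys",    2L, NA,
    "m.4104A>G",   "p.Leu266Leu",    2L, NA,
    "m.4216T>C",   "p.Tyr304His",    6L, "JT",
    "m.4248T>C",   "p.Ile314Ile",    7L, "AE",
    "m.4259C>T",   "p.Thr318Ile",    1L, NA,
    "m.11251A>G",  "p.Leu164Leu",    3L, NA,
    "m.11299T>C",  "p.Thr180Thr",    1L, NA,
    "m.11377G>A",  "p.Lys206Lys",    1L, NA,
    "m.11467A>G",  "p.Leu236Leu",    1L, NA,
    "m.11611G>A",  "p.Ser284Ser",    2L, NA,
    "m.11719G>A",  "p.Gly320Gly",   56L, NA,
    "m.11776T>C",  "p.Ser339Ser",    2L, NA,
    "m.14305G>A",  "p.Ser123Ser",    1L, NA,
    "m.14318T>C",  "p.Asn119Ser",   14L, "C",
    "m.14359C>T",  "p.Trp105Trp",    1L, NA,
    "m.14364G>A",  "p.Leu104Leu",    1L, NA,
    "m.14410G>A",  "p.Val88Val",     1L, NA,
    "m.14461T>C",  "p.Trp71Trp",     1L, NA,
    "m.14527A>G",  "p.Gly49Gly",     1L, NA,
    "m.14560G>A",  "p.Val38Val",     1L, NA,
    "m.14561A>G",  "p.Val38Ala",     1L, NA,
    "m.14566A>G",  "p.Gly36Gly",     1L, NA,
    "m.14582A>G",  "p.Val31Ala",     1L, NA,
    "m.14587A>G",  "p.Gly29Gly",     4L, NA,
    "m.14634T>C",  "p.Met14Val",     1L, NA
  )
  bn$mitomap_status <- "benign"

  out <- dplyr::bind_rows(dc, bn)
  out$gene <- mt_gene(as.integer(stringr::str_match(out$variant, "^m\\.(\\d+)")[, 2]))
  dplyr::arrange(
    out[, c("variant", "gene", "protein_change", "carriers",
            "mitomap_status", "haplogroup_tag")],
    as.integer(stringr::str_match(.data$variant, "^m\\.(\\d+)")[, 2])
  )
}
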