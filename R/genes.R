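#' Gene models for the three LHON screening genes
#'
#' Coordinates of *MT-ND1*, *MT-ND4* and *MT-ND6* on the rCRS
#' (revised Cambridge Reference Sequence, 16,569 bp, 1-based, heavy strand).
#' *MT-ND6* is the only light-strand gene of the three: its coding sequence
#' is the reverse complement of the rCRS interval, with codon 1 at the
#' 3'-most heavy-strand coordinate.
#'
#' @return A tibble with one row per gene: `gene`, `start`, `end`, `strand`
#'   (`"heavy"` or `"light"`) and `n_codons` (complete codons in the
#'   interval, terminal incomplete stop codons excluded).
#' @examples
#' mt_gene_models()
#' @export
mt_gene_models <- function() {
  tibble::tibble(
    gene   = c("MT-ND1", "MT-ND4", "MT-ND6"),
    start  = c(3307L, 10760L, 14149L),
    end    = c(4262L, 12137L, 14673L),
    strand = c("heavy", "heavy", "light"),
    # ND1 and ND4 end in incomplete stop codons (TA- and T--) completed by
    # polyadenylation; only full codons are translatable.
    n_codons = c(318L, 459L, 175L)
  )
}

#' rCRS genome length in base pairs
#' @keywords internal
RCRS_LENGTH <- 16569L

#' Assign an mtDNA position to a screened gene
#'
#' Pure lookup against the bundled gene intervals: positions inside
#' *MT-ND1*, *MT-ND4* or *MT-ND6* return that gene name, anything else
#' (control region, other genes) returns `"other"`.
#'
#' @param position Integer vector of 1-based rCRS coordinates.
#' @return Character vector, same length as `position`.
#' @examples
#' mt_gene(c(3460, 11778, 14484, 16000))
#' @export
mt_gene <- function(position) {
  position <- as.integer(position)
  if (any(is.na(position)) || any(position < 1L) || any(position > RCRS_LENGTH)) {
    rlang::abort(
      sprintf("positions must lie in [1, %d]", RCRS_LENGTH),
      class = "mtlhon_position_error"
    )
  }
  models <- mt_gene_models()
  out <- rep("other", length(position))
  for (i in seq_len(nrow(models))) {
    hit <- position >= models$start[i] & position <= models$end[i]
    out[hit] <- models$gene[i]
  }
  out
}

# vertebrate mitochondrial genetic code, as used for human mtDNA
mito_code <- function() {
  Biostrings::getGeneticCode("SGC1")
}

# one-letter -> three-letter amino acid names, HGVS style
AA3 <- c(
  A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
  E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
  M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
  Y = "Tyr", V = "Val", `*` = "Ter"
)

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

aa_three <- function(aa1) unname(AA3[aa1])

translate_codon <- function(codon) {
  unname(mito_code()[codon])
}
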