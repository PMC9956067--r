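#' Read an mtDNA reference sequence
#'
#' Reads a single-record FASTA covering the rCRS coordinate frame.  The
#' record id is not interpreted; the sequence must be 16,569 bases
#' (positions outside the regions of interest may be `N`).  The bundled
#' reference (`mt_reference_path()`) is a synthetic reconstruction of the
#' three ND gene regions; see `vignette("mtdna-lhon-interpretation")`.
#'
#' @param path Path to a FASTA file. Defaults to the bundled reconstruction.
#' @return A single character string of length-16,569 sequence.
#' @examples
#' ref <- read_mt_reference()
#' substr(ref, 3307, 3309)  # MT-ND1 start codon
#' @export
read_mt_reference <- function(path = mt_reference_path()) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) != 1L) {
    rlang::abort("reference FASTA must contain exactly one record",
                 class = "mtlhon_reference_error")
  }
  s <- toupper(as.character(seqs[[1]]))
  if (nchar(s) != RCRS_LENGTH) {
    rlang::abort(
      sprintf("reference length %d; expected rCRS length %d",
              nchar(s), RCRS_LENGTH),
      class = "mtlhon_reference_error"
    )
  }
  s
}

#' Path to the bundled synthetic rCRS gene-region reference
#'
#' @return File path of `rcrs_nd_genes_synthetic.fa` inside the installed
#'   package.
#' @export
mt_reference_path <- function() {
  system.file("extdata", "rcrs_nd_genes_synthetic.fa", package = "mtlhon",
              mustWork = TRUE)
}

# codon context of a position inside a screened gene: gene, codon index,
# offset of the position within the coding codon (1..3), the coding-strand
# codon and its amino acid.  Light-strand genes (MT-ND6) are read on the
# reverse complement with codon 1 at the 3'-most heavy-strand coordinate.
codon_info <- function(reference, position) {
  gene <- mt_gene(position)
  if (gene == "other") {
    rlang::abort(
      sprintf("position %d lies outside MT-ND1/MT-ND4/MT-ND6; protein consequence unsupported",
              position),
      class = "mtlhon_consequence_error"
    )
  }
  gm <- mt_gene_models()
  gm <- gm[gm$gene == gene, ]
  if (gm$strand == "heavy") {
    codon_idx <- (position - gm$start) %/% 3L + 1L
    codon_start <- gm$start + 3L * (codon_idx - 1L)
    offset <- position - codon_start + 1L
    codon <- substr(reference, codon_start, codon_start + 2L)
  } else {
    light_pos <- gm$end - position + 1L
    codon_idx <- (light_pos - 1L) %/% 3L + 1L
    heavy_first <- gm$end - 3L * (codon_idx - 1L)  # heavy coord of codon pos 1
    offset <- ((gm$end - position) %% 3L) + 1L
    heavy_bases <- strsplit(substr(reference, heavy_first - 2L, heavy_first), "")[[1]]
    codon <- paste(rev(unname(COMPLEMENT[heavy_bases])), collapse = "")
  }
  if (codon_idx > gm$n_codons || is.na(codon) || nchar(codon) != 3L) {
    rlang::abort(
      sprintf("position %d falls in the incomplete terminal codon of %s",
              position, gene),
      class = "mtlhon_consequence_error"
    )
  }
  if (grepl("[^ACGT]", codon)) {
    rlang::abort(
      sprintf("reference codon at position %d contains non-ACGT bases", position),
      class = "mtlhon_consequence_error"
    )
  }
  list(gene = gene, strand = gm$strand, codon_idx = codon_idx,
       offset = offset, codon = codon, ref_aa = translate_codon(codon))
}

#' Translate protein consequences of mtDNA variants
#'
#' Computes HGVS-style protein-change strings (`"p.Arg340His"`;
#' synonymous changes render as `"p.Gly320Gly"`) for substitutions inside
#' the three screened genes, using the vertebrate mitochondrial genetic
#' code.  *MT-ND6* codons are read on the light strand (reverse
#' complement), codon 1 at heavy-strand position 14,673.
#'
#' @param variants Tibble from [parse_mt_variants()].
#' @param reference Reference sequence string from [read_mt_reference()].
#' @return The input tibble with a `protein_change` column appended.
#' @examples
#' ref <- read_mt_reference()
#' translate_consequence(parse_mt_variants("m.11778G>A"), ref)
#' @export
translate_consequence <- function(variants, reference = read_mt_reference()) {
  pc <- character(nrow(variants))
  for (i in seq_len(nrow(variants))) {
    pos <- variants$position[i]
    ref <- variants$ref[i]
    alt <- variants$alt[i]
    if (mt_gene(pos) == "other") {
      rlang::abort(
        sprintf("position %d lies outside MT-ND1/MT-ND4/MT-ND6; protein consequence unsupported",
                pos),
        class = "mtlhon_consequence_error"
      )
    }
    ref_base <- substr(reference, pos, pos)
    if (ref_base != ref) {
      rlang::abort(
        sprintf("reference mismatch at position %d: reference has %s, variant states %s",
                pos, ref_base, ref),
        class = "mtlhon_reference_error"
      )
    }
    info <- codon_info(reference, pos)
    coding_alt <- if (info$strand == "heavy") alt else unname(COMPLEMENT[alt])
    alt_codon <- info$codon
    substr(alt_codon, info$offset, info$offset) <- coding_alt
    pc[i] <- sprintf("p.%s%d%s",
                     aa_three(info$ref_aa), info$codon_idx,
                     aa_three(translate_codon(alt_codon)))
  }
  variants$protein_change <- pc
  variants
}
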