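#' The twenty canonical amino acids
#'
#' Lowercase full names, used throughout as metabolite identifiers (an
#' `_e` / `_c` suffix marks the compartment in generated models).
#' Essentiality follows the standard human classification; arginine is
#' tagged conditionally essential.
#'
#' @return `amino_acids()` returns a character vector of the 20 names,
#'   alphabetically ordered. `amino_acid_essentiality()` returns a named
#'   character vector with values `"essential"`, `"conditional"` or
#'   `"nonessential"`.
#' @examples
#' amino_acids()
#' amino_acid_essentiality()[c("leucine", "arginine", "glutamine")]
#' @export
amino_acids <- function() {
  c("alanine", "arginine", "asparagine", "aspartate", "cysteine",
    "glutamate", "glutamine", "glycine", "histidine", "isoleucine",
    "leucine", "lysine", "methionine", "phenylalanine", "proline",
    "serine", "threonine", "tryptophan", "tyrosine", "valine")
}

#' @rdname amino_acids
#' @export
amino_acid_essentiality <- function() {
  aa <- amino_acids()
  essential <- c("histidine", "isoleucine", "leucine", "lysine",
                 "methionine", "phenylalanine", "threonine",
                 "tryptophan", "valine")
  conditional <- c("arginine", "cysteine", "glutamine", "glycine",
                   "proline", "tyrosine")
  out <- ifelse(aa %in% essential, "essential",
                ifelse(aa %in% conditional, "conditional", "nonessential"))
  names(out) <- aa
  out
}

#' Branched-chain amino acids
#'
#' Isoleucine, leucine and valine: the amino acids muscle tissue can
#' oxidize for energy in quantity.
#' @return character vector of length 3
#' @export
bcaa <- function() c("isoleucine", "leucine", "valine")

# internal: single-letter -> full-name lookup for FASTA residue counting
.aa_one_letter <- c(
  A = "alanine", R = "arginine", N = "asparagine", D = "aspartate",
  C = "cysteine", E = "glutamate", Q = "glutamine", G = "glycine",
  H = "histidine", I = "isoleucine", L = "leucine", K = "lysine",
  M = "methionine", F = "phenylalanine", P = "proline", S = "serine",
  T = "threonine", W = "tryptophan", Y = "tyrosine", V = "valine")
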