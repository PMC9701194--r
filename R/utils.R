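DNA_BASES <- c("A", "C", "G", "T")

# IUPAC code keyed by the sorted base set it encodes
IUPAC_BY_SET <- c(
  A = "A", C = "C", G = "G", T = "T",
  AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K",
  ACG = "V", ACT = "H", AGT = "D", CGT = "B", ACGT = "N"
)

# allowed base sets per IUPAC code
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

is_dna <- function(x) {
  all(grepl("^[ACGT]+$", x))
}

#' Reverse-complement DNA strings
#'
#' Thin vectorized wrapper around [Biostrings::reverseComplement()] that
#' takes and returns plain character vectors.
#'
#' @param x Character vector of DNA sequences (IUPAC letters allowed).
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp("GTACGTAT")
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# all L-mers over ACGT in lexicographic order (L <= 8 -> at most 65536)
all_kmers <- function(L) {
  stopifnot(L >= 1, L <= 10)
  grids <- rev(rep(list(DNA_BASES), L))
  do.call(paste0, rev(expand.grid(grids, stringsAsFactors = FALSE)))
}

# split k-mers into a character matrix (n x L)
kmer_matrix <- function(pams) {
  if (length(pams) == 0) {
    return(matrix(character(), nrow = 0, ncol = 0))
  }
  L <- nchar(pams[1])
  matrix(unlist(strsplit(pams, "", fixed = TRUE)),
    ncol = L, byrow = TRUE
  )
}

# draw random DNA of given lengths, vectorized
random_dna <- function(n, len) {
  if (n == 0) return(character())
  lens <- rep_len(len, n)
  flat <- sample(DNA_BASES, sum(lens), replace = TRUE)
  idx <- rep.int(seq_len(n), lens)
  vapply(split(flat, idx), paste0, character(1), collapse = "")
}

with_seed_if <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(seed, code)
}
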