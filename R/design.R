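#' Define an excision-reporter library design
#'
#' A PAM-discovery library is an amplicon with two constant anchor sequences
#' flanking a randomized PAM cassette (default 8 N). The anchors are what the
#' read extractor aligns to; the cassette is what gets counted.
#'
#' @param upstream_anchor,downstream_anchor Constant DNA sequences 5' and 3'
#'   of the cassette. Must be A/C/G/T only and at least 12 nt each.
#' @param cassette_length Length L of the randomized cassette (default 8).
#' @param library_bias Optional 4 x L matrix of per-position base
#'   probabilities (rows A, C, G, T). Default: uniform 0.25. Each column must
#'   sum to 1 (tolerance 1e-9).
#' @return An object of class `library_design`.
#' @export
#' @examples
#' d <- library_design()
#' d$cassette_length
library_design <- function(upstream_anchor = "GTCAGTCAGCATGC",
                           downstream_anchor = "GATCACGGTCTGAC",
                           cassette_length = 8L,
                           library_bias = NULL) {
  upstream_anchor <- toupper(upstream_anchor)
  downstream_anchor <- toupper(downstream_anchor)
  if (!is_dna(upstream_anchor) || !is_dna(downstream_anchor)) {
    abort("anchors must contain only A/C/G/T")
  }
  if (nchar(upstream_anchor) < 12 || nchar(downstream_anchor) < 12) {
    abort("anchors must be at least 12 nt long")
  }
  L <- as.integer(cassette_length)
  if (L < 1) abort("cassette_length must be >= 1")
  if (is.null(library_bias)) {
    library_bias <- matrix(0.25, nrow = 4, ncol = L,
      dimnames = list(DNA_BASES, NULL))
  }
  library_bias <- as.matrix(library_bias)
  if (!all(dim(library_bias) == c(4L, L))) {
    abort("library_bias must be a 4 x cassette_length matrix (rows A,C,G,T)")
  }
  if (is.null(rownames(library_bias))) rownames(library_bias) <- DNA_BASES
  library_bias <- library_bias[DNA_BASES, , drop = FALSE]
  if (any(library_bias < 0) ||
      any(abs(colSums(library_bias) - 1) > 1e-9)) {
    abort("each library_bias column must be a probability vector summing to 1")
  }
  structure(
    list(
      upstream_anchor = upstream_anchor,
      downstream_anchor = downstream_anchor,
      cassette_length = L,
      library_bias = library_bias
    ),
    class = "library_design"
  )
}

#' @export
print.library_design <- function(x, ...) {
  cat("<library_design>\n")
  cat("  upstream anchor:  ", x$upstream_anchor, "\n", sep = "")
  cat("  cassette:          ", x$cassette_length, " N\n", sep = "")
  cat("  downstream anchor: ", x$downstream_anchor, "\n", sep = "")
  invisible(x)
}

# probability of each cassette k-mer under the design's library bias
design_bias_prob <- function(design, pams) {
  mat <- kmer_matrix(pams)
  p <- rep(1, length(pams))
  for (j in seq_len(ncol(mat))) {
    p <- p * design$library_bias[mat[, j], j]
  }
  p
}

#' Define a ground-truth PAM cleavage-activity model
#'
#' Maps every cassette k-mer to a cleavage probability in \[0, 1\]. Three
#' parameterizations are supported:
#'
#' * `table`: an explicit named vector of activities; k-mers absent from the
#'   table get `default_activity`. Names may be full cassette k-mers or
#'   IUPAC patterns of cassette length (e.g. `"NNNNGTAT"`), expanded on use.
#' * `positional`: a 4 x L weight matrix; activity is the product of
#'   per-position weights.
#' * `consensus`: a single IUPAC pattern with `on`/`off` probabilities.
#'
#' @param mode One of `"table"`, `"positional"`, `"consensus"`.
#' @param table Named numeric vector (table mode).
#' @param default_activity Activity for k-mers not named in `table`.
#' @param weights 4 x L matrix of per-position weights in \[0,1\]
#'   (positional mode).
#' @param pattern IUPAC pattern (consensus mode).
#' @param on,off Cleavage probabilities for pattern match / non-match.
#' @return An object of class `activity_model`.
#' @export
#' @examples
#' # the planted NcCas9-like preference: GTAT optimal, GCAT suboptimal
#' m <- activity_model("table",
#'   table = c(NNNNGTAT = 1, NNNNGCAT = 0.8, NNNNATAT = 0.3, NNNNGTTT = 0.3))
activity_model <- function(mode = c("table", "positional", "consensus"),
                           table = NULL, default_activity = 0,
                           weights = NULL,
                           pattern = NULL, on = 1, off = 0) {
  mode <- match.arg(mode)
  obj <- list(mode = mode)
  if (mode == "table") {
    if (is.null(table) || is.null(names(table))) {
      abort("table mode needs a named numeric vector of activities")
    }
    if (any(table < 0 | table > 1) ||
        default_activity < 0 || default_activity > 1) {
      abort("activities must lie in [0, 1]")
    }
    obj$table <- table
    obj$default_activity <- default_activity
  } else if (mode == "positional") {
    weights <- as.matrix(weights)
    if (nrow(weights) != 4) abort("weights must have 4 rows (A,C,G,T)")
    if (is.null(rownames(weights))) rownames(weights) <- DNA_BASES
    if (any(weights < 0 | weights > 1)) abort("weights must lie in [0, 1]")
    obj$weights <- weights[DNA_BASES, , drop = FALSE]
  } else {
    check_iupac(pattern)
    if (any(c(on, off) < 0 | c(on, off) > 1)) {
      abort("on/off probabilities must lie in [0, 1]")
    }
    obj$pattern <- toupper(pattern)
    obj$on <- on
    obj$off <- off
  }
  structure(obj, class = "activity_model")
}

check_iupac <- function(pattern) {
  if (is.null(pattern) || !nzchar(pattern)) abort("pattern must be non-empty")
  chars <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% names(IUPAC_SETS))
  if (length(bad) > 0) {
    abort(sprintf(
      "invalid IUPAC character '%s' at position %d", chars[bad[1]], bad[1]
    ))
  }
  invisible(chars)
}

iupac_matches <- function(pams, pattern) {
  chars <- check_iupac(pattern)
  mat <- kmer_matrix(pams)
  if (ncol(mat) != length(chars)) {
    abort("pattern length must equal cassette length")
  }
  ok <- rep(TRUE, length(pams))
  for (j in seq_along(chars)) {
    ok <- ok & mat[, j] %in% IUPAC_SETS[[chars[j]]]
  }
  ok
}

#' Evaluate a cleavage-activity model on cassette k-mers
#'
#' @param model An [activity_model()].
#' @param pams Character vector of cassette k-mers.
#' @return Numeric vector of cleavage probabilities in \[0, 1\].
#' @export
activity_of <- function(model, pams) {
  stopifnot(inherits(model, "activity_model"))
  switch(model$mode,
    table = {
      a <- rep(model$default_activity, length(pams))
      for (key in names(model$table)) {
        if (grepl("^[ACGT]+$", key)) {
          a[pams == key] <- model$table[[key]]
        } else {
          a[iupac_matches(pams, key)] <- model$table[[key]]
        }
      }
      a
    },
    positional = {
      mat <- kmer_matrix(pams)
      a <- rep(1, length(pams))
      for (j in seq_len(ncol(mat))) a <- a * model$weights[mat[, j], j]
      unname(a)
    },
    consensus = ifelse(iupac_matches(pams, model$pattern), model$on, model$off)
  )
}

#' Expected cleaved-pool PAM distribution
#'
#' The cleaved pool samples cassette k-mers with probability proportional to
#' `bias * activity`; this returns that normalized distribution alongside
#' the ground-truth activity for every cassette k-mer.
#'
#' @inheritParams activity_of
#' @param design A [library_design()].
#' @return A tibble with columns `pam`, `activity`, `bias_prob`,
#'   `expected_freq`.
#' @export
expected_cleaved_distribution <- function(design, model) {
  pams <- all_kmers(design$cassette_length)
  bias <- design_bias_prob(design, pams)
  a <- activity_of(model, pams)
  mass <- bias * a
  if (sum(mass) <= 0) {
    abort("activity model assigns zero cleavage mass to the entire library")
  }
  tibble(
    pam = pams,
    activity = a,
    bias_prob = bias,
    expected_freq = mass / sum(mass)
  )
}

#' Define a sequencing error model
#'
#' @param substitution_rate Per-base substitution probability.
#' @param indel_rate Per-read probability of a single 1-bp insertion or
#'   deletion at a uniformly chosen position.
#' @param read_length Optional read length; reads shorter than this are
#'   padded 3' with random bases. `NULL` means emit the bare amplicon.
#' @return An object of class `error_model`.
#' @export
error_model <- function(substitution_rate = 0.002, indel_rate = 0.001,
                        read_length = NULL) {
  if (substitution_rate < 0 || substitution_rate >= 1 ||
      indel_rate < 0 || indel_rate >= 1) {
    abort("error rates must lie in [0, 1)")
  }
  structure(
    list(
      substitution_rate = substitution_rate,
      indel_rate = indel_rate,
      read_length = read_length
    ),
    class = "error_model"
  )
}
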