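#' Compile an IUPAC PAM pattern
#'
#' @param iupac IUPAC string, e.g. `"NNNNGYAT"` (position 6 then allows
#'   C/T). Invalid characters fail with the offending position named.
#' @return Object of class `pam_pattern`: list with `iupac` and `sets`
#'   (per-position allowed base sets).
#' @export
#' @examples
#' compile_pam("NNNNGYAT")$sets[[6]]
compile_pam <- function(iupac) {
  chars <- check_iupac(iupac)
  structure(
    list(iupac = toupper(iupac), sets = IUPAC_SETS[chars]),
    class = "pam_pattern"
  )
}

#' @export
print.pam_pattern <- function(x, ...) {
  cat("<pam_pattern> ", x$iupac, "\n", sep = "")
  invisible(x)
}

#' Scan sequences for guide-RNA target sites
#'
#' Finds every position (on one or both strands) where a spacer-length
#' window is immediately followed by a PAM matching the pattern. Windows
#' containing non-ACGT bases are skipped; soft-masked (lowercase) bases are
#' uppercased and matched. Overlapping sites are all reported.
#'
#' The sgRNA spacer follows the 5'-G transcription rule: when the genomic
#' spacer does not begin with G, either its first base is substituted by G
#' (`g_rule = "substitute"`, keeping the total at `spacer_length`, the
#' G + 23 reading of a 24-nt guide) or a G is prepended
#' (`g_rule = "prepend"`, total `spacer_length + 1`).
#'
#' @param x FASTA path, named character vector, or
#'   [Biostrings::DNAStringSet].
#' @param pattern A [compile_pam()] object or IUPAC string (default
#'   `"NNNNGYAT"`).
#' @param spacer_length Spacer length S (default 24).
#' @param strands `"both"`, `"+"`, or `"-"`.
#' @param g_rule `"substitute"` (default) or `"prepend"`.
#' @return Tibble sorted by `sequence_id`, `spacer_start`, then strand
#'   (+ before -): columns `sequence_id`, `spacer_start`, `spacer_end`
#'   (0-based half-open on the forward reference), `strand`, `spacer_seq`,
#'   `pam_seq` (both 5'->3' on the targeted strand), `sgrna_spacer`,
#'   `g_modified`.
#' @export
scan_targets <- function(x, pattern = "NNNNGYAT", spacer_length = 24L,
                         strands = c("both", "+", "-"),
                         g_rule = c("substitute", "prepend")) {
  strands <- match.arg(strands)
  g_rule <- match.arg(g_rule)
  if (is.character(pattern)) pattern <- compile_pam(pattern)
  seqs <- load_sequences(x)
  S <- as.integer(spacer_length)
  plen <- length(pattern$sets)
  hits <- purrr::imap(seqs, function(seq, id) {
    seq <- toupper(seq)
    len <- nchar(seq)
    out <- list()
    if (len >= S + plen) {
      if (strands %in% c("both", "+")) {
        out$fwd <- scan_one_strand(seq, id, pattern, S, "+")
      }
      if (strands %in% c("both", "-")) {
        rc <- revcomp_iupac(seq)
        minus <- scan_one_strand(rc, id, pattern, S, "-")
        if (nrow(minus) > 0) {
          # map revcomp coordinates back to the forward reference
          minus$spacer_start <- len - (minus$spacer_start + S)
          minus$spacer_end <- minus$spacer_start + S
        }
        out$rev <- minus
      }
    }
    bind_rows(out)
  })
  sites <- bind_rows(hits)
  if (nrow(sites) == 0) {
    return(tibble(
      sequence_id = character(), spacer_start = integer(),
      spacer_end = integer(), strand = character(),
      spacer_seq = character(), pam_seq = character(),
      sgrna_spacer = character(), g_modified = logical()
    ))
  }
  needs_g <- !startsWith(sites$spacer_seq, "G")
  sites$sgrna_spacer <- ifelse(needs_g,
    if (g_rule == "substitute") {
      paste0("G", substr(sites$spacer_seq, 2, S))
    } else {
      paste0("G", sites$spacer_seq)
    },
    sites$spacer_seq)
  sites$g_modified <- needs_g
  sites |>
    mutate(strand = factor(.data$strand, levels = c("+", "-"))) |>
    arrange(.data$sequence_id, .data$spacer_start, .data$strand) |>
    mutate(strand = as.character(.data$strand))
}

# scan one already-oriented sequence; coordinates 0-based half-open in the
# oriented frame (caller remaps for minus strand)
scan_one_strand <- function(seq, id, pattern, S, strand) {
  plen <- length(pattern$sets)
  subj <- Biostrings::DNAString(seq)
  pam_hits <- Biostrings::matchPattern(
    Biostrings::DNAString(pattern$iupac), subj, fixed = FALSE)
  starts <- IRanges::start(pam_hits)   # 1-based PAM starts
  starts <- starts[starts > S]
  if (length(starts) == 0) {
    return(tibble(sequence_id = character(), spacer_start = integer(),
      spacer_end = integer(), strand = character(),
      spacer_seq = character(), pam_seq = character()))
  }
  spacer <- substr(rep(seq, length(starts)), starts - S, starts - 1)
  pam <- substr(rep(seq, length(starts)), starts, starts + plen - 1)
  # N (or other ambiguity) in the reference window: skip, don't wildcard
  keep <- grepl("^[ACGT]+$", spacer) & grepl("^[ACGT]+$", pam)
  tibble(
    sequence_id = id,
    spacer_start = as.integer(starts[keep] - S - 1L),
    spacer_end = as.integer(starts[keep] - 1L),
    strand = strand,
    spacer_seq = spacer[keep],
    pam_seq = pam[keep]
  )
}

# reverse complement preserving ambiguity codes
revcomp_iupac <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

load_sequences <- function(x) {
  if (inherits(x, "DNAStringSet")) {
    s <- as.character(x)
    names(s) <- names(x) %||% paste0("seq_", seq_along(x))
    return(s)
  }
  if (is.character(x) && length(x) == 1 && file.exists(x)) {
    xs <- Biostrings::readDNAStringSet(x)
    s <- as.character(xs)
    names(s) <- sub("\\s.*$", "", names(xs))
    return(s)
  }
  s <- toupper(x)
  names(s) <- names(x) %||% paste0("seq_", seq_along(x))
  s
}

#' Target-site density and its analytic expectation
#'
#' Observed site density per bp over the requested strands, against the
#' closed-form expectation for i.i.d. base composition: per
#' strand-position, `prod_j sum_{b in allowed_j} comp_b`. For N4GYAT under
#' uniform composition this is 1/128 per strand-position (2/128 per bp over
#' both strands). A normal-approximation binomial CI on the observed
#' density is attached.
#'
#' @inheritParams scan_targets
#' @param composition Base composition used for the expectation (A, C, G,
#'   T); default uniform.
#' @return One-row tibble: `n_sites`, `n_positions`, `length_bp`,
#'   `observed_density`, `expected_density` (both per bp over the scanned
#'   strands), `conf_low`, `conf_high`.
#' @export
pam_density <- function(x, pattern = "NNNNGYAT", spacer_length = 24L,
                        strands = "both", composition = rep(0.25, 4)) {
  if (is.character(pattern)) pattern <- compile_pam(pattern)
  composition <- setNames(composition / sum(composition), DNA_BASES)
  per_pos <- prod(vapply(pattern$sets, function(s) {
    sum(composition[s])
  }, numeric(1)))
  sites <- scan_targets(x, pattern, spacer_length = spacer_length,
    strands = strands)
  seqs <- load_sequences(x)
  len <- sum(nchar(seqs))
  nstrand <- if (strands == "both") 2L else 1L
  span <- spacer_length + length(pattern$sets)
  n_positions <- sum(pmax(nchar(seqs) - span + 1, 0)) * nstrand
  n_sites <- nrow(sites)
  obs <- n_sites / len
  phat <- if (n_positions > 0) n_sites / n_positions else NA_real_
  se <- sqrt(phat * (1 - phat) / n_positions)
  tibble(
    n_sites = n_sites,
    n_positions = n_positions,
    length_bp = len,
    observed_density = obs,
    expected_density = per_pos * nstrand,
    conf_low = (phat - 1.96 * se) * n_positions / len,
    conf_high = (phat + 1.96 * se) * n_positions / len
  )
}

#' Write target sites as BED6
#'
#' Name is `spacer_seq|pam_seq`, score 0; coordinates are the spacer's
#' 0-based half-open forward-reference interval.
#'
#' @param sites Tibble from [scan_targets()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(sites, path) {
  bed <- tibble(
    chrom = sites$sequence_id,
    start = sites$spacer_start,
    end = sites$spacer_end,
    name = paste0(sites$spacer_seq, "|", sites$pam_seq),
    score = 0L,
    strand = sites$strand
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}
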