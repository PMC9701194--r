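# Independent brute-force oracles used across tests. These deliberately
# avoid the package's extraction/scanning code paths: plain substring and
# position-by-position logic only.

BASES <- c("A", "C", "G", "T")

rc_chr <- function(x) {
  chartr("ACGT", "TGCA",
    vapply(strsplit(x, "", fixed = TRUE),
      function(s) paste0(rev(s), collapse = ""), character(1)))
}

# exact-substring cassette counter: both anchors verbatim, cassette of the
# designed length between them; tries forward then reverse complement
naive_count_pams <- function(reads, design) {
  L <- design$cassette_length
  up <- design$upstream_anchor
  dn <- design$downstream_anchor
  pull_cassette <- function(r) {
    iu <- regexpr(up, r, fixed = TRUE)
    if (iu < 0) return(NA_character_)
    cs <- iu + nchar(up)
    if (substr(r, cs + L, cs + L + nchar(dn) - 1) != dn) return(NA_character_)
    substr(r, cs, cs + L - 1)
  }
  cas <- vapply(reads, function(r) {
    hit <- pull_cassette(r)
    if (is.na(hit)) hit <- pull_cassette(rc_chr(r))
    hit
  }, character(1), USE.NAMES = FALSE)
  table(cas[!is.na(cas)])
}

# position-by-position target-site matcher on one forward sequence
iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = BASES
)

naive_scan_one <- function(seq, pam, S) {
  pchars <- strsplit(pam, "", fixed = TRUE)[[1]]
  plen <- length(pchars)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hits <- list()
  for (start in seq_len(max(nchar(seq) - S - plen + 1, 0))) {
    win <- chars[start:(start + S + plen - 1)]
    if (any(!win %in% BASES)) next
    pam_win <- win[(S + 1):(S + plen)]
    if (all(mapply(function(b, code) b %in% iupac_sets[[code]],
                   pam_win, pchars))) {
      hits[[length(hits) + 1]] <- list(
        spacer_start = start - 1L,
        spacer_seq = paste0(win[1:S], collapse = ""),
        pam_seq = paste0(pam_win, collapse = "")
      )
    }
  }
  hits
}

# expected indel-filter rejection per simulated read, from simulator truth
# (zone rule: deletions at amplicon positions [u-2, u+L+3], insertions
# before positions [u-1, u+L+3], window 3)
truth_indel_rejected <- function(pool, design, window = 3) {
  u <- nchar(design$upstream_anchor)
  L <- design$cassette_length
  lo_del <- u - window + 1
  lo_ins <- u - window + 2
  hi <- u + L + window
  ifelse(pool$indel == "del",
    pool$indel_pos >= lo_del & pool$indel_pos <= hi,
    ifelse(pool$indel == "ins",
      pool$indel_pos >= lo_ins & pool$indel_pos <= hi,
      FALSE))
}

# small planted activity model used in several end-to-end tests
planted_model <- function() {
  activity_model("table", table = c(
    NNNNGTAT = 1, NNNNGCAT = 0.8, NNNNATAT = 0.3, NNNNGTTT = 0.3))
}
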