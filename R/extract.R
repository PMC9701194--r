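#' Anchor reads and extract the PAM cassette
#'
#' Locates both constant anchors in each read (forward first, then
#' reverse-complement), extracts the cassette between them, and records any
#' alignment gaps as signed distances from the cassette: `d < 0` means
#' `|d|` bases upstream of the cassette start, `d = 0` inside the cassette,
#' `d > 0` bases downstream of the cassette end.
#'
#' Most reads are resolved by an exact/mismatch-only anchor search
#' ([Biostrings::vmatchPattern()]); reads that fail it (i.e. that carry an
#' indel in an anchor) fall back to semi-global gapped alignment
#' ([Biostrings::pairwiseAlignment()], match +1, mismatch -1, gap -2).
#' Anchors exceeding `max_mismatch` substitutions, or 3 gap bases, after
#' alignment make the read a no-anchor failure. Ties between orientations
#' go to the higher-scoring frame, then to forward.
#'
#' @param reads Character vector of read sequences (or a tibble with a
#'   `seq` column, as returned by [read_fastq()]).
#' @param design A [library_design()].
#' @param max_mismatch Maximum substitutions tolerated per anchor
#'   (default 1).
#' @return Tibble with one row per read: `read_id`, `status`
#'   (`"ok"`/`"no_anchor"`), `orientation` (`"+"`/`"-"`), `cassette`
#'   (forward frame), and `gaps` (list column of signed gap distances).
#' @export
anchor_reads <- function(reads, design, max_mismatch = 1L) {
  ids <- NULL
  if (is.data.frame(reads)) {
    ids <- reads$read_id
    reads <- reads$seq
  }
  n <- length(reads)
  ids <- ids %||% paste0("read_", seq_len(n))
  out <- tibble(
    read_id = ids,
    status = rep("no_anchor", n),
    orientation = rep(NA_character_, n),
    cassette = rep(NA_character_, n),
    gaps = vector("list", n)
  )
  if (n == 0) return(out)
  reads <- toupper(reads)
  fwd <- reads
  rev <- revcomp(reads)
  resF <- ungapped_anchor_scan(fwd, design, max_mismatch)
  resR <- ungapped_anchor_scan(rev, design, max_mismatch)
  useF <- resF$ok & (!resR$ok | resF$nmis <= resR$nmis)
  useR <- resR$ok & !useF
  for (o in c("+", "-")) {
    use <- if (o == "+") useF else useR
    res <- if (o == "+") resF else resR
    oriented <- if (o == "+") fwd else rev
    if (!any(use)) next
    i <- which(use)
    cas <- substr(oriented[i], res$up_end[i] + 1, res$down_start[i] - 1)
    out$status[i] <- "ok"
    out$orientation[i] <- o
    out$cassette[i] <- cas
    bad <- i[nchar(cas) != design$cassette_length]
    out$gaps[bad] <- list(0)
  }
  todo <- which(!(useF | useR))
  if (length(todo) > 0) {
    gb <- gapped_anchor_scan(fwd[todo], rev[todo], design, max_mismatch)
    out$status[todo] <- gb$status
    out$orientation[todo] <- gb$orientation
    out$cassette[todo] <- gb$cassette
    out$gaps[todo] <- gb$gaps
  }
  out
}

# mismatch-only anchor placement for a whole pool; returns per-read
# up_end / down_start (NA when not found) and total mismatch count
ungapped_anchor_scan <- function(reads, design, max_mismatch) {
  xs <- Biostrings::DNAStringSet(reads)
  up <- design$upstream_anchor
  dn <- design$downstream_anchor
  su <- Biostrings::startIndex(
    Biostrings::vmatchPattern(up, xs, max.mismatch = max_mismatch))
  sd <- Biostrings::startIndex(
    Biostrings::vmatchPattern(dn, xs, max.mismatch = max_mismatch))
  widths <- nchar(reads)
  # vmatchPattern with mismatches may report out-of-limits matches that
  # overhang the read; keep in-bounds hits only
  up_start <- mapply(function(v, w) {
    if (is.null(v)) return(NA_integer_)
    v <- v[v >= 1 & v + nchar(up) - 1L <= w]
    if (length(v)) v[[1]] else NA_integer_
  }, su, widths)
  up_end <- up_start + nchar(up) - 1L
  down_start <- mapply(function(v, ue, w) {
    if (is.na(ue) || is.null(v)) return(NA_integer_)
    v <- v[v > ue & v + nchar(dn) - 1L <= w]
    if (length(v)) v[[1]] else NA_integer_
  }, sd, up_end, widths)
  ok <- !is.na(up_start) & !is.na(down_start)
  nmis <- rep(NA_real_, length(reads))
  if (any(ok)) {
    i <- which(ok)
    nu <- count_mismatches(
      substr(reads[i], up_start[i], up_end[i]), up)
    nd <- count_mismatches(
      substr(reads[i], down_start[i], down_start[i] + nchar(dn) - 1L), dn)
    nmis[i] <- nu + nd
  }
  list(ok = ok, up_end = up_end, down_start = down_start, nmis = nmis)
}

# vectorized Hamming distance of equal-length strings against one anchor
count_mismatches <- function(x, anchor) {
  if (length(x) == 0) return(integer())
  k <- nchar(anchor)
  m <- matrix(charToRaw(paste0(x, collapse = "")), nrow = k)
  colSums(m != charToRaw(anchor))
}

# gapped fallback: semi-global alignment of each anchor in both frames
gapped_anchor_scan <- function(fwd, rev, design, max_mismatch) {
  n <- length(fwd)
  mat <- Biostrings::nucleotideSubstitutionMatrix(1, -1)
  align <- function(reads, anchor) {
    Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(reads), subject = anchor,
      type = "local-global", substitutionMatrix = mat,
      gapOpening = 0, gapExtension = 2)
  }
  alUF <- align(fwd, design$upstream_anchor)
  alDF <- align(fwd, design$downstream_anchor)
  alUR <- align(rev, design$upstream_anchor)
  alDR <- align(rev, design$downstream_anchor)
  scoreF <- Biostrings::score(alUF) + Biostrings::score(alDF)
  scoreR <- Biostrings::score(alUR) + Biostrings::score(alDR)
  use_fwd <- scoreF >= scoreR
  status <- rep("no_anchor", n)
  orientation <- rep(NA_character_, n)
  cassette <- rep(NA_character_, n)
  gaps <- vector("list", n)
  u_len <- nchar(design$upstream_anchor)
  L <- design$cassette_length
  for (i in seq_len(n)) {
    alU <- if (use_fwd[i]) alUF[i] else alUR[i]
    alD <- if (use_fwd[i]) alDF[i] else alDR[i]
    read <- if (use_fwd[i]) fwd[i] else rev[i]
    gu <- anchor_gap_info(alU)
    gd <- anchor_gap_info(alD)
    up_end <- IRanges::end(Biostrings::pattern(alU))
    down_start <- IRanges::start(Biostrings::pattern(alD))
    ok <- gu$nmis <= max_mismatch && gd$nmis <= max_mismatch &&
      gu$gap_bases <= 3 && gd$gap_bases <= 3 && down_start > up_end
    if (!ok) next
    status[i] <- "ok"
    orientation[i] <- if (use_fwd[i]) "+" else "-"
    cas <- substr(read, up_end + 1, down_start - 1)
    cassette[i] <- cas
    # upstream anchor gaps -> negative distances; downstream -> positive
    d <- c(
      -(u_len - gu$del + 1),   # deletion of anchor base a, a bases from 3' end
      -(u_len - gu$ins + 2),   # insertion preceding anchor base p
      gd$del,                  # deletion of downstream anchor base a
      gd$ins                   # insertion preceding downstream anchor base a
    )
    if (nchar(cas) != L) d <- c(d, 0)
    gaps[[i]] <- d
  }
  list(status = status, orientation = orientation,
       cassette = cassette, gaps = gaps)
}

# per-anchor alignment summary: substitution count, gap base count and the
# anchor-coordinate positions of deletions / insertion points
anchor_gap_info <- function(al) {
  ins <- Biostrings::insertion(al)[[1]]
  del <- Biostrings::deletion(al)[[1]]
  ins_pos <- rep(IRanges::start(ins), IRanges::width(ins))
  del_pos <- unlist(lapply(seq_along(del), function(k) {
    seq(IRanges::start(del)[k], IRanges::end(del)[k])
  }))
  list(
    nmis = Biostrings::nmismatch(al),
    gap_bases = sum(IRanges::width(ins)) + sum(IRanges::width(del)),
    ins = ins_pos,
    del = if (is.null(del_pos)) integer() else del_pos
  )
}

#' Locate the PAM cassette in a single read
#'
#' Single-read convenience wrapper around [anchor_reads()].
#'
#' @param read A single read sequence.
#' @inheritParams anchor_reads
#' @return One-row tibble as from [anchor_reads()].
#' @export
#' @examples
#' d <- library_design()
#' read <- paste0(d$upstream_anchor, "GTACGTAT", d$downstream_anchor)
#' locate_cassette(read, d, max_mismatch = 0)$cassette
locate_cassette <- function(read, design, max_mismatch = 1L) {
  stopifnot(length(read) == 1, nzchar(read))
  anchor_reads(read, design, max_mismatch = max_mismatch)
}

#' Reject reads with indels near the PAM cassette
#'
#' A read fails if any alignment gap (insertion or deletion) lies inside
#' the cassette or within `window` bases of either cassette boundary.
#' Substitutions never trigger this filter.
#'
#' @param anchored Tibble from [anchor_reads()] (rows with
#'   `status != "ok"` are passed through unchanged).
#' @param window Exclusion window in bases around each cassette boundary
#'   (default 3).
#' @return The input tibble with logical column `indel_fail` added.
#' @export
filter_indel_near_pam <- function(anchored, window = 3L) {
  fail <- vapply(anchored$gaps, function(d) {
    length(d) > 0 && any(d == 0 | abs(d) <= window)
  }, logical(1))
  mutate(anchored, indel_fail = .data$status == "ok" & fail)
}

#' Count PAM cassettes from cleaved (and optionally input) FASTQ pools
#'
#' Runs the full extraction pipeline on each pool: anchor location, the
#' indel-near-PAM filter, and an ambiguous-base check on the cassette.
#' Each read is assigned exactly one first-failing category, in the fixed
#' order no-anchor, indel-near-PAM, ambiguous-base, so the filter ledger
#' always partitions the total.
#'
#' @param cleaved FASTQ path, character vector of reads, or tibble with a
#'   `seq` column for the cleaved pool.
#' @param input Same, for the input (pre-selection) pool, or `NULL`; when
#'   absent, downstream normalization falls back to the design's library
#'   bias.
#' @param design A [library_design()].
#' @param max_mismatch Per-anchor substitution tolerance (default 1).
#' @param window Indel exclusion window (default 3).
#' @return An object of class `pam_count_table`: list with tibble `counts`
#'   (`pam`, `count_cleaved` and, if an input pool was given,
#'   `count_input`), `filter` (per-pool ledgers), `design`, and
#'   `background` (`"input-pool"` or `"design-bias"`).
#' @export
count_pams <- function(cleaved, input = NULL, design,
                       max_mismatch = 1L, window = 3L) {
  pool_cleaved <- count_pool(cleaved, design, max_mismatch, window)
  filter <- list(cleaved = pool_cleaved$report)
  counts <- pool_cleaved$counts
  names(counts)[names(counts) == "count"] <- "count_cleaved"
  background <- "design-bias"
  if (!is.null(input)) {
    pool_input <- count_pool(input, design, max_mismatch, window)
    filter$input <- pool_input$report
    ic <- pool_input$counts
    names(ic)[names(ic) == "count"] <- "count_input"
    counts <- dplyr::full_join(counts, ic, by = "pam")
    counts$count_cleaved[is.na(counts$count_cleaved)] <- 0L
    counts$count_input[is.na(counts$count_input)] <- 0L
    counts <- arrange(counts, .data$pam)
    background <- "input-pool"
  }
  structure(
    list(counts = counts, filter = filter, design = design,
         background = background),
    class = "pam_count_table"
  )
}

count_pool <- function(pool, design, max_mismatch, window) {
  if (is.character(pool) && length(pool) == 1 && file.exists(pool)) {
    pool <- read_fastq(pool)
  }
  anchored <- anchor_reads(pool, design, max_mismatch = max_mismatch)
  anchored <- filter_indel_near_pam(anchored, window = window)
  ok <- anchored$status == "ok" & !anchored$indel_fail
  ambiguous <- ok & !grepl("^[ACGT]*$", anchored$cassette)
  passed <- ok & !ambiguous
  report <- tibble(
    n_total = nrow(anchored),
    n_no_anchor = sum(anchored$status != "ok"),
    n_indel_near_pam = sum(anchored$indel_fail),
    n_ambiguous_base = sum(ambiguous),
    n_passed = sum(passed)
  )
  counts <- anchored[passed, ] |>
    count(.data$cassette, name = "count") |>
    dplyr::rename(pam = "cassette") |>
    arrange(.data$pam)
  list(counts = counts, report = report)
}

#' @export
print.pam_count_table <- function(x, ...) {
  cat("<pam_count_table>\n")
  cat("  distinct PAMs:", nrow(x$counts), "\n")
  cat("  cleaved reads passed:", x$filter$cleaved$n_passed, "of",
    x$filter$cleaved$n_total, "\n")
  if (!is.null(x$filter$input)) {
    cat("  input reads passed:  ", x$filter$input$n_passed, "of",
      x$filter$input$n_total, "\n")
  }
  cat("  background:", x$background, "\n")
  invisible(x)
}

#' @describeIn count_pams `tidy()` returns the per-PAM count tibble.
#' @param x A `pam_count_table`.
#' @param ... Unused.
#' @export
tidy.pam_count_table <- function(x, ...) x$counts

#' @describeIn count_pams `glance()` returns the filter ledgers as a
#'   one-row tibble per pool (column `pool`).
#' @export
glance.pam_count_table <- function(x, ...) {
  bind_rows(x$filter, .id = "pool")
}
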