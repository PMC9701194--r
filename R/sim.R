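#' Simulate an excision-reporter PAM library sequencing experiment
#'
#' Generates a cleaved pool (cassette k-mers drawn from the normalized
#' product of library bias and cleavage activity) and an input pool
#' (library bias only), embeds each cassette between the design's constant
#' anchors, and applies a substitution + single-1bp-indel error model. Every
#' source of randomness is governed by `seed`, so identical calls are
#' byte-identical.
#'
#' @param design A [library_design()].
#' @param model An [activity_model()]; must assign positive cleavage mass to
#'   at least one cassette k-mer.
#' @param err An [error_model()].
#' @param n_reads Number of reads to emit per pool.
#' @param seed Integer seed (or `NULL` to use the current RNG state).
#' @param revcomp_frac Fraction of reads emitted reverse-complemented
#'   (default 0).
#' @param n_input Reads in the input pool (default `n_reads`).
#' @param cleaved_path,input_path Optional FASTQ output paths; written when
#'   non-`NULL`.
#' @return A list of class `pamdose_sim` with tibbles `cleaved` and `input`
#'   (columns `read_id`, `seq`, `cassette`, `revcomp`, `indel`, `indel_pos`
#'   — cassette and indel coordinates refer to the error-free forward
#'   amplicon), the ground-truth `truth` tibble from
#'   [expected_cleaved_distribution()], and the `design`/`model`/`err` used.
#' @export
#' @examples
#' d <- library_design()
#' m <- activity_model("table", table = c(NNNNGTAT = 1))
#' sim <- simulate_pamdose(d, m, error_model(0, 0), n_reads = 50, seed = 1)
#' all(endsWith(sim$cleaved$cassette, "GTAT"))
simulate_pamdose <- function(design, model, err = error_model(),
                             n_reads, seed = NULL, revcomp_frac = 0,
                             n_input = n_reads,
                             cleaved_path = NULL, input_path = NULL) {
  stopifnot(inherits(design, "library_design"),
            inherits(model, "activity_model"),
            inherits(err, "error_model"))
  if (n_reads < 1) abort("n_reads must be >= 1")
  truth <- expected_cleaved_distribution(design, model)
  out <- with_seed_if(seed, {
    cleaved_cassettes <- sample(truth$pam, n_reads, replace = TRUE,
      prob = truth$expected_freq)
    input_cassettes <- sample_cassettes(design, n_input)
    list(
      cleaved = emit_pool(cleaved_cassettes, design, err, revcomp_frac, "clv"),
      input = emit_pool(input_cassettes, design, err, revcomp_frac, "inp")
    )
  })
  if (!is.null(cleaved_path)) {
    write_fastq(out$cleaved$seq, cleaved_path, ids = out$cleaved$read_id)
  }
  if (!is.null(input_path)) {
    write_fastq(out$input$seq, input_path, ids = out$input$read_id)
  }
  structure(
    list(cleaved = out$cleaved, input = out$input, truth = truth,
         design = design, model = model, err = err),
    class = "pamdose_sim"
  )
}

# sample cassettes position-by-position from the library bias
sample_cassettes <- function(design, n) {
  L <- design$cassette_length
  cols <- lapply(seq_len(L), function(j) {
    sample(DNA_BASES, n, replace = TRUE, prob = design$library_bias[, j])
  })
  do.call(paste0, cols)
}

emit_pool <- function(cassettes, design, err, revcomp_frac, prefix) {
  n <- length(cassettes)
  amplicon <- paste0(design$upstream_anchor, cassettes,
    design$downstream_anchor)
  ind <- apply_indels(amplicon, err$indel_rate)
  seqs <- apply_substitutions(ind$seqs, err$substitution_rate)
  rc <- runif(n) < revcomp_frac
  if (any(rc)) seqs[rc] <- revcomp(seqs[rc])
  if (!is.null(err$read_length)) {
    pad <- err$read_length - nchar(seqs)
    if (any(pad < 0)) abort("read_length shorter than the amplicon")
    topad <- which(pad > 0)
    if (length(topad) > 0) {
      seqs[topad] <- paste0(seqs[topad],
        random_dna(length(topad), pad[topad]))
    }
  }
  tibble(
    read_id = paste0(prefix, "_", seq_len(n)),
    seq = seqs,
    cassette = cassettes,
    revcomp = rc,
    indel = ind$indel,
    indel_pos = ind$indel_pos
  )
}

# one 1-bp insertion or deletion per flagged read, uniform position.
# indel_pos is in error-free amplicon coordinates: for "del" the index of
# the removed base, for "ins" the index of the base the insert precedes
# (len + 1 = appended at the end).
apply_indels <- function(seqs, rate) {
  n <- length(seqs)
  hit <- runif(n) < rate
  indel <- rep("none", n)
  indel_pos <- rep(NA_integer_, n)
  for (i in which(hit)) {
    len <- nchar(seqs[i])
    if (runif(1) < 0.5) {
      p <- sample.int(len, 1)
      seqs[i] <- paste0(substr(seqs[i], 1, p - 1),
        substr(seqs[i], p + 1, len))
      indel[i] <- "del"
    } else {
      p <- sample.int(len + 1, 1)
      seqs[i] <- paste0(substr(seqs[i], 1, p - 1),
        sample(DNA_BASES, 1),
        substr(seqs[i], p, len))
      indel[i] <- "ins"
    }
    indel_pos[i] <- p
  }
  list(seqs = seqs, indel = indel, indel_pos = indel_pos)
}

# i.i.d. per-base substitutions; a substituted base is replaced by one of
# the three other bases uniformly
apply_substitutions <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  lens <- nchar(seqs)
  total <- sum(lens)
  hits <- which(runif(total) < rate)
  if (length(hits) == 0) return(seqs)
  read_of <- rep.int(seq_along(seqs), lens)
  offset <- c(0, cumsum(lens))[seq_along(seqs)]
  for (h in hits) {
    i <- read_of[h]
    p <- h - offset[i]
    old <- substr(seqs[i], p, p)
    new <- sample(setdiff(DNA_BASES, old), 1)
    substr(seqs[i], p, p) <- new
  }
  seqs
}

#' Simulate fluorescent-reporter flow-cytometry events
#'
#' Models the tdTomato/EGFP switch reporter: every transfected cell is
#' red-positive, and a Bernoulli(`edit_prob`) subset is additionally
#' green-positive (edited). Channel intensities are Gaussian with the given
#' means/sds.
#'
#' @param n_cells Number of cells (rows); must be >= 1.
#' @param edit_prob Probability a cell is edited (green-positive).
#' @param intensity_params Named list with numeric `c(mean, sd)` entries
#'   `green_pos`, `green_neg`, `red`.
#' @param seed Integer seed or `NULL`.
#' @return Tibble with columns `cell_id`, `green`, `red` and the
#'   ground-truth logical `label` (edited or not).
#' @export
simulate_reporter_events <- function(n_cells, edit_prob,
                                     intensity_params = list(
                                       green_pos = c(3000, 400),
                                       green_neg = c(100, 50),
                                       red = c(5000, 500)
                                     ),
                                     seed = NULL) {
  if (n_cells < 1) abort("n_cells must be >= 1")
  if (edit_prob < 0 || edit_prob > 1) abort("edit_prob must lie in [0, 1]")
  p <- intensity_params
  with_seed_if(seed, {
    edited <- runif(n_cells) < edit_prob
    green <- ifelse(edited,
      rnorm(n_cells, p$green_pos[1], p$green_pos[2]),
      rnorm(n_cells, p$green_neg[1], p$green_neg[2]))
    tibble(
      cell_id = paste0("cell_", seq_len(n_cells)),
      green = green,
      red = rnorm(n_cells, p$red[1], p$red[2]),
      label = edited
    )
  })
}

#' Simulate a base-editing conversion pileup
#'
#' Per spacer position, draws converted-read counts as
#' Binomial(`depth`, rate).
#'
#' @param rates Per-position conversion probabilities (length = spacer
#'   length); positions are numbered from the 5' (PAM-distal) end.
#' @param depth Read depth per position.
#' @param seed Integer seed or `NULL`.
#' @return Tibble with columns `position`, `converted`, `depth`.
#' @export
#' @examples
#' simulate_base_edit_pileup(rep(0, 24), depth = 100, seed = 1)
simulate_base_edit_pileup <- function(rates, depth, seed = NULL) {
  if (length(rates) < 1) abort("rates must have length >= 1 (spacer length)")
  if (any(rates < 0 | rates > 1)) abort("rates must lie in [0, 1]")
  if (depth < 1) abort("depth must be >= 1")
  with_seed_if(seed, {
    tibble(
      position = seq_along(rates),
      converted = rbinom(length(rates), depth, rates),
      depth = depth
    )
  })
}

#' Write a simulated ground-truth table to TSV
#'
#' Columns `pam`, `activity`, `expected_freq`.
#'
#' @param sim A `pamdose_sim` object (or a truth tibble).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(sim, path) {
  truth <- if (inherits(sim, "pamdose_sim")) sim$truth else sim
  readr::write_tsv(truth[, c("pam", "activity", "expected_freq")], path)
  invisible(path)
}

#' @export
print.pamdose_sim <- function(x, ...) {
  cat("<pamdose_sim>\n")
  cat("  cleaved reads:", nrow(x$cleaved), "\n")
  cat("  input reads:  ", nrow(x$input), "\n")
  cat("  active PAMs:  ", sum(x$truth$activity > 0), "of",
    nrow(x$truth), "\n")
  invisible(x)
}
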