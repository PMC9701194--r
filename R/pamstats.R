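#' Per-PAM enrichment of the cleaved pool over background
#'
#' Computes `e(pam) = freq_cleaved(pam) / freq_background(pam)` with a
#' shared pseudocount: frequencies are `(count + alpha) / sum(count +
#' alpha)` over the complete cassette k-mer space. Background is the input
#' pool when the table has one, otherwise the design's library bias.
#'
#' @param table A [count_pams()] result, or a tibble with columns `pam`,
#'   `count_cleaved` and optionally `count_input`.
#' @param pseudocount Pseudocount `alpha >= 0` (default 1).
#' @param design Required when `table` is a bare tibble without input
#'   counts, to supply the bias background.
#' @return Tibble with columns `pam`, `enrichment` over all cassette
#'   k-mers, plus attributes `pseudocount` and `background`.
#' @export
pam_enrichment <- function(table, pseudocount = 1, design = NULL) {
  if (pseudocount < 0) abort("pseudocount must be >= 0")
  if (inherits(table, "pam_count_table")) {
    design <- table$design
    counts <- table$counts
    background <- table$background
  } else {
    counts <- table
    background <- if ("count_input" %in% names(counts)) {
      "input-pool"
    } else {
      "design-bias"
    }
  }
  if (sum(counts$count_cleaved) == 0) {
    abort("cleaved pool is empty; cannot compute enrichment")
  }
  L <- nchar(counts$pam[1])
  pams <- all_kmers(L)
  cl <- setNames(rep(0, length(pams)), pams)
  cl[counts$pam] <- counts$count_cleaved
  f_cl <- (cl + pseudocount) / sum(cl + pseudocount)
  if (background == "input-pool") {
    inp <- setNames(rep(0, length(pams)), pams)
    inp[counts$pam] <- counts$count_input
    f_bg <- (inp + pseudocount) / sum(inp + pseudocount)
  } else {
    if (is.null(design)) abort("design needed for design-bias background")
    f_bg <- design_bias_prob(design, pams)
  }
  # absent from the cleaved pool -> 0 regardless of background; positive
  # cleaved mass over a zero background is undefined
  e <- ifelse(f_cl == 0, 0, ifelse(f_bg > 0, f_cl / f_bg, NA_real_))
  out <- tibble(pam = pams, enrichment = unname(e))
  attr(out, "pseudocount") <- pseudocount
  attr(out, "background") <- background
  out
}

#' Average enrichment by cassette suffix
#'
#' Averages per-PAM enrichment over all prefixes sharing the same last-`k`
#' bases — e.g. with `k = 4` this ranks the "N4 + suffix" PAM families
#' (GTAT vs GCAT vs ...).
#'
#' @param scores Tibble from [pam_enrichment()].
#' @param k Suffix length (default 4).
#' @return Tibble `suffix`, `mean_enrichment`, sorted decreasing.
#' @export
suffix_enrichment <- function(scores, k = 4L) {
  scores |>
    mutate(suffix = stringr::str_sub(.data$pam, -k)) |>
    group_by(.data$suffix) |>
    summarise(mean_enrichment = mean(.data$enrichment), .groups = "drop") |>
    arrange(dplyr::desc(.data$mean_enrichment))
}

#' Build a position probability matrix from PAM counts or enrichments
#'
#' `p[j, b]` is proportional to the summed weight of all cassette k-mers
#' with base `b` at position `j`, plus a pseudocount, with columns
#' normalized to 1. Weights are raw cleaved-pool counts (the default,
#' matching a counted-PAMs logo) or enrichment scores.
#'
#' @param x A [count_pams()] result, a tibble with `pam` +
#'   `count_cleaved`/`count` columns, or a [pam_enrichment()] tibble.
#' @param weighting `"raw-count"` or `"enrichment-weighted"`.
#' @param pseudocount Per-base pseudocount added to each cell. Default
#'   0.01 * total weight / 4.
#' @return Tibble of class `pam_ppm` with columns `position`, `A`, `C`,
#'   `G`, `T`; each row sums to 1.
#' @export
build_ppm <- function(x, weighting = c("raw-count", "enrichment-weighted"),
                      pseudocount = NULL) {
  weighting <- match.arg(weighting)
  if (inherits(x, "pam_count_table")) x <- x$counts
  wcol <- if (weighting == "raw-count") {
    intersect(c("count_cleaved", "count"), names(x))[1]
  } else {
    "enrichment"
  }
  if (is.na(wcol) || !wcol %in% names(x)) {
    abort(paste0("no '", wcol %||% "count", "' column for weighting mode '",
      weighting, "'"))
  }
  w <- x[[wcol]]
  if (any(w < 0, na.rm = TRUE)) abort("weights must be non-negative")
  w[is.na(w)] <- 0
  pseudocount <- pseudocount %||% (0.01 * sum(w) / 4)
  if (sum(w) + pseudocount <= 0) {
    abort("all-zero weight with zero pseudocount")
  }
  mat <- kmer_matrix(x$pam)
  L <- ncol(mat)
  p <- matrix(0, nrow = L, ncol = 4, dimnames = list(NULL, DNA_BASES))
  for (j in seq_len(L)) {
    tot <- vapply(DNA_BASES, function(b) sum(w[mat[, j] == b]), numeric(1))
    tot <- tot + pseudocount
    p[j, ] <- tot / sum(tot)
  }
  out <- as_tibble(p)
  out <- mutate(out, position = seq_len(L), .before = 1)
  class(out) <- c("pam_ppm", class(out))
  attr(out, "weighting") <- weighting
  attr(out, "pseudocount") <- pseudocount
  out
}

ppm_matrix <- function(ppm) {
  as.matrix(ppm[, DNA_BASES])
}

#' Per-position information content (logo heights)
#'
#' `IC[j] = sum_b p[j,b] * log2(p[j,b] / q_b)` with `0 * log 0 := 0`; for a
#' uniform background this is `2 + sum_b p log2 p`, bounded in \[0, 2\]
#' bits.
#'
#' @param ppm A [build_ppm()] result (or plain matrix/tibble with columns
#'   A, C, G, T).
#' @param background Background base distribution `q` (A, C, G, T); must be
#'   strictly positive. Default uniform.
#' @return Tibble with columns `position`, `ic` (bits).
#' @export
information_content <- function(ppm, background = rep(0.25, 4)) {
  if (length(background) != 4 || any(background <= 0)) {
    abort("background must be a strictly positive length-4 distribution")
  }
  background <- background / sum(background)
  p <- ppm_matrix(ppm)
  ic <- apply(p, 1, function(row) {
    nz <- row > 0
    sum(row[nz] * log2(row[nz] / background[nz]))
  })
  tibble(position = seq_len(nrow(p)), ic = ic)
}

#' Call a degenerate IUPAC consensus from a position probability matrix
#'
#' Per position, every base with probability `>= threshold` is included
#' (plus always the argmax base, so the set is never empty) and the
#' included set is written as its IUPAC code; all four bases included
#' gives N.
#'
#' Probabilities estimated from counts carry multinomial noise, so a
#' uniform column (true p = 0.25) would otherwise straddle the default
#' threshold at random; the comparison therefore allows a small boundary
#' tolerance `tol` (include when `p >= threshold - tol`). The default
#' 0.005 exceeds the sampling noise of any column estimated from more than
#' a few thousand reads while staying far from the gaps that separate
#' genuinely preferred from disfavoured bases. Exact ties at the
#' threshold are included.
#'
#' @inheritParams information_content
#' @param threshold Inclusion threshold `t`, `0 < t <= 0.5`.
#' @param tol Boundary tolerance for the inclusion comparison
#'   (default 0.005).
#' @return Object of class `pam_consensus`: the IUPAC string with
#'   attributes `threshold` and `included` (list of base sets).
#' @export
#' @examples
#' # a column split 50/45 between T and C at threshold 0.25 reads as Y
call_consensus <- function(ppm, threshold = 0.25, tol = 0.005) {
  if (threshold <= 0 || threshold > 0.5) {
    abort("threshold must lie in (0, 0.5]")
  }
  p <- ppm_matrix(ppm)
  sets <- apply(p, 1, function(row) {
    keep <- DNA_BASES[row >= threshold - tol]
    if (length(keep) == 0) keep <- DNA_BASES[which.max(row)]
    keep
  }, simplify = FALSE)
  codes <- vapply(sets, function(s) {
    IUPAC_BY_SET[[paste0(sort(s), collapse = "")]]
  }, character(1))
  structure(paste0(codes, collapse = ""),
    threshold = threshold, included = sets, class = "pam_consensus")
}

#' @export
print.pam_consensus <- function(x, ...) {
  cat("<pam_consensus> ", unclass(x), "  (threshold ",
    attr(x, "threshold"), ")\n", sep = "")
  invisible(x)
}

#' @export
as.character.pam_consensus <- function(x, ...) unclass(x)[1]

#' Pairwise positional dependence (mutual information) of PAM counts
#'
#' `MI[j, k]` in bits from the cleaved-pool joint base frequencies of
#' cassette positions `j` and `k`; the diagonal holds the positional
#' entropy. Near-zero off-diagonal MI indicates a position-independent
#' logo is an adequate summary.
#'
#' @inheritParams pam_enrichment
#' @return Tibble with columns `pos_i`, `pos_j`, `mi` (bits), symmetric.
#' @export
positional_dependence <- function(table) {
  if (inherits(table, "pam_count_table")) table <- table$counts
  wcol <- intersect(c("count_cleaved", "count"), names(table))[1]
  w <- table[[wcol]]
  if (sum(w) < 1) abort("need at least one counted read")
  mat <- kmer_matrix(table$pam)
  L <- ncol(mat)
  marg <- lapply(seq_len(L), function(j) {
    p <- vapply(DNA_BASES, function(b) sum(w[mat[, j] == b]), numeric(1))
    p / sum(p)
  })
  res <- expand.grid(pos_i = seq_len(L), pos_j = seq_len(L))
  res$mi <- mapply(function(j, k) {
    if (j == k) {
      p <- marg[[j]]
      nz <- p > 0
      return(-sum(p[nz] * log2(p[nz])))
    }
    joint <- matrix(0, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
    for (a in DNA_BASES) for (b in DNA_BASES) {
      joint[a, b] <- sum(w[mat[, j] == a & mat[, k] == b])
    }
    joint <- joint / sum(joint)
    ind <- outer(marg[[j]], marg[[k]])
    nz <- joint > 0
    sum(joint[nz] * log2(joint[nz] / ind[nz]))
  }, res$pos_i, res$pos_j)
  as_tibble(res)
}

#' Full PAM specificity profile
#'
#' One-call wrapper running enrichment, the position probability matrix,
#' information content and consensus calling on a PAM count table.
#'
#' @inheritParams pam_enrichment
#' @inheritParams build_ppm
#' @inheritParams call_consensus
#' @return Object of class `pam_profile`: list with `scores`, `ppm`, `ic`,
#'   `consensus`, and the source `table`.
#' @export
pam_profile <- function(table, weighting = "raw-count",
                        pseudocount = NULL, enrichment_pseudocount = 1,
                        threshold = 0.25, tol = 0.005) {
  scores <- pam_enrichment(table, pseudocount = enrichment_pseudocount)
  ppm_source <- if (weighting == "enrichment-weighted") scores else table
  ppm <- build_ppm(ppm_source, weighting = weighting,
    pseudocount = pseudocount)
  ic <- information_content(ppm)
  consensus <- call_consensus(ppm, threshold = threshold, tol = tol)
  structure(
    list(scores = scores, ppm = ppm, ic = ic, consensus = consensus,
         table = table),
    class = "pam_profile"
  )
}

#' @export
print.pam_profile <- function(x, ...) {
  cat("<pam_profile>\n")
  cat("  consensus:", as.character(x$consensus),
    " (threshold", attr(x$consensus, "threshold"), ")\n")
  cat("  max IC:", round(max(x$ic$ic), 3), "bits at position",
    x$ic$position[which.max(x$ic$ic)], "\n")
  invisible(x)
}

#' @describeIn pam_profile `tidy()` returns a per-position tibble with the
#'   base probabilities and information content.
#' @param x A `pam_profile`.
#' @param ... Unused.
#' @export
tidy.pam_profile <- function(x, ...) {
  left_join(as_tibble(x$ppm), x$ic, by = "position")
}

#' @describeIn pam_profile `glance()` returns a one-row summary
#'   (consensus, threshold, max/total IC).
#' @export
glance.pam_profile <- function(x, ...) {
  tibble(
    consensus = as.character(x$consensus),
    threshold = attr(x$consensus, "threshold"),
    max_ic = max(x$ic$ic),
    total_ic = sum(x$ic$ic)
  )
}

#' Per-position, per-base logo heights
#'
#' The numeric contract behind a sequence logo: each base's height is its
#' probability times the position's information content.
#'
#' @inheritParams information_content
#' @return Tibble `position`, `base`, `prob`, `height` (bits).
#' @export
logo_heights <- function(ppm, background = rep(0.25, 4)) {
  ic <- information_content(ppm, background)
  as_tibble(ppm) |>
    tidyr::pivot_longer(dplyr::all_of(DNA_BASES),
      names_to = "base", values_to = "prob") |>
    left_join(ic, by = "position") |>
    mutate(height = .data$prob * .data$ic) |>
    select("position", "base", "prob", "height")
}
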