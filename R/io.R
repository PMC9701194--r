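#' Write a PAM count table to TSV (plus a JSON filter ledger)
#'
#' TSV columns are `pam`, `count_cleaved` and (when an input pool exists)
#' `count_input`. The per-pool filter ledgers and the background source go
#' to `<path>.filter.json`.
#'
#' @param table A [count_pams()] result.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_pam_counts <- function(table, path) {
  stopifnot(inherits(table, "pam_count_table"))
  readr::write_tsv(table$counts, path)
  meta <- list(
    background = table$background,
    filter = lapply(table$filter, as.list)
  )
  jsonlite::write_json(meta, paste0(path, ".filter.json"),
    auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a PAM count table written by [write_pam_counts()]
#'
#' @param path TSV path; `<path>.filter.json` is read back when present.
#' @param design The [library_design()] the counts refer to.
#' @return A `pam_count_table`.
#' @export
read_pam_counts <- function(path, design) {
  counts <- readr::read_tsv(path, show_col_types = FALSE)
  meta_path <- paste0(path, ".filter.json")
  background <- if ("count_input" %in% names(counts)) {
    "input-pool"
  } else {
    "design-bias"
  }
  filter <- list()
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path)
    background <- meta$background %||% background
    filter <- lapply(meta$filter, function(f) as_tibble(f))
  }
  structure(
    list(counts = counts, filter = filter, design = design,
         background = background),
    class = "pam_count_table"
  )
}

#' Read a library design from YAML
#'
#' Expected keys: `upstream_anchor`, `downstream_anchor`,
#' `cassette_length` (optional), `library_bias` (optional 4 x L matrix as
#' list of rows A, C, G, T).
#'
#' @param path YAML path.
#' @return A [library_design()].
#' @export
read_design_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  bias <- NULL
  if (!is.null(y$library_bias)) {
    bias <- do.call(rbind, lapply(y$library_bias, unlist))
    rownames(bias) <- DNA_BASES
  }
  library_design(
    upstream_anchor = y$upstream_anchor,
    downstream_anchor = y$downstream_anchor,
    cassette_length = y$cassette_length %||% 8L,
    library_bias = bias
  )
}
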