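test_that("compile_pam expands IUPAC codes and names bad positions", {
  p <- compile_pam("NNNNGYAT")
  expect_equal(p$sets[[6]], c("C", "T"))
  expect_equal(p$sets[[5]], "G")
  expect_equal(compile_pam("NNNNGATT")$sets[[5]], "G")
  expect_error(compile_pam("NNXNGYAT"), "position 3")
  expect_error(compile_pam(""), "non-empty")
})

test_that("scan_targets finds a constructed site on both strands", {
  spacer <- "GACGTACGTACGTACGTACGTACG"  # 24 nt, starts with G
  seq <- paste0(spacer, "AAAAGTAT")
  hits <- scan_targets(c(chr = seq), "NNNNGYAT")
  expect_equal(nrow(hits), 1)
  expect_equal(hits$strand, "+")
  expect_equal(hits$spacer_seq, spacer)
  expect_equal(hits$pam_seq, "AAAAGTAT")
  expect_equal(c(hits$spacer_start, hits$spacer_end), c(0, 24))
  expect_equal(hits$sgrna_spacer, spacer)  # already starts with G
  expect_false(hits$g_modified)
  # same site from the reverse complement, on the minus strand
  rc_hits <- scan_targets(c(chr = rc_chr(seq)), "NNNNGYAT")
  expect_equal(nrow(rc_hits), 1)
  expect_equal(rc_hits$strand, "-")
  expect_equal(rc_hits$spacer_seq, spacer)
  expect_equal(rc_hits$pam_seq, "AAAAGTAT")
})

test_that("the 5'-G rule substitutes by default and can prepend", {
  spacer <- paste0("A", substr("GACGTACGTACGTACGTACGTACG", 2, 24))
  seq <- paste0(spacer, "AAAAGTAT")
  sub <- scan_targets(c(chr = seq), "NNNNGYAT", g_rule = "substitute")
  expect_equal(nchar(sub$sgrna_spacer), 24)
  expect_equal(sub$sgrna_spacer, paste0("G", substr(spacer, 2, 24)))
  expect_true(sub$g_modified)
  pre <- scan_targets(c(chr = seq), "NNNNGYAT", g_rule = "prepend")
  expect_equal(nchar(pre$sgrna_spacer), 25)
  expect_equal(pre$sgrna_spacer, paste0("G", spacer))
})

test_that("overlapping sites are all reported and N windows skipped", {
  # two overlapping GYAT PAMs four bases apart
  core <- paste0(strrep("AC", 14), "GTATGTAT")
  hits <- scan_targets(c(x = core), "NNNNGYAT", strands = "+")
  expect_equal(nrow(hits), 2)
  # an N inside the would-be spacer suppresses the site
  seqN <- paste0("GACGTACGTACGNACGTACGTACG", "AAAAGTAT")
  expect_equal(nrow(scan_targets(c(x = seqN), "NNNNGYAT")), 0)
  # soft-masked lowercase is matched
  seql <- tolower(paste0("GACGTACGTACGTACGTACGTACG", "AAAAGTAT"))
  expect_equal(nrow(scan_targets(c(x = seql), "NNNNGYAT")), 1)
})

test_that("scanning matches the naive matcher on random sequence", {
  set.seed(23)
  seq <- paste0(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = "")
  hits <- scan_targets(c(chr1 = seq), "NNNNGYAT", strands = "+")
  oracle <- naive_scan_one(seq, "NNNNGYAT", 24)
  expect_equal(nrow(hits), length(oracle))
  expect_equal(hits$spacer_start,
    vapply(oracle, `[[`, integer(1), "spacer_start"))
  expect_equal(hits$spacer_seq,
    vapply(oracle, `[[`, character(1), "spacer_seq"))
  expect_equal(hits$pam_seq,
    vapply(oracle, `[[`, character(1), "pam_seq"))
  # minus strand via the oracle run on the reverse complement
  minus <- scan_targets(c(chr1 = seq), "NNNNGYAT", strands = "-")
  oracle_rc <- naive_scan_one(rc_chr(seq), "NNNNGYAT", 24)
  expect_equal(nrow(minus), length(oracle_rc))
  expect_equal(sort(minus$spacer_seq),
    sort(vapply(oracle_rc, `[[`, character(1), "spacer_seq")))
})

test_that("scanning a sequence and its reverse complement are in bijection", {
  set.seed(29)
  seq <- paste0(sample(c("A", "C", "G", "T"), 1500, TRUE), collapse = "")
  len <- nchar(seq)
  a <- scan_targets(c(s = seq), "NNNNGYAT")
  b <- scan_targets(c(s = rc_chr(seq)), "NNNNGYAT")
  expect_equal(nrow(a), nrow(b))
  # each site maps to one with mirrored coordinates, swapped strand and
  # identical targeted-strand sequences
  key_a <- paste(a$spacer_start, a$spacer_end, a$strand,
    a$spacer_seq, a$pam_seq)
  key_b <- paste(len - b$spacer_end, len - b$spacer_start,
    c("-", "+")[match(b$strand, c("+", "-"))],
    b$spacer_seq, b$pam_seq)
  expect_setequal(key_a, key_b)
})

test_that("too-short sequences give an empty result, not an error", {
  expect_equal(nrow(scan_targets(c(x = "ACGTACGT"), "NNNNGYAT")), 0)
})

test_that("density expectation matches the closed forms", {
  d1 <- pam_density(c(x = strrep("A", 200)), "NNNNGYAT", strands = "+")
  expect_equal(d1$expected_density, 1 / 128)
  d2 <- pam_density(c(x = strrep("A", 200)), "NNNNCC",
    spacer_length = 24, strands = "+")
  expect_equal(d2$expected_density, 1 / 16)
  dboth <- pam_density(c(x = strrep("A", 200)), "NNNNGYAT", strands = "both")
  expect_equal(dboth$expected_density, 2 / 128)
})

test_that("observed density on random sequence is near its expectation", {
  set.seed(101)
  seq <- paste0(sample(c("A", "C", "G", "T"), 1e5, TRUE), collapse = "")
  d <- pam_density(c(g = seq), "NNNNGYAT", strands = "both")
  p <- 1 / 128
  se <- sqrt(p * (1 - p) / d$n_positions)
  expect_lt(abs(d$n_sites / d$n_positions - p), 3 * se)
})

test_that("BED output is six-column with spacer coordinates", {
  seq <- paste0("GACGTACGTACGTACGTACGTACG", "AAAAGTAT")
  hits <- scan_targets(c(chr = seq), "NNNNGYAT")
  path <- tempfile(fileext = ".bed")
  write_sites_bed(hits, path)
  bed <- read.delim(path, header = FALSE)
  expect_equal(ncol(bed), 6)
  expect_equal(bed$V2, 0)
  expect_equal(bed$V3, 24)
  expect_equal(bed$V6, "+")
})
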