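test_that("enrichment is the ratio of pseudocounted pool frequencies", {
  # 2-mer space keeps the arithmetic inspectable
  counts <- tibble::tibble(
    pam = c("AA", "AC", "AG"),
    count_cleaved = c(2, 49, 49),
    count_input = c(1, 49, 50)
  )
  e <- pam_enrichment(counts, pseudocount = 0)
  get <- function(p) e$enrichment[e$pam == p]
  expect_equal(get("AA"), (2 / 100) / (1 / 100))  # 2.0
  expect_equal(get("AT"), 0)                      # absent from cleaved
  # identical distributions -> e = 1 everywhere observed
  same <- tibble::tibble(pam = c("AA", "CC"), count_cleaved = c(3, 7),
    count_input = c(3, 7))
  e2 <- pam_enrichment(same, pseudocount = 0)
  expect_equal(e2$enrichment[e2$pam %in% c("AA", "CC")], c(1, 1))
  expect_error(
    pam_enrichment(tibble::tibble(pam = "AA", count_cleaved = 0,
      count_input = 5), pseudocount = 0),
    "empty")
})

test_that("design-bias background is used when no input pool exists", {
  d <- library_design(cassette_length = 2)
  counts <- tibble::tibble(pam = "GT", count_cleaved = 10)
  e <- pam_enrichment(counts, pseudocount = 0, design = d)
  # all mass on GT: freq 1 against bias 1/16
  expect_equal(e$enrichment[e$pam == "GT"], 16)
})

test_that("PPM columns tally weights and always sum to one", {
  counts <- tibble::tibble(
    pam = c("GAAAA", "GCCCC", "GGGGG"),
    count_cleaved = c(5, 3, 2)
  )
  ppm <- build_ppm(counts, pseudocount = 0)
  m <- as.matrix(ppm[, c("A", "C", "G", "T")])
  expect_equal(unname(m[1, "G"]), 1)          # only G seen at position 1
  expect_equal(unname(rowSums(m)), rep(1, 5))
  # zero counts with pseudocount 1 -> uniform columns
  z <- tibble::tibble(pam = c("AA", "CC"), count_cleaved = c(0, 0))
  mu <- as.matrix(build_ppm(z, pseudocount = 1)[, c("A", "C", "G", "T")])
  expect_equal(unname(mu), matrix(0.25, 2, 4))
  expect_error(build_ppm(z, pseudocount = 0), "all-zero")
})

test_that("PPM equals a hand-computed tally on a small mixed table", {
  counts <- tibble::tibble(
    pam = c("AAG", "ACG", "CAG", "CCT", "GTA", "TTA"),
    count_cleaved = c(4, 2, 1, 1, 1, 1)
  )
  ppm <- build_ppm(counts, pseudocount = 0)
  m <- as.matrix(ppm[, c("A", "C", "G", "T")])
  # brute-force tally oracle
  mat <- do.call(rbind, strsplit(counts$pam, ""))
  w <- counts$count_cleaved
  for (j in 1:3) {
    for (b in c("A", "C", "G", "T")) {
      expect_equal(unname(m[j, b]), sum(w[mat[, j] == b]) / sum(w),
        label = paste("pos", j, "base", b))
    }
  }
})

test_that("pseudocount shrinks the PPM toward uniform, never past it", {
  counts <- tibble::tibble(pam = c("GG", "GT"), count_cleaved = c(7, 3))
  alphas <- c(0, 0.5, 2, 10, 1e4)
  g1 <- sapply(alphas, function(a) {
    as.matrix(build_ppm(counts, pseudocount = a)[, c("A", "C", "G", "T")])[1, "G"]
  })
  # p(G at 1) starts at 1, decreases monotonically, stays >= 0.25
  expect_equal(unname(g1[1]), 1)
  expect_true(all(diff(g1) < 0))
  expect_true(all(g1 >= 0.25))
})

test_that("information content reproduces the analytic identities", {
  ppm <- tibble::tibble(position = 1:3,
    A = c(0.25, 1, 0.5), C = c(0.25, 0, 0.5),
    G = c(0.25, 0, 0), T = c(0.25, 0, 0))
  ic <- information_content(ppm)
  expect_equal(ic$ic, c(0, 2, 1))
  expect_error(information_content(ppm, background = c(0.5, 0.5, 0, 0)),
    "positive")
  # non-uniform background: IC is relative entropy, not bounded by 2
  ic2 <- information_content(ppm[2, ], background = c(0.1, 0.3, 0.3, 0.3))
  expect_equal(ic2$ic, log2(1 / 0.1))
})

test_that("consensus encodes the included base set as IUPAC", {
  ppm <- tibble::tibble(position = 1:3,
    A = c(0.04, 0.03, 0.25), C = c(0.03, 0.45, 0.25),
    G = c(0.90, 0.02, 0.25), T = c(0.03, 0.50, 0.25))
  cons <- call_consensus(ppm, threshold = 0.25)
  expect_equal(as.character(cons), "GYN")
  # the argmax base is always included even under an extreme threshold
  skew <- tibble::tibble(position = 1, A = 0.4, C = 0.3, G = 0.2, T = 0.1)
  expect_equal(as.character(call_consensus(skew, threshold = 0.5)), "A")
  expect_error(call_consensus(ppm, threshold = 0.7), "threshold")
  expect_error(call_consensus(ppm, threshold = 0), "threshold")
})

test_that("positional dependence recovers coupling and independence", {
  # perfectly coupled positions: 1 bit everywhere, entropy on the diagonal
  coupled <- tibble::tibble(
    pam = c("AAAAAAAA", "CCCCCCCC"), count_cleaved = c(1, 1))
  mi <- positional_dependence(coupled)
  expect_equal(mi$mi, rep(1, 64))
  # a copied position carries the full entropy of its source
  copied <- tibble::tibble(pam = c("AA", "CC", "GG", "AA"),
    count_cleaved = c(3, 1, 1, 1))
  mi2 <- positional_dependence(copied)
  h1 <- mi2$mi[mi2$pos_i == 1 & mi2$pos_j == 1]
  expect_equal(mi2$mi[mi2$pos_i == 1 & mi2$pos_j == 2], h1)
  # independently filled positions: off-diagonal MI stays near zero
  set.seed(41)
  pams <- replicate(5000, paste0(
    sample(c("A", "C", "G", "T"), 4, replace = TRUE), collapse = ""))
  tab <- dplyr::count(tibble::tibble(pam = pams), pam,
    name = "count_cleaved")
  mi3 <- positional_dependence(tab)
  offdiag <- mi3$mi[mi3$pos_i != mi3$pos_j]
  expect_lt(max(offdiag), 0.02)
})

test_that("logo heights are probability times information content", {
  ppm <- tibble::tibble(position = 1:2, A = c(1, 0.5), C = c(0, 0.5),
    G = c(0, 0), T = c(0, 0))
  lh <- logo_heights(ppm)
  expect_equal(lh$height[lh$position == 1 & lh$base == "A"], 2)
  expect_equal(lh$height[lh$position == 2 & lh$base == "A"], 0.5)
  expect_equal(sum(lh$height[lh$position == 2]), 1)
})

test_that("suffix enrichment averages families over their prefixes", {
  e <- tibble::tibble(
    pam = c("AAGT", "ACGT", "AATT", "ACTT"),
    enrichment = c(4, 2, 1, 1))
  s <- suffix_enrichment(e, k = 2)
  expect_equal(s$suffix, c("GT", "TT"))
  expect_equal(s$mean_enrichment, c(3, 1))
})
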