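test_that("canonical 4-mer enumerations have the stated capacities", {
  expect_equal(length(enumerate_4mers(aa_alphabet())), 160000)
  expect_equal(length(enumerate_4mers(code_alphabet())), 2401)
})

test_that("rank and unrank are inverse bijections over both alphabets", {
  codes <- enumerate_4mers(code_alphabet())
  expect_identical(code4_rank(codes), 0:2400)
  expect_identical(code4_unrank(0:2400), codes)
  # sequence side: full round trip on ranks, spot order on strings
  expect_identical(seq4_unrank(seq4_rank(c("AAAA", "ACDE", "YYYY"))), c("AAAA", "ACDE", "YYYY"))
  expect_identical(seq4_rank("AAAA"), 0L)
  expect_identical(seq4_rank("YYYY"), 159999L)
  set.seed(6)
  r <- sample(0:159999, 500)
  expect_identical(seq4_rank(seq4_unrank(r)), r)
  expect_error(seq4_rank("ABCD"), "invalid key") # B is not an amino acid
})

test_that("window extraction counts, labels and straddle-drops correctly", {
  w <- extract_windows(strrep("A", 10), strrep("C", 10))
  expect_equal(nrow(w), 7)
  expect_true(all(w$set_label == "compliant"))
  # 8 coded residues, statuses CCCCNNNN: only the two flush windows survive
  w2 <- extract_windows(
    "ACDEFGHI", "AABBCCDD",
    status = c("C", "C", "C", "C", "N", "N", "N", "N"),
    origin_compliant = FALSE
  )
  expect_equal(nrow(w2), 2)
  expect_equal(w2$seq4, c("ACDE", "FGHI"))
  expect_equal(w2$set_label, c("compliant", "noncompliant"))
  # undefined codes and X residues poison their windows
  w3 <- extract_windows("ACDEFGHI", "AAB-CCDD")
  expect_equal(nrow(w3), 1)
  expect_equal(w3$seq4, "FGHI")
  w4 <- extract_windows("ACXEFGHI", "AABBCCDD")
  expect_equal(w4$seq4, c("EFGH", "FGHI"))
  expect_equal(nrow(extract_windows("ACD", "AAB")), 0)
})

test_that("table building aggregates counts with fixed logical capacity", {
  pairs <- tibble::tibble(
    seq4 = rep("ACDE", 5), code4 = rep("CCCC", 5), set_label = "compliant"
  )
  tab <- build_table(pairs)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$n, 5)
  expect_equal(attr(tab, "total"), 5)
  g <- glance(tab)
  expect_equal(c(g$n_seq_columns, g$n_code_rows), c(160000, 2401))
  empty <- build_table(pairs[0, ])
  expect_equal(attr(empty, "total"), 0)
  # reduced two-letter alphabet: 2^4 distinct columns
  combos <- expand.grid(rep(list(c("A", "C")), 4))
  seqs <- apply(combos, 1, paste, collapse = "")
  tab2 <- build_table(tibble::tibble(seq4 = seqs, code4 = "AAAA"))
  expect_equal(length(unique(tab2$seq4)), 16)
  expect_error(
    build_table(tibble::tibble(seq4 = "ACDE", code4 = "AAHZ")),
    "invalid key"
  )
})

test_that("scaling multiplies the smaller table by the size ratio", {
  big <- build_table(tibble::tibble(
    seq4 = rep("ACDE", 1000), code4 = rep("AAAA", 1000)
  ))
  small <- build_table(tibble::tibble(
    seq4 = rep(c("ACDE", "LLLL"), c(150, 100)),
    code4 = rep(c("AAAA", "BBBB"), c(150, 100))
  ), label = "noncompliant")
  sc <- scale_table(small, big)
  expect_equal(attr(sc, "scale_factor"), 4)
  expect_equal(sc$n, small$n * 4)
  expect_equal(attr(sc, "total"), attr(big, "total"), tolerance = 1e-9)
  # order-insensitive
  sc2 <- scale_table(big, small)
  expect_equal(sc2$n, sc$n)
  same <- scale_table(big, big)
  expect_equal(attr(same, "scale_factor"), 1)
  expect_error(scale_table(build_table(big[0, ]), big), "empty set")
})

test_that("column and row vectors are dense, canonical, and conserve counts", {
  tab <- build_table(tibble::tibble(seq4 = "ACDE", code4 = "CCCC", count = 3))
  v <- column_vector(tab, "ACDE")
  expect_length(v, 2401)
  expect_equal(sum(v != 0), 1)
  # positional-arithmetic rank oracle over the 7-letter alphabet
  rank_oracle <- sum((match(c("C", "C", "C", "C"), LETTERS[1:7]) - 1) * 7^(3:0))
  expect_equal(which(v != 0) - 1, rank_oracle)
  expect_equal(v[rank_oracle + 1], 3)
  r <- row_vector(tab, "CCCC")
  expect_length(r, 160000)
  expect_equal(which(r != 0) - 1, seq4_rank("ACDE"))
  expect_equal(sum(column_vector(tab, "ACDE")), sum(tab$n[tab$seq4 == "ACDE"]))
  expect_equal(sum(column_vector(build_table(tab[0, ]), "ACDE")), 0)
  expect_error(column_vector(tab, "AZZZ"), "invalid key")
})

test_that("pearson_r matches the closed-form oracle and guards its domain", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_r(x, 2 * x + 1), 1)
  expect_equal(pearson_r(x, -x), -1)
  # hand evaluation: cov = 3, sd products = 5 -> r = 0.6
  expect_equal(pearson_r(x, c(2, 1, 4, 3)), 0.6, tolerance = 1e-12)
  expect_error(pearson_r(c(1, 2), c(3, 4)), "insufficient")
  expect_error(pearson_r(x, rep(2, 4)), "undefined correlation")
})

test_that("significance uses the large-sample 1.96 cutoff", {
  s0 <- significance(0, 100)
  expect_equal(s0$z_stat, 0)
  expect_false(s0$significant)
  expect_equal(s0$critical, 1.96)
  expect_true(significance(1, 10)$significant)
  expect_true(significance(-1, 10)$significant)
  # minimal significant |r| at n = 2401 from a numeric root oracle
  root <- stats::uniroot(
    function(r) r * sqrt(2399) / sqrt(1 - r^2) - 1.96,
    c(1e-6, 0.5), tol = 1e-12
  )$root
  expect_equal(root, 0.04, tolerance = 0.01)
  expect_true(significance(root * 1.001, 2401)$significant)
  expect_false(significance(root * 0.999, 2401)$significant)
  expect_error(significance(0.5, 2), "insufficient n")
})

random_table_pair <- function(seed, n_seqs = 12, m = 300) {
  set.seed(seed)
  seqs <- seq4_unrank(sample(0:159999, n_seqs))
  mk <- function(label) {
    rows <- lapply(seqs, function(s) {
      w <- rgamma(2401, 0.02)
      x <- as.integer(rmultinom(1, m, w / sum(w)))
      tibble::tibble(
        seq4 = s, code4 = code4_unrank(which(x > 0) - 1L), count = x[x > 0]
      )
    })
    build_table(dplyr::bind_rows(rows), label = label)
  }
  list(a = mk("compliant"), b = mk("noncompliant"))
}

test_that("screen of identical tables gives r = 1 everywhere, no negatives", {
  tabs <- random_table_pair(1)
  scr <- correlation_screen(tabs$a, tabs$a)
  expect_true(all(scr$r == 1))
  expect_equal(nrow(negative_keys(scr)), 0)
  expect_true(all(scr$n == 2401))
})

test_that("scaling cannot change any screen verdict", {
  tabs <- random_table_pair(2)
  scr1 <- correlation_screen(tabs$a, tabs$b)
  scaled <- scale_table(tabs$b, tabs$a)
  scr2 <- correlation_screen(tabs$a, scaled)
  expect_equal(scr1$r, scr2$r, tolerance = 1e-12)
  expect_identical(scr1$significant, scr2$significant)
  expect_identical(scr1$sign, scr2$sign)
})

test_that("the screen is symmetric in its two tables", {
  tabs <- random_table_pair(3)
  ab <- correlation_screen(tabs$a, tabs$b)
  ba <- correlation_screen(tabs$b, tabs$a)
  expect_identical(ab$key, ba$key)
  expect_equal(ab$r, ba$r, tolerance = 1e-12)
})

test_that("row mode screens code 4-mers over the 160000 sequence cells", {
  tabs <- random_table_pair(4, n_seqs = 6, m = 120)
  scr <- correlation_screen(tabs$a, tabs$b, mode = "rows")
  expect_true(all(scr$n == 160000))
  expect_true(all(scr$key %in% enumerate_4mers(code_alphabet())))
})

test_that("joint-nonzero cell mode changes n but keeps r well-defined", {
  tabs <- random_table_pair(5)
  scr <- correlation_screen(tabs$a, tabs$b, cells = "joint_nonzero")
  expect_true(all(scr$n <= 2401))
  ok <- !is.na(scr$r)
  expect_true(all(abs(scr$r[ok]) <= 1))
})

test_that("contingency tables survive a TSV round trip", {
  tabs <- random_table_pair(6, n_seqs = 4, m = 50)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_contingency(tabs$a, f)
  back <- read_contingency(f)
  expect_equal(attr(back, "total"), attr(tabs$a, "total"))
  expect_equal(attr(back, "label"), "compliant")
  expect_equal(
    dplyr::arrange(tibble::as_tibble(back), seq4, code4)$n,
    dplyr::arrange(tibble::as_tibble(tabs$a), seq4, code4)$n
  )
})

test_that("screening empty tables is an error", {
  e <- build_table(tibble::tibble(seq4 = character(), code4 = character()))
  expect_error(correlation_screen(e, e), "empty")
})
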