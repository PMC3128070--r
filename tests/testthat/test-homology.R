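test_that("identical sequences align fully at 100% identity", {
  s <- "ACGTACGTACGTACGTACGT"
  a <- smith_waterman(s, s)
  expect_equal(a$score, 20)
  expect_equal(a$pident, 100)
  expect_equal(a$identities, 20L)
  expect_equal(c(a$q_start, a$q_end), c(0L, 20L))
  expect_equal(c(a$s_start, a$s_end), c(0L, 20L))
})

test_that("sequences with no positive-scoring cell give the empty alignment", {
  a <- smith_waterman("AAAA", "TTTT")
  expect_equal(a$score, 0)
  expect_equal(a$aligned_length, 0L)
  expect_equal(a$identities, 0L)
})

test_that("alignment scores equal brute-force Gotoh DP on random pairs", {
  set.seed(31)
  for (i in 1:200) {
    q <- random_seq(30)
    s <- random_seq(30)
    expect_equal(smith_waterman(q, s)$score, sw_score_oracle(q, s),
                 info = paste(q, s))
  }
})

test_that("local alignment score is symmetric for a symmetric scheme", {
  set.seed(32)
  for (i in 1:20) {
    q <- random_seq(40)
    s <- random_seq(60)
    expect_equal(smith_waterman(q, s)$score, smith_waterman(s, q)$score)
  }
})

test_that("E-values follow the Karlin-Altschul form", {
  sch <- scoring_scheme()
  # linear in the database length
  expect_equal(evalue_of(25, 100, 2000, sch),
               2 * evalue_of(25, 100, 1000, sch))
  # a score increment of ln(2)/lambda halves E
  d <- log(2) / sch$lambda
  expect_equal(evalue_of(30 + d, 100, 1000, sch),
               evalue_of(30, 100, 1000, sch) / 2)
  # frozen reference values computed from E = K m n exp(-lambda S)
  # with the tabulated ungapped +1/-3 parameters lambda=1.374, K=0.711
  ref <- data.frame(
    S = c(20, 30, 40, 55, 80),
    m = c(100, 250, 500, 1000, 2000),
    n = c(1e3, 1e4, 5e5, 1e6, 2e7),
    E = c(8.269081e-08, 2.229416e-12, 2.404279e-16, 1.077049e-24,
          5.203315e-38)
  )
  expect_equal(evalue_of(ref$S, ref$m, ref$n, sch), ref$E,
               tolerance = 1e-6)
  # strictly decreasing in score
  e <- evalue_of(0:50, 100, 1000, sch)
  expect_true(all(diff(e) < 0))
})

test_that("filter_hits applies strict cutoffs on E-value and query length", {
  hits <- tibble::tibble(
    query_id = c("q1", "q2", "q3"),
    subject_id = "s",
    evalue = c(1e-4, 1e-6, 1e-12),
    bitscore = c(30, 40, 80)
  )
  expect_equal(filter_hits(hits, 1e-5)$query_id, c("q2", "q3"))
  lens <- c(q1 = 150, q2 = 250, q3 = 300)
  kept <- filter_hits(hits, 1e-3, min_query_length = 200,
                      query_lengths = lens)
  expect_equal(kept$query_id, c("q2", "q3"))
  expect_error(
    filter_hits(hits, 1e-3, min_query_length = 200,
                query_lengths = c(q1 = 150)),
    "q2"
  )
})

test_that("filter_hits equals a brute-force predicate filter", {
  set.seed(33)
  n <- 300L
  hits <- tibble::tibble(
    query_id = sprintf("q%02d", sample(1:40, n, replace = TRUE)),
    subject_id = sprintf("s%02d", sample(1:40, n, replace = TRUE)),
    evalue = 10^runif(n, -30, 1),
    bitscore = runif(n, 20, 200)
  )
  lens <- stats::setNames(sample(50:800, 40), sprintf("q%02d", 1:40))
  got <- filter_hits(hits, 1e-5, min_query_length = 200,
                     query_lengths = lens)
  keep <- hits$evalue < 1e-5 & lens[hits$query_id] > 200
  expect_equal(got, hits[keep, ])
  # the stringent cutoff always yields a subset of the moderate one
  e5 <- filter_hits(hits, 1e-5)
  e10 <- filter_hits(hits, 1e-10)
  expect_true(all(do.call(paste, e10) %in% do.call(paste, e5)))
})

test_that("unigene_reduce keeps the single best hit per subject", {
  hits <- tibble::tibble(
    query_id = c("c1", "c2", "c3"),
    subject_id = c("g1", "g1", "g2"),
    evalue = c(1e-10, 1e-20, 1e-8),
    bitscore = c(50, 90, 40)
  )
  ug <- unigene_reduce(hits)
  expect_equal(nrow(ug), 2L)
  expect_equal(ug$query_id[ug$subject_id == "g1"], "c2")
  expect_equal(nrow(unigene_reduce(hits[0, ])), 0L)
})

test_that("unigene_reduce equals group-by-min oracle and is idempotent", {
  set.seed(34)
  n <- 400L
  hits <- tibble::tibble(
    query_id = sprintf("c%03d", sample(1:60, n, replace = TRUE)),
    subject_id = sprintf("g%03d", sample(1:25, n, replace = TRUE)),
    evalue = 10^(-sample(1:30, n, replace = TRUE)),  # forces ties
    bitscore = sample(seq(20, 200, by = 5), n, replace = TRUE)
  )
  ug <- unigene_reduce(hits)
  expect_lte(nrow(ug), nrow(hits))
  expect_equal(as.data.frame(ug), as.data.frame(unigene_oracle(hits)),
               ignore_attr = TRUE)
  expect_equal(unigene_reduce(ug), ug)
})

test_that("shared_unigenes counts set intersections and differences", {
  a <- tibble::tibble(subject_id = c("g1", "g2"))
  b <- tibble::tibble(subject_id = c("g2", "g3"))
  expect_equal(unlist(shared_unigenes(a, b)),
               c(shared = 1L, only_a = 1L, only_b = 1L))
  expect_equal(unlist(shared_unigenes(a, a)),
               c(shared = 2L, only_a = 0L, only_b = 0L))

  set.seed(35)
  for (i in 1:20) {
    sa <- sample(sprintf("g%02d", 1:40), sample(5:30, 1))
    sb <- sample(sprintf("g%02d", 1:40), sample(5:30, 1))
    got <- shared_unigenes(tibble::tibble(subject_id = sa),
                           tibble::tibble(subject_id = sb))
    expect_equal(got$shared, sum(sa %in% sb))
    expect_equal(got$shared + got$only_a, length(sa))
    expect_equal(got$shared + got$only_b, length(sb))
  }
})

test_that("align_contigs finds planted homology and orders hits", {
  set.seed(36)
  genes <- tibble::tibble(id = c("gA", "gB"),
                          seq = c(random_seq(500), random_seq(500)))
  contigs <- tibble::tibble(
    id = c("exact", "partial", "unrelated"),
    seq = c(genes$seq[1],
            substr(genes$seq[2], 101, 300),
            random_seq(400))
  )
  hits <- align_contigs(contigs, genes, max_evalue = 1e-5)
  expect_true(all(c("exact", "partial") %in% hits$query_id))
  exact <- hits[hits$query_id == "exact" & hits$subject_id == "gA", ]
  expect_equal(exact$pident, 100)
  expect_equal(exact$aligned_length, 500L)
  partial <- hits[hits$query_id == "partial" & hits$subject_id == "gB", ]
  expect_equal(c(partial$s_start, partial$s_end), c(100L, 300L))
  expect_false("unrelated" %in% hits$query_id)
})
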