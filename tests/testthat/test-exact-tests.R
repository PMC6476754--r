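test_that("Fisher two-sided p-values match hand-checked tables", {
  # balanced table carries no signal
  expect_equal(fisher_two_sided(c(1, 1, 1, 1))$p_two_sided, 1)
  # diagonal 5/5 table: only 2 of the 6 fixed-margin tables are as extreme
  expect_equal(fisher_two_sided(c(5, 0, 0, 5))$p_two_sided, 2 / 252,
               tolerance = 1e-12)
  # all-zero table: p = 1 by convention
  expect_equal(fisher_two_sided(c(0, 0, 0, 0))$p_two_sided, 1)
  expect_error(fisher_two_sided(c(-1, 1, 1, 1)),
               class = "chplex_validation_error")
  expect_error(fisher_two_sided(matrix(1, 3, 3)),
               class = "chplex_validation_error")

  res <- fisher_two_sided(matrix(c(0, 22, 9, 25), 2, byrow = TRUE))
  expect_equal(round(res$p_two_sided, 3), 0.008)
  td <- tidy(res)
  expect_equal(td$p_two_sided, res$p_two_sided)
  expect_equal(glance(res)$n, 56)
})

test_that("Fisher equals full fixed-margin enumeration on random tables", {
  set.seed(404)
  for (rep in 1:300) {
    total <- sample(4:60, 1)
    cuts <- sort(sample(0:total, 3, replace = TRUE))
    tab <- matrix(c(cuts[1], cuts[2] - cuts[1], cuts[3] - cuts[2],
                    total - cuts[3]), 2, byrow = TRUE)
    expect_equal(fisher_two_sided(tab)$p_two_sided, oracle_fisher(tab),
                 tolerance = 1e-10)
    # agreement with the reference implementation in stats
    if (sum(tab[1, ]) > 0 && sum(tab[2, ]) > 0 &&
        sum(tab[, 1]) > 0 && sum(tab[, 2]) > 0) {
      expect_equal(fisher_two_sided(tab)$p_two_sided,
                   stats::fisher.test(tab)$p.value, tolerance = 1e-7)
    }
  }
})

test_that("binomial tails match exact rational arithmetic", {
  # frozen values computed with exact fraction arithmetic
  cases <- list(
    list(n = 10, k = 7, p0 = 115 / 446,
         pm = 0.9994770237445544, pp = 0.004240052956243463),
    list(n = 21, k = 13, p0 = 115 / 446,
         pm = 0.9999018309463328, pp = 0.0005152370961419453),
    list(n = 8, k = 3, p0 = 115 / 446,
         pm = 0.8750386511729944, pp = 0.34110508152286156),
    list(n = 28, k = 0, p0 = 173 / 1262,
         pm = 0.016110858961117018, pp = 1.0),
    list(n = 66, k = 0, p0 = 173 / 1262,
         pm = 5.941863079053954e-05, pp = 1.0),
    list(n = 190, k = 11, p0 = 173 / 1262,
         pm = 0.0003797795848140761, pp = 0.9998613527072777),
    list(n = 30, k = 11, p0 = 1 / 3,
         pm = 0.7238643653096383, pp = 0.41524040122898986))
  for (cs in cases) {
    bt <- binomial_tails(cs$n, cs$k, cs$p0)
    expect_equal(bt$p_minus, cs$pm, tolerance = 1e-12)
    expect_equal(bt$p_plus, cs$pp, tolerance = 1e-12)
  }
})

test_that("binomial tails satisfy closed forms and the inclusion identity", {
  # k = 0 closed form
  bt <- binomial_tails(12, 0, 0.3)
  expect_equal(bt$p_minus, 0.7^12, tolerance = 1e-12)
  expect_equal(bt$p_plus, 1)
  # k = n closed form
  bt <- binomial_tails(8, 8, 0.05)
  expect_equal(bt$p_plus, 0.05^8, tolerance = 1e-15)

  # p_minus + p_plus = 1 + P(X = k), up to n = 1e4
  set.seed(505)
  for (rep in 1:50) {
    n <- sample(c(1:30, 100, 1000, 10000), 1)
    k <- sample(0:n, 1)
    p0 <- runif(1, 0.01, 0.99)
    bt <- binomial_tails(n, k, p0)
    expect_equal(bt$p_minus + bt$p_plus - dbinom(k, n, p0), 1,
                 tolerance = 1e-12)
  }

  # p_plus nonincreasing in k
  bt <- binomial_tails(rep(40, 41), 0:40, 0.26)
  expect_true(all(diff(bt$p_plus) <= 1e-15))

  expect_error(binomial_tails(10, 11, 0.5),
               class = "chplex_validation_error")
  expect_error(binomial_tails(10, 2, 0), class = "chplex_validation_error")
})

test_that("the polymorphism scan reproduces published-style tail columns", {
  # the ten largest genera of the survey: sizes, polymorphic counts and the
  # upper-tail probabilities they imply at the overall rate 115/446
  genus_n <- c(8, 8, 10, 11, 11, 11, 10, 16, 19, 21)
  genus_k <- c(3, 1, 7, 3, 2, 6, 2, 7, 4, 13)
  su <- scan_summaries(genus_n, genus_k, 446, 115)
  scan <- genus_polymorphism_scan(su, min_species = 8)
  expect_equal(nrow(scan), 10)
  expect_equal(scan$p0, rep(115 / 446, 10))
  expect_true(all(diff(scan$n) >= 0))

  by_nk <- function(n, k) scan[scan$n == n & scan$k == k, ]
  expect_equal(round(by_nk(10, 7)$p_plus, 3), 0.004)
  expect_equal(round(by_nk(11, 6)$p_plus, 2), 0.04)
  expect_equal(round(by_nk(21, 13)$p_plus, 3), 0.001)
  expect_equal(round(by_nk(8, 3)$p_plus, 2), 0.34)
  expect_equal(round(by_nk(8, 1)$p_plus, 2), 0.91)
  expect_equal(round(by_nk(16, 7)$p_plus, 2), 0.09)
  expect_equal(round(by_nk(19, 4)$p_plus, 2), 0.76)

  # genera below the size threshold are absent
  su7 <- scan_summaries(7, 3, 100, 30)
  expect_equal(nrow(genus_polymorphism_scan(su7, min_species = 8)), 0)

  # k = n with small p0: closed form p_plus = p0^n
  su_all <- scan_summaries(8, 8, 100, 20)
  scan_all <- genus_polymorphism_scan(su_all, min_species = 8)
  s8 <- scan_all[scan_all$genus == "Scan01", ]
  expect_equal(s8$p_plus, (20 / 100)^8, tolerance = 1e-12)
})

test_that("the pair-sharing scan reproduces published-style tail columns", {
  # ten large genera: pair counts and sharing-pair counts with the overall
  # sharing rate 173/1262
  gp <- tibble::tibble(
    genus = sprintf("Big%02d", 1:10),
    n_species_analyzed = c(8, 8, 10, 12, 12, 13, 14, 17, 20, 23),
    n_pairs = c(28, 28, 45, 66, 66, 78, 91, 136, 190, 253),
    n_pairs_sharing = c(2, 0, 8, 8, 0, 5, 13, 9, 11, 71))
  # filler genera (below threshold) complete the universe to 1262 pairs and
  # 173 sharing pairs: 13 x C(7,2) + C(4,2) + 2 x C(2,2) = 281 pairs
  fill <- tibble::tibble(
    genus = sprintf("Sml%02d", 1:16),
    n_species_analyzed = c(rep(7L, 13), 4L, 2L, 2L),
    n_pairs = c(rep(21L, 13), 6L, 1L, 1L),
    n_pairs_sharing = c(rep(3L, 13), 5L, 1L, 1L))
  gp_all <- dplyr::bind_rows(gp, fill)
  expect_equal(sum(gp_all$n_pairs), 1262)
  expect_equal(sum(gp_all$n_pairs_sharing), 173)

  scan <- genus_pair_sharing_scan(gp_all, min_species = 8)
  expect_equal(nrow(scan), 10)
  expect_equal(scan$p0, rep(173 / 1262, 10))

  by_nk <- function(n, k) scan[scan$n == n & scan$k == k, ]
  expect_equal(signif(by_nk(66, 0)$p_minus, 1), 6e-5)
  expect_equal(round(by_nk(28, 0)$p_minus, 2), 0.02)
  expect_equal(round(by_nk(136, 9)$p_minus, 3), 0.007)
  expect_equal(round(by_nk(190, 11)$p_minus, 4), 0.0004)
  expect_equal(round(by_nk(28, 2)$p_minus, 2), 0.24)
  expect_equal(round(by_nk(78, 5)$p_minus, 3), 0.035)
  expect_true(by_nk(253, 71)$p_plus < 1e-8)

  # a genus of 8 species contributes C(8,2) = 28 pairs
  expect_equal(by_nk(28, 0)$n, 28)
})
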