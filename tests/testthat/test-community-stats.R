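toy_genus <- function() {
  # species A carries H1 only; species B carries H1 and H2
  s1 <- ac_base(20)
  s3 <- ac_variant(s1, c(3, 4))
  rec <- make_records(c("a1", "a2", "b1", "b2"), "Toy",
                      c("Toy spA", "Toy spA", "Toy spB", "Toy spB"),
                      c(s1, s1, s1, s3))
  meta <- tibble::tibble(sample_id = rec$sample_id, genus = rec$genus,
                         species = rec$species, dispersal_raw = "zoochorous",
                         voucher = TRUE)
  inv <- tibble::tibble(genus = "Toy", species_count = 2L)
  list(rec = rec, meta = meta, inv = inv)
}

test_that("dispersal syndromes map onto abiotic/biotic classes", {
  expect_equal(classify_dispersal(c("anemochorous", "autochorous",
                                    "hydrochorous")),
               rep("abiotic", 3))
  expect_equal(classify_dispersal(c("zoochorous", "mixed")),
               rep("biotic", 2))
  expect_error(classify_dispersal("wind"), class = "chplex_validation_error")
})

test_that("congener groups come from the site inventory", {
  inv <- tibble::tibble(genus = c("Solo", "Pair", "Big"),
                        species_count = c(1L, 2L, 34L))
  expect_equal(classify_group(c("Solo", "Pair", "Big"), inv), c(1L, 2L, 2L))
  expect_error(classify_group("Missing", inv),
               class = "chplex_validation_error")
})

test_that("species summaries flag singletons and call polymorphism", {
  s1 <- ac_base(20)
  s2 <- ac_variant(s1, c(1, 2))
  rec <- make_records(c("x1", "x2", "x3", "y1", "y2", "z1"), "G",
                      c("G spX", "G spX", "G spX", "G spY", "G spY", "G spZ"),
                      c(s1, s1, s1, s1, s2, s2))
  meta <- tibble::tibble(sample_id = rec$sample_id, genus = "G",
                         species = rec$species,
                         dispersal_raw = c(rep("zoochorous", 5),
                                           "anemochorous"),
                         voucher = TRUE)
  inv <- tibble::tibble(genus = "G", species_count = 3L)
  cl <- collapse_haplotypes(rec)
  su <- summarize_species(cl, meta, inv)

  expect_equal(nrow(su), 3)
  x <- su[su$species == "G spX", ]
  expect_equal(x$n_haplotypes, 1L)
  expect_false(x$polymorphic)
  y <- su[su$species == "G spY", ]
  expect_equal(y$n_haplotypes, 2L)
  expect_true(y$polymorphic)
  z <- su[su$species == "G spZ", ]
  expect_true(z$excluded)
  expect_true(is.na(z$polymorphic))
  expect_equal(z$dispersal_class, "abiotic")

  # sample present in clusters but missing from metadata errors
  expect_error(summarize_species(cl, meta[-1, ], inv),
               class = "chplex_validation_error")
})

test_that("contingency tables add up across strata", {
  cells <- tibble::tibble(
    dispersal = c("abiotic", "abiotic", "biotic", "biotic"),
    group = c(1, 2, 1, 2),
    n_poly = c(0, 3, 2, 10),
    n_total = c(5, 6, 7, 20))
  com <- build_count_community(cells)
  cl <- collapse_haplotypes(com$records)
  su <- summarize_species(cl, com$metadata, com$inventory)
  tab_a <- polymorphism_contingency(su, "abiotic")
  tab_b <- polymorphism_contingency(su, "biotic")
  tab_all <- polymorphism_contingency(su, "all")
  expect_equal(tab_a, matrix(c(0L, 5L, 3L, 3L), 2, byrow = TRUE,
                             dimnames = dimnames(tab_a)))
  expect_equal(tab_b, matrix(c(2L, 5L, 10L, 10L), 2, byrow = TRUE,
                             dimnames = dimnames(tab_b)))
  expect_equal(tab_all, tab_a + tab_b)
  expect_equal(sum(tab_all), sum(cells$n_total))
})

test_that("an all-monomorphic stratum yields a zero polymorphic column", {
  cells <- tibble::tibble(dispersal = "biotic", group = c(1, 2),
                          n_poly = c(0, 0), n_total = c(3, 4))
  com <- build_count_community(cells)
  cl <- collapse_haplotypes(com$records)
  su <- summarize_species(cl, com$metadata, com$inventory)
  tab <- polymorphism_contingency(su, "all")
  expect_equal(unname(tab[, "polymorphic"]), c(0L, 0L))
  expect_error(polymorphism_contingency(su, "abiotic"),
               class = "chplex_validation_error")
})

test_that("sharing incidences follow the worked single-genus example", {
  toy <- toy_genus()
  cl <- collapse_haplotypes(toy$rec)
  su <- summarize_species(cl, toy$meta, toy$inv)
  sh <- sharing_incidences(cl, su)

  inc <- sh$incidences
  expect_equal(nrow(inc), 3)
  h_of_b2 <- cluster_membership_of(cl, "b2")
  expect_true(all(inc$shared[inc$haplotype_id != h_of_b2]))
  expect_false(any(inc$shared[inc$haplotype_id == h_of_b2]))

  gp <- sh$genus_pairs
  expect_equal(gp$n_pairs, 1)
  expect_equal(gp$n_pairs_sharing, 1)

  # every sharing pair has a witness haplotype containing both species
  expect_true(all(gp$n_pairs_sharing <= gp$n_pairs))

  sbp <- sharing_by_polymorphism(su, sh)
  expect_equal(sbp, matrix(c(1L, 1L, 1L, 0L), 2, byrow = TRUE,
                           dimnames = dimnames(sbp)))
})

test_that("single-analyzed-species genera are outside the sharing universe", {
  toy <- toy_genus()
  # second genus with a single analyzed species
  extra_rec <- make_records(c("c1", "c2"), "Mono", "Mono spA",
                            rep(ac_base(20), 2))
  rec <- dplyr::bind_rows(toy$rec, extra_rec)
  meta <- dplyr::bind_rows(
    toy$meta,
    tibble::tibble(sample_id = c("c1", "c2"), genus = "Mono",
                   species = "Mono spA", dispersal_raw = "zoochorous",
                   voucher = TRUE))
  inv <- dplyr::bind_rows(toy$inv,
                          tibble::tibble(genus = "Mono", species_count = 3L))
  cl <- collapse_haplotypes(rec)
  su <- summarize_species(cl, meta, inv)
  sh <- sharing_incidences(cl, su)
  expect_false("Mono" %in% sh$incidences$genus)
  expect_false("Mono" %in% sh$genus_pairs$genus)
})

test_that("incidences with no multi-species haplotype are all private", {
  s1 <- ac_base(20)
  s2 <- ac_variant(s1, c(1, 2))
  rec <- make_records(c("a1", "a2", "b1", "b2"), "G",
                      c("G spA", "G spA", "G spB", "G spB"),
                      c(s1, s1, s2, s2))
  meta <- tibble::tibble(sample_id = rec$sample_id, genus = "G",
                         species = rec$species, dispersal_raw = "mixed",
                         voucher = TRUE)
  inv <- tibble::tibble(genus = "G", species_count = 2L)
  cl <- collapse_haplotypes(rec)
  su <- summarize_species(cl, meta, inv)
  sh <- sharing_incidences(cl, su)
  expect_false(any(sh$incidences$shared))
  expect_equal(sh$genus_pairs$n_pairs_sharing, 0)
})

test_that("review report lists cross-species shared haplotypes deterministically", {
  toy <- toy_genus()
  cl <- collapse_haplotypes(toy$rec)
  rep1 <- review_report(cl, toy$meta)
  shared_h <- cluster_membership_of(cl, "a1")
  expect_equal(rep1$sample_id, c("a1", "a2", "b1"))
  expect_equal(unique(rep1$haplotype_id), shared_h)

  # no sharing -> empty report
  s1 <- ac_base(20)
  rec <- make_records(c("a1", "b1"), "G", c("G spA", "G spB"),
                      c(s1, ac_variant(s1, c(1, 2))))
  meta <- tibble::tibble(sample_id = rec$sample_id, genus = "G",
                         species = rec$species, dispersal_raw = "mixed",
                         voucher = TRUE)
  cl2 <- collapse_haplotypes(rec)
  expect_equal(nrow(review_report(cl2, meta)), 0)
})
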