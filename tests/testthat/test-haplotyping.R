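test_that("pairwise differences count substitutions, indel events, inversions", {
  expect_equal(pairwise_difference("ACGTACGT", "ACGTACGT")$total_units, 0)
  d <- pairwise_difference("ACGTACGT", "ACGAACGT")
  expect_equal(d$substitutions, 1)
  expect_equal(d$total_units, 1)

  # one maximal gap run is one event regardless of length
  d <- pairwise_difference("ACG---GT", "ACGTTAGT")
  expect_equal(d$indel_events, 1)
  expect_equal(d$total_units, 1)
  d <- pairwise_difference("ACG---GT", "ACGTTAGT", indel_mode = "site")
  expect_equal(d$indel_events, 3)
  expect_equal(d$total_units, 3)

  # reverse-complement segment counts once, its columns leave the
  # substitution count
  d <- pairwise_difference("ATGCCCGA", "ATGGGGGA", min_inversion_len = 3)
  expect_equal(d$inversion_events, 1)
  expect_equal(d$substitutions, 0)
  expect_equal(d$total_units, 1)

  # symmetry and case normalisation
  expect_equal(pairwise_difference("atgcccga", "ATGGGGGA")$total_units,
               pairwise_difference("ATGGGGGA", "ATGCCCGA")$total_units)

  # ambiguity codes drop the column from counting
  expect_equal(pairwise_difference("ACNT", "ACGT")$total_units, 0)
  expect_equal(pairwise_difference("ANNT", "AC-T")$total_units, 0)

  expect_error(pairwise_difference("ACGT", "ACG"),
               class = "chplex_validation_error")
  a <- make_records("s1", "Inga", "x", "ACGT")
  b <- make_records("s2", "Protium", "y", "ACGT")
  expect_error(pairwise_difference(a, b), class = "chplex_validation_error")
})

test_that("inversion detection finds reverse-complement segments only when mismatched", {
  expect_equal(nrow(detect_inversions("AAAA", "AAAA", 3)), 0)
  iv <- detect_inversions("ATGCCCGA", "ATGGGGGA", 3)
  expect_equal(iv$start, 4)
  expect_equal(iv$end, 6)
  # palindrome guard: ACGT is its own reverse complement but identical
  expect_equal(nrow(detect_inversions("ACGT", "ACGT", 4)), 0)
  # below the length threshold nothing is flagged
  expect_equal(nrow(detect_inversions("ATGCCCGA", "ATGGGGGA", 4)), 0)
})

test_that("inversion detection matches the window-enumeration oracle", {
  set.seed(101)
  for (rep in 1:60) {
    L <- sample(20:50, 1)
    seqs <- random_oracle_genus(2, L)
    got <- detect_inversions(seqs[1], seqs[2], 3)
    want <- oracle_inversions(seqs[1], seqs[2], 3)
    expect_equal(cbind(got$start, got$end),
                 matrix(as.integer(want), ncol = 2),
                 ignore_attr = TRUE)
    gu <- pairwise_difference(seqs[1], seqs[2])
    wu <- oracle_units(seqs[1], seqs[2])
    expect_equal(gu$total_units, unname(wu[["total"]]))
    expect_equal(gu$substitutions, unname(wu[["substitutions"]]))
  }
})

test_that("collapsing applies the two-difference rule with single linkage", {
  # identical pair -> one haplotype
  rec <- make_records(c("a", "b"), "G", "sp1", c("ACGTACGT", "ACGTACGT"))
  cl <- collapse_haplotypes(rec)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$n_members, 2L)

  # two substitutions -> distinct haplotypes
  rec <- make_records(c("a", "b"), "G", "sp1", c("ACGTACGT", "TCGTACGA"))
  expect_equal(nrow(collapse_haplotypes(rec)), 2)

  # chain a-b=1, b-c=1, a-c=2: single linkage keeps one cluster
  rec <- make_records(c("a", "b", "c"), "G", "sp1",
                      c("ACGTACGT", "ACGAACGT", "ACAAACGT"))
  cl <- collapse_haplotypes(rec)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$n_members, 3L)

  expect_error(collapse_haplotypes(NULL), class = "chplex_validation_error")

  # representative comes from the lexicographically smallest member
  rec <- make_records(c("b2", "a1"), "G", "sp1", c("ACGTACGT", "ACGAACGT"))
  cl <- collapse_haplotypes(rec)
  expect_equal(cl$representative, "ACGAACGT")
})

test_that("a species-fixed single nucleotide splits haplotypes", {
  base <- "ACGTACGT"
  alt <- "ACGTTCGT" # single substitution at column 5
  rec <- make_records(c("s1", "s2", "s3", "s4"), "G",
                      c("spX", "spX", "spY", "spY"),
                      c(alt, alt, base, base))
  cl <- collapse_haplotypes(rec)
  expect_equal(nrow(cl), 2)
  expect_setequal(vapply(cl$species_set, paste, character(1)),
                  c("spX", "spY"))

  # not diagnostic when one individual of the species lacks the variant
  rec2 <- make_records(c("s1", "s2", "s3", "s4"), "G",
                       c("spX", "spX", "spY", "spY"),
                       c(alt, base, base, base))
  expect_equal(nrow(collapse_haplotypes(rec2)), 1)

  # two diagnostic units do not trigger the exception (>= 2 differences
  # would already separate the species)
  alt2 <- "TCGTTCGT"
  rec3 <- make_records(c("s1", "s2", "s3"), "G", c("spX", "spX", "spY"),
                       c(alt2, alt2, base))
  expect_equal(nrow(collapse_haplotypes(rec3)), 2) # already 2 units apart
})

test_that("cluster ids are deterministic and conservation holds", {
  set.seed(202)
  for (rep in 1:20) {
    n <- sample(3:10, 1)
    seqs <- random_oracle_genus(n, 40)
    rec <- make_records(sprintf("s%02d", seq_len(n)), "G", "sp1", seqs)
    cl <- collapse_haplotypes(rec)
    # conservation: every record in exactly one cluster
    members <- sort(unlist(cl$member_sample_ids))
    expect_equal(members, sort(rec$sample_id))
    # permutation invariance of the partition and of ids
    perm <- sample.int(n)
    cl2 <- collapse_haplotypes(rec[perm, ])
    expect_equal(cl, cl2)
    # ids ordered by size then smallest member
    expect_true(all(diff(cl$n_members) <= 0))
  }
})

test_that("collapsing equals the transitive-closure oracle on random genera", {
  set.seed(303)
  for (rep in 1:60) {
    n <- sample(3:9, 1)
    seqs <- random_oracle_genus(n, sample(25:50, 1))
    ids <- sprintf("s%02d", seq_len(n))
    rec <- make_records(ids, "G", "sp1", seqs) # one species: no exception pass
    cl <- collapse_haplotypes(rec)
    comp <- oracle_components(seqs)
    expect_equal(canonical_partition(ids, cluster_membership_of(cl, ids)),
                 canonical_partition(ids, comp))
  }
})
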