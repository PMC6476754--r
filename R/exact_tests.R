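#' Two-sided Fisher exact test on a 2x2 table
#'
#' Exact two-sided p-value under the point-probability rule: with margins
#' fixed, the p-value is the sum of hypergeometric point probabilities of
#' all tables whose probability does not exceed that of the observed table
#' (ties detected with relative tolerance 1e-7). Computation is exact via
#' the hypergeometric pmf; no normal approximation is used. An all-zero
#' table has p = 1 by convention.
#'
#' @param table 2x2 matrix (or length-4 vector, row-major) of nonnegative
#'   integer counts.
#' @return An object of class `chplex_fisher` with elements `table` and
#'   `p_two_sided`; see [tidy.chplex_fisher()].
#' @export
fisher_two_sided <- function(table) {
  if (!is.matrix(table)) {
    table <- matrix(as.numeric(table), nrow = 2, byrow = TRUE)
  }
  if (!all(dim(table) == c(2, 2))) {
    chplex_abort("Fisher test requires a 2x2 table", "chplex_validation_error")
  }
  if (any(is.na(table)) || any(table < 0) || any(table != round(table))) {
    chplex_abort("Table cells must be nonnegative integers",
                 "chplex_validation_error")
  }
  m <- table[1, 1] + table[1, 2]      # row 1 margin
  n <- table[2, 1] + table[2, 2]      # row 2 margin
  k <- table[1, 1] + table[2, 1]      # column 1 margin
  if (m + n == 0) {
    p <- 1
  } else {
    support <- max(0, k - n):min(k, m)
    probs <- dhyper(support, m, n, k)
    p_obs <- dhyper(table[1, 1], m, n, k)
    p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
    p <- min(p, 1)
  }
  structure(list(table = table, p_two_sided = p), class = "chplex_fisher")
}

#' @export
print.chplex_fisher <- function(x, ...) {
  cat("Two-sided Fisher exact test\n")
  print(x$table)
  cat(sprintf("p (two-sided) = %.4g\n", x$p_two_sided))
  invisible(x)
}

#' @rdname fisher_two_sided
#' @param x A `chplex_fisher` object.
#' @param ... Unused.
#' @export
tidy.chplex_fisher <- function(x, ...) {
  tibble::tibble(
    a = x$table[1, 1], b = x$table[1, 2],
    c = x$table[2, 1], d = x$table[2, 2],
    p_two_sided = x$p_two_sided
  )
}

#' @rdname fisher_two_sided
#' @export
glance.chplex_fisher <- function(x, ...) {
  or <- (x$table[1, 1] * x$table[2, 2]) / (x$table[1, 2] * x$table[2, 1])
  tibble::tibble(
    n = sum(x$table),
    odds_ratio = or,
    p_two_sided = x$p_two_sided,
    method = "Fisher exact (two-sided, point-probability rule)"
  )
}

#' Inclusive binomial tail probabilities
#'
#' For X ~ Binomial(n, p0), returns the lower tail `p_minus` = P(X <= k) and
#' the upper tail `p_plus` = P(X >= k), both inclusive of k, computed with
#' stable partial pmf sums (so `p_minus + p_plus = 1 + P(X = k)` to
#' numerical tolerance). Vectorised over `n` and `k`.
#'
#' @param n Number of trials (species, or species pairs).
#' @param k Observed number of successes, `0 <= k <= n`.
#' @param p0 Null success probability, in (0, 1).
#' @return A tibble with columns `n`, `k`, `p0`, `p_minus`, `p_plus`.
#' @export
binomial_tails <- function(n, k, p0) {
  if (length(p0) != 1 || is.na(p0) || p0 <= 0 || p0 >= 1) {
    chplex_abort("p0 must be a single probability strictly inside (0, 1)",
                 "chplex_validation_error")
  }
  if (any(is.na(n)) || any(is.na(k)) || any(k < 0) || any(k > n) ||
      any(n < 1) || any(n != round(n)) || any(k != round(k))) {
    chplex_abort("Require integer 0 <= k <= n with n >= 1",
                 "chplex_validation_error")
  }
  tibble::tibble(
    n = as.integer(n), k = as.integer(k), p0 = p0,
    p_minus = pbinom(k, n, p0),
    p_plus = pbinom(k - 1, n, p0, lower.tail = FALSE)
  )
}

#' Per-genus binomial scan of polymorphism rates
#'
#' For every genus with at least `min_species` analyzed species, compares
#' the genus' number of polymorphic species against a uniform-rate null:
#' the null rate `p0` is the overall polymorphic fraction across all
#' analyzed species (focal genus included). `p_minus` is the probability of
#' observing as few or fewer polymorphic species, `p_plus` of as many or
#' more.
#'
#' @param summaries Species summary tibble from [summarize_species()].
#' @param min_species Minimum number of analyzed species per genus
#'   (default 8).
#' @return A tibble of class `chplex_scan`, sorted by `n` then genus:
#'   `genus`, `n`, `k`, `p0`, `p_minus`, `p_plus`.
#' @export
genus_polymorphism_scan <- function(summaries, min_species = 8L) {
  inc <- included_species(summaries)
  p0 <- mean(inc$polymorphic)
  if (nrow(inc) == 0 || !is.finite(p0) || p0 <= 0 || p0 >= 1) {
    # uniform-rate null degenerate: every genus trivially conforms
    scan <- tibble::tibble(genus = character(), n = integer(), k = integer(),
                           p0 = numeric(), p_minus = numeric(),
                           p_plus = numeric())
    return(structure(scan, class = c("chplex_scan", class(scan)),
                     scan_type = "polymorphism"))
  }
  counts <- inc %>%
    dplyr::group_by(.data$genus) %>%
    dplyr::summarise(n = dplyr::n(), k = sum(.data$polymorphic),
                     .groups = "drop") %>%
    dplyr::filter(.data$n >= min_species)
  scan <- binomial_tails(counts$n, counts$k, p0) %>%
    dplyr::mutate(genus = counts$genus, .before = 1) %>%
    dplyr::arrange(.data$n, .data$genus)
  structure(scan, class = c("chplex_scan", class(scan)),
            scan_type = "polymorphism")
}

#' Per-genus binomial scan of species-pair haplotype sharing
#'
#' For every genus with at least `min_species` analyzed species, compares
#' the number of congeneric species pairs sharing at least one haplotype
#' against a uniform sharing rate across all pairs: `p0` is the overall
#' fraction of sharing pairs over all pairs in the sharing universe (all
#' genera with >= 2 analyzed species, not only the scanned ones).
#'
#' @param genus_pairs Per-genus pair counts: the `genus_pairs` element of a
#'   [sharing_incidences()] result (or any tibble with columns `genus`,
#'   `n_species_analyzed`, `n_pairs`, `n_pairs_sharing`). A `chplex_sharing`
#'   object may be passed directly.
#' @param min_species Minimum number of analyzed species per genus
#'   (default 8).
#' @return A tibble of class `chplex_scan`, sorted by `n` then genus:
#'   `genus`, `n` (pairs), `k` (sharing pairs), `p0`, `p_minus`, `p_plus`.
#' @export
genus_pair_sharing_scan <- function(genus_pairs, min_species = 8L) {
  if (inherits(genus_pairs, "chplex_sharing")) {
    genus_pairs <- genus_pairs$genus_pairs
  }
  total_pairs <- sum(genus_pairs$n_pairs)
  total_sharing <- sum(genus_pairs$n_pairs_sharing)
  empty <- tibble::tibble(genus = character(), n = integer(), k = integer(),
                          p0 = numeric(), p_minus = numeric(),
                          p_plus = numeric())
  if (total_pairs == 0 || total_sharing == 0 ||
      total_sharing == total_pairs) {
    return(structure(empty, class = c("chplex_scan", class(empty)),
                     scan_type = "pair_sharing"))
  }
  p0 <- total_sharing / total_pairs
  counts <- dplyr::filter(genus_pairs, .data$n_species_analyzed >= min_species)
  if (nrow(counts) == 0) {
    return(structure(empty, class = c("chplex_scan", class(empty)),
                     scan_type = "pair_sharing"))
  }
  scan <- binomial_tails(counts$n_pairs, counts$n_pairs_sharing, p0) %>%
    dplyr::mutate(genus = counts$genus, .before = 1) %>%
    dplyr::arrange(.data$n, .data$genus)
  structure(scan, class = c("chplex_scan", class(scan)),
            scan_type = "pair_sharing")
}
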