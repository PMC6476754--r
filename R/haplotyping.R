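#' Count difference units between two aligned sequences
#'
#' The difference metric that underlies haplotype collapsing. Three classes
#' of difference each count one unit:
#'
#' * substitutions: aligned columns where both sequences carry a base
#'   (A/C/G/T) and the bases differ, excluding columns inside a detected
#'   inversion segment;
#' * indel events: by default, one unit per maximal contiguous run of
#'   columns where exactly one sequence has a gap (`indel_mode = "event"`),
#'   so a long mononucleotide-repeat indel counts once; with
#'   `indel_mode = "site"` every gap-vs-base column counts one unit;
#' * inversion events: one unit per detected reverse-complement segment
#'   (see [detect_inversions()]); the segment's internal columns are removed
#'   from the substitution count.
#'
#' Columns where both sequences have a gap are ignored, and any column where
#' either sequence carries a non-`{A,C,G,T,-}` symbol (N or another IUPAC
#' ambiguity letter) is excluded from difference counting; neither breaks a
#' gap run. The metric is symmetric and is zero iff the two sequences are
#' identical after case normalisation.
#'
#' @param a,b Aligned sequences: either residue strings or one-row record
#'   tibbles (in which case both must belong to the same genus).
#' @param min_inversion_len Minimum inversion segment length (>= 2).
#' @param indel_mode `"event"` (default) or `"site"`; see above.
#' @return A one-row tibble: `substitutions`, `indel_events`,
#'   `inversion_events`, `total_units`.
#' @export
pairwise_difference <- function(a, b, min_inversion_len = 3L,
                                indel_mode = c("event", "site")) {
  indel_mode <- match.arg(indel_mode)
  if (min_inversion_len < 2) {
    chplex_abort("min_inversion_len must be >= 2", "chplex_validation_error")
  }
  if (is.data.frame(a) && is.data.frame(b)) {
    if (a$genus[1] != b$genus[1]) {
      chplex_abort(paste0("Cannot compare records from different genera: ",
                          a$genus[1], " vs ", b$genus[1]),
                   "chplex_validation_error")
    }
    a <- a$residues[1]
    b <- b$residues[1]
  }
  a <- toupper(a)
  b <- toupper(b)
  if (nchar(a) != nchar(b)) {
    chplex_abort(paste0("Sequences have unequal lengths: ", nchar(a), " vs ",
                        nchar(b)), "chplex_validation_error")
  }
  u <- cpp_pairwise_units(a, b, as.integer(min_inversion_len))
  indel <- if (indel_mode == "event") u[["indel_events"]] else u[["indel_sites"]]
  tibble::tibble(
    substitutions = u[["substitutions"]],
    indel_events = indel,
    inversion_events = u[["inversion_events"]],
    total_units = u[["substitutions"]] + indel + u[["inversion_events"]]
  )
}

#' Detect small inversion segments between two aligned sequences
#'
#' Finds maximal, non-overlapping, gap-free column intervals of length at
#' least `min_inversion_len` where one sequence's segment equals the reverse
#' complement of the other's and at least one column inside the segment
#' mismatches (the mismatch requirement stops palindromic but identical
#' segments from being flagged). Intervals are chosen greedily left to
#' right, longest first on ties.
#'
#' @param a,b Aligned residue strings of equal length.
#' @param min_inversion_len Minimum segment length (>= 2); default 3, since a
#'   length-1 "inversion" is indistinguishable from a substitution and
#'   length-2 windows flag too many coincidental matches.
#' @return A tibble with columns `start`, `end` (1-based, inclusive).
#' @export
detect_inversions <- function(a, b, min_inversion_len = 3L) {
  a <- toupper(a)
  b <- toupper(b)
  if (nchar(a) != nchar(b)) {
    chplex_abort(paste0("Sequences have unequal lengths: ", nchar(a), " vs ",
                        nchar(b)), "chplex_validation_error")
  }
  m <- cpp_detect_inversions(a, b, as.integer(min_inversion_len))
  tibble::tibble(start = m[, 1] + 1L, end = m[, 2] + 1L)
}

#' Collapse aligned sequences into haplotypes
#'
#' Applies the two-difference rule: sequences whose pairwise distance is at
#' most one difference unit (see [pairwise_difference()]) are taken to be
#' the same haplotype, a conservative merging that limits the impact of
#' sequencing error on polymorphism estimates. Merging is single linkage:
#' provisional haplotypes are the connected components of the at-most-one-
#' unit graph. A species-diagnostic exception then restores distinctions
#' fixed between species: within a provisional cluster, if all records of
#' one species share a variant state at exactly one difference unit that no
#' record of any other species in the cluster carries, that species' records
#' are split into their own haplotype.
#'
#' Haplotype ids are genus-scoped (`H1`, `H2`, ...), assigned by descending
#' member count then lexicographically smallest member sample id; the
#' representative sequence is that of the lexicographically smallest member.
#'
#' @param records Record tibble (`sample_id`, `genus`, `species`,
#'   `residues`); may span several genera, which are collapsed independently.
#' @param min_inversion_len Passed to [pairwise_difference()].
#' @param indel_mode Passed to [pairwise_difference()].
#' @return A tibble with one row per haplotype: `genus`, `haplotype_id`,
#'   `n_members`, `member_sample_ids` (list), `species_set` (list),
#'   `representative`.
#' @export
collapse_haplotypes <- function(records, min_inversion_len = 3L,
                                indel_mode = c("event", "site")) {
  indel_mode <- match.arg(indel_mode)
  if (is.null(records) || nrow(records) == 0) {
    chplex_abort("No records to collapse", "chplex_validation_error")
  }
  validate_records(records)
  out <- lapply(split(records, records$genus), collapse_one_genus,
                min_inversion_len = as.integer(min_inversion_len),
                site_mode = identical(indel_mode, "site"))
  dplyr::bind_rows(out)
}

collapse_one_genus <- function(records, min_inversion_len, site_mode) {
  genus <- records$genus[1]
  seqs <- toupper(records$residues)
  uniq <- unique(seqs)
  useq_of <- match(seqs, uniq)

  if (length(uniq) == 1) {
    comp_of_record <- rep(1L, nrow(records))
  } else {
    units <- cpp_units_matrix(uniq, min_inversion_len, site_mode)
    adj <- (units <= 1L)
    diag(adj) <- FALSE
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    comp_of_record <- igraph::components(g)$membership[useq_of]
  }

  clusters <- split(seq_len(nrow(records)), comp_of_record)
  final <- list()
  for (idx in clusters) {
    final <- c(final, split_diagnostic_species(records[idx, , drop = FALSE]))
  }

  n_members <- vapply(final, nrow, integer(1))
  min_id <- vapply(final, function(d) min(d$sample_id), character(1))
  ord <- order(-n_members, min_id)
  final <- final[ord]
  tibble::new_tibble(list(
    genus = rep(genus, length(final)),
    haplotype_id = paste0("H", seq_along(final)),
    n_members = n_members[ord],
    member_sample_ids = lapply(final, function(d) sort(d$sample_id)),
    species_set = lapply(final, function(d) sort(unique(d$species))),
    representative = vapply(final, function(d) {
      d$residues[order(d$sample_id)[1]]
    }, character(1))
  ), nrow = length(final))
}

# Species-diagnostic exception within one provisional cluster. Returns a
# list of record tibbles (the final clusters derived from this one).
split_diagnostic_species <- function(cluster) {
  species <- unique(cluster$species)
  if (length(species) < 2 || length(unique(cluster$residues)) < 2) {
    return(list(cluster))
  }
  mat <- do.call(rbind, strsplit(toupper(cluster$residues), "", fixed = TRUE))
  # only columns where the cluster varies can carry a diagnostic state
  varying <- which(colSums(mat != mat[rep(1L, nrow(mat)), , drop = FALSE]) > 0)
  split_out <- character(0)
  for (s in species) {
    rows_s <- which(cluster$species == s)
    rows_o <- which(cluster$species != s)
    if (diagnostic_unit_count(mat, rows_s, rows_o, varying) == 1L) {
      split_out <- c(split_out, s)
    }
  }
  if (length(split_out) == 0) {
    return(list(cluster))
  }
  parts <- lapply(split_out, function(s) cluster[cluster$species == s, ,
                                                 drop = FALSE])
  rest <- cluster[!cluster$species %in% split_out, , drop = FALSE]
  if (nrow(rest) > 0) {
    parts <- c(parts, list(rest))
  }
  parts
}

# Number of diagnostic difference units for the records in rows_s against
# rows_o: columns where all rows_s share one unambiguous state that no row
# of rows_o carries. Consecutive diagnostic columns forming a single indel
# run (a gap run in the focal species, or in all other records) are merged
# into one unit, mirroring event-based indel counting. Only `candidates`
# (columns where the cluster varies at all) need inspection.
diagnostic_unit_count <- function(mat, rows_s, rows_o, candidates) {
  state <- character(ncol(mat))
  cols <- integer(0)
  for (j in candidates) {
    col_s <- mat[rows_s, j]
    vs <- col_s[1]
    if (!all(col_s == vs) || !vs %in% c("A", "C", "G", "T", "-")) next
    if (vs %in% mat[rows_o, j]) next
    cols <- c(cols, j)
    state[j] <- vs
  }
  if (length(cols) == 0) {
    return(0L)
  }
  units <- 1L
  for (k in seq_along(cols)[-1]) {
    j_prev <- cols[k - 1]
    j <- cols[k]
    same_run <- (j == j_prev + 1L) &&
      ((state[j] == "-" && state[j_prev] == "-") ||
         (state[j] != "-" && state[j_prev] != "-" &&
            all(mat[rows_o, j] == "-") && all(mat[rows_o, j_prev] == "-")))
    if (!same_run) {
      units <- units + 1L
    }
  }
  units
}

#' Long view of haplotype cluster membership
#'
#' @param clusters Cluster tibble from [collapse_haplotypes()].
#' @return A tibble with one row per (haplotype, member sample): `genus`,
#'   `haplotype_id`, `sample_id`.
#' @export
cluster_members <- function(clusters) {
  tidyr::unnest(
    dplyr::select(clusters, "genus", "haplotype_id",
                  sample_id = "member_sample_ids"),
    "sample_id")
}
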