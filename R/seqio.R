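#' Read aligned per-genus sequences from FASTA
#'
#' Reads an aligned FASTA file whose headers encode sample identity as
#' `sample_id|genus|species` (pipe-delimited, species may contain spaces).
#' Residues are upper-cased on input. Gaps are `-`; IUPAC ambiguity letters
#' are accepted. Sequences must be aligned (equal length) within each genus;
#' no cross-genus alignment is assumed or required.
#'
#' @param path Path to a FASTA file.
#' @param genus Optional genus name. When supplied, every record in the file
#'   must belong to this genus.
#' @return A tibble with one row per record: `sample_id`, `genus`, `species`,
#'   `residues`.
#' @export
read_alignment_fasta <- function(path, genus = NULL) {
  if (!file.exists(path)) {
    chplex_abort(paste0("FASTA file not found: ", path), "chplex_io_error")
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) {
    chplex_abort(paste0("FASTA file contains no records: ", path),
                 "chplex_parse_error")
  }
  headers <- names(set)
  fields <- strsplit(headers, "|", fixed = TRUE)
  bad <- which(vapply(fields, length, integer(1)) != 3L)
  if (length(bad) > 0) {
    chplex_abort(
      paste0("Malformed FASTA header (expected sample_id|genus|species): '",
             headers[bad[1]], "'"),
      "chplex_parse_error")
  }
  records <- tibble::tibble(
    sample_id = vapply(fields, `[[`, character(1), 1L),
    genus = vapply(fields, `[[`, character(1), 2L),
    species = vapply(fields, `[[`, character(1), 3L),
    residues = unname(toupper(as.character(set)))
  )
  if (!is.null(genus)) {
    off <- unique(records$genus[records$genus != genus])
    if (length(off) > 0) {
      chplex_abort(
        paste0("File declared as genus '", genus, "' contains records of: ",
               paste(off, collapse = ", ")),
        "chplex_validation_error")
    }
  }
  validate_records(records)
  records
}

#' Validate a table of aligned sequence records
#'
#' Enforces the record invariants: non-empty residues drawn from the accepted
#' alphabet (bases, `-`, IUPAC ambiguity letters), unique sample ids, and
#' equal alignment length within each genus.
#'
#' @param records A tibble as returned by [read_alignment_fasta()].
#' @return The input, invisibly.
#' @export
validate_records <- function(records) {
  stopifnot(all(c("sample_id", "genus", "species", "residues") %in%
                  names(records)))
  dup <- records$sample_id[duplicated(records$sample_id)]
  if (length(dup) > 0) {
    chplex_abort(paste0("Duplicate sample_id: ",
                        paste(unique(dup), collapse = ", ")),
                 "chplex_validation_error")
  }
  if (any(nchar(records$residues) == 0)) {
    empty <- records$sample_id[nchar(records$residues) == 0]
    chplex_abort(paste0("Empty sequence for sample: ", empty[1]),
                 "chplex_validation_error")
  }
  for (i in seq_len(nrow(records))) {
    chars <- strsplit(records$residues[i], "", fixed = TRUE)[[1]]
    illegal <- which(!chars %in% CHPLEX_ALPHABET)
    if (length(illegal) > 0) {
      chplex_abort(
        paste0("Illegal residue '", chars[illegal[1]], "' at position ",
               illegal[1], " in sample ", records$sample_id[i]),
        "chplex_validation_error")
    }
  }
  lens <- split(nchar(records$residues), records$genus)
  ids <- split(records$sample_id, records$genus)
  for (g in names(lens)) {
    if (length(unique(lens[[g]])) > 1) {
      chplex_abort(
        paste0("Unequal alignment lengths within genus ", g, ": ",
               paste(ids[[g]], " (", lens[[g]], ")", sep = "", collapse = ", ")),
        "chplex_validation_error")
    }
  }
  invisible(records)
}

#' Write aligned sequence records to FASTA
#'
#' Headers are written as `sample_id|genus|species`, matching
#' [read_alignment_fasta()]. Output is byte-stable given identical input.
#'
#' @param records Record tibble (`sample_id`, `genus`, `species`, `residues`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_alignment_fasta <- function(records, path) {
  validate_records(records)
  set <- Biostrings::BStringSet(records$residues)
  names(set) <- paste(records$sample_id, records$genus, records$species,
                      sep = "|")
  Biostrings::writeXStringSet(set, path, width = 10000L)
  invisible(path)
}

#' Read per-sample metadata
#'
#' Expects a tab-separated file with header columns `sample_id`, `genus`,
#' `species`, `dispersal`, `voucher`. The dispersal vocabulary is closed:
#' autochorous, anemochorous, hydrochorous, zoochorous, mixed.
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns `sample_id`, `genus`, `species`,
#'   `dispersal_raw`, `voucher`.
#' @export
read_metadata <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    genus = readr::col_character(),
    species = readr::col_character(),
    dispersal = readr::col_character(),
    voucher = readr::col_logical()
  ))
  bad <- which(!tab$dispersal %in% DISPERSAL_VOCAB)
  if (length(bad) > 0) {
    chplex_abort(
      paste0("Unknown dispersal value '", tab$dispersal[bad[1]],
             "' in metadata row ", bad[1], " (sample ",
             tab$sample_id[bad[1]], ")"),
      "chplex_validation_error")
  }
  dup <- tab$sample_id[duplicated(tab$sample_id)]
  if (length(dup) > 0) {
    chplex_abort(paste0("Duplicate sample_id in metadata: ",
                        paste(unique(dup), collapse = ", ")),
                 "chplex_validation_error")
  }
  dplyr::rename(tab, dispersal_raw = "dispersal")
}

#' Write per-sample metadata
#'
#' @param metadata Tibble as returned by [read_metadata()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(metadata, path) {
  out <- dplyr::rename(metadata, dispersal = "dispersal_raw")
  readr::write_tsv(out, path, quote = "none")
  invisible(path)
}

#' Read the site species inventory
#'
#' Tab-separated table mapping `genus` to `species_count`, the number of
#' species of that genus recorded at the study site (not just the sequenced
#' subset); used to classify species by congener presence.
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns `genus`, `species_count`.
#' @export
read_inventory <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    genus = readr::col_character(),
    species_count = readr::col_integer()
  ))
  bad <- which(is.na(tab$species_count) | tab$species_count < 1)
  if (length(bad) > 0) {
    chplex_abort(
      paste0("Nonpositive or missing species_count for genus ",
             tab$genus[bad[1]]),
      "chplex_validation_error")
  }
  dup <- tab$genus[duplicated(tab$genus)]
  if (length(dup) > 0) {
    chplex_abort(paste0("Duplicate genus in inventory: ",
                        paste(unique(dup), collapse = ", ")),
                 "chplex_validation_error")
  }
  tab
}

#' Write the site species inventory
#'
#' @param inventory Tibble with columns `genus`, `species_count`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_inventory <- function(inventory, path) {
  readr::write_tsv(inventory, path, quote = "none")
  invisible(path)
}

#' Write a haplotype cluster table
#'
#' One row per haplotype with genus-scoped ids (ids restart at H1 in every
#' genus, so designations are consistent within each genus). Member sample
#' ids and member species are comma-joined in sorted order, which makes the
#' output byte-stable and round-trippable via [read_haplotype_table()].
#'
#' @param clusters Cluster tibble from [collapse_haplotypes()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_haplotype_table <- function(clusters, path) {
  if (is.null(clusters) || nrow(clusters) == 0) {
    chplex_abort("Refusing to write an empty haplotype table",
                 "chplex_validation_error")
  }
  out <- tibble::tibble(
    genus = clusters$genus,
    haplotype_id = clusters$haplotype_id,
    n_members = clusters$n_members,
    member_sample_ids = vapply(clusters$member_sample_ids,
                               function(x) paste(sort(x), collapse = ","),
                               character(1)),
    species_set = vapply(clusters$species_set,
                         function(x) paste(sort(x), collapse = ","),
                         character(1)),
    representative = clusters$representative
  )
  readr::write_tsv(out, path, quote = "none")
  invisible(path)
}

#' Read a haplotype cluster table written by [write_haplotype_table()]
#'
#' @param path Path to a TSV file.
#' @return A cluster tibble with list-columns `member_sample_ids` and
#'   `species_set`.
#' @export
read_haplotype_table <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    genus = readr::col_character(),
    haplotype_id = readr::col_character(),
    n_members = readr::col_integer(),
    member_sample_ids = readr::col_character(),
    species_set = readr::col_character(),
    representative = readr::col_character()
  ))
  tab$member_sample_ids <- strsplit(tab$member_sample_ids, ",", fixed = TRUE)
  tab$species_set <- strsplit(tab$species_set, ",", fixed = TRUE)
  tab
}

#' Cross-validate sequences, metadata and inventory
#'
#' Checks the joint consistency required before analysis: every sequenced
#' sample has metadata and vice versa, every genus in the metadata appears in
#' the inventory, and inventory counts are at least the number of distinct
#' sampled species per genus.
#'
#' @param records Sequence record tibble.
#' @param metadata Sample metadata tibble.
#' @param inventory Site inventory tibble.
#' @return Invisibly `TRUE` on success; otherwise an error naming the
#'   offending sample or genus.
#' @export
validate_dataset <- function(records, metadata, inventory) {
  miss_meta <- setdiff(records$sample_id, metadata$sample_id)
  if (length(miss_meta) > 0) {
    chplex_abort(paste0("Sample in FASTA but not in metadata: ",
                        miss_meta[1]), "chplex_validation_error")
  }
  miss_seq <- setdiff(metadata$sample_id, records$sample_id)
  if (length(miss_seq) > 0) {
    chplex_abort(paste0("Sample in metadata but not in FASTA: ",
                        miss_seq[1]), "chplex_validation_error")
  }
  miss_gen <- setdiff(unique(metadata$genus), inventory$genus)
  if (length(miss_gen) > 0) {
    chplex_abort(paste0("Genus missing from site inventory: ",
                        paste(miss_gen, collapse = ", ")),
                 "chplex_validation_error")
  }
  sampled <- dplyr::summarise(dplyr::group_by(metadata, .data$genus),
                              n_sp = dplyr::n_distinct(.data$species))
  joined <- dplyr::inner_join(sampled, inventory, by = "genus")
  short <- joined$genus[joined$species_count < joined$n_sp]
  if (length(short) > 0) {
    chplex_abort(
      paste0("Inventory count below number of sampled species for genus: ",
             paste(short, collapse = ", ")),
      "chplex_validation_error")
  }
  invisible(TRUE)
}
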