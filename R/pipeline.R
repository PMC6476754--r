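#' Run the whole analysis pipeline and write its reports
#'
#' Wires every stage together: read (or accept in-memory) aligned
#' sequences, metadata and inventory; cross-validate them; collapse
#' haplotypes; summarise species; build the polymorphism-by-group
#' contingency reports with Fisher p-values; run both per-genus binomial
#' scans; write sharing and review reports and a run manifest. All outputs
#' are plain TSV/JSON without timestamps, so reruns on identical inputs are
#' byte-identical.
#'
#' @param fasta_dir Directory of per-genus aligned FASTA files (`.fasta`,
#'   `.fa`), or `NULL` when `records` is given.
#' @param metadata_path,inventory_path Paths to the TSV inputs, or `NULL`
#'   when the corresponding tibbles are given.
#' @param out_dir Output directory (created if needed).
#' @param records,metadata,inventory In-memory alternatives to the path
#'   arguments (e.g. from [simulate_community()]).
#' @param min_inversion_len,indel_mode Haplotyping parameters; see
#'   [collapse_haplotypes()].
#' @param min_species_for_scan Genus-size threshold for the binomial scans
#'   (default 8).
#' @param digits Decimals used in the presentation-rounded columns of the
#'   report files (default 3); full-precision columns are always written
#'   alongside.
#' @return Invisibly, a list with the in-memory results (`clusters`,
#'   `summaries`, `contingency`, `sharing`, `scans`, `review`, `paths`).
#' @export
run_pipeline <- function(fasta_dir = NULL, metadata_path = NULL,
                         inventory_path = NULL, out_dir,
                         records = NULL, metadata = NULL, inventory = NULL,
                         min_inversion_len = 3L,
                         indel_mode = c("event", "site"),
                         min_species_for_scan = 8L, digits = 3L) {
  indel_mode <- match.arg(indel_mode)
  if (is.null(records)) {
    if (is.null(fasta_dir)) {
      chplex_abort("Provide either fasta_dir or records",
                   "chplex_validation_error")
    }
    files <- sort(list.files(fasta_dir, pattern = "\\.(fasta|fa)$",
                             full.names = TRUE))
    if (length(files) == 0) {
      chplex_abort(paste0("No FASTA files found under ", fasta_dir),
                   "chplex_io_error")
    }
    records <- dplyr::bind_rows(lapply(files, read_alignment_fasta))
    validate_records(records)
  }
  if (is.null(metadata)) metadata <- read_metadata(metadata_path)
  if (is.null(inventory)) inventory <- read_inventory(inventory_path)
  validate_dataset(records, metadata, inventory)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  message("chplex: collapsing ", nrow(records), " sequences from ",
          dplyr::n_distinct(records$genus), " genera")
  clusters <- collapse_haplotypes(records, min_inversion_len, indel_mode)
  summaries <- summarize_species(clusters, metadata, inventory)
  message("chplex: ", nrow(clusters), " haplotypes across ",
          nrow(summaries), " species")

  strata <- c("abiotic", "biotic", "all")
  contingency <- dplyr::bind_rows(lapply(strata, function(s) {
    tab <- tryCatch(polymorphism_contingency(summaries, s),
                    chplex_error = function(e) NULL)
    if (is.null(tab)) return(NULL)
    p <- fisher_two_sided(tab)$p_two_sided
    tibble::tibble(
      stratum = s,
      group1_polymorphic = tab["group1", "polymorphic"],
      group1_total = sum(tab["group1", ]),
      group2_polymorphic = tab["group2", "polymorphic"],
      group2_total = sum(tab["group2", ]),
      p_value = p,
      p_rounded = round(p, digits)
    )
  }))

  sharing <- sharing_incidences(clusters, summaries)
  sbp <- sharing_by_polymorphism(summaries, sharing)
  sbp_p <- fisher_two_sided(sbp)$p_two_sided
  sharing_report <- tibble::tibble(
    polymorphic_shared = sbp["polymorphic", "shared"],
    polymorphic_private = sbp["polymorphic", "private"],
    monomorphic_shared = sbp["monomorphic", "shared"],
    monomorphic_private = sbp["monomorphic", "private"],
    p_value = sbp_p,
    p_rounded = round(sbp_p, digits)
  )

  poly_scan <- genus_polymorphism_scan(summaries, min_species_for_scan)
  pair_scan <- genus_pair_sharing_scan(sharing, min_species_for_scan)
  review <- review_report(clusters, metadata)

  paths <- list(
    haplotypes = file.path(out_dir, "haplotypes.tsv"),
    species_summary = file.path(out_dir, "species_summary.tsv"),
    contingency = file.path(out_dir, "contingency.tsv"),
    polymorphism_scan = file.path(out_dir, "polymorphism_scan.tsv"),
    pair_sharing_scan = file.path(out_dir, "pair_sharing_scan.tsv"),
    sharing_incidences = file.path(out_dir, "sharing_incidences.tsv"),
    genus_pairs = file.path(out_dir, "genus_pairs.tsv"),
    sharing_report = file.path(out_dir, "sharing_report.tsv"),
    review_report = file.path(out_dir, "review_report.tsv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  write_haplotype_table(clusters, paths$haplotypes)
  readr::write_tsv(summaries, paths$species_summary, quote = "none")
  readr::write_tsv(contingency, paths$contingency, quote = "none")
  write_scan <- function(scan, path) {
    out <- tibble::as_tibble(scan)
    if (nrow(out) > 0) {
      out <- dplyr::mutate(out,
                           p_minus_rounded = round(.data$p_minus, digits),
                           p_plus_rounded = round(.data$p_plus, digits))
    }
    readr::write_tsv(out, path, quote = "none")
  }
  write_scan(poly_scan, paths$polymorphism_scan)
  write_scan(pair_scan, paths$pair_sharing_scan)
  readr::write_tsv(sharing$incidences, paths$sharing_incidences,
                   quote = "none")
  readr::write_tsv(sharing$genus_pairs, paths$genus_pairs, quote = "none")
  readr::write_tsv(sharing_report, paths$sharing_report, quote = "none")
  readr::write_tsv(review, paths$review_report, quote = "none")

  manifest <- list(
    package = "chplex",
    version = as.character(utils::packageVersion("chplex")),
    parameters = list(min_inversion_len = min_inversion_len,
                      indel_mode = indel_mode,
                      min_species_for_scan = min_species_for_scan,
                      digits = digits),
    inputs = list(
      n_sequences = nrow(records),
      n_genera = dplyr::n_distinct(records$genus),
      n_species = dplyr::n_distinct(paste(records$genus, records$species)),
      checksums = input_checksums(fasta_dir, metadata_path, inventory_path)
    ),
    outputs = lapply(paths[names(paths) != "manifest"], function(p) {
      unname(tools::md5sum(p))
    })
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE)

  invisible(list(clusters = clusters, summaries = summaries,
                 contingency = contingency, sharing = sharing,
                 sharing_report = sharing_report,
                 scans = list(polymorphism = poly_scan,
                              pair_sharing = pair_scan),
                 review = review, paths = paths))
}

input_checksums <- function(fasta_dir, metadata_path, inventory_path) {
  files <- character(0)
  if (!is.null(fasta_dir)) {
    files <- c(files, sort(list.files(fasta_dir,
                                      pattern = "\\.(fasta|fa)$",
                                      full.names = TRUE)))
  }
  files <- c(files, metadata_path, inventory_path)
  files <- files[!vapply(files, is.null, logical(1))]
  if (length(files) == 0) {
    return(list(in_memory = TRUE))
  }
  sums <- tools::md5sum(unlist(files))
  as.list(setNames(unname(sums), basename(names(sums))))
}
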