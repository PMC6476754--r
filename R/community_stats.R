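#' Classify a dispersal syndrome as abiotic or biotic
#'
#' Autochorous, anemochorous and hydrochorous syndromes are combined into an
#' abiotic class; zoochorous and mixed syndromes form the biotic class
#' (species with partly biotic dispersal are treated as biotic, so the
#' abiotic class is purely abiotic).
#'
#' @param dispersal_raw Character vector over the closed vocabulary
#'   autochorous, anemochorous, hydrochorous, zoochorous, mixed.
#' @return Character vector of `"abiotic"` / `"biotic"`.
#' @export
classify_dispersal <- function(dispersal_raw) {
  bad <- unique(dispersal_raw[!dispersal_raw %in% DISPERSAL_VOCAB])
  if (length(bad) > 0) {
    chplex_abort(paste0("Unknown dispersal value: ",
                        paste(bad, collapse = ", ")),
                 "chplex_validation_error")
  }
  ifelse(dispersal_raw %in% c("autochorous", "anemochorous", "hydrochorous"),
         "abiotic", "biotic")
}

#' Classify a genus by congener presence at the site
#'
#' Group 1: the genus has a single species recorded at the study site (the
#' species has no local congeners). Group 2: at least two species recorded.
#' Classification uses the full site inventory, not the sequenced subset.
#'
#' @param genus Character vector of genus names.
#' @param inventory Site inventory tibble (`genus`, `species_count`).
#' @return Integer vector of 1s and 2s.
#' @export
classify_group <- function(genus, inventory) {
  idx <- match(genus, inventory$genus)
  if (anyNA(idx)) {
    chplex_abort(paste0("Genus missing from site inventory: ",
                        paste(unique(genus[is.na(idx)]), collapse = ", ")),
                 "chplex_validation_error")
  }
  ifelse(inventory$species_count[idx] == 1L, 1L, 2L)
}

#' Per-species polymorphism summary
#'
#' One row per sequenced species with its number of sequenced individuals,
#' number of distinct haplotypes, polymorphism call, congener group and
#' dispersal class. Species with a single sequenced individual are flagged
#' `excluded` (their polymorphism cannot be assessed) but are kept in the
#' table; their haplotypes still count toward sharing via cluster
#' membership.
#'
#' @param clusters Cluster tibble from [collapse_haplotypes()].
#' @param metadata Sample metadata tibble.
#' @param inventory Site inventory tibble.
#' @return A tibble with columns `genus`, `species`, `n_individuals`,
#'   `n_haplotypes`, `excluded`, `polymorphic` (NA for excluded species),
#'   `group`, `dispersal_class`.
#' @export
summarize_species <- function(clusters, metadata, inventory) {
  members <- cluster_members(clusters)
  miss <- setdiff(members$sample_id, metadata$sample_id)
  if (length(miss) > 0) {
    chplex_abort(paste0("Sample in clusters but not in metadata: ", miss[1]),
                 "chplex_validation_error")
  }
  joined <- dplyr::inner_join(members, metadata, by = "sample_id",
                              suffix = c("", ".meta"))
  disp <- dplyr::distinct(metadata, .data$genus, .data$species,
                          .data$dispersal_raw)
  conflicting <- disp$species[duplicated(paste(disp$genus, disp$species))]
  if (length(conflicting) > 0) {
    chplex_abort(paste0("Conflicting dispersal values within species: ",
                        conflicting[1]), "chplex_validation_error")
  }
  summaries <- joined %>%
    dplyr::group_by(.data$genus, .data$species) %>%
    dplyr::summarise(
      n_individuals = dplyr::n(),
      n_haplotypes = dplyr::n_distinct(.data$haplotype_id),
      .groups = "drop"
    ) %>%
    dplyr::left_join(disp, by = c("genus", "species")) %>%
    dplyr::mutate(
      excluded = .data$n_individuals == 1L,
      polymorphic = ifelse(.data$excluded, NA, .data$n_haplotypes >= 2L),
      group = classify_group(.data$genus, inventory),
      dispersal_class = classify_dispersal(.data$dispersal_raw)
    ) %>%
    dplyr::select(-"dispersal_raw") %>%
    dplyr::arrange(.data$genus, .data$species)
  summaries
}

included_species <- function(summaries) {
  dplyr::filter(summaries, !.data$excluded)
}

#' Polymorphism-by-congener-group contingency table
#'
#' Builds the 2x2 table contrasting polymorphism rates between species with
#' no local congeners (group 1) and species with congeners (group 2), within
#' one dispersal stratum or overall. Species excluded for having a single
#' sequenced individual are dropped first.
#'
#' @param summaries Species summary tibble from [summarize_species()].
#' @param stratum `"abiotic"`, `"biotic"` or `"all"`.
#' @return A 2x2 integer matrix, rows `group1`/`group2`, columns
#'   `polymorphic`/`monomorphic`.
#' @export
polymorphism_contingency <- function(summaries,
                                     stratum = c("all", "abiotic", "biotic")) {
  stratum <- match.arg(stratum)
  inc <- included_species(summaries)
  if (stratum != "all") {
    inc <- dplyr::filter(inc, .data$dispersal_class == stratum)
  }
  if (nrow(inc) == 0) {
    chplex_abort(paste0("No included species in stratum '", stratum, "'"),
                 "chplex_validation_error")
  }
  tab <- matrix(
    c(sum(inc$group == 1L & inc$polymorphic),
      sum(inc$group == 1L & !inc$polymorphic),
      sum(inc$group == 2L & inc$polymorphic),
      sum(inc$group == 2L & !inc$polymorphic)),
    nrow = 2, byrow = TRUE,
    dimnames = list(c("group1", "group2"), c("polymorphic", "monomorphic")))
  storage.mode(tab) <- "integer"
  tab
}

#' Shared/private haplotype incidence accounting
#'
#' Restricts attention to genera with at least two analyzed species (species
#' with >= 2 sequenced individuals), and, for every (species, haplotype)
#' incidence in that universe, records whether the haplotype is shared
#' (present in at least one other congeneric species, including species
#' excluded from polymorphism calls) or private. Also counts, per genus, how
#' many analyzed species pairs share at least one haplotype.
#'
#' @param clusters Cluster tibble from [collapse_haplotypes()].
#' @param summaries Species summary tibble from [summarize_species()].
#' @return A list of class `chplex_sharing` with elements `incidences`
#'   (tibble: `genus`, `species`, `haplotype_id`, `shared`) and
#'   `genus_pairs` (tibble: `genus`, `n_species_analyzed`, `n_pairs`,
#'   `n_pairs_sharing`).
#' @export
sharing_incidences <- function(clusters, summaries) {
  inc_sp <- included_species(summaries)
  universe_genera <- inc_sp %>%
    dplyr::count(.data$genus, name = "n_species_analyzed") %>%
    dplyr::filter(.data$n_species_analyzed >= 2L)

  occ <- clusters %>%
    dplyr::select("genus", "haplotype_id", species = "species_set") %>%
    tidyr::unnest("species")
  n_sp_per_hap <- occ %>%
    dplyr::count(.data$genus, .data$haplotype_id, name = "n_species_in_hap")

  incidences <- occ %>%
    dplyr::semi_join(universe_genera, by = "genus") %>%
    dplyr::semi_join(inc_sp, by = c("genus", "species")) %>%
    dplyr::left_join(n_sp_per_hap, by = c("genus", "haplotype_id")) %>%
    dplyr::mutate(shared = .data$n_species_in_hap >= 2L) %>%
    dplyr::select("genus", "species", "haplotype_id", "shared") %>%
    dplyr::arrange(.data$genus, .data$haplotype_id, .data$species)

  pair_tab <- universe_genera %>%
    dplyr::mutate(n_pairs = choose(.data$n_species_analyzed, 2L))
  sharing_pairs <- occ %>%
    dplyr::semi_join(inc_sp, by = c("genus", "species")) %>%
    dplyr::inner_join(occ %>% dplyr::semi_join(inc_sp,
                                               by = c("genus", "species")),
                      by = c("genus", "haplotype_id"),
                      relationship = "many-to-many") %>%
    dplyr::filter(.data$species.x < .data$species.y) %>%
    dplyr::distinct(.data$genus, .data$species.x, .data$species.y) %>%
    dplyr::count(.data$genus, name = "n_pairs_sharing")
  genus_pairs <- pair_tab %>%
    dplyr::left_join(sharing_pairs, by = "genus") %>%
    dplyr::mutate(n_pairs_sharing = dplyr::coalesce(.data$n_pairs_sharing,
                                                    0L)) %>%
    dplyr::arrange(.data$genus)

  structure(list(incidences = incidences, genus_pairs = genus_pairs),
            class = "chplex_sharing")
}

#' @export
print.chplex_sharing <- function(x, ...) {
  cat("Haplotype sharing summary\n")
  cat("  incidences:", nrow(x$incidences),
      sprintf("(%d shared, %d private)\n", sum(x$incidences$shared),
              sum(!x$incidences$shared)))
  cat("  genera in universe:", nrow(x$genus_pairs), "\n")
  cat("  species pairs:", sum(x$genus_pairs$n_pairs), "of which sharing:",
      sum(x$genus_pairs$n_pairs_sharing), "\n")
  invisible(x)
}

#' Sharing-by-polymorphism contingency table
#'
#' Cross-tabulates (species, haplotype) incidences by the polymorphism
#' status of the species carrying them: rows polymorphic/monomorphic
#' species, columns shared/private incidences. Under introgression, shared
#' incidences concentrate in polymorphic species; under retention of
#' ancestral variants alone they should not.
#'
#' @param summaries Species summary tibble from [summarize_species()].
#' @param sharing `chplex_sharing` object from [sharing_incidences()].
#' @return A 2x2 integer matrix, rows `polymorphic`/`monomorphic`, columns
#'   `shared`/`private`.
#' @export
sharing_by_polymorphism <- function(summaries, sharing) {
  inc <- dplyr::inner_join(
    sharing$incidences,
    dplyr::select(included_species(summaries), "genus", "species",
                  "polymorphic"),
    by = c("genus", "species"))
  tab <- matrix(
    c(sum(inc$polymorphic & inc$shared),
      sum(inc$polymorphic & !inc$shared),
      sum(!inc$polymorphic & inc$shared),
      sum(!inc$polymorphic & !inc$shared)),
    nrow = 2, byrow = TRUE,
    dimnames = list(c("polymorphic", "monomorphic"),
                    c("shared", "private")))
  storage.mode(tab) <- "integer"
  tab
}

#' Samples flagged for identification review
#'
#' Advisory report listing every sample whose haplotype is shared across
#' species of the same genus; in a real survey these are the vouchers whose
#' sequences and botanical identifications deserve rechecking, since
#' misidentification mimics introgression. Ordering is deterministic
#' (genus, haplotype id, sample id).
#'
#' @param clusters Cluster tibble from [collapse_haplotypes()].
#' @param metadata Sample metadata tibble.
#' @return A tibble: `genus`, `haplotype_id`, `sample_id`, `species`,
#'   `n_species_sharing`.
#' @export
review_report <- function(clusters, metadata) {
  multi <- clusters %>%
    dplyr::mutate(n_species_sharing = vapply(.data$species_set, length,
                                             integer(1))) %>%
    dplyr::filter(.data$n_species_sharing >= 2L)
  if (nrow(multi) == 0) {
    return(tibble::tibble(genus = character(), haplotype_id = character(),
                          sample_id = character(), species = character(),
                          n_species_sharing = integer()))
  }
  cluster_members(multi) %>%
    dplyr::left_join(dplyr::select(multi, "genus", "haplotype_id",
                                   "n_species_sharing"),
                     by = c("genus", "haplotype_id")) %>%
    dplyr::left_join(dplyr::select(metadata, "sample_id", "species"),
                     by = "sample_id") %>%
    dplyr::arrange(.data$genus, .data$haplotype_id, .data$sample_id) %>%
    dplyr::select("genus", "haplotype_id", "sample_id", "species",
                  "n_species_sharing")
}
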